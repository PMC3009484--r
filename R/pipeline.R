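## Config-driven pipeline entry points; the shell scripts under
## inst/scripts/ are thin wrappers over these three functions.

resolveConfig <- function(config, defaults) {
  out <- utils::modifyList(defaults, config)
  ## a user-supplied library list replaces the default set wholesale
  if (!is.null(config$libraries)) out$libraries <- config$libraries
  out
}

writeResolvedConfig <- function(config, dir, name) {
  yaml::write_yaml(config, file.path(dir, name))
}

#' Run a full simulation from a config list
#'
#' Generates a synthetic community and one or more read libraries, writing
#' genomes (FASTA), gene annotation (GFF3-like), reads (FASTQ for paired
#' Illumina, FASTA for 454-style), a truth manifest (TSV), a per-library
#' stats block (JSON; reads, bases, insertion / deletion / substitution
#' counts and percentages) and the fully resolved config (YAML) to
#' \code{outDir}.
#'
#' Config keys (all optional unless noted): \code{seed};
#' \code{community}: \code{n_taxa}, \code{complexity}, \code{dominance_ratio},
#' \code{genome_length}; \code{libraries}: a named list, each entry with
#' \code{type} ("illumina" or "454"), \code{n_clones}, and for illumina
#' \code{mu}, \code{sigma}, \code{read_length}, for 454 \code{mu},
#' \code{sigma}, \code{flow_cycles}.
#'
#' @param config Nested list, typically \code{yaml::read_yaml()} output.
#' @param outDir Output directory.
#' @return Invisibly, a list with the community, per-library results and
#'   stats.
#' @export
runSimulate <- function(config, outDir) {
  config <- resolveConfig(config, list(
    seed = 1L,
    community = list(n_taxa = 104L, complexity = "HC",
                     dominance_ratio = NULL, genome_length = 20000L),
    libraries = list(
      short = list(type = "illumina", mu = 200, sigma = 20,
                   read_length = 75L, n_clones = 10000L),
      long = list(type = "illumina", mu = 1900, sigma = 300,
                  read_length = 75L, n_clones = 10000L))))
  cc <- config$community
  if (!cc$complexity %in% c("LC", "MC", "HC"))
    stop("config error: community complexity must be LC, MC or HC")
  for (lib in config$libraries)
    if (!lib$type %in% c("illumina", "454"))
      stop("config error: library type must be 'illumina' or '454'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  community <- makeSyntheticCommunity(
    cc$n_taxa, cc$complexity, dominanceRatio = cc$dominance_ratio,
    genomeLength = cc$genome_length, seed = config$seed)
  writeCommunity(community, outDir)
  out <- list(community = community, libraries = list())
  libSeed <- 0L
  for (nm in names(config$libraries)) {
    lib <- config$libraries[[nm]]
    libSeed <- libSeed + 1L
    if (lib$type == "illumina") {
      spec <- cloneLibrarySpec(lib$mu, lib$sigma,
                               readLength = lib$read_length %||% 75L)
      clones <- sampleClones(community, spec, lib$n_clones,
                             seed = subSeed(config$seed, libSeed))
      sim <- sequenceIlluminaPairs(community, clones,
                                   readLength = spec@readLength,
                                   seed = subSeed(config$seed,
                                                  libSeed + 100L))
      half <- lib$n_clones
      writeReads(sim$reads[seq_len(half)],
                 file.path(outDir, paste0(nm, "_1.fastq")))
      writeReads(sim$reads[half + seq_len(half)],
                 file.path(outDir, paste0(nm, "_2.fastq")))
    } else {
      spec <- cloneLibrarySpec(lib$mu %||% 400, lib$sigma %||% 30,
                               readLength = 250L, paired = FALSE)
      clones <- sampleClones(community, spec, lib$n_clones,
                             seed = subSeed(config$seed, libSeed))
      sim <- sequence454Reads(
        community, clones,
        flowSpec = flow454Spec(lib$flow_cycles %||% 98L),
        seed = subSeed(config$seed, libSeed + 100L))
      writeReads(sim$reads, file.path(outDir, paste0(nm, ".fasta")),
                 format = "fasta")
    }
    writeTsv(sim$truth, file.path(outDir, paste0(nm, "_truth.tsv")))
    jsonlite::write_json(sim$stats,
                         file.path(outDir, paste0(nm, "_stats.json")),
                         auto_unbox = TRUE, digits = NA)
    out$libraries[[nm]] <- sim
  }
  writeResolvedConfig(config, outDir, "simulate_config.yaml")
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the assignment pipeline from files
#'
#' Reads a match table (BLAST tabular with a 13th taxon column) and a
#' taxonomy, runs the single-read or paired pipeline, and writes the
#' per-read assignment TSV (\code{query_id}, \code{taxon_id},
#' \code{status}), the per-taxon count TSV (before and after min
#' support), the filter-stage tallies (JSON) and the resolved config.
#'
#' @param matchFile BLAST tabular path.
#' @param taxonomyFile Taxonomy path (see [readTaxonomy()]).
#' @param outDir Output directory.
#' @param paired Run in paired mode.
#' @param params An [AssignmentParams].
#' @param pairParams A [CombinedScoreParams] (paired mode).
#' @param queryIds Optional full read universe.
#' @return The [AssignmentResult], invisibly.
#' @export
runAssign <- function(matchFile, taxonomyFile, outDir, paired = FALSE,
                      params = assignmentParams(),
                      pairParams = combinedScoreParams(),
                      queryIds = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  taxonomy <- readTaxonomy(taxonomyFile)
  mt <- readBlastTab(matchFile)
  result <- if (paired)
    assignReadsPaired(taxonomy, mt, params, pairParams,
                      queryIds = queryIds)
  else assignReads(taxonomy, mt, params, queryIds = queryIds)
  writeTsv(assignments(result), file.path(outDir, "assignments.tsv"))
  counts <- merge(assignedCountsBefore(result), assignedCounts(result),
                  by = "taxon_id", all = TRUE,
                  suffixes = c("_before_support", "_after_support"))
  counts[is.na(counts)] <- 0L
  writeTsv(counts, file.path(outDir, "taxon_counts.tsv"))
  jsonlite::write_json(assignmentTallies(result),
                       file.path(outDir, "tallies.json"),
                       auto_unbox = TRUE, digits = NA)
  writeResolvedConfig(list(
    paired = paired, min_score = params@minScore,
    top_percent = params@topPercent, min_support = params@minSupport,
    excluded_clades = as.list(params@excludedClades),
    k = pairParams@k, gap_size = pairParams@g, h = pairParams@h),
    outDir, "assign_config.yaml")
  invisible(result)
}

#' Evaluate assignments against a truth manifest
#'
#' Writes the species-detection report, the per-rank histogram, the
#' correct-assignment percentages and (optionally) a min-support sweep,
#' all as TSV/JSON under \code{outDir}. Exit status is success even when
#' FP/FN are non-zero; mismatched read ids raise an integrity error.
#'
#' @param result An [AssignmentResult] (e.g. from [runAssign()]).
#' @param truth Truth manifest data.frame or TSV path.
#' @param taxonomy A [Taxonomy] or taxonomy file path.
#' @param outDir Output directory.
#' @param sweep Optional integer vector of min-support values.
#' @param normalizeTo Optional histogram normalisation total.
#' @return Invisibly, a list of the computed reports.
#' @export
runEvaluate <- function(result, truth, taxonomy, outDir, sweep = NULL,
                        normalizeTo = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(truth)) truth <- readTsv(truth)
  if (is.character(taxonomy)) taxonomy <- readTaxonomy(taxonomy)
  truthSpecies <- unique(truth$taxon_id)
  det <- speciesDetection(result, truthSpecies, taxonomy)
  hist <- rankHistogram(result, taxonomy, normalizeTo = normalizeTo)
  rates <- correctAssignmentRate(result, truth, taxonomy)
  reports <- list(detection = det, rank_histogram = hist,
                  correct_assignment = rates)
  writeTsv(hist, file.path(outDir, "rank_histogram.tsv"))
  jsonlite::write_json(
    list(false_positives = det$falsePositives,
         false_negatives = det$falseNegatives,
         fp_rate = det$fpRate, fn_rate = det$fnRate,
         correct_pct = rates$correctPct, false_pct = rates$falsePct,
         ancestor_credit_pct = rates$ancestorCreditPct),
    file.path(outDir, "detection.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(sweep)) {
    sw <- minSupportSweep(result, truthSpecies, taxonomy, sweep)
    writeTsv(sw, file.path(outDir, "min_support_sweep.tsv"))
    reports$sweep <- sw
  }
  invisible(reports)
}
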