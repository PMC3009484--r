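## Synthetic match tables: a BLAST-free stand-in that turns simulated
## reads into homology matches using a gene-conservation model, so the
## binning and paired modules are testable end to end.

#' Gene-conservation model for synthetic match tables
#'
#' Each gene is assigned a conservation level drawn from
#' \code{sharingProbs}: a gene conserved at, say, the genus level has
#' homologs in every community species inside the source species' genus.
#' Matches to homologs decay geometrically with the taxonomy path distance
#' between source and target species and receive Gaussian jitter.
#'
#' @param sharingProbs Named numeric vector of probabilities over
#'   conservation levels; names are major ranks (\code{"species"} =
#'   species-specific) and must sum to 1.
#' @param bitsPerBase Score of a perfect source match per overlapping base
#'   (default 0.67 bits/bp, i.e. about 50 bits for a fully overlapping
#'   75 bp read, typical of translated searches).
#' @param decayPerStep Multiplicative score decay per taxonomy edge
#'   between source and homolog species (default 0.9).
#' @param jitterSd Gaussian score jitter in bits (default 1.5).
#' @return A list of class parameters consumed by [simulateMatchTable()].
#' @export
conservationModel <- function(sharingProbs = c(species = 0.5, genus = 0.3,
                                               family = 0.2),
                              bitsPerBase = 0.67, decayPerStep = 0.9,
                              jitterSd = 1.5) {
  if (abs(sum(sharingProbs) - 1) > 1e-8)
    stop("sharingProbs must sum to 1")
  if (!all(names(sharingProbs) %in% MAJOR_RANKS))
    stop("sharingProbs must be named by major ranks")
  list(sharingProbs = sharingProbs, bitsPerBase = bitsPerBase,
       decayPerStep = decayPerStep, jitterSd = jitterSd)
}

## Ancestor of `taxon` at `rank`, or NA when the lineage lacks that rank.
ancestorAtRank <- function(taxonomy, taxon, rank) {
  path <- ancestorPath(taxonomy, taxon)
  ranks <- taxonRank(taxonomy, path)
  hit <- path[ranks == rank]
  if (length(hit)) hit[1] else NA_integer_
}

## Path distance between two taxa (edges via their LCA).
taxonDistance <- function(taxonomy, a, b) {
  anc <- lca(taxonomy, c(a, b))
  d <- taxonDepth(taxonomy, c(a, b, anc))
  unname(d[1] + d[2] - 2L * d[3])
}

#' Simulate a match table from read truth
#'
#' Every read that overlaps a gene by at least \code{minOverlap} bp emits
#' one match to its source taxon (the highest-scoring hit, score
#' proportional to the overlap) and one decayed, jittered match to every
#' other community species sharing that gene under the conservation
#' model. Reads overlapping no gene emit nothing. Deterministic under a
#' fixed seed.
#'
#' @param community A [SyntheticCommunity].
#' @param truth Read truth data.frame (needs \code{read_id},
#'   \code{taxon_id}, \code{genome}, \code{start}, \code{end}).
#' @param model A [conservationModel()].
#' @param minOverlap Minimum read-gene overlap in bp (default 50).
#' @param minScore Matches falling below this many bits after decay and
#'   jitter are not emitted (default 2).
#' @param seed Optional integer seed.
#' @return A [MatchTable]; subject ids encode gene and target taxon as
#'   \code{<gene_id>|<taxon_id>}.
#' @export
simulateMatchTable <- function(community, truth,
                               model = conservationModel(),
                               minOverlap = 50, minScore = 2, seed = NULL) {
  withSeed(seed, {
    taxonomy <- community@taxonomy
    genes <- community@genes
    species <- sort(community@profile$taxon_id)
    ## conservation level and homolog set per gene
    levels <- sample(names(model$sharingProbs), length(genes),
                     replace = TRUE, prob = model$sharingProbs)
    geneIds <- genes$gene_id
    sharers <- lapply(seq_along(genes), function(i) {
      src <- genes$taxon_id[i]
      if (levels[i] == "species") return(src)
      cladeRoot <- ancestorAtRank(taxonomy, src, levels[i])
      if (is.na(cladeRoot)) return(src)
      intersect(subtreeTaxa(taxonomy, cladeRoot), species)
    })
    reads <- GenomicRanges::GRanges(
      seqnames = truth$genome,
      ranges = IRanges::IRanges(truth$start, truth$end))
    hits <- GenomicRanges::findOverlaps(reads, genes,
                                        minoverlap = minOverlap)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(reads)[qh], IRanges::ranges(genes)[sh]))
    ## distance cache: source species x target species
    distCache <- new.env(parent = emptyenv())
    getDist <- function(a, b) {
      key <- paste0(a, "_", b)
      d <- distCache[[key]]
      if (is.null(d)) {
        d <- taxonDistance(taxonomy, a, b)
        distCache[[key]] <- d
      }
      d
    }
    rows <- vector("list", length(qh))
    for (j in seq_along(qh)) {
      i <- sh[j]
      src <- truth$taxon_id[qh[j]]
      base <- model$bitsPerBase * ov[j]
      targets <- sharers[[i]]
      if (!(src %in% targets)) targets <- c(src, targets)
      decay <- vapply(targets, function(t)
        if (t == src) 1 else model$decayPerStep ^ getDist(src, t),
        numeric(1))
      score <- base * decay + stats::rnorm(length(targets), 0,
                                           model$jitterSd)
      ## the source keeps the top score by construction
      score[targets == src] <- base
      score[targets != src] <- pmin(score[targets != src], base - 0.1)
      keep <- score >= minScore
      if (!any(keep)) next
      rows[[j]] <- data.frame(
        query_id = truth$read_id[qh[j]],
        subject_id = paste0(geneIds[i], "|", targets[keep]),
        bit_score = round(score[keep], 1),
        taxon_id = targets[keep],
        subject_length = round(IRanges::width(genes)[i] / 3),
        query_length = truth$end[qh[j]] - truth$start[qh[j]] + 1L,
        stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
      return(MatchTable(data.frame(query_id = character(),
                                   subject_id = character(),
                                   bit_score = numeric(),
                                   taxon_id = integer()), 0L))
    MatchTable(do.call(rbind, rows), 0L)
  })
}

#' Write a match table as 13-column BLAST-style tabular text
#'
#' Columns 3-11 (identity, alignment length, mismatches, gaps,
#' coordinates, e-value) are filled with placeholder values; column 12 is
#' the bit score and column 13 the taxon id, the fields the assignment
#' pipeline consumes.
#'
#' @param matchTable A [MatchTable].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBlastTab <- function(matchTable, path) {
  m <- matches(matchTable)
  lines <- sprintf("%s\t%s\t100.0\t%d\t0\t0\t1\t%d\t1\t%d\t1e-10\t%.1f\t%d",
                   m$query_id, m$subject_id,
                   as.integer(ifelse(is.na(m$query_length), 75,
                                     m$query_length)),
                   as.integer(ifelse(is.na(m$query_length), 75,
                                     m$query_length)),
                   as.integer(ifelse(is.na(m$subject_length), 300,
                                     m$subject_length)),
                   m$bit_score, m$taxon_id)
  writeLines(lines, path)
  invisible(path)
}
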