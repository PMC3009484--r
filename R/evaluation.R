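## Evaluation statistics: species detection FP/FN, rank histograms,
## same-gene co-hit fraction, correct-assignment rates, min-support
## sweeps.

#' Species-level detection: false positives and false negatives
#'
#' A species counts as detected iff at least one read remains assigned to
#' its node after the min support filter. False positives are detected
#' species absent from the truth; false negatives are truth species that
#' went undetected.
#'
#' @param result An [AssignmentResult] (min support applied).
#' @param truthSpecies Integer vector of species taxon ids truly present.
#' @param taxonomy A [Taxonomy].
#' @return A list: \code{detected}, \code{falsePositives},
#'   \code{falseNegatives} (integer vectors), \code{fpRate} and
#'   \code{fnRate} (fractions of the truth-species count).
#' @export
speciesDetection <- function(result, truthSpecies, taxonomy) {
  counts <- assignedCounts(result)
  spp <- speciesIds(taxonomy)
  detected <- counts$taxon_id[counts$count >= 1L &
                                counts$taxon_id %in% spp]
  truthSpecies <- unique(as.integer(truthSpecies))
  fp <- setdiff(detected, truthSpecies)
  fn <- setdiff(truthSpecies, detected)
  list(detected = sort(detected), falsePositives = sort(fp),
       falseNegatives = sort(fn),
       fpRate = length(fp) / length(truthSpecies),
       fnRate = length(fn) / length(truthSpecies))
}

#' Per-rank assignment histogram
#'
#' Counts, for each major rank from superkingdom down to species, the
#' reads assigned to a node of that rank; unranked nodes are mapped to the
#' nearest ranked ancestor first, and reads landing on the root (or on no
#' ranked node) go to an \code{above_superkingdom} bucket. Unassigned and
#' no-hit reads are reported alongside. Counts can be normalised to a
#' fixed total for display.
#'
#' @param result An [AssignmentResult].
#' @param taxonomy A [Taxonomy].
#' @param normalizeTo Optional total (e.g. 100000) to scale all buckets
#'   to; raw counts when NULL.
#' @return data.frame with columns \code{bucket} and \code{count}.
#' @export
rankHistogram <- function(result, taxonomy, normalizeTo = NULL) {
  a <- assignments(result)
  buckets <- c("above_superkingdom", MAJOR_RANKS, "unassigned", "no_hits")
  counts <- stats::setNames(numeric(length(buckets)), buckets)
  assigned <- a[a$status == "assigned", , drop = FALSE]
  if (nrow(assigned)) {
    node <- nearestRankedAncestor(taxonomy, assigned$taxon_id)
    rk <- taxonRank(taxonomy, node)
    rk[node == rootId(taxonomy) & rk == "no-rank"] <- "above_superkingdom"
    tb <- table(rk)
    counts[names(tb)] <- as.numeric(tb)
  }
  counts["unassigned"] <- sum(a$status == "unassigned")
  counts["no_hits"] <- sum(a$status == "no_hits")
  if (!is.null(normalizeTo) && sum(counts) > 0)
    counts <- counts * normalizeTo / sum(counts)
  data.frame(bucket = buckets, count = unname(counts),
             stringsAsFactors = FALSE)
}

#' Same-gene co-hit fraction of a paired library
#'
#' Among clone pairs in which each mate overlaps some gene by at least
#' \code{overlapThreshold} bp, the fraction of pairs whose two mates
#' overlap one common gene. This geometric statistic is what separates
#' short clones (both mates usually in the same gene) from long clones
#' (mates usually in different genes).
#'
#' @param truth Paired read truth from [sequenceIlluminaPairs()] (needs
#'   \code{pair_id}, \code{mate}, \code{genome}, \code{start},
#'   \code{end}).
#' @param genes Gene [GenomicRanges::GRanges] (e.g.
#'   [communityGenes()]).
#' @param overlapThreshold Minimum overlap in bp (default 50).
#' @return A list: \code{fraction}, \code{nBothInGenes} (pairs where both
#'   mates hit genes), \code{nSameGene}, \code{nPairs}.
#' @export
sameGeneFraction <- function(truth, genes, overlapThreshold = 50) {
  if (is.null(truth$pair_id) || is.null(truth$mate))
    stop("configuration error: truth lacks pair annotations")
  reads <- GenomicRanges::GRanges(
    seqnames = truth$genome,
    ranges = IRanges::IRanges(truth$start, truth$end))
  hits <- GenomicRanges::findOverlaps(reads, genes,
                                      minoverlap = overlapThreshold)
  geneSets <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  idx <- as.integer(names(geneSets))
  key <- paste0(truth$pair_id[idx], "_", truth$mate[idx])
  byMate <- stats::setNames(geneSets, key)
  pairs <- unique(truth$pair_id)
  g1 <- byMate[paste0(pairs, "_1")]
  g2 <- byMate[paste0(pairs, "_2")]
  both <- !vapply(g1, is.null, logical(1)) & !vapply(g2, is.null, logical(1))
  same <- vapply(which(both), function(i)
    length(intersect(g1[[i]], g2[[i]])) > 0, logical(1))
  list(fraction = if (any(both)) mean(same) else NA_real_,
       nBothInGenes = sum(both), nSameGene = sum(same),
       nPairs = length(pairs))
}

#' Percentage of correctly assigned reads at a rank
#'
#' A read is correctly assigned at the species level when its assigned
#' node is exactly the truth source species (truth taxa are first mapped
#' to their ancestor-or-self at the chosen rank). Also reported: the
#' percentage assigned at that rank but to the wrong node (falsely
#' assigned), and the percentage whose assignment is an ancestor-or-self
#' of the truth node (ancestor credit).
#'
#' @param result An [AssignmentResult].
#' @param truth Read truth data.frame (\code{read_id} or \code{pair_id}
#'   matching the result's query ids, and \code{taxon_id}).
#' @param taxonomy A [Taxonomy].
#' @param rank Evaluation rank (default "species").
#' @return A list: \code{correctPct}, \code{falsePct},
#'   \code{ancestorCreditPct}, \code{n}.
#' @export
correctAssignmentRate <- function(result, truth, taxonomy,
                                  rank = "species") {
  a <- assignments(result)
  idCol <- if (all(a$query_id %in% truth$read_id)) "read_id" else "pair_id"
  truthTax <- truth$taxon_id[match(a$query_id, truth[[idCol]])]
  if (anyNA(truthTax))
    stop("integrity error: query ids missing from truth, e.g. ",
         paste(utils::head(a$query_id[is.na(truthTax)], 3), collapse = ", "))
  uniqueTruth <- unique(truthTax)
  atRank <- stats::setNames(vapply(uniqueTruth, function(t)
    ancestorAtRank(taxonomy, t, rank), integer(1)),
    as.character(uniqueTruth))
  truthNode <- atRank[as.character(truthTax)]
  assigned <- a$status == "assigned"
  assignedRank <- rep(NA_character_, nrow(a))
  assignedRank[assigned] <- taxonRank(taxonomy, a$taxon_id[assigned])
  correct <- assigned & !is.na(truthNode) & a$taxon_id == truthNode
  correct[is.na(correct)] <- FALSE
  false <- assigned & assignedRank == rank & !correct
  false[is.na(false)] <- FALSE
  ancestor <- rep(FALSE, nrow(a))
  for (i in which(assigned & !is.na(truthNode)))
    ancestor[i] <- isInClade(taxonomy, truthNode[i], a$taxon_id[i])
  n <- nrow(a)
  list(correctPct = 100 * sum(correct) / n,
       falsePct = 100 * sum(false) / n,
       ancestorCreditPct = 100 * sum(ancestor) / n,
       n = n)
}

#' Min-support sweep of detection errors
#'
#' Re-applies the min support filter at each value (without re-running
#' assignment) and reports species-level false positive and false
#' negative counts. FP counts are non-increasing and FN counts
#' non-decreasing in the threshold - the usual trade-off.
#'
#' @param result An [AssignmentResult] before (or at minSupport = 1 of)
#'   the support filter.
#' @param truthSpecies Integer vector of truth species ids.
#' @param taxonomy A [Taxonomy].
#' @param values Integer thresholds to sweep.
#' @return data.frame with columns \code{min_support}, \code{n_fp},
#'   \code{n_fn}.
#' @export
minSupportSweep <- function(result, truthSpecies, taxonomy, values) {
  if (!length(values)) stop("argument error: empty sweep")
  rows <- lapply(sort(as.integer(values)), function(v) {
    r <- applyMinSupport(result, v, taxonomy = taxonomy)
    d <- speciesDetection(r, truthSpecies, taxonomy)
    data.frame(min_support = v, n_fp = length(d$falsePositives),
               n_fn = length(d$falseNegatives))
  })
  do.call(rbind, rows)
}
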