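## The LCA gene-content assignment pipeline: min score, top percent, LCA,
## min support, clade exclusion.

#' Construct assignment parameters
#'
#' @param minScore Absolute bit-score floor; a match is kept when its score
#'   is at least this value (default 35 bits).
#' @param topPercent Per-read relative filter; a match is kept when its
#'   score is at least \code{(1 - topPercent/100)} times the read's best
#'   score (default 10).
#' @param minSupport Minimum number of reads a taxon needs to stay in the
#'   reported result (inclusive; default 1 = off).
#' @param excludedClades Integer vector of clade-root taxon ids whose whole
#'   clades are ignored before any score filter.
#' @param promoteToParent If TRUE, reads on taxa failing min support move
#'   to the parent node instead of becoming unassigned.
#' @param cladeSummedSupport If TRUE, min support tests the clade-summed
#'   count instead of the direct count.
#' @return An [AssignmentParams] object.
#' @examples
#' assignmentParams()                        # single-read defaults
#' assignmentParams(minScore = 50, minSupport = 50)  # paired-mode settings
#' @export
assignmentParams <- function(minScore = 35, topPercent = 10,
                             minSupport = 1L, excludedClades = integer(),
                             promoteToParent = FALSE,
                             cladeSummedSupport = FALSE) {
  new("AssignmentParams", minScore = minScore, topPercent = topPercent,
      minSupport = as.integer(minSupport),
      excludedClades = as.integer(excludedClades),
      promoteToParent = promoteToParent,
      cladeSummedSupport = cladeSummedSupport)
}

setMethod("show", "AssignmentParams", function(object) {
  cat("AssignmentParams: min score", object@minScore,
      "| top percent", object@topPercent,
      "| min support", object@minSupport, "\n")
  if (length(object@excludedClades))
    cat("  excluded clades:",
        paste(object@excludedClades, collapse = ", "), "\n")
})

#' The min score filter
#'
#' @param df data.frame of matches.
#' @param minScore Bit-score floor (kept iff \code{bit_score >= minScore}).
#' @return Filtered data.frame.
#' @export
filterMinScore <- function(df, minScore) {
  df[df$bit_score >= minScore, , drop = FALSE]
}

#' The top percent filter
#'
#' Keeps, among the matches of one read, those scoring within
#' \code{topPercent} percent of the read's best score.
#'
#' @param df data.frame of matches sharing one query.
#' @param topPercent Percentage in [0, 100].
#' @return Filtered data.frame.
#' @export
filterTopPercent <- function(df, topPercent) {
  if (nrow(df) <= 1L) return(df)
  thr <- (1 - topPercent / 100) * max(df$bit_score)
  df[df$bit_score >= thr, , drop = FALSE]
}

## Expand clade roots into the full excluded taxon set once per run.
expandExcluded <- function(taxonomy, excludedClades) {
  if (!length(excludedClades)) return(integer())
  subtreeTaxa(taxonomy, excludedClades)
}

#' Assign one read by the LCA gene-content rule
#'
#' Pipeline: drop matches to excluded clades, apply the min score filter,
#' apply the top percent filter, then place the read on the LCA of the
#' surviving taxa. A read with no matches at all is \code{NO_HITS}; a read
#' whose matches all fail the filters is \code{UNASSIGNED}.
#'
#' @param taxonomy A [Taxonomy].
#' @param df data.frame of the read's matches, already reduced by
#'   [bestPerTaxon()].
#' @param params An [AssignmentParams].
#' @param excludedSet Optional precomputed expansion of
#'   \code{params@excludedClades} (see [subtreeTaxa()]); computed on the
#'   fly when missing.
#' @return A list with \code{taxon_id} (NA unless assigned) and
#'   \code{status} ("assigned", "unassigned" or "no_hits").
#' @export
assignRead <- function(taxonomy, df, params = assignmentParams(),
                       excludedSet = NULL) {
  if (is.null(df) || nrow(df) == 0L)
    return(list(taxon_id = NA_integer_, status = "no_hits"))
  if (is.null(excludedSet))
    excludedSet <- expandExcluded(taxonomy, params@excludedClades)
  if (length(excludedSet))
    df <- df[!(df$taxon_id %in% excludedSet), , drop = FALSE]
  df <- filterMinScore(df, params@minScore)
  df <- filterTopPercent(df, params@topPercent)
  if (nrow(df) == 0L)
    return(list(taxon_id = NA_integer_, status = "unassigned"))
  list(taxon_id = lca(taxonomy, df$taxon_id), status = "assigned")
}

## Assemble an AssignmentResult from a per-query assignment data.frame.
buildResult <- function(assignments, minSupportApplied = FALSE,
                        extraTallies = list()) {
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  tab <- table(assigned$taxon_id)
  counts <- data.frame(taxon_id = as.integer(names(tab)),
                       count = as.integer(tab))
  tallies <- c(list(
    queries = nrow(assignments),
    assigned = sum(assignments$status == "assigned"),
    unassigned = sum(assignments$status == "unassigned"),
    no_hits = sum(assignments$status == "no_hits")), extraTallies)
  new("AssignmentResult", assignments = assignments,
      countsBefore = counts, countsAfter = counts, tallies = tallies)
}

#' Assign every read of a match table
#'
#' Runs [assignRead()] over all queries and applies the min support filter.
#' Queries listed in \code{queryIds} but absent from the table are counted
#' as \code{NO_HITS}, so the conservation identity
#' \code{assigned + unassigned + no_hits == length(queryIds)} always holds.
#'
#' @param taxonomy A [Taxonomy].
#' @param matchTable A [MatchTable].
#' @param params An [AssignmentParams].
#' @param queryIds Optional character vector: the full read universe
#'   (defaults to the queries present in the table).
#' @return An [AssignmentResult] (min support already applied; the
#'   pre-support counts are kept in \code{countsBefore}).
#' @export
assignReads <- function(taxonomy, matchTable, params = assignmentParams(),
                        queryIds = NULL) {
  m <- matches(matchTable)
  if (is.null(queryIds)) queryIds <- unique(m$query_id)
  excludedSet <- expandExcluded(taxonomy, params@excludedClades)
  groups <- split(seq_len(nrow(m)), m$query_id)
  taxon <- rep(NA_integer_, length(queryIds))
  status <- rep("no_hits", length(queryIds))
  names(taxon) <- names(status) <- queryIds
  for (q in intersect(queryIds, names(groups))) {
    df <- bestPerTaxon(m[groups[[q]], , drop = FALSE])
    a <- assignRead(taxonomy, df, params, excludedSet)
    taxon[q] <- a$taxon_id
    status[q] <- a$status
  }
  assignments <- data.frame(query_id = queryIds, taxon_id = unname(taxon),
                            status = unname(status),
                            stringsAsFactors = FALSE)
  res <- buildResult(assignments)
  applyMinSupport(res, params@minSupport, taxonomy = taxonomy,
                  promoteToParent = params@promoteToParent,
                  cladeSummed = params@cladeSummedSupport)
}

#' Apply (or re-apply) the min support filter
#'
#' Every taxon whose read count falls below \code{minSupport} is removed
#' from the reported result; its reads become \code{UNASSIGNED} (or move to
#' the parent node when \code{promoteToParent}). Re-applicable at any
#' threshold without re-running assignment, which is what the min-support
#' sweep does.
#'
#' @param result An [AssignmentResult].
#' @param minSupport Integer threshold (inclusive: a taxon with exactly
#'   this many reads survives).
#' @param taxonomy Needed for \code{promoteToParent} / \code{cladeSummed}.
#' @param promoteToParent Promote reads of removed taxa to the parent node
#'   (re-tested iteratively) instead of unassigning them.
#' @param cladeSummed Compare clade-summed counts rather than direct
#'   counts.
#' @return A new [AssignmentResult]; \code{countsBefore} keeps the
#'   pre-support counts of the input.
#' @export
applyMinSupport <- function(result, minSupport, taxonomy = NULL,
                            promoteToParent = FALSE, cladeSummed = FALSE) {
  minSupport <- as.integer(minSupport)
  assignments <- result@assignments
  before <- result@countsBefore
  if (minSupport <= 1L || nrow(before) == 0L) {
    out <- buildResult(assignments,
                       extraTallies = list(min_support = minSupport,
                                           support_removed_taxa = 0L))
    out@countsBefore <- before
    return(out)
  }
  if ((promoteToParent || cladeSummed) && is.null(taxonomy))
    stop("taxonomy required for promoteToParent / cladeSummed")
  removedTaxa <- 0L
  repeat {
    assigned <- assignments$status == "assigned"
    counts <- table(assignments$taxon_id[assigned])
    if (cladeSummed) {
      eff <- vapply(names(counts), function(t) {
        sum(counts[names(counts) %in%
                     as.character(subtreeTaxa(taxonomy, as.integer(t)))])
      }, numeric(1))
    } else eff <- as.numeric(counts)
    failing <- as.integer(names(counts))[eff < minSupport]
    if (!length(failing)) break
    removedTaxa <- removedTaxa + length(failing)
    hit <- assigned & assignments$taxon_id %in% failing
    if (promoteToParent) {
      parents <- taxonParent(taxonomy, assignments$taxon_id[hit])
      atRoot <- assignments$taxon_id[hit] == rootId(taxonomy)
      assignments$taxon_id[hit] <- unname(parents)
      if (any(atRoot)) {
        idx <- which(hit)[atRoot]
        assignments$taxon_id[idx] <- NA_integer_
        assignments$status[idx] <- "unassigned"
      }
    } else {
      assignments$taxon_id[hit] <- NA_integer_
      assignments$status[hit] <- "unassigned"
      break   # one pass: remaining taxa all meet the threshold already
    }
  }
  out <- buildResult(assignments,
                     extraTallies = list(min_support = minSupport,
                                         support_removed_taxa = removedTaxa))
  out@countsBefore <- before
  out
}

#' Accessors for AssignmentResult
#'
#' @param result An [AssignmentResult].
#' @return \code{assignments()}: the per-query data.frame;
#'   \code{assignedCounts()}: per-taxon counts after min support;
#'   \code{assignedCountsBefore()}: counts before min support;
#'   \code{assignmentTallies()}: the tally list.
#' @export
assignments <- function(result) result@assignments

#' @rdname assignments
#' @export
assignedCounts <- function(result) result@countsAfter

#' @rdname assignments
#' @export
assignedCountsBefore <- function(result) result@countsBefore

#' @rdname assignments
#' @export
assignmentTallies <- function(result) result@tallies

setMethod("show", "AssignmentResult", function(object) {
  t <- object@tallies
  cat("AssignmentResult:", t$queries, "queries |", t$assigned,
      "assigned,", t$unassigned, "unassigned,", t$no_hits, "no hits\n")
  cat("  taxa reported:", nrow(object@countsAfter), "\n")
})
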