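## Paired-reads mode: mate pairing, per-organism score combination,
## pair-level assignment.

#' Construct combined-score parameters
#'
#' See [CombinedScoreParams-class] for the meaning of each field. Defaults
#' follow the reported BLAST database parameters: r = 2, k = 0.041, gap
#' size g = 50, effective HSP length h = 0, translated (BLASTX-style)
#' search.
#'
#' @param r,k,g,h,translated,defaultQueryLength,defaultSubjectLength,correction
#'   See [CombinedScoreParams-class].
#' @return A [CombinedScoreParams] object.
#' @export
combinedScoreParams <- function(r = 2L, k = 0.041, g = 50, h = 0,
                                translated = TRUE, defaultQueryLength = 75,
                                defaultSubjectLength = 300,
                                correction = c("g", "g2")) {
  new("CombinedScoreParams", r = as.integer(r), k = k, g = g, h = h,
      translated = translated, defaultQueryLength = defaultQueryLength,
      defaultSubjectLength = defaultSubjectLength,
      correction = match.arg(correction))
}

setMethod("show", "CombinedScoreParams", function(object) {
  cat("CombinedScoreParams: r =", object@r, "k =", object@k,
      "g =", object@g, "h =", object@h,
      if (object@translated) "(translated)" else "(nucleotide)", "\n")
})

#' Combine the bit scores of two mates hitting the same organism
#'
#' Karlin-Altschul pair-sum correction in the bits domain:
#' \deqn{s = \max(s_1 + s_2 - \log_2(k \, g \, m' n'),\ \max(s_1, s_2))}
#' with \eqn{m' = m/3 - h} for translated searches (else \eqn{m - h}) and
#' \eqn{n' = n - h}. The clamp at the better single score keeps the
#' combination from ever penalising a doubly-hit organism. Strictly
#' increasing in both scores (up to the clamp) and symmetric. Vectorised.
#'
#' @param s1,s2 Mate bit scores (bits, > 0).
#' @param params A [CombinedScoreParams].
#' @param m Total query length in nucleotides (sum of the two mate
#'   lengths; default from \code{params}).
#' @param n Subject length in residues (default from \code{params}).
#' @return Combined bit score(s).
#' @examples
#' p <- combinedScoreParams()
#' combinedBitScore(50, 50, p, m = 450, n = 300)   # about 83.5 bits
#' @export
combinedBitScore <- function(s1, s2, params = combinedScoreParams(),
                             m = 2 * params@defaultQueryLength,
                             n = params@defaultSubjectLength) {
  mPrime <- (if (params@translated) m / 3 else m) - params@h
  nPrime <- n - params@h
  if (any(mPrime <= 0) || any(nPrime <= 0))
    stop("parameter error: non-positive effective length (check h, m, n)")
  gTerm <- if (params@correction == "g2") params@g^2 else params@g
  corr <- log2(params@k * gTerm * mPrime * nPrime)
  pmax(s1 + s2 - corr, pmax(s1, s2))
}

#' Group read ids into mate pairs
#'
#' Ids whose stems agree after stripping a mate suffix (by default a
#' trailing \code{/1}, \code{/2}, \code{_1}, \code{_2}, \code{.1} or
#' \code{.2}) form a pair; ids without a recognised suffix, or with a
#' partner missing, are returned as unpaired and are meant to be processed
#' in single-read mode.
#'
#' @param ids Character vector of read ids.
#' @param suffixPattern Regular expression matching the mate suffix at the
#'   end of an id; its first capture group must be the mate number.
#' @return A list with \code{pairs} (data.frame \code{pair_id},
#'   \code{mate1}, \code{mate2}) and \code{unpaired} (character vector).
#' @export
pairReads <- function(ids, suffixPattern = "[/._]([12])$") {
  hasSuffix <- grepl(suffixPattern, ids)
  stem <- sub(suffixPattern, "", ids)
  mate <- rep(NA_character_, length(ids))
  mate[hasSuffix] <- sub(paste0(".*", suffixPattern), "\\1", ids[hasSuffix])
  unpaired <- ids[!hasSuffix]
  tab <- split(seq_along(ids)[hasSuffix], stem[hasSuffix])
  sizes <- lengths(tab)
  if (any(sizes > 2L)) {
    bad <- tab[[which(sizes > 2L)[1]]]
    stop("ambiguity error: more than two reads share a stem: ",
         paste(ids[bad], collapse = ", "))
  }
  full <- tab[sizes == 2L]
  ok <- vapply(full, function(i) setequal(mate[i], c("1", "2")), logical(1))
  singles <- c(unlist(tab[sizes == 1L], use.names = FALSE),
               unlist(full[!ok], use.names = FALSE))
  full <- full[ok]
  m1 <- vapply(full, function(i) ids[i][mate[i] == "1"], character(1))
  m2 <- vapply(full, function(i) ids[i][mate[i] == "2"], character(1))
  list(pairs = data.frame(pair_id = names(full), mate1 = unname(m1),
                          mate2 = unname(m2), stringsAsFactors = FALSE,
                          row.names = NULL),
       unpaired = c(unpaired, ids[singles]))
}

#' Merge the matches of two mates per organism
#'
#' For every taxon hit by both mates the two matches are replaced by one
#' match carrying the combined bit score; taxa hit by a single mate keep
#' their single score. The merged taxon set is exactly the union of the
#' mates' taxa.
#'
#' @param df1,df2 Match data.frames of the two mates, each already reduced
#'   by [bestPerTaxon()] (either may be empty or NULL).
#' @param pairParams A [CombinedScoreParams].
#' @return A merged match data.frame with an extra logical column
#'   \code{combined}.
#' @export
mergeMateMatches <- function(df1, df2, pairParams = combinedScoreParams()) {
  empty1 <- is.null(df1) || nrow(df1) == 0L
  empty2 <- is.null(df2) || nrow(df2) == 0L
  addFlag <- function(df, flag) { df$combined <- rep(flag, nrow(df)); df }
  if (empty1 && empty2) return(NULL)
  if (empty1) return(addFlag(df2, FALSE))
  if (empty2) return(addFlag(df1, FALSE))
  shared <- intersect(df1$taxon_id, df2$taxon_id)
  only1 <- df1[!(df1$taxon_id %in% shared), , drop = FALSE]
  only2 <- df2[!(df2$taxon_id %in% shared), , drop = FALSE]
  singles <- rbind(addFlag(only1, FALSE), addFlag(only2, FALSE))
  if (!length(shared)) return(singles)
  a <- df1[match(shared, df1$taxon_id), , drop = FALSE]
  b <- df2[match(shared, df2$taxon_id), , drop = FALSE]
  L <- pairParams@defaultQueryLength
  m <- ifelse(is.na(a$query_length), L, a$query_length) +
       ifelse(is.na(b$query_length), L, b$query_length)
  nlen <- pmax(ifelse(is.na(a$subject_length),
                      pairParams@defaultSubjectLength, a$subject_length),
               ifelse(is.na(b$subject_length),
                      pairParams@defaultSubjectLength, b$subject_length))
  s <- combinedBitScore(a$bit_score, b$bit_score, pairParams, m = m, n = nlen)
  ## carry the identity of the better-scoring mate's subject
  takeA <- a$bit_score > b$bit_score |
    (a$bit_score == b$bit_score & a$subject_id <= b$subject_id)
  merged <- a
  merged$subject_id <- ifelse(takeA, a$subject_id, b$subject_id)
  merged$bit_score <- s
  merged$subject_length <- nlen
  merged$query_length <- m
  merged$combined <- TRUE
  rbind(singles, merged)
}

#' Assign a read pair by the LCA gene-content rule
#'
#' Merges the two mates' matches per organism with [mergeMateMatches()]
#' (combined bit scores for doubly-hit organisms), then runs the standard
#' single-read pipeline on the merged list. Both mates receive the pair's
#' assignment. A pair with one empty mate degenerates to single-read mode
#' on the other mate.
#'
#' @param taxonomy A [Taxonomy].
#' @param df1,df2 Per-mate match data.frames, reduced by [bestPerTaxon()].
#' @param params An [AssignmentParams].
#' @param pairParams A [CombinedScoreParams].
#' @param excludedSet Optional precomputed excluded taxon set.
#' @return As [assignRead()].
#' @export
assignPair <- function(taxonomy, df1, df2, params = assignmentParams(),
                       pairParams = combinedScoreParams(),
                       excludedSet = NULL) {
  merged <- mergeMateMatches(df1, df2, pairParams)
  assignRead(taxonomy, merged, params, excludedSet)
}

#' Assign all reads of a match table in paired mode
#'
#' Pairs the query ids with [pairReads()], assigns each pair once via
#' [assignPair()], processes leftover unpaired reads in single-read mode,
#' then applies min support. With \code{accounting = "pair"} each pair
#' contributes one row (keyed by pair id); with \code{"read"} both mates
#' appear, duplicating the pair's assignment (for figures normalised by
#' read count).
#'
#' @param taxonomy A [Taxonomy].
#' @param matchTable A [MatchTable].
#' @param params An [AssignmentParams].
#' @param pairParams A [CombinedScoreParams].
#' @param queryIds Optional full read universe (reads with no matches
#'   count as NO_HITS).
#' @param accounting \code{"pair"} or \code{"read"}.
#' @param suffixPattern Mate-suffix pattern, see [pairReads()].
#' @return An [AssignmentResult].
#' @export
assignReadsPaired <- function(taxonomy, matchTable,
                              params = assignmentParams(),
                              pairParams = combinedScoreParams(),
                              queryIds = NULL,
                              accounting = c("pair", "read"),
                              suffixPattern = "[/._]([12])$") {
  accounting <- match.arg(accounting)
  m <- matches(matchTable)
  if (is.null(queryIds)) queryIds <- unique(m$query_id)
  pr <- pairReads(queryIds, suffixPattern)
  excludedSet <- expandExcluded(taxonomy, params@excludedClades)
  groups <- split(seq_len(nrow(m)), m$query_id)
  reduced <- function(q) {
    i <- groups[[q]]
    if (is.null(i)) NULL else bestPerTaxon(m[i, , drop = FALSE])
  }
  n <- nrow(pr$pairs)
  pairTaxon <- rep(NA_integer_, n)
  pairStatus <- rep("no_hits", n)
  for (i in seq_len(n)) {
    a <- assignPair(taxonomy, reduced(pr$pairs$mate1[i]),
                    reduced(pr$pairs$mate2[i]), params, pairParams,
                    excludedSet)
    pairTaxon[i] <- a$taxon_id
    pairStatus[i] <- a$status
  }
  uTaxon <- rep(NA_integer_, length(pr$unpaired))
  uStatus <- rep("no_hits", length(pr$unpaired))
  for (i in seq_along(pr$unpaired)) {
    a <- assignRead(taxonomy, reduced(pr$unpaired[i]), params, excludedSet)
    uTaxon[i] <- a$taxon_id
    uStatus[i] <- a$status
  }
  if (accounting == "pair") {
    assignments <- data.frame(
      query_id = c(pr$pairs$pair_id, pr$unpaired),
      taxon_id = c(pairTaxon, uTaxon),
      status = c(pairStatus, uStatus), stringsAsFactors = FALSE)
  } else {
    assignments <- data.frame(
      query_id = c(pr$pairs$mate1, pr$pairs$mate2, pr$unpaired),
      taxon_id = c(pairTaxon, pairTaxon, uTaxon),
      status = c(pairStatus, pairStatus, uStatus),
      stringsAsFactors = FALSE)
  }
  res <- buildResult(assignments,
                     extraTallies = list(pairs = n,
                                         unpaired = length(pr$unpaired)))
  res <- applyMinSupport(res, params@minSupport, taxonomy = taxonomy,
                         promoteToParent = params@promoteToParent,
                         cladeSummed = params@cladeSummedSupport)
  res@tallies$pairs <- n
  res@tallies$unpaired <- length(pr$unpaired)
  res
}
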