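## BLAST-tabular input and per-query match handling.

#' Construct a MatchTable from a data.frame of matches
#'
#' @param matches data.frame with at least \code{query_id},
#'   \code{subject_id}, \code{bit_score}, \code{taxon_id}; missing
#'   \code{subject_length} / \code{query_length} columns are filled with NA.
#' @param skipped integer, number of unmappable input lines.
#' @return A [MatchTable].
#' @export
MatchTable <- function(matches, skipped = 0L) {
  if (is.null(matches$subject_length))
    matches$subject_length <- rep(NA_real_, nrow(matches))
  if (is.null(matches$query_length))
    matches$query_length <- rep(NA_real_, nrow(matches))
  matches$taxon_id <- as.integer(matches$taxon_id)
  cols <- c("query_id", "subject_id", "bit_score", "taxon_id",
            "subject_length", "query_length")
  new("MatchTable", matches = as.data.frame(matches)[cols],
      skipped = as.integer(skipped))
}

#' @describeIn MatchTable the match data.frame.
#' @param x A [MatchTable].
#' @export
matches <- function(x) x@matches

#' @describeIn MatchTable number of unmappable lines skipped at parse time.
#' @export
skippedLines <- function(x) x@skipped

#' @describeIn MatchTable distinct query ids present in the table.
#' @export
queryIds <- function(x) unique(x@matches$query_id)

setMethod("show", "MatchTable", function(object) {
  cat("MatchTable:", nrow(object@matches), "matches,",
      length(unique(object@matches$query_id)), "queries,",
      object@skipped, "lines skipped\n")
})

#' Read a BLAST tabular match file
#'
#' Parses 12-column BLAST tabular output (\code{-outfmt 6}: query, subject,
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bit score), optionally with a 13th column holding the
#' subject's taxon id. Without a 13th column a \code{taxonMap} is required;
#' lines whose subject has no mapping are counted in \code{skippedLines()}
#' and dropped, so \code{nrow(matches()) + skippedLines()} equals the number
#' of data lines. Matches below 1 bit are rejected as malformed.
#'
#' @param path Path to the tabular file.
#' @param taxonMap Named integer vector (names = subject ids) mapping
#'   subjects to taxa, or \code{"column"} to use the 13th column.
#' @param subjectLengths Optional named numeric vector (names = subject
#'   ids) of subject lengths in residues (used by the paired-mode score
#'   correction).
#' @param defaultSubjectLength Subject length assumed when no sidecar
#'   length is available (default 300 residues).
#' @return A [MatchTable].
#' @export
readBlastTab <- function(path, taxonMap = "column", subjectLengths = NULL,
                         defaultSubjectLength = 300) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines))
    return(MatchTable(data.frame(query_id = character(),
                                 subject_id = character(),
                                 bit_score = numeric(),
                                 taxon_id = integer()), 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("parse error: line ", which(nf < 12L)[1],
         " has fewer than 12 columns")
  useColumn <- identical(taxonMap, "column")
  if (useColumn && any(nf < 13L))
    stop("configuration error: no taxon map supplied and line ",
         which(nf < 13L)[1], " lacks a 13th taxon column")
  if (!useColumn && is.null(names(taxonMap)))
    stop("configuration error: taxonMap must be named by subject id")
  qid <- vapply(fields, `[`, character(1), 1L)
  sid <- vapply(fields, `[`, character(1), 2L)
  bits <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 12L)))
  if (anyNA(bits))
    stop("parse error: non-numeric bit score at line ", which(is.na(bits))[1])
  if (useColumn) {
    taxon <- suppressWarnings(
      as.integer(vapply(fields, `[`, character(1), 13L)))
    mapped <- !is.na(taxon)
  } else {
    taxon <- unname(taxonMap[sid])
    mapped <- !is.na(taxon)
  }
  keep <- mapped & bits >= 1
  skipped <- sum(!mapped)
  if (any(mapped & bits < 1))
    warning(sum(mapped & bits < 1), " match(es) below the 1-bit floor dropped")
  slen <- if (is.null(subjectLengths)) rep(defaultSubjectLength, length(sid))
          else ifelse(sid %in% names(subjectLengths),
                      unname(subjectLengths[sid]), defaultSubjectLength)
  MatchTable(data.frame(query_id = qid[keep], subject_id = sid[keep],
                        bit_score = bits[keep],
                        taxon_id = as.integer(taxon[keep]),
                        subject_length = slen[keep],
                        query_length = NA_real_,
                        stringsAsFactors = FALSE),
             skipped)
}

#' Keep the best match per taxon for one query
#'
#' Reduces the matches of a single read to one match per distinct taxon:
#' the highest-scoring one, ties broken by the lexicographically smallest
#' subject id (deterministic across platforms). Idempotent.
#'
#' @param df data.frame of matches sharing one \code{query_id}.
#' @return The reduced data.frame.
#' @export
bestPerTaxon <- function(df) {
  if (nrow(df) <= 1L) return(df)
  ord <- order(df$taxon_id, -df$bit_score, df$subject_id)
  df <- df[ord, , drop = FALSE]
  df[!duplicated(df$taxon_id), , drop = FALSE]
}
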