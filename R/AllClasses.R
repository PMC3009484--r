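#' @import methods
NULL

MAJOR_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Rooted, ranked taxonomy
#'
#' Holds a rooted tree of taxon nodes, each with an integer id, a parent id,
#' a rank and a name. Ranks outside the seven major ranks (superkingdom,
#' phylum, class, order, family, genus, species) are normalised to
#' \code{"no-rank"}. The root is its own parent, following the NCBI taxdump
#' convention for taxon 1.
#'
#' @slot nodes data.frame with columns \code{taxon_id}, \code{parent_id},
#'   \code{rank}, \code{name}, one row per node.
#' @slot rootId integer id of the root node.
#' @slot depth named integer vector, depth of every node (root = 0).
#'
#' @seealso [readTaxonomy()], [makeSyntheticTaxonomy()], [lca()]
#' @exportClass Taxonomy
setClass("Taxonomy",
         representation(nodes = "data.frame",
                        rootId = "integer",
                        depth = "integer"))

setValidity("Taxonomy", function(object) {
  nd <- object@nodes
  msg <- character()
  need <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$taxon_id))
    msg <- c(msg, "duplicated taxon ids")
  if (!(object@rootId %in% nd$taxon_id))
    msg <- c(msg, "root id not among nodes")
  dangling <- setdiff(nd$parent_id, nd$taxon_id)
  if (length(dangling))
    msg <- c(msg, paste("dangling parent ids:",
                        paste(utils::head(dangling, 5), collapse = ", ")))
  root <- nd$taxon_id[nd$taxon_id == nd$parent_id]
  if (!identical(as.integer(root), object@rootId))
    msg <- c(msg, "exactly the root must be its own parent")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Collection of per-read homology matches
#'
#' One row per BLAST-style match that passed parsing: the query (read) id,
#' the subject (reference protein) id, the bit score, the taxon the subject
#' belongs to, and the subject length in residues (needed by the paired
#' combined-score correction).
#'
#' @slot matches data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{bit_score}, \code{taxon_id}, \code{subject_length},
#'   \code{query_length}.
#' @slot skipped integer, number of input lines whose subject could not be
#'   mapped to a taxon (counted, not silently lost).
#'
#' @seealso [readBlastTab()], [bestPerTaxon()]
#' @exportClass MatchTable
setClass("MatchTable",
         representation(matches = "data.frame", skipped = "integer"))

setValidity("MatchTable", function(object) {
  m <- object@matches
  need <- c("query_id", "subject_id", "bit_score", "taxon_id",
            "subject_length", "query_length")
  if (!all(need %in% names(m)))
    return(paste("matches must have columns", paste(need, collapse = ", ")))
  if (nrow(m) && any(m$bit_score <= 0))
    return("all bit scores must be positive")
  TRUE
})

#' Parameters of the LCA read-assignment pipeline
#'
#' The three MEGAN-style filters plus clade exclusion. \code{minScore} is an
#' absolute bit-score floor (kept if score >= minScore); \code{topPercent}
#' keeps, per read, matches scoring within that percentage of the read's
#' best match; \code{minSupport} removes reported taxa hit by fewer reads
#' (boundary inclusive: a taxon with exactly \code{minSupport} reads is
#' kept). \code{excludedClades} drops, before any score filter, every match
#' to a taxon inside one of the given clades (the unknown-species
#' experiment).
#'
#' @slot minScore numeric bits, default 35.
#' @slot topPercent numeric percent in [0, 100], default 10.
#' @slot minSupport integer >= 1, default 1.
#' @slot excludedClades integer vector of clade-root taxon ids.
#' @slot promoteToParent logical; if TRUE reads on taxa failing min support
#'   are promoted to the parent node instead of becoming unassigned.
#' @slot cladeSummedSupport logical; if TRUE min support compares the
#'   clade-summed count rather than the direct count.
#'
#' @seealso [assignmentParams()], [assignReads()], [applyMinSupport()]
#' @exportClass AssignmentParams
setClass("AssignmentParams",
         representation(minScore = "numeric", topPercent = "numeric",
                        minSupport = "integer", excludedClades = "integer",
                        promoteToParent = "logical",
                        cladeSummedSupport = "logical"))

setValidity("AssignmentParams", function(object) {
  if (object@minScore < 0) return("minScore must be >= 0")
  if (object@topPercent < 0 || object@topPercent > 100)
    return("topPercent must be in [0, 100]")
  if (object@minSupport < 1L) return("minSupport must be >= 1")
  TRUE
})

#' Parameters of the paired-read combined bit score
#'
#' Karlin-Altschul sum-statistics correction for combining the bit scores of
#' the two mates of a clone that hit the same organism. The combined score
#' is \code{max(s1 + s2 - log2(k * g * m' * n'), max(s1, s2))} with
#' effective query length \code{m' = m/3 - h} for translated searches
#' (\code{m' = m - h} otherwise, \code{m} the total clone query length in
#' nucleotides) and effective subject length \code{n' = n - h}.
#'
#' @slot r integer, number of combined segments (fixed at 2).
#' @slot k numeric, Karlin-Altschul database parameter (default 0.041).
#' @slot g numeric, gap size (default 50).
#' @slot h numeric, effective HSP length in residues (default 0).
#' @slot translated logical, TRUE for BLASTX-style searches (query length
#'   divided by 3 when computing m').
#' @slot defaultQueryLength numeric, per-mate query length in nucleotides
#'   used when a match carries no query length (default 75).
#' @slot defaultSubjectLength numeric, subject length in residues used when
#'   a match carries no subject length (default 300).
#' @slot correction character, \code{"g"} for the default log2(k g m' n')
#'   term or \code{"g2"} for an alternative with the gap size squared.
#'
#' @seealso [combinedScoreParams()], [combinedBitScore()], [assignPair()]
#' @exportClass CombinedScoreParams
setClass("CombinedScoreParams",
         representation(r = "integer", k = "numeric", g = "numeric",
                        h = "numeric", translated = "logical",
                        defaultQueryLength = "numeric",
                        defaultSubjectLength = "numeric",
                        correction = "character"))

setValidity("CombinedScoreParams", function(object) {
  if (object@r != 2L) return("r is fixed at 2 (two mates)")
  if (object@k <= 0) return("k must be > 0")
  if (object@g <= 0) return("g must be > 0")
  if (!object@correction %in% c("g", "g2"))
    return("correction must be 'g' or 'g2'")
  TRUE
})

#' Result of an assignment run
#'
#' Per-query assignment (a taxon id, or the buckets UNASSIGNED / NO_HITS)
#' together with per-taxon read counts before and after the min-support
#' filter and the filter-stage tallies. The conservation identity
#' \code{assigned + unassigned + no_hits == nQueries} holds on every run.
#'
#' @slot assignments data.frame with columns \code{query_id},
#'   \code{taxon_id} (NA unless assigned), \code{status} (one of
#'   \code{"assigned"}, \code{"unassigned"}, \code{"no_hits"}).
#' @slot countsBefore data.frame (\code{taxon_id}, \code{count}) before min
#'   support.
#' @slot countsAfter data.frame (\code{taxon_id}, \code{count}) after min
#'   support.
#' @slot tallies named list of integers (queries, assigned, unassigned,
#'   no_hits, min-support removals, ...).
#'
#' @seealso [assignReads()], [applyMinSupport()], [assignedCounts()]
#' @exportClass AssignmentResult
setClass("AssignmentResult",
         representation(assignments = "data.frame",
                        countsBefore = "data.frame",
                        countsAfter = "data.frame",
                        tallies = "list"))

setValidity("AssignmentResult", function(object) {
  a <- object@assignments
  if (!all(c("query_id", "taxon_id", "status") %in% names(a)))
    return("assignments must have query_id, taxon_id, status")
  if (nrow(a) && !all(a$status %in% c("assigned", "unassigned", "no_hits")))
    return("unknown status value")
  n <- nrow(a)
  tot <- sum(a$status == "assigned") + sum(a$status == "unassigned") +
    sum(a$status == "no_hits")
  if (tot != n) return("status buckets must partition the queries")
  TRUE
})

#' Clone library specification
#'
#' Clone lengths are drawn from Normal(mu, sigma), rounded, and truncated
#' below at twice the read length for paired libraries (at the read length
#' for single-read libraries) and above at the genome length.
#'
#' @slot mu numeric, mean clone length in bp.
#' @slot sigma numeric, standard deviation in bp.
#' @slot readLength integer, read length in bp (75 for the Illumina
#'   protocols modelled here).
#' @slot paired logical, whether both clone ends are sequenced.
#'
#' @seealso [cloneLibrarySpec()], [sampleClones()]
#' @exportClass CloneLibrarySpec
setClass("CloneLibrarySpec",
         representation(mu = "numeric", sigma = "numeric",
                        readLength = "integer", paired = "logical"))

setValidity("CloneLibrarySpec", function(object) {
  if (object@sigma < 0) return("sigma must be >= 0")
  if (object@readLength < 1L) return("readLength must be >= 1")
  if (object@paired && object@mu < 2 * object@readLength)
    return("paired libraries need mu >= 2 * readLength")
  TRUE
})

#' Positional substitution-error model for Illumina reads
#'
#' Per-position substitution probability f(x) = a * exp(b * x) + c, fitted
#' over a 36-position profile and stretched proportionally to the simulated
#' read length: position t of an L bp read is evaluated at
#' x = profileDomain * t / L.
#'
#' @slot a,b,c numeric regression constants (defaults 3.957e-4, 1.319e-1,
#'   5.362e-3).
#' @slot profileDomain integer, length of the fitted profile (36).
#'
#' @seealso [illuminaErrorModel()], [illuminaErrorProbability()]
#' @exportClass IlluminaErrorModel
setClass("IlluminaErrorModel",
         representation(a = "numeric", b = "numeric", c = "numeric",
                        profileDomain = "integer"))

setValidity("IlluminaErrorModel", function(object) {
  x <- seq_len(object@profileDomain)
  p <- object@a * exp(object@b * x) + object@c
  if (any(p <= 0 | p >= 1))
    return("f(x) must lie in (0,1) over the profile domain")
  TRUE
})

#' Flow-cycle specification for 454-style reads
#'
#' Reads are built by cycling over the flow order; each flow reads the
#' homopolymer of the flowed nucleotide at the current template position.
#' The called homopolymer length is round(Normal(l + bias, sd)), clamped
#' at zero, so miscalls create insertions and deletions but never
#' substitutions. The small positive call bias models flow carry-forward,
#' which makes over-calls (insertions) several times more frequent than
#' under-calls (deletions), as observed in flow-cycle data.
#'
#' @slot flowCycles integer, number of passes over the flow order
#'   (default 98, giving reads of roughly 250 bp).
#' @slot flowOrder character, the four-letter flow order (default "TACG").
#' @slot homopolymerNoiseSd numeric, standard deviation of the call noise;
#'   the single calibration constant (default 0.217, calibrated once so
#'   insertion/deletion rates on random sequence land at about 2.3 and
#'   0.5 percent).
#' @slot callBias numeric, fixed positive shift of the called length
#'   (default 0.035).
#'
#' @seealso [flow454Spec()], [sequence454Reads()]
#' @exportClass Flow454Spec
setClass("Flow454Spec",
         representation(flowCycles = "integer", flowOrder = "character",
                        homopolymerNoiseSd = "numeric",
                        callBias = "numeric"))

setValidity("Flow454Spec", function(object) {
  if (object@flowCycles < 1L) return("flowCycles must be > 0")
  if (nchar(object@flowOrder) != 4L ||
      !setequal(strsplit(object@flowOrder, "")[[1]], c("A", "C", "G", "T")))
    return("flowOrder must be a permutation of ACGT")
  if (object@homopolymerNoiseSd < 0)
    return("homopolymerNoiseSd must be >= 0")
  TRUE
})

#' Gene-annotation specification for synthetic genomes
#'
#' Synthetic genomes are tiled with genes whose lengths follow a Gamma
#' distribution (shape 2, mean 950 bp by default) truncated below at
#' 100 bp, separated by intergenic gaps drawn uniformly from [50, 150] bp.
#'
#' @slot shape,meanLength numeric, Gamma shape and mean gene length (bp).
#' @slot minLength numeric, truncation floor for gene lengths (bp).
#' @slot gapMin,gapMax numeric, bounds of the uniform intergenic gap (bp).
#'
#' @seealso [geneAnnotationSpec()], [makeSyntheticCommunity()]
#' @exportClass GeneAnnotationSpec
setClass("GeneAnnotationSpec",
         representation(shape = "numeric", meanLength = "numeric",
                        minLength = "numeric", gapMin = "numeric",
                        gapMax = "numeric"))

setValidity("GeneAnnotationSpec", function(object) {
  if (object@shape <= 0 || object@meanLength <= 0)
    return("shape and meanLength must be > 0")
  if (object@gapMin < 0 || object@gapMax < object@gapMin)
    return("need 0 <= gapMin <= gapMax")
  TRUE
})

#' A synthetic community: taxonomy, genomes, genes, abundances
#'
#' Bundles everything the simulator generates for one community: a ranked
#' taxonomy, one random annotated genome per community member, and the
#' abundance profile of one of the three complexity classes (LC: one
#' dominant species; MC: six dominant species; HC: all species equally
#' abundant).
#'
#' @slot taxonomy [Taxonomy] over the community members.
#' @slot profile data.frame with columns \code{taxon_id}, \code{genome},
#'   \code{abundance} (abundances sum to 1).
#' @slot complexity character, one of "LC", "MC", "HC".
#' @slot genomes [Biostrings::DNAStringSet] named by genome id.
#' @slot genes [GenomicRanges::GRanges] of gene intervals; seqnames are
#'   genome ids, metadata columns \code{gene_id} and \code{taxon_id}.
#'
#' @seealso [makeSyntheticCommunity()], [sampleClones()]
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
         representation(taxonomy = "Taxonomy", profile = "data.frame",
                        complexity = "character", genomes = "ANY",
                        genes = "ANY"))

setValidity("SyntheticCommunity", function(object) {
  p <- object@profile
  if (!all(c("taxon_id", "genome", "abundance") %in% names(p)))
    return("profile must have taxon_id, genome, abundance")
  if (any(p$abundance <= 0)) return("abundances must be > 0")
  if (abs(sum(p$abundance) - 1) > 1e-8) return("abundances must sum to 1")
  if (!object@complexity %in% c("LC", "MC", "HC"))
    return("complexity must be LC, MC or HC")
  TRUE
})
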