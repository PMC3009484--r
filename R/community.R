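## Synthetic communities: ranked taxonomy, random annotated genomes,
## LC/MC/HC abundance profiles.

#' Gene-annotation spec constructor
#'
#' @param shape Gamma shape of gene lengths (default 2).
#' @param meanLength Mean gene length in bp (default 950).
#' @param minLength Truncation floor in bp (default 100).
#' @param gapMin,gapMax Uniform intergenic gap bounds in bp (50, 150).
#' @return A [GeneAnnotationSpec].
#' @export
geneAnnotationSpec <- function(shape = 2, meanLength = 950, minLength = 100,
                               gapMin = 50, gapMax = 150) {
  new("GeneAnnotationSpec", shape = shape, meanLength = meanLength,
      minLength = minLength, gapMin = gapMin, gapMax = gapMax)
}

## Tile one genome with genes; returns IRanges-style start/end/strand df.
tileGenes <- function(genomeLength, spec) {
  scale <- spec@meanLength / spec@shape
  starts <- integer(); ends <- integer()
  pos <- 1 + round(stats::runif(1, spec@gapMin, spec@gapMax))
  repeat {
    len <- round(stats::rgamma(1, shape = spec@shape, scale = scale))
    len <- max(len, spec@minLength)
    if (pos + len - 1 > genomeLength) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + len - 1)
    pos <- pos + len + round(stats::runif(1, spec@gapMin, spec@gapMax))
  }
  data.frame(start = starts, end = ends,
             strand = sample(c("+", "-"), length(starts), replace = TRUE))
}

#' Generate a synthetic community
#'
#' Builds a ranked taxonomy with \code{nTaxa} species, one random genome
#' per species tiled with genes (lengths Gamma, gaps uniform; see
#' [geneAnnotationSpec()]), and an abundance profile of the requested
#' complexity class: \code{"LC"} has one dominant species whose abundance
#' is \code{dominanceRatio} times that of every other species, \code{"MC"}
#' has six such dominant species, \code{"HC"} has all species at equal
#' abundance. Deterministic under a fixed seed.
#'
#' @param nTaxa Number of community species (>= 7 for MC).
#' @param complexity "LC", "MC" or "HC".
#' @param dominanceRatio Abundance ratio of a dominant to a background
#'   species; required for LC and MC (no canonical default exists),
#'   ignored for HC.
#' @param genomeLength Length of every synthetic genome in bp.
#' @param geneSpec A [GeneAnnotationSpec].
#' @param seed Optional integer seed.
#' @return A [SyntheticCommunity].
#' @examples
#' comm <- makeSyntheticCommunity(10, "HC", genomeLength = 10000, seed = 1)
#' communityProfile(comm)$abundance   # all equal to 1/10
#' @export
makeSyntheticCommunity <- function(nTaxa, complexity = c("HC", "LC", "MC"),
                                   dominanceRatio = NULL,
                                   genomeLength = 20000,
                                   geneSpec = geneAnnotationSpec(),
                                   seed = NULL) {
  complexity <- match.arg(complexity)
  if (complexity == "MC" && nTaxa < 7L)
    stop("argument error: MC needs at least 7 taxa")
  if (complexity %in% c("LC", "MC") &&
      (is.null(dominanceRatio) || dominanceRatio <= 1))
    stop("argument error: LC/MC require dominanceRatio > 1")
  withSeed(seed, {
    taxonomy <- makeSyntheticTaxonomy(nTaxa)
    species <- sort(speciesIds(taxonomy))
    nDom <- switch(complexity, LC = 1L, MC = 6L, HC = 0L)
    w <- rep(1, nTaxa)
    if (nDom > 0) w[seq_len(nDom)] <- dominanceRatio
    genomeIds <- sprintf("genome_%03d", seq_len(nTaxa))
    profile <- data.frame(taxon_id = species, genome = genomeIds,
                          abundance = w / sum(w), stringsAsFactors = FALSE)
    alphabet <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(nTaxa), function(i)
      paste(sample(alphabet, genomeLength, replace = TRUE), collapse = ""),
      character(1))
    genomes <- Biostrings::DNAStringSet(seqs)
    names(genomes) <- genomeIds
    geneDfs <- lapply(seq_len(nTaxa), function(i) {
      g <- tileGenes(genomeLength, geneSpec)
      if (!nrow(g)) return(NULL)
      g$genome <- genomeIds[i]
      g$taxon_id <- species[i]
      g$gene_id <- sprintf("%s_g%03d", genomeIds[i], seq_len(nrow(g)))
      g
    })
    gd <- do.call(rbind, geneDfs)
    genes <- GenomicRanges::GRanges(
      seqnames = gd$genome,
      ranges = IRanges::IRanges(start = gd$start, end = gd$end),
      strand = gd$strand, gene_id = gd$gene_id, taxon_id = gd$taxon_id)
    new("SyntheticCommunity", taxonomy = taxonomy, profile = profile,
        complexity = complexity, genomes = genomes, genes = genes)
  })
}

#' Accessors for SyntheticCommunity
#'
#' @param community A [SyntheticCommunity].
#' @return \code{communityProfile()}: abundance data.frame;
#'   \code{communityGenomes()}: named [Biostrings::DNAStringSet];
#'   \code{communityGenes()}: gene [GenomicRanges::GRanges];
#'   \code{communityTaxonomy()}: the [Taxonomy].
#' @export
communityProfile <- function(community) community@profile

#' @rdname communityProfile
#' @export
communityGenomes <- function(community) community@genomes

#' @rdname communityProfile
#' @export
communityGenes <- function(community) community@genes

#' @rdname communityProfile
#' @export
communityTaxonomy <- function(community) community@taxonomy

setMethod("show", "SyntheticCommunity", function(object) {
  cat("SyntheticCommunity (", object@complexity, "): ",
      nrow(object@profile), " species, ",
      length(object@genes), " genes over ",
      sum(Biostrings::width(object@genomes)), " bp\n", sep = "")
})

#' Write community files (genomes FASTA, genes GFF3, abundance TSV)
#'
#' @param community A [SyntheticCommunity].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeCommunity <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genomes.fasta")
  Biostrings::writeXStringSet(community@genomes, fa)
  gff <- file.path(dir, "genes.gff3")
  g <- community@genes
  writeLines(c("##gff-version 3", sprintf(
    "%s\tpairedLCA\tgene\t%d\t%d\t.\t%s\t.\tID=%s;taxon_id=%d",
    as.character(GenomicRanges::seqnames(g)),
    GenomicRanges::start(g), GenomicRanges::end(g),
    as.character(GenomicRanges::strand(g)),
    g$gene_id, g$taxon_id)), gff)
  ab <- file.path(dir, "abundance.tsv")
  writeTsv(community@profile, ab)
  tx <- file.path(dir, "taxonomy.tsv")
  writeTaxonomy(community@taxonomy, tx)
  invisible(c(genomes = fa, genes = gff, abundance = ab, taxonomy = tx))
}
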