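## Clone sampling and read sequencing: Illumina 75 bp pairs with a
## positional substitution profile; flow-cycle 454-like single reads.

#' Clone library spec constructor
#'
#' The two Illumina protocols modelled here are short clones,
#' Normal(200, 20) bp, and long clones, Normal(1900, 300) bp, both read
#' with 75 bp mates from either end.
#'
#' @param mu Mean clone length (bp).
#' @param sigma Standard deviation (bp).
#' @param readLength Read length (bp, default 75).
#' @param paired Sequence both clone ends (default TRUE).
#' @return A [CloneLibrarySpec].
#' @examples
#' shortClones <- cloneLibrarySpec(200, 20)
#' longClones  <- cloneLibrarySpec(1900, 300)
#' @export
cloneLibrarySpec <- function(mu, sigma, readLength = 75L, paired = TRUE) {
  new("CloneLibrarySpec", mu = mu, sigma = sigma,
      readLength = as.integer(readLength), paired = paired)
}

#' Sample clones from a community
#'
#' Source taxa are drawn proportional to abundance times genome length;
#' clone lengths are Normal(mu, sigma), rounded and truncated to
#' [2 * readLength, genome length] ([readLength, genome length] for
#' unpaired specs); start positions are uniform and both strands equally
#' likely. Taxa whose genome is shorter than the minimum clone are skipped
#' with a warning.
#'
#' @param community A [SyntheticCommunity].
#' @param librarySpec A [CloneLibrarySpec].
#' @param nClones Number of clones to draw.
#' @param seed Optional integer seed.
#' @return data.frame with columns \code{clone_id}, \code{taxon_id},
#'   \code{genome}, \code{start}, \code{end}, \code{length},
#'   \code{strand} (1-based inclusive genome coordinates).
#' @export
sampleClones <- function(community, librarySpec, nClones, seed = NULL) {
  stopifnot(nClones >= 1)
  withSeed(seed, {
    prof <- community@profile
    glen <- stats::setNames(Biostrings::width(community@genomes),
                            names(community@genomes))[prof$genome]
    minLen <- (if (librarySpec@paired) 2L else 1L) * librarySpec@readLength
    usable <- glen >= minLen
    if (!all(usable)) {
      warning("skipping ", sum(!usable), " taxa with genomes shorter than ",
              minLen, " bp")
      prof <- prof[usable, , drop = FALSE]
      glen <- glen[usable]
      if (!nrow(prof)) stop("no genome long enough for this library")
    }
    w <- prof$abundance * glen
    pick <- sample.int(nrow(prof), nClones, replace = TRUE, prob = w)
    len <- round(stats::rnorm(nClones, librarySpec@mu, librarySpec@sigma))
    len <- pmin(pmax(len, minLen), glen[pick])
    start <- floor(stats::runif(nClones) * (glen[pick] - len + 1)) + 1L
    data.frame(clone_id = sprintf("clone_%06d", seq_len(nClones)),
               taxon_id = prof$taxon_id[pick],
               genome = prof$genome[pick],
               start = as.integer(start),
               end = as.integer(start + len - 1),
               length = as.integer(len),
               strand = sample(c("+", "-"), nClones, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Illumina error model constructor
#'
#' @param a,b,c Regression constants of the fitted positional profile
#'   f(x) = a * exp(b * x) + c (defaults 3.957e-4, 1.319e-1, 5.362e-3).
#' @param profileDomain Length of the fitted profile (default 36).
#' @return An [IlluminaErrorModel].
#' @export
illuminaErrorModel <- function(a = 3.957e-4, b = 1.319e-1, c = 5.362e-3,
                               profileDomain = 36L) {
  new("IlluminaErrorModel", a = a, b = b, c = c,
      profileDomain = as.integer(profileDomain))
}

#' Per-position substitution probability
#'
#' Evaluates the fitted profile at position \code{t} of an \code{L} bp
#' read, stretching the 36-position domain proportionally:
#' x = profileDomain * t / L. Monotone non-decreasing in t; the last
#' position of any read length maps to f(profileDomain). Averaged over a
#' 75 bp read the default model gives a substitution rate of about 1.5
#' percent.
#'
#' @param t Position(s) in 1..L.
#' @param L Read length.
#' @param model An [IlluminaErrorModel].
#' @return Substitution probability/ies.
#' @export
illuminaErrorProbability <- function(t, L, model = illuminaErrorModel()) {
  if (any(t < 1 | t > L)) stop("argument error: position out of 1..L")
  x <- model@profileDomain * t / L
  model@a * exp(model@b * x) + model@c
}

## Substitute bases of a character-matrix of reads in place; returns the
## mutated matrix plus per-read substitution counts.
substituteBases <- function(mat, pPos) {
  n <- nrow(mat); L <- ncol(mat)
  u <- matrix(stats::runif(n * L), n, L)
  hit <- u < matrix(pPos, n, L, byrow = TRUE)
  idx <- which(hit)
  if (length(idx)) {
    alphabet <- c("A", "C", "G", "T")
    cur <- match(mat[idx], alphabet)
    ## shift by 1..3 positions in the alphabet: uniform over the other 3
    repl <- ((cur - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
    mat[idx] <- alphabet[repl]
  }
  list(mat = mat, nSub = as.integer(rowSums(hit)))
}

collapseRows <- function(mat) {
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Sequence Illumina read pairs from clones
#'
#' Mate 1 is the first \code{readLength} bases of the clone and mate 2 the
#' reverse complement of its last \code{readLength} bases
#' (forward-reverse orientation). Errors are substitutions only - each
#' base is substituted with probability [illuminaErrorProbability()] at
#' its read position, the replacement uniform over the three other bases -
#' so reads contain no insertions or deletions, matching the structure of
#' the short-read error tables. Read ids are \code{<clone_id>/1} and
#' \code{<clone_id>/2}.
#'
#' @param community A [SyntheticCommunity].
#' @param clones Clone data.frame from [sampleClones()].
#' @param readLength Read length in bp (default 75).
#' @param model An [IlluminaErrorModel]; pass
#'   \code{illuminaErrorModel(0, 0, 0)} wouldn't validate, use
#'   \code{errorFree = TRUE} for error-free reads instead.
#' @param errorFree If TRUE no substitutions are applied.
#' @param seed Optional integer seed.
#' @return A list: \code{reads} ([Biostrings::DNAStringSet], two entries
#'   per clone), \code{truth} (data.frame: read_id, pair_id, mate,
#'   taxon_id, genome, start, end, strand, n_substitutions) and
#'   \code{stats} (list mirroring the run-statistics table: reads, bases,
#'   insertions, deletions, substitutions and their percentages).
#' @export
sequenceIlluminaPairs <- function(community, clones, readLength = 75L,
                                  model = illuminaErrorModel(),
                                  errorFree = FALSE, seed = NULL) {
  stopifnot(all(clones$length >= 2L * readLength))
  withSeed(seed, {
    gen <- community@genomes
    genSeq <- as.character(gen)[clones$genome]
    ## genome-coordinate windows of the two mates
    fwdStart <- clones$start                  # window at clone 5' (genome +)
    revStart <- clones$end - readLength + 1L  # window at clone 3'
    winA <- substring(genSeq, fwdStart, fwdStart + readLength - 1L)
    winB <- substring(genSeq, revStart, clones$end)
    plus <- clones$strand == "+"
    ## on + clones mate1 reads winA forward, mate2 is revcomp(winB);
    ## on - clones mate1 is revcomp(winB), mate2 reads winA forward
    rc <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x)))
    mate1 <- ifelse(plus, winA, rc(winB))
    mate2 <- ifelse(plus, rc(winB), winA)
    n <- nrow(clones)
    toMat <- function(s) matrix(unlist(strsplit(s, "", fixed = TRUE),
                                       use.names = FALSE),
                                nrow = length(s), byrow = TRUE)
    m1 <- toMat(mate1); m2 <- toMat(mate2)
    if (errorFree) {
      n1 <- n2 <- integer(n)
    } else {
      pPos <- illuminaErrorProbability(seq_len(readLength), readLength, model)
      s1 <- substituteBases(m1, pPos); m1 <- s1$mat; n1 <- s1$nSub
      s2 <- substituteBases(m2, pPos); m2 <- s2$mat; n2 <- s2$nSub
    }
    reads <- Biostrings::DNAStringSet(c(collapseRows(m1), collapseRows(m2)))
    names(reads) <- c(paste0(clones$clone_id, "/1"),
                      paste0(clones$clone_id, "/2"))
    truth <- data.frame(
      read_id = names(reads),
      pair_id = rep(clones$clone_id, 2L),
      mate = rep(1:2, each = n),
      taxon_id = rep(clones$taxon_id, 2L),
      genome = rep(clones$genome, 2L),
      start = c(ifelse(plus, fwdStart, revStart),
                ifelse(plus, revStart, fwdStart)),
      end = c(ifelse(plus, fwdStart, revStart),
              ifelse(plus, revStart, fwdStart)) + readLength - 1L,
      strand = c(ifelse(plus, "+", "-"), ifelse(plus, "-", "+")),
      n_substitutions = c(n1, n2),
      stringsAsFactors = FALSE)
    bases <- 2L * n * readLength
    subs <- sum(n1) + sum(n2)
    list(reads = reads, truth = truth,
         stats = list(reads = 2L * n, bases = bases,
                      read_length = readLength,
                      insertions = 0L, deletions = 0L,
                      substitutions = subs,
                      insertion_pct = 0, deletion_pct = 0,
                      substitution_pct = 100 * subs / bases))
  })
}

#' Flow-cycle spec constructor for 454-style reads
#'
#' @param flowCycles Passes over the flow order (default 98, ~250 bp
#'   reads).
#' @param flowOrder Four-letter flow order (default "TACG").
#' @param homopolymerNoiseSd Homopolymer call-noise constant (default
#'   0.217; calibrated once against the ~2.3 percent insertion / ~0.5
#'   percent deletion rates of flow-cycle simulation on random sequence).
#' @param callBias Fixed positive call-length bias modelling flow
#'   carry-forward (default 0.035); this is what skews miscalls towards
#'   insertions.
#' @return A [Flow454Spec].
#' @export
flow454Spec <- function(flowCycles = 98L, flowOrder = "TACG",
                        homopolymerNoiseSd = 0.217, callBias = 0.035) {
  new("Flow454Spec", flowCycles = as.integer(flowCycles),
      flowOrder = flowOrder, homopolymerNoiseSd = homopolymerNoiseSd,
      callBias = callBias)
}

## Simulate one 454 read from a template string. Walks the homopolymer
## runs of the template; the flow reaching run i is determined by the
## cyclic distance between consecutive run bases in the flow order, and
## the intervening zero flows may insert bases of their own nucleotide.
flowRead <- function(template, spec) {
  flowOrder <- strsplit(spec@flowOrder, "")[[1]]
  totalFlows <- 4L * spec@flowCycles
  r <- rle(strsplit(template, "")[[1]])
  k <- length(r$values)
  posInOrder <- match(r$values, flowOrder)
  ## cyclic flow distance from previous run's flow (first run: from slot 0)
  dist <- ((posInOrder - c(0L, posInOrder[-k]) - 1L) %% 4L) + 1L
  flowAt <- cumsum(dist)
  use <- flowAt <= totalFlows
  if (!any(use)) {
    return(list(read = "", nIns = 0L, nDel = 0L, refBases = 0L))
  }
  k <- max(which(use))
  lens <- r$lengths[seq_len(k)]
  bases <- r$values[seq_len(k)]
  sd <- spec@homopolymerNoiseSd
  bias <- spec@callBias
  called <- pmax(0L, as.integer(round(stats::rnorm(k, lens + bias, sd))))
  ## zero flows between runs: each may miscall a positive length
  gapFlows <- dist[seq_len(k)] - 1L
  z <- sum(gapFlows)
  inserted <- character(0)
  insCount <- 0L
  if (z > 0L && sd > 0) {
    zCalled <- pmax(0L, as.integer(round(stats::rnorm(z, bias, sd))))
    if (any(zCalled > 0L)) {
      ## identify the nucleotide of each zero flow
      runIdx <- rep(seq_len(k), gapFlows)
      offset <- unlist(lapply(gapFlows[gapFlows > 0L], seq_len),
                       use.names = FALSE)
      prevPos <- c(0L, posInOrder[-length(posInOrder)])[runIdx]
      zNuc <- flowOrder[((prevPos + offset - 1L) %% 4L) + 1L]
      ins <- zCalled > 0L
      insCount <- sum(zCalled[ins])
      ## interleave: inserted homopolymers come right before their run
      pieces <- character(k)
      insStr <- vapply(which(ins), function(i)
        strrep(zNuc[i], zCalled[i]), character(1))
      for (j in seq_along(insStr)) {
        i <- runIdx[which(ins)[j]]
        pieces[i] <- paste0(pieces[i], insStr[j])
      }
      read <- paste0(paste0(pieces, strrep(bases, called)), collapse = "")
      nIns <- insCount + sum(pmax(called - lens, 0L))
      nDel <- sum(pmax(lens - called, 0L))
      return(list(read = read, nIns = nIns, nDel = nDel,
                  refBases = sum(lens)))
    }
  }
  read <- paste0(strrep(bases, called), collapse = "")
  list(read = read, nIns = sum(pmax(called - lens, 0L)),
       nDel = sum(pmax(lens - called, 0L)), refBases = sum(lens))
}

#' Sequence 454-style single reads from clones
#'
#' Models the flow-cycle base-calling procedure: the template is read
#' homopolymer by homopolymer as flows of the four nucleotides cycle in
#' the flow order; the called length of each homopolymer of true length l
#' is round(Normal(l + bias, sd)) clamped at zero. Miscalls therefore
#' produce insertions and deletions but never substitutions; the small
#' positive bias skews them towards insertions, as in flow-cycle data.
#' The read ends when the flows are exhausted, which with 98 cycles gives
#' reads of roughly 250 bp.
#'
#' @param community A [SyntheticCommunity].
#' @param clones Clone data.frame from [sampleClones()] (use an unpaired
#'   [cloneLibrarySpec()] with mu comfortably above the expected read
#'   length).
#' @param flowSpec A [Flow454Spec].
#' @param seed Optional integer seed.
#' @return A list: \code{reads} ([Biostrings::DNAStringSet], one per
#'   clone), \code{truth} (read_id, taxon_id, genome, start, end, strand,
#'   n_insertions, n_deletions) and \code{stats} (reads, bases, average
#'   read length, insertion/deletion/substitution counts and percentages;
#'   substitutions always 0).
#' @export
sequence454Reads <- function(community, clones, flowSpec = flow454Spec(),
                             seed = NULL) {
  withSeed(seed, {
    genSeq <- as.character(community@genomes)[clones$genome]
    tmpl <- substring(genSeq, clones$start, clones$end)
    minus <- clones$strand == "-"
    if (any(minus))
      tmpl[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(tmpl[minus])))
    out <- lapply(tmpl, flowRead, spec = flowSpec)
    reads <- Biostrings::DNAStringSet(vapply(out, `[[`, character(1), "read"))
    names(reads) <- clones$clone_id
    nIns <- vapply(out, `[[`, integer(1), "nIns")
    nDel <- vapply(out, `[[`, integer(1), "nDel")
    truth <- data.frame(read_id = clones$clone_id,
                        taxon_id = clones$taxon_id,
                        genome = clones$genome,
                        start = clones$start, end = clones$end,
                        strand = clones$strand,
                        n_insertions = nIns, n_deletions = nDel,
                        stringsAsFactors = FALSE)
    bases <- sum(Biostrings::width(reads))
    list(reads = reads, truth = truth,
         stats = list(reads = length(reads), bases = bases,
                      mean_read_length = bases / length(reads),
                      insertions = sum(nIns), deletions = sum(nDel),
                      substitutions = 0L,
                      insertion_pct = 100 * sum(nIns) / bases,
                      deletion_pct = 100 * sum(nDel) / bases,
                      substitution_pct = 0))
  })
}

#' Write reads to FASTQ (constant quality) or FASTA
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param format "fastq" or "fasta".
#' @param quality Constant Phred+33 quality character for FASTQ output
#'   (default "?", Q30).
#' @return The path, invisibly.
#' @export
writeReads <- function(reads, path, format = c("fastq", "fasta"),
                       quality = "?") {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads, path)
  } else {
    q <- Biostrings::BStringSet(strrep(quality, Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  }
  invisible(path)
}
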