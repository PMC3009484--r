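test_that("community abundance structure follows the complexity class", {
  hc <- makeSyntheticCommunity(104, "HC", genomeLength = 5000, seed = 1)
  expect_equal(communityProfile(hc)$abundance, rep(1 / 104, 104))

  lc <- makeSyntheticCommunity(10, "LC", dominanceRatio = 20,
                               genomeLength = 5000, seed = 1)
  ab <- sort(communityProfile(lc)$abundance, decreasing = TRUE)
  expect_equal(ab[1] / ab[2], 20)
  expect_equal(sum(ab), 1)

  mc <- makeSyntheticCommunity(20, "MC", dominanceRatio = 10,
                               genomeLength = 5000, seed = 1)
  abm <- communityProfile(mc)$abundance
  expect_equal(sum(abm > 2 * min(abm)), 6L)

  expect_error(makeSyntheticCommunity(10, "LC", genomeLength = 5000),
               "dominanceRatio")
  expect_error(makeSyntheticCommunity(5, "MC", dominanceRatio = 10),
               "at least 7")
})

test_that("community generation is byte-identical under a fixed seed", {
  a <- makeSyntheticCommunity(8, "HC", genomeLength = 8000, seed = 99)
  b <- makeSyntheticCommunity(8, "HC", genomeLength = 8000, seed = 99)
  expect_identical(as.character(communityGenomes(a)),
                   as.character(communityGenomes(b)))
  expect_identical(as.data.frame(communityGenes(a)),
                   as.data.frame(communityGenes(b)))
})

test_that("gene tiling respects the annotation spec", {
  comm <- makeSyntheticCommunity(10, "HC", genomeLength = 50000, seed = 3)
  g <- communityGenes(comm)
  w <- IRanges::width(g)
  expect_true(all(w >= 100))
  expect_gt(length(w), 200)
  expect_equal(mean(w), 950, tolerance = 0.1)
  # gaps between consecutive genes on one genome lie in [50, 150]
  df <- as.data.frame(g)
  one <- df[df$seqnames == df$seqnames[1], ]
  gaps <- one$start[-1] - one$end[-nrow(one)] - 1
  expect_true(all(gaps >= 50 & gaps <= 150))
})

test_that("clone length moments recover the library spec", {
  comm <- makeSyntheticCommunity(10, "HC", genomeLength = 20000, seed = 4)
  cl <- sampleClones(comm, cloneLibrarySpec(200, 20), 10000, seed = 5)
  expect_lt(abs(mean(cl$length) - 200), 1)
  expect_lt(abs(sd(cl$length) - 20), 1)
  # sigma = 0 gives exactly mu
  cl0 <- sampleClones(comm, cloneLibrarySpec(200, 0), 100, seed = 6)
  expect_true(all(cl0$length == 200))
  # single-source community
  lc <- makeSyntheticCommunity(10, "LC", dominanceRatio = 1e9,
                               genomeLength = 20000, seed = 4)
  clA <- sampleClones(lc, cloneLibrarySpec(200, 20), 200, seed = 7)
  expect_equal(length(unique(clA$taxon_id)), 1L)
})

test_that("positional error profile is stretched to the read length", {
  m <- illuminaErrorModel()
  f36 <- 3.957e-4 * exp(0.1319 * 36) + 5.362e-3
  expect_equal(illuminaErrorProbability(36, 36, m), f36, tolerance = 1e-10)
  expect_equal(illuminaErrorProbability(75, 75, m), f36, tolerance = 1e-10)
  p <- illuminaErrorProbability(1:75, 75, m)
  expect_true(all(diff(p) >= 0))
  expect_error(illuminaErrorProbability(76, 75, m), "out of")
  flat <- illuminaErrorModel(a = 1e-12, b = 1e-6, c = 0.01)
  expect_equal(illuminaErrorProbability(40, 75, flat), 0.01,
               tolerance = 1e-6)
})

test_that("Illumina pairs carry substitutions only, at the profile rate", {
  comm <- makeSyntheticCommunity(10, "HC", genomeLength = 20000, seed = 8)
  cl <- sampleClones(comm, cloneLibrarySpec(200, 20), 5000, seed = 9)
  sim <- sequenceIlluminaPairs(comm, cl, seed = 10)
  expect_equal(sim$stats$reads, 10000L)
  expect_equal(sim$stats$bases, 750000L)
  expect_equal(sim$stats$insertions, 0L)
  expect_equal(sim$stats$deletions, 0L)
  expect_true(all(Biostrings::width(sim$reads) == 75L))
  # realized substitution rate ~1.5% (profile mean 1.52%)
  expect_lt(abs(sim$stats$substitution_pct - 1.5), 0.2)
  # error-free mode reproduces the clone ends exactly
  ef <- sequenceIlluminaPairs(comm, cl[1:50, ], errorFree = TRUE, seed = 11)
  expect_equal(ef$stats$substitutions, 0L)
  g <- as.character(communityGenomes(comm))[cl$genome[1]]
  plus <- cl$strand[1] == "+"
  m1 <- as.character(ef$reads[[1]])
  win5 <- substring(g, cl$start[1], cl$start[1] + 74)
  win3 <- substring(g, cl$end[1] - 74, cl$end[1])
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  expect_equal(m1, unname(if (plus) win5 else rc(win3)))
})

test_that("truth manifest is complete and consistent", {
  comm <- makeSyntheticCommunity(10, "HC", genomeLength = 20000, seed = 12)
  cl <- sampleClones(comm, cloneLibrarySpec(200, 20), 300, seed = 13)
  sim <- sequenceIlluminaPairs(comm, cl, seed = 14)
  expect_equal(anyDuplicated(sim$truth$read_id), 0L)
  expect_equal(nrow(sim$truth), 600L)
  expect_equal(sum(table(sim$truth$taxon_id)), 600L)
  expect_equal(sum(sim$truth$n_substitutions), sim$stats$substitutions)
  # mate windows lie inside the clone
  tr <- merge(sim$truth, cl, by.x = "pair_id", by.y = "clone_id")
  expect_true(all(tr$start.x >= tr$start.y & tr$end.x <= tr$end.y))
})

test_that("454 reads contain indels but never substitutions", {
  comm <- makeSyntheticCommunity(15, "HC", genomeLength = 30000, seed = 15)
  cl <- sampleClones(comm, cloneLibrarySpec(400, 30, readLength = 250L,
                                            paired = FALSE), 6000, seed = 16)
  sim <- sequence454Reads(comm, cl, seed = 17)
  expect_equal(sim$stats$substitutions, 0L)
  expect_gt(sim$stats$mean_read_length, 240)
  expect_lt(sim$stats$mean_read_length, 290)
  # calibrated rates bracket the flow-cycle error profile
  expect_gt(sim$stats$insertion_pct, 1.5)
  expect_lt(sim$stats$insertion_pct, 3.5)
  expect_gt(sim$stats$deletion_pct, 0.2)
  expect_lt(sim$stats$deletion_pct, 1.0)
  # noise-free flows reproduce the template prefix
  quiet <- flow454Spec(homopolymerNoiseSd = 0)
  one <- sequence454Reads(comm, cl[1, , drop = FALSE], quiet, seed = 18)
  g <- as.character(communityGenomes(comm))[cl$genome[1]]
  tmpl <- substring(g, cl$start[1], cl$end[1])
  if (cl$strand[1] == "-")
    tmpl <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tmpl)))
  r <- as.character(one$reads[[1]])
  expect_equal(r, substring(tmpl, 1, nchar(r)))
  expect_equal(one$stats$insertions, 0L)
  expect_equal(one$stats$deletions, 0L)
})
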