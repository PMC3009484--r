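test_that("combined bit score follows the pair-sum correction", {
  p <- combinedScoreParams()
  # s1 = s2 = 50, m = 450 nt (m' = 150 aa), n = 300:
  # 100 - log2(0.041 * 50 * 150 * 300) = 83.50674, checked by direct
  # arithmetic independent of the implementation
  expect_equal(combinedBitScore(50, 50, p, m = 450, n = 300),
               100 - log2(0.041 * 50 * 150 * 300), tolerance = 1e-12)
  expect_equal(combinedBitScore(50, 50, p, m = 450, n = 300), 83.50674,
               tolerance = 1e-5)
  # clamp: correction exceeding the weaker score falls back to the best
  pBig <- combinedScoreParams(g = 1e12)
  expect_equal(combinedBitScore(50, 48, pBig, m = 450, n = 300), 50)
  # symmetry and monotonicity
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 30, 90); b <- runif(1, 30, 90)
    expect_equal(combinedBitScore(a, b, p), combinedBitScore(b, a, p))
    expect_gte(combinedBitScore(a + 1, b, p), combinedBitScore(a, b, p))
  }
  # translated vs nucleotide effective lengths
  pNt <- combinedScoreParams(translated = FALSE)
  expect_lt(combinedBitScore(50, 50, pNt, m = 450, n = 300),
            combinedBitScore(50, 50, p, m = 450, n = 300))
  expect_error(combinedBitScore(50, 50, combinedScoreParams(h = 500)),
               "effective length")
})

test_that("pairReads groups mates and flags ambiguity", {
  pr <- pairReads(c("c7/1", "c7/2"))
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$pairs$pair_id, "c7")
  expect_equal(length(pr$unpaired), 0L)

  pr2 <- pairReads(c("c7/1"))
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(pr2$unpaired, "c7/1")

  pr3 <- pairReads(c("a_1", "a_2", "b.1", "b.2", "solo"))
  expect_equal(sort(pr3$pairs$pair_id), c("a", "b"))
  expect_equal(pr3$unpaired, "solo")

  expect_error(pairReads(c("x/1", "x/2", "x_1")), "ambiguity")
})

test_that("simulated clone libraries pair completely", {
  comm <- makeSyntheticCommunity(10, "HC", genomeLength = 12000, seed = 5)
  cl <- sampleClones(comm, cloneLibrarySpec(200, 20), 500, seed = 6)
  sim <- sequenceIlluminaPairs(comm, cl, seed = 7)
  pr <- pairReads(sim$truth$read_id)
  expect_equal(nrow(pr$pairs), 500L)
  expect_equal(length(pr$unpaired), 0L)
})

test_that("mate merging unions taxa and never lowers a doubly-hit score", {
  p <- combinedScoreParams()
  df1 <- mkMatches(c(100, 200), c(50, 48), query = "c1/1")
  df2 <- mkMatches(c(100, 300), c(50, 47), query = "c1/2",
                   subjects = c("t1", "t2"))
  merged <- mergeMateMatches(df1, df2, p)
  expect_setequal(merged$taxon_id, c(100L, 200L, 300L))
  comb <- merged[merged$taxon_id == 100, ]
  expect_true(comb$combined)
  expect_gte(comb$bit_score, 50)
  # degenerate pair: empty mate behaves as single-read mode
  expect_equal(mergeMateMatches(df1, NULL, p)$bit_score, df1$bit_score)
  expect_null(mergeMateMatches(NULL, NULL, p))
})

test_that("assignPair is more specific than single-read LCA on the fixture", {
  tax <- tinyTaxonomy()
  params <- assignmentParams(topPercent = 10)
  # mate1 hits a1 (50) and a2 (48); mate2 hits a1 (50).
  df1 <- mkMatches(c(11, 12), c(50, 48), query = "c1/1")
  df2 <- mkMatches(11, 50, query = "c1/2")
  single <- assignRead(tax, df1, params)
  expect_equal(single$taxon_id, 10L)   # lca(a1, a2) = genus
  paired <- assignPair(tax, df1, df2, params)
  expect_equal(paired$taxon_id, 11L)   # combined ~83.5 passes alone
  # both mates on one taxon
  expect_equal(assignPair(tax, mkMatches(11, 50), mkMatches(11, 50),
                          params)$taxon_id, 11L)
})

test_that("paired assignments are at least as deep as single-read ones", {
  tax <- makeSyntheticTaxonomy(50, seed = 9)
  fix <- decoyMatchTable(tax, 200, seed = 10)
  params <- assignmentParams(minScore = 35, topPercent = 10)
  paired <- assignReadsPaired(tax, fix$table, params)
  single <- assignReads(tax, fix$table, params)
  pa <- assignments(paired)
  sa <- assignments(single)
  depthOf <- function(t) ifelse(is.na(t), -1, unname(taxonDepth(tax, t)))
  # compare each pair against its mate-1 single-read assignment
  d_pair <- depthOf(pa$taxon_id)
  d_single <- depthOf(sa$taxon_id[match(paste0(pa$query_id, "/1"),
                                        sa$query_id)])
  expect_gte(mean(d_pair >= d_single), 0.95)
})

test_that("paired accounting modes count pairs once or twice", {
  tax <- tinyTaxonomy()
  m <- rbind(mkMatches(11, 60, query = "c1/1"),
             mkMatches(11, 58, query = "c1/2"))
  mt <- MatchTable(m)
  byPair <- assignReadsPaired(tax, mt, accounting = "pair")
  byRead <- assignReadsPaired(tax, mt, accounting = "read")
  expect_equal(sum(assignedCounts(byPair)$count), 1L)
  expect_equal(sum(assignedCounts(byRead)$count), 2L)
})
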