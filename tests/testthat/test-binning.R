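test_that("min score filter uses an inclusive boundary", {
  df <- mkMatches(1:3, c(34.9, 35.0, 60))
  kept <- filterMinScore(df, 35)
  expect_equal(kept$bit_score, c(35.0, 60))
  expect_equal(filterMinScore(df, 0), df)
  # brute-force oracle on random scores
  set.seed(5)
  s <- round(runif(50, 20, 80), 1)
  df <- mkMatches(seq_along(s), s, subjects = paste0("s", seq_along(s)))
  expect_equal(filterMinScore(df, 40)$bit_score, s[s >= 40])
})

test_that("top percent filter keeps scores within the band of the best", {
  df <- mkMatches(1:3, c(100, 92, 89))
  expect_equal(filterTopPercent(df, 10)$bit_score, c(100, 92))
  expect_equal(nrow(filterTopPercent(df[1, ], 10)), 1L)   # singleton kept
  expect_equal(filterTopPercent(df, 100), df)             # 100% = identity
})

test_that("assignRead runs the pipeline and distinguishes its buckets", {
  tax <- tinyTaxonomy()
  # both species of genus A survive -> LCA is the genus
  a <- assignRead(tax, mkMatches(c(11, 12), c(55, 54)))
  expect_equal(a$taxon_id, 10L)
  expect_equal(a$status, "assigned")
  # singleton
  expect_equal(assignRead(tax, mkMatches(11, 60))$taxon_id, 11L)
  # top-percent excludes the weak cross-genus hit: threshold 54 > 40
  expect_equal(assignRead(tax, mkMatches(c(11, 21), c(60, 40)))$taxon_id, 11L)
  # no matches at all vs all-filtered
  expect_equal(assignRead(tax, NULL)$status, "no_hits")
  expect_equal(assignRead(tax, mkMatches(11, 20))$status, "unassigned")
})

test_that("assigned node is an ancestor-or-self of every surviving taxon", {
  set.seed(21)
  tax <- makeSyntheticTaxonomy(30, seed = 2)
  sp <- speciesIds(tax)
  for (i in 1:30) {
    taxa <- sample(sp, sample(1:5, 1))
    df <- mkMatches(taxa, runif(length(taxa), 40, 60),
                    subjects = paste0("s", seq_along(taxa)))
    a <- assignRead(tax, df, assignmentParams(topPercent = 100))
    expect_true(all(vapply(taxa, function(t)
      isInClade(tax, t, a$taxon_id), logical(1))))
  }
})

test_that("min support clears weak taxa into UNASSIGNED, inclusively", {
  tax <- tinyTaxonomy()
  m <- rbind(
    do.call(rbind, lapply(1:5, function(i)
      mkMatches(11, 60, query = paste0("a", i)))),
    do.call(rbind, lapply(1:2, function(i)
      mkMatches(21, 60, query = paste0("b", i)))))
  res <- assignReads(tax, MatchTable(m), assignmentParams(minSupport = 3))
  counts <- assignedCounts(res)
  expect_equal(counts$taxon_id, 11L)
  expect_equal(counts$count, 5L)
  expect_equal(assignmentTallies(res)$unassigned, 2L)
  # boundary: exactly minSupport reads survive
  res3 <- assignReads(tax, MatchTable(m[m$taxon_id == 11, ][1:3, ]),
                      assignmentParams(minSupport = 3))
  expect_equal(assignedCounts(res3)$count, 3L)
  # minSupport = 1 is the identity
  res1 <- assignReads(tax, MatchTable(m), assignmentParams())
  expect_equal(sum(assignedCounts(res1)$count), 7L)
})

test_that("conservation identity holds and queryIds adds NO_HITS", {
  tax <- tinyTaxonomy()
  mt <- MatchTable(mkMatches(11, 60, query = "r1"))
  res <- assignReads(tax, mt, queryIds = c("r1", "r2", "r3"))
  t <- assignmentTallies(res)
  expect_equal(t$assigned + t$unassigned + t$no_hits, t$queries)
  expect_equal(t$no_hits, 2L)
})

test_that("stricter filters never increase species-level assignments", {
  set.seed(31)
  tax <- makeSyntheticTaxonomy(20, seed = 3)
  sp <- speciesIds(tax)
  rows <- do.call(rbind, lapply(1:120, function(i) {
    taxa <- sample(sp, sample(1:3, 1))
    mkMatches(taxa, runif(length(taxa), 30, 70), query = paste0("q", i),
              subjects = paste0("s", i, "_", seq_along(taxa)))
  }))
  mt <- MatchTable(rows)
  nSpecies <- function(params) {
    r <- assignReads(tax, mt, params)
    c <- assignedCounts(r)
    sum(c$count[c$taxon_id %in% sp])
  }
  base <- nSpecies(assignmentParams(minScore = 35, topPercent = 10))
  expect_lte(nSpecies(assignmentParams(minScore = 50)), base)
  expect_lte(nSpecies(assignmentParams(minSupport = 5)), base)
  # a stricter (smaller) top percent keeps fewer taxa per read, so the
  # LCA can only get deeper: species-level assignments never shrink
  expect_gte(nSpecies(assignmentParams(topPercent = 5)), base)
})

test_that("excluded clades never receive assignments", {
  tax <- tinyTaxonomy()
  params <- assignmentParams(excludedClades = 10L)
  # read hitting only genus A members ends up unassigned
  expect_equal(assignRead(tax, mkMatches(c(11, 12), c(55, 54)),
                          params)$status, "unassigned")
  # mixed read falls back to the surviving taxon
  a <- assignRead(tax, mkMatches(c(11, 21), c(55, 54)), params)
  expect_equal(a$taxon_id, 21L)
})

test_that("min support can promote reads to the parent when asked", {
  tax <- tinyTaxonomy()
  m <- rbind(do.call(rbind, lapply(1:2, function(i)
    mkMatches(11, 60, query = paste0("a", i)))),
    do.call(rbind, lapply(1:3, function(i)
      mkMatches(12, 60, query = paste0("c", i)))))
  res <- assignReads(tax, MatchTable(m),
                     assignmentParams(minSupport = 5, promoteToParent = TRUE))
  # both species fail alone; promoted to genus A which then holds 5 reads
  counts <- assignedCounts(res)
  expect_equal(counts$taxon_id, 10L)
  expect_equal(counts$count, 5L)
})
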