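# Shared fixture: one simulated HC community run through the single-read
# pipeline, reused by several blocks below.
evalFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    comm <- makeSyntheticCommunity(20, "HC", genomeLength = 20000, seed = 40)
    cl <- sampleClones(comm, cloneLibrarySpec(200, 20), 1500, seed = 41)
    sim <- sequenceIlluminaPairs(comm, cl, seed = 42)
    mt <- simulateMatchTable(comm, sim$truth, seed = 43)
    res <- assignReads(communityTaxonomy(comm), mt,
                       queryIds = sim$truth$read_id)
    cache <<- list(comm = comm, sim = sim, mt = mt, res = res)
    cache
  }
})

test_that("species detection is plain set algebra over detected taxa", {
  fx <- evalFixture()
  tax <- communityTaxonomy(fx$comm)
  truth <- unique(fx$sim$truth$taxon_id)
  det <- speciesDetection(fx$res, truth, tax)
  expect_length(intersect(det$falsePositives, det$falseNegatives), 0)
  expect_setequal(det$detected,
                  union(setdiff(truth, det$falseNegatives),
                        det$falsePositives))
  # species-specific construction: every sampled species is detected
  expect_length(det$falseNegatives, 0)
  # synthetic truth/detected sets
  r <- fx$res
  r@countsAfter <- data.frame(taxon_id = det$detected[1], count = 5L)
  d2 <- speciesDetection(r, truth, tax)
  expect_equal(length(d2$falseNegatives), length(truth) - 1L)
})

test_that("rank histogram buckets conserve reads and normalise", {
  fx <- evalFixture()
  tax <- communityTaxonomy(fx$comm)
  h <- rankHistogram(fx$res, tax)
  expect_equal(sum(h$count), assignmentTallies(fx$res)$queries)
  hn <- rankHistogram(fx$res, tax, normalizeTo = 100000)
  expect_equal(sum(hn$count), 100000)
  # all reads on species nodes -> everything in the species bucket
  a <- assignments(fx$res)
  sp <- speciesIds(tax)
  allSpecies <- data.frame(query_id = c("x1", "x2"),
                           taxon_id = sp[1:2], status = "assigned")
  r <- pairedLCA:::buildResult(allSpecies)
  h2 <- rankHistogram(r, tax)
  expect_equal(h2$count[h2$bucket == "species"], 2)
  # a root assignment lands in the above-superkingdom bucket
  atRoot <- data.frame(query_id = "x", taxon_id = rootId(tax),
                       status = "assigned")
  h3 <- rankHistogram(pairedLCA:::buildResult(atRoot), tax)
  expect_equal(h3$count[h3$bucket == "above_superkingdom"], 1)
})

test_that("same-gene fraction separates short from long clones", {
  comm <- makeSyntheticCommunity(10, "HC", genomeLength = 30000, seed = 44)
  genes <- communityGenes(comm)
  short <- sequenceIlluminaPairs(
    comm, sampleClones(comm, cloneLibrarySpec(200, 20), 2000, seed = 45),
    seed = 46)
  long <- sequenceIlluminaPairs(
    comm, sampleClones(comm, cloneLibrarySpec(1900, 300), 2000, seed = 47),
    seed = 48)
  sgS <- sameGeneFraction(short$truth, genes)
  sgL <- sameGeneFraction(long$truth, genes)
  expect_gt(sgS$fraction, 0.8)
  expect_lt(sgL$fraction, 0.12)
  expect_lte(sgS$nSameGene, sgS$nBothInGenes)
  # a clone entirely inside one gene counts as same-gene
  g1 <- as.data.frame(genes)[1, ]
  tr <- data.frame(read_id = c("c/1", "c/2"), pair_id = "c", mate = 1:2,
                   genome = g1$seqnames,
                   start = c(g1$start, g1$start + 80),
                   end = c(g1$start + 74, g1$start + 154))
  expect_equal(sameGeneFraction(tr, genes)$fraction, 1)
  expect_error(sameGeneFraction(data.frame(genome = "g"), genes),
               "configuration error")
})

test_that("correct-assignment rate scores exact species identity", {
  fx <- evalFixture()
  tax <- communityTaxonomy(fx$comm)
  cr <- correctAssignmentRate(fx$res, fx$sim$truth, tax)
  expect_gte(cr$correctPct, 0)
  expect_lte(cr$correctPct + cr$falsePct, 100)
  expect_gte(cr$ancestorCreditPct, cr$correctPct)
  # all-unassigned result scores 0 / 0
  blank <- data.frame(query_id = fx$sim$truth$read_id,
                      taxon_id = NA_integer_, status = "unassigned")
  cr0 <- correctAssignmentRate(pairedLCA:::buildResult(blank),
                               fx$sim$truth, tax)
  expect_equal(cr0$correctPct, 0)
  expect_equal(cr0$falsePct, 0)
  # mismatched ids raise an integrity error
  bad <- data.frame(query_id = "ghost", taxon_id = NA_integer_,
                    status = "no_hits")
  expect_error(correctAssignmentRate(pairedLCA:::buildResult(bad),
                                     fx$sim$truth, tax),
               "integrity error")
})

test_that("min-support sweep trades false positives for false negatives", {
  fx <- evalFixture()
  tax <- communityTaxonomy(fx$comm)
  truth <- unique(fx$sim$truth$taxon_id)
  sw <- minSupportSweep(fx$res, truth, tax, c(1, 3, 10, 50, 100))
  expect_equal(nrow(sw), 5L)
  expect_true(all(diff(sw$n_fp) <= 0))
  expect_true(all(diff(sw$n_fn) >= 0))
  expect_error(minSupportSweep(fx$res, truth, tax, integer()), "empty")
})

test_that("excluding the source genus sends its reads to UNASSIGNED", {
  comm <- makeSyntheticCommunity(30, "HC", genomeLength = 20000, seed = 50)
  tax <- communityTaxonomy(comm)
  cl <- sampleClones(comm, cloneLibrarySpec(200, 20), 1500, seed = 51)
  sim <- sequenceIlluminaPairs(comm, cl, seed = 52)
  mt <- simulateMatchTable(comm, sim$truth, seed = 53)
  # pick the genus of the most-sampled species
  topSpecies <- as.integer(names(sort(table(sim$truth$taxon_id),
                                      decreasing = TRUE))[1])
  genus <- pairedLCA:::ancestorAtRank(tax, topSpecies, "genus")
  res <- assignReads(tax, mt,
                     assignmentParams(excludedClades = genus),
                     queryIds = sim$truth$read_id)
  a <- assignments(res)
  inGenus <- sim$truth$taxon_id[match(a$query_id, sim$truth$read_id)] %in%
    subtreeTaxa(tax, genus)
  # no read may be assigned inside the excluded clade
  assignedIn <- a$status == "assigned" &
    a$taxon_id %in% subtreeTaxa(tax, genus)
  expect_false(any(assignedIn))
  # reads from the excluded genus are predominantly unassigned, and the
  # species-level false positive rate stays small
  genusReads <- a[inGenus & a$status != "no_hits", ]
  expect_gt(mean(genusReads$status == "unassigned"), 0.5)
  det <- speciesDetection(res, unique(sim$truth$taxon_id), tax)
  expect_lt(det$fpRate, 0.05)
})
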