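# Fixtures built in code: a hand-laid small tree, an independent LCA
# oracle, random-tree and match-table generators.

# root(1) -> kingdom(2) -> genus A(10){a1=11, a2=12}, genus B(20){b1=21}
tinyTaxonomy <- function() {
  Taxonomy(data.frame(
    taxon_id = c(1L, 2L, 10L, 11L, 12L, 20L, 21L),
    parent_id = c(1L, 1L, 2L, 10L, 10L, 2L, 20L),
    rank = c("no-rank", "superkingdom", "genus", "species", "species",
             "genus", "species"),
    name = c("root", "kingdom", "genusA", "a1", "a2", "genusB", "b1")))
}

# Brute-force LCA oracle: explicit ancestor-path intersection on the raw
# node table, independent of the package's lock-step implementation.
oracleLca <- function(nodes, taxa) {
  pathOf <- function(t) {
    p <- t
    while (nodes$parent_id[nodes$taxon_id == t] != t) {
      t <- nodes$parent_id[nodes$taxon_id == t]
      p <- c(p, t)
    }
    p
  }
  paths <- lapply(taxa, pathOf)
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(t) length(pathOf(t)), integer(1))
  common[which.max(depths)]
}

# Random valid tree: node 1 is the root, every later node parents an
# earlier one (guarantees acyclicity); ranks drawn freely.
randomTree <- function(n, rankPool = c("no-rank", "phylum", "class",
                                       "order", "family", "genus",
                                       "species")) {
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                         integer(1)))
  data.frame(taxon_id = seq_len(n), parent_id = parent,
             rank = sample(rankPool, n, replace = TRUE),
             name = paste0("n", seq_len(n)))
}

# One-query match data.frame.
mkMatches <- function(taxa, scores, query = "r1",
                      subjects = paste0("s", seq_along(taxa))) {
  data.frame(query_id = query, subject_id = subjects,
             bit_score = scores, taxon_id = as.integer(taxa),
             subject_length = 300, query_length = 75,
             stringsAsFactors = FALSE)
}

# Small decoy community used by the paired-vs-single depth property: each
# pair truly comes from species `src`; both mates hit src (~50 bits) and
# each mate additionally hits one decoy species.
decoyMatchTable <- function(taxonomy, nPairs, seed) {
  set.seed(seed)
  species <- speciesIds(taxonomy)
  rows <- list()
  for (i in seq_len(nPairs)) {
    src <- sample(species, 1)
    decoys <- sample(setdiff(species, src), 2)
    s <- stats::rnorm(4, 50, 1.5)
    rows[[i]] <- data.frame(
      query_id = rep(c(sprintf("p%04d/1", i), sprintf("p%04d/2", i)),
                     each = 2),
      subject_id = paste0("sub", i, "_", 1:4),
      bit_score = pmax(s, 40),
      taxon_id = c(src, decoys[1], src, decoys[2]),
      subject_length = 300, query_length = 75,
      stringsAsFactors = FALSE)
  }
  list(table = MatchTable(do.call(rbind, rows)),
       src = NULL)
}
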