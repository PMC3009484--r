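# pairedLCA

Taxonomic binning of shotgun metagenomic reads with the
lowest-common-ancestor (LCA) gene-content algorithm, including a
**paired-reads mode** that merges the evidence of the two mates of a clone
before assignment. The package also ships a MetaSim-style simulator
(synthetic communities, clone libraries, Illumina 75 bp read pairs with a
fitted positional substitution profile, flow-cycle 454-like reads) and an
evaluation suite, so the whole single-reads vs short-clones vs long-clones
comparison can be reproduced end to end on synthetic data, without BLAST
or any reference database download.

## The method

Each read is compared against a protein reference database (externally;
the package consumes BLAST-tabular match files) and then filtered:

1. **min score** — keep matches with bit score ≥ *minScore* (default 35);
2. **top percent** — keep matches scoring within *topPercent* % of the
   read's best match (default 10);
3. the read is placed on the **LCA** of the taxa of all surviving matches;
4. **min support** — taxa hit by fewer than *minSupport* reads are removed
   from the report and their reads become unassigned.

In paired mode, matches of the two mates *s₁*, *s₂* to the same organism
are treated as one match with the Karlin–Altschul pair-sum combined score

```
s = max( s1 + s2 − log2(k · g · m′ · n′),  max(s1, s2) )
```

with database parameter *k* = 0.041, gap size *g* = 50, effective query
length *m′* = *m*/3 − *h* for translated searches (*m* the total clone
query length in nucleotides, *h* the effective HSP length, default 0) and
effective subject length *n′* = *n* − *h*. Combined scores (≈ 80 bits for
two ~50-bit mates) tower over single-mate scores, so with a 10% top-percent
band only organisms hit by *both* mates enter the LCA — which is why long
clones, whose mates usually sample two *different* genes with different
conservation patterns, give the most specific assignments.

## Worked example

Simulate a 20-species community, a long-clone library, synthetic matches,
and compare single-read against paired assignment:

```r
library(pairedLCA)

comm <- makeSyntheticCommunity(20, "HC", genomeLength = 30000, seed = 1)
#> SyntheticCommunity (HC): 20 species, 562 genes over 600000 bp
tax <- communityTaxonomy(comm)

clones <- sampleClones(comm, cloneLibrarySpec(1900, 300), 2000, seed = 2)
sim    <- sequenceIlluminaPairs(comm, clones, seed = 3)
round(sim$stats$substitution_pct, 2)
#> [1] 1.54          # the stretched positional error profile averages ~1.5%

mt <- simulateMatchTable(comm, sim$truth, seed = 4)
#> MatchTable: 11406 matches, 3456 queries, 0 lines skipped

single <- assignReads(tax, mt, assignmentParams(),
                      queryIds = sim$truth$read_id)
#> AssignmentResult: 4000 queries | 3430 assigned, 26 unassigned, 544 no hits

paired <- assignReadsPaired(tax, mt,
                            assignmentParams(minScore = 50, minSupport = 50),
                            queryIds = sim$truth$read_id)
#> AssignmentResult: 2000 queries | 1939 assigned, 25 unassigned, 36 no hits

truthPairs <- sim$truth[!duplicated(sim$truth$pair_id), ]
round(correctAssignmentRate(paired, truthPairs, tax)$correctPct, 1)
#> [1] 97            # 97% of pairs land exactly on their source species
```

Single reads are scattered over species, genus and family nodes by
conserved genes; paired mode concentrates essentially all assignments at
the species level (here all 1939 assigned pairs), because only taxa hit by
both mates survive the top-percent filter. The same-gene co-hit fraction
of this long-clone library is 7.8%, against ~98% for a 200 bp short-clone
library — the geometric driver of the specificity gain.

A command-line wrapper over the same functions
(`simulate` / `assign` / `evaluate` subcommands) is installed at
`inst/scripts/pairedlca.R`.

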