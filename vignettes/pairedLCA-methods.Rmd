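---
title: "Models and design choices in pairedLCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pairedLCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedLCA)
```

# The assignment model

The LCA gene-content algorithm places a read on the lowest common ancestor
of all organisms whose reference sequences it matches significantly. The
placement depth therefore reflects gene conservation: a read from a gene
shared across a genus can at best be placed on the genus node, while a
read from a species-specific gene can reach the species. Three filters
shape the match set:

* **min score** (bits, default 35): an absolute significance floor. The
  boundary is inclusive — a 35.0-bit match is kept. For paired data a
  floor of 50 bits is the recommended setting: combined matches clear it
  easily, single-mate matches rarely do, so pairs are assigned almost
  exclusively from organisms hit by both mates.
* **top percent** (default 10): per read, keep matches scoring at least
  `(1 - topPercent/100)` times the read's best score. Note the monotone
  directions: *raising* `minScore` or `minSupport` can only shrink the set
  of species-level assignments, while *lowering* `topPercent` (a stricter
  band) removes taxa from each read's LCA set and therefore makes
  placements deeper — species-level assignments can only grow. The tests
  assert these directions.
* **min support** (reads, default 1, recommended 50 for paired libraries;
  inclusive boundary): taxa hit by fewer reads are dropped from the
  report. By default their reads become unassigned, following the reading
  that removed taxa simply vanish from the report; promotion of those
  reads to the parent node, and clade-summed (rather than direct) counting
  are available as flags. Min support counts direct assignments.

Clade exclusion (the unknown-species experiment) removes all matches to a
given clade *before* any score filter, exactly as if those reference
sequences did not exist. `NO_HITS` (a read with no matches at all) and
`UNASSIGNED` (matches existed, none survived) are kept separate so that
evaluation can distinguish unsampled reads from filtered ones, and the
identity `assigned + unassigned + no_hits = queries` is enforced by the
result class.

# The combined bit score

For a pair of mates hitting the same organism with bit scores $s_1, s_2$
the package uses a Karlin–Altschul sum-statistics correction in the bits
domain:

$$ s = \max\bigl(s_1 + s_2 - \log_2(k\,g\,m'n'),\ \max(s_1, s_2)\bigr) $$

with $k = 0.041$, gap size $g = 50$, $m' = m/3 - h$ for translated
searches ($m$ = total clone query length in nucleotides), $n' = n - h$,
and effective HSP length $h = 0$ by default ($h$ shifts every combined
score by the same constant, so its default does not affect relative
filtering). With two 50-bit mates, 75 bp reads and a 300-residue subject
this gives $100 - \log_2(0.041 \cdot 50 \cdot 150 \cdot 300) \approx 83.5$
bits — combined scores cluster in the low 80s, well above single-mate
scores. Design notes:

* The exact algebraic form of pair-sum corrections varies between
  formulations (in particular whether the gap size enters once or
  squared); the correction term is therefore selectable
  (`combinedScoreParams(correction = "g2")`) without touching any other
  code.
* The clamp at $\max(s_1, s_2)$ guarantees that merging evidence never
  *penalises* a doubly-hit organism, which keeps the top-percent filter
  monotone under merging.
* Combination is applied to the best match per organism per mate
  (`bestPerTaxon`, ties broken by smallest subject id for cross-platform
  determinism).
* Pairs are counted once in per-taxon counts by default
  (`accounting = "pair"`); `accounting = "read"` duplicates the pair's
  assignment onto both mates for figures normalised by read count.

# The simulator

The simulator emulates the study conditions end to end; all generators
take an explicit integer seed and are byte-identical under it.

**Communities.** A ranked taxonomy (superkingdom … species under an
unranked root) is generated by randomly grouping species into genera,
genera into families, and so on; each community species receives one
random genome (default 20–50 kb in the examples and acceptance runs)
tiled with genes. Gene lengths follow Gamma(shape 2, mean 950 bp)
truncated at 100 bp with intergenic gaps Uniform(50, 150) bp — desk-scale
stand-ins for prokaryotic gene geometry. The three abundance classes are
LC (one dominant species), MC (six dominant) and HC (all equal). The
dominance ratio of LC/MC has no canonical value, so it is a required
argument rather than a default.

**Clone libraries.** Clone lengths are Normal($\mu$, $\sigma$) — short
clones Normal(200, 20), long clones Normal(1900, 300) — rounded and
truncated to [2 × read length, genome length]; sources are drawn
proportional to abundance × genome length; starts are uniform and strands
equiprobable.

**Illumina pairs.** Mate 1 is the first 75 bp of the clone, mate 2 the
reverse complement of the last 75 bp (forward–reverse orientation; the
study protocol is silent on orientation and nothing downstream depends on
it). Errors are substitutions only. The per-position substitution
probability is $f(x) = a e^{bx} + c$ with $a = 3.957\times10^{-4}$,
$b = 0.1319$, $c = 5.362\times10^{-3}$, a model fitted over a 36-position
profile. Evaluating $f$ literally at positions up to 75 would exceed 5%
per base (and the profile's validity), so the domain is stretched
proportionally: position $t$ of an $L$ bp read is scored at
$x = 36t/L$. Numerically, $\tfrac1{75}\sum_{t=1}^{75} f(36t/75) = 0.0152$,
so simulated libraries realise the ~1.5% substitution rate of the
protocol this model describes; the acceptance script verifies the
realized rate over 1.5 Mb. FASTQ output carries constant Q30 qualities —
the analysis uses none.

**454-style reads.** Reads are built flow by flow (98 cycles over the
order TACG, giving ~250–265 bp): each flow calls the homopolymer of the
flowed nucleotide, and the called length of a true length-$\ell$
homopolymer is $\mathrm{round}(\mathcal N(\ell + \beta, \sigma_f))$
clamped at zero — insertions and deletions, never substitutions. We first
tried call noise scaled by $\sqrt{\ell}$, but that model's insertion and
deletion rates are structurally near-symmetric (ratio ≈ 1.4 on random
sequence), and flow-cycle data show insertions several times more
frequent than deletions (≈ 2.3% vs 0.5% of bases). A constant noise
s.d. $\sigma_f = 0.217$ with a small fixed positive call bias
$\beta = 0.035$ — a one-parameter stand-in for flow carry-forward, which
only ever adds signal — was calibrated once against those rates
(simulation on random sequence gives 2.34% insertions, 0.51% deletions)
and frozen. The mean read length under 98 cycles is not asserted anywhere:
it depends on homopolymer statistics of the template and the flow model is
deliberately minimal.

**Synthetic match tables.** To test binning without BLAST or a reference
database, `simulateMatchTable` turns read truth into matches: each gene
is assigned a conservation level (species-specific / genus-wide /
family-wide, probabilities 0.5 / 0.3 / 0.2 by default), reads overlapping
a gene by ≥ 50 bp hit their source taxon at ~0.67 bits/bp of overlap
(≈ 50 bits for a full 75 bp read, typical of translated searches) and
every species sharing the gene at a geometrically decayed, jittered
score. This reproduces the *structure* that drives the LCA algorithm —
shared genes pull assignments up, specific genes push them down — but not
the absolute sensitivity of a real database search; detection-rate
percentages from real NCBI-nr analyses are therefore out of scope for
numerical reproduction and are covered by property tests instead
(monotone FP/FN trade-off, exclusion experiments, paired-vs-single
specificity).

# Evaluation

`speciesDetection` ties detection to the min-support filter (a species is
detected iff ≥ 1 read remains on its node); `minSupportSweep` re-applies
the filter per threshold without re-running assignment, so the FP/FN
trade-off is computed on identical assignments. `rankHistogram` maps
unranked nodes to their nearest ranked ancestor and reports
above-superkingdom, unassigned and no-hit buckets alongside the seven
major ranks; normalisation (e.g. to 100,000 reads) is a display option and
never touches internal counts. `correctAssignmentRate` requires exact
node identity at the evaluation rank and reports ancestor-credit
(assignment is an ancestor of the truth species) as a separate column,
since "correct" can reasonably be read either way.
`sameGeneFraction` conditions on pairs whose two mates each overlap some
gene by ≥ 50 bp and asks whether a common gene is overlapped by both.

# Problem sizes and reproducibility

The test suite and the acceptance script run on communities of 8–30
species with 10–50 kb genomes, clone libraries of 200–100,000 clones, and
10,000-clone libraries for the same-gene statistics — sizes chosen so a
single desk run reproduces every asserted quantity in seconds while
keeping Monte-Carlo error well inside the stated tolerances (the
substitution-rate check, for instance, uses ≥ 750,000 simulated bases,
where the binomial standard error is < 0.02 percentage points). Every
randomised stage takes an explicit seed and restores the caller's RNG
state, and the determinism test asserts byte-identical genomes, reads,
match tables and assignments across repeated runs.

# Known limitations

* Synthetic genomes are i.i.d. uniform sequence; there is no codon
  structure, GC skew or repeat content, so alignment-level effects
  (e.g. spurious low-complexity matches) are not modelled.
* The match simulator's conservation model is gene-level and clade-shaped;
  horizontal transfer, partial-gene homology and database incompleteness
  are not represented.
* The 454 flow model omits corrective post-processing and quality values;
  its indel rates are calibrated, not mechanistic.
* Absolute detection numbers from real reference databases (false
  negative percentages, species-level read counts) depend on the database
  and genome set and are deliberately not asserted.
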