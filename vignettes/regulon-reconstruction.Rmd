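---
title: "Reconstructing bacterial regulons by phylogenetic footprinting"
author: "regufoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing bacterial regulons by phylogenetic footprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regufoot)
```

## The inference problem

Given a set of closely related annotated bacterial genomes and a
transcription factor of interest, the goal is to reconstruct the TF's
regulon — the set of operons it controls — together with its binding
motif, without any experimental binding data. Two assumptions carry
the whole method:

1. *Footprinting*: binding sites are under purifying selection, so in
   an alignment of orthologous upstream regions they appear as islands
   of conservation against a background of diverged spacer DNA.
2. *Consistency*: regulons tend to be conserved among genomes that
   carry orthologous regulators. A candidate site confirmed upstream
   of orthologous genes in several genomes is likely functional; a
   site seen once is likely noise.

Both assumptions weaken as genomes become too close (everything looks
conserved) or too distant (orthology and alignment decay). The
package targets the useful middle — congeneric genomes at roughly
0.1–0.4 substitutions per site.

## Pipeline stages and their parameters

### Orthology

Orthologs are called as bidirectional best hits (BBH): `x` in genome A
and `y` in genome B are paired when each is the other's top-scoring
Smith–Waterman local alignment and the alignment identity is at least
`min_identity` (default **0.30**, counted over all aligned columns
including gaps — a deliberately conservative denominator). Score ties
are broken by lexicographic locus tag so group membership is invariant
to input order. Alignments use BLOSUM62 with gap open 11 / extend 1
(a gap of length $L$ costs $11 + L$). Regulator paralogs are grouped
with neighbor-joining trees built from Poisson-corrected distances
($-\ln(1-d)$, $d$ the aligned mismatch fraction) of their DNA-binding
domains; negative NJ branch lengths are clamped to zero.

### Upstream regions and operons

Operons are predicted with the standard distance heuristic:
consecutive same-strand genes with intergenic gaps of at most
`max_gap` (default **100 bp**) are co-transcribed. Upstream regions
run from **−400 to +50** relative to the translation start of an
operon's leader gene, read 5′→3′ toward the gene and clamped at contig
edges. By default the window is taken literally even when it overlaps
the previous gene; `truncate_at_neighbor = TRUE` cuts it at the
neighbor's boundary. Coordinates are 0-based half-open everywhere;
GenBank input is converted at the parser.

### Footprinting

Orthologous upstream regions are aligned with the built-in progressive
aligner (match +1, mismatch −1, linear gap −2; guide tree by average
linkage on pairwise alignment distances). The aligner is pluggable:
anything whose rows degap back to the inputs satisfies the contract.

Column identity is the **mean pairwise identity among non-gap rows**;
columns with more than 50% gaps score 0. We chose the pairwise mean
over the majority-character frequency deliberately: for $n$ rows at
per-branch divergence $d$ the majority frequency concentrates near the
single-row match probability $(1-d)$ and stays above 0.8 even at
$d = 0.2$, whereas the pairwise mean tracks $(1-d)^2 + d^2/3$ (about
0.65 at $d = 0.2$), leaving a wide margin below the island threshold.
Islands are maximal runs of columns covered by a sliding window
(default **10 columns**) whose mean identity reaches `min_identity`
(default **0.8**), with edges trimmed until the boundary columns are
themselves conserved — otherwise a passing window overruns into
diverged flanks and stretches the reported span by several columns.
The thresholds are package decisions; "island" has no canonical
quantitative definition.

### Direct-repeat (dyad) discovery

The HTCS/SusR motif archetype is two conserved boxes of equal length
in the same orientation around a non-conserved spacer. Discovery is a
grid search over box length (default **10–18**) and spacer (default
**3–12**; `susr_mode` switches to center-to-center distances of
60–80 bp). For each geometry, seeds are the box-pair words whose two
boxes match each other best (a running-sum self-match scan, O(n) per
sequence); each seed is refined by the usual greedy loop — pick the
best-scoring occurrence in every sequence on either strand, rebuild
the PWM (pseudocount **0.5**, background estimated from the input),
repeat to an occupancy fixed point.

Model selection across geometries is the one genuinely open design
point. Raw total information content is monotone under box widening:
absorbing a weakly conserved flank column always adds a little IC, so
the widest geometry wins. Two corrections fix this:

* the selection objective uses the **folded** frequency matrix — the
  two box halves averaged — so a spuriously absorbed column, which
  pairs a random spacer column with an unrelated flank column, folds
  to near-background;
* an MDL-style penalty of **0.5 bits per scored column** is
  subtracted, so columns must be substantially conserved to pay for
  themselves.

The grid is pruned to the `n_refine` (default **12**) geometries with
the best seed self-match fraction before refinement; geometries whose
spacing misses the repeat have near-background seed quality and cannot
win the objective, so pruning only removes certain losers. Everything
is deterministic given `seed`.

### Palindrome EM

For palindromic motifs the package runs a one-occurrence-per-sequence
(OOPS) EM of fixed length (ZOOPS available by flag, prior 0.5), with
the M-step symmetrization
$f_{b,j} \leftarrow (f_{b,j} + f_{\bar b, L-1-j})/2$, which makes the
frequency matrix exactly reverse-complement symmetric after every
iteration — the formal counterpart of "the best palindrome".
Convergence is $\max|\Delta f| < 10^{-6}$ or 200 iterations; the best
of `n_restarts` (default **20**) random restarts by information
content wins. OOPS is appropriate because the training sequences are
footprint- or curation-selected and should each contain a site. When
regulon refinement later rebuilds a palindromic PWM from hard site
counts, the symmetrization is re-applied so the constraint survives
refinement.

### Scanning, consistency, refinement

The scan threshold is the **smallest score of the training set**:
workflows calibrate it in leave-one-out form — each training site is
scored under the PWM rebuilt from the other sites — which removes the
self-counting inflation that otherwise makes thresholds from small
training sets overshoot. Every training site still passes the
resulting scan, since leave-one-out scores never exceed self scores.
All operon-leader upstream windows in all genomes are scanned on both
strands; per position the better strand is reported, and for direct
repeats overlapping hits closer than one center distance collapse to
the best one (score ties, compared at $10^{-9}$ bits to absorb
floating-point summation order, go to the smaller position). Sites
containing `N` score $-\infty$ and can never pass.

A target operon is accepted when conserved sites support it in at
least `min_support` genomes carrying the orthologous regulator
(default **2**, counting the member's own genome); remaining operon
genes inherit membership. An optional functional-link rule (off by
default) admits a non-conserved site scoring at least threshold
+ 2 bits upstream of a gene sharing a functional-category tag with an
accepted member — the flag makes an otherwise expert judgment explicit
and testable. Accepted sites are realigned into a new PWM, rescanned
and re-filtered until the accepted set is a fixed point (at most 10
rounds; non-convergence is flagged, never hidden). Raising
`min_support` can only shrink the accepted set.

### Motif comparison

Motif similarity is the Pearson correlation of aligned frequency
columns, maximized over all offsets with at least 4 overlapping
columns and both orientations (ties: smaller |offset|, then forward).
P-values come from a seeded column-shuffle permutation null (default
1000 shuffles) — self-contained and reproducible, unlike tool-internal
E-values. All-pairs distances $1-r$ are clustered by average linkage.

## The synthetic benchmark

`generate_collection()` emulates the study design: an ancestral genome
of random sense-codon genes and i.i.d. intergenic sequence at a chosen
GC content (default **0.43**, a *Bacteroides*-like value), diverged
independently per genome (star phylogeny, default **0.2**
substitutions/site). A regulator gene sits inside the locus it
controls — its own operon and both chromosomal neighbors are always
targets, mirroring polysaccharide-utilization-locus architecture — and
each target operon receives a binding site in each genome.

Site instances are **independent draws from the motif model**: each
box is the consensus with per-base noise (default **0.05**, keeping
orthologous site columns near 0.9 pairwise identity), and the spacer
is random per instance — non-conserved even between orthologous sites,
which is precisely what lets the grid search identify where the boxes
end. Sites are planted after divergence, i.e. they are conserved the
way functional sequence is under purifying selection. Planting is
confined to −350..−30 ahead of the leader start; planting intervals
are reserved so sites never overwrite each other, and a non-target
neighbor that would share a target's upstream window through divergent
transcription is co-oriented away, so every planted site has exactly
one owner operon and the truth manifest is unambiguous. `corrupt_sites()`
adds per-base noise and site dropout for stress tests.

What the generator does *not* emulate: genome rearrangement, gene
gain/loss, tree-shaped (non-star) evolution, repeat structure and
compositional heterogeneity of real intergenic DNA, and operonization
beyond the distance heuristic. Passing the benchmark therefore shows
that the statistical machinery recovers what it is designed to
recover under its own assumptions — it does not certify performance on
real genomes, where orthology errors and background structure dominate.

## Benchmark results computed by the tests

The acceptance suite runs the full Workflow 1 on 20 seeded
benchmark collections (5 genomes, 24 genes each, one (16, 5) regulator
with 6 target operons, divergence 0.2) and requires exact geometry
recovery in at least 18 runs and mean membership F1 of at least 0.9;
the palindrome benchmark requires the recovered frequency matrix to be
exactly reverse-complement symmetric and the consensus to match the
planted string at all non-degenerate positions; a 20-run null control
(site-free collections scanned with a foreign planted-motif PWM at its
training threshold) must accept zero members in at least 19 runs.
These sizes keep the full suite within a few minutes on one core while
leaving each property statistically meaningful; the same drivers
(`benchmark_direct_repeat()`, `benchmark_palindrome()`,
`benchmark_null_members()`) are exported so the numbers can be
recomputed at any scale.

## Numerical and degenerate-input conventions

* PWM formula and IC are exactly as documented (`build_pwm`); the
  pseudocount is additive and background-weighted, so tests can assert
  entries to machine precision.
* Ambiguity code `N` is allowed in genomes; any scored word containing
  `N` gets $-\infty$.
* All tie-breaks are deterministic and documented (lexicographic tags
  in orthology, smaller position/forward strand in scanning, smaller
  |offset| in motif comparison), so identical configs and seeds give
  byte-identical artifacts; the run manifest records every parameter
  and seed and deliberately contains no timestamps.
* Degenerate inputs fail loudly: empty training sets, non-finite
  thresholds, all-`N` discovery input, upstream windows that clamp to
  nothing, and missing similarity pairs are all errors, not silent
  defaults.

## Known limitations

* The minimum-training-score threshold is conservative by design even
  in leave-one-out form; occasional weak true sites still fall below
  it (the sub-1 tail of benchmark F1). Iterative refinement recovers
  some of these when PWM re-estimation reorders scores, but it is a
  confirmation loop, not a search.
* Box-length selection relies on spacer/flank columns being less
  conserved than boxes across training instances; a training set of
  near-identical sequences (one operon family only) cannot pin the
  geometry and the grid search will return one of several equivalent
  parses.
* BBH orthology with a single gene per genome is degenerate (any
  mutual pair is "best"); the identity threshold is the only guard.
* The progressive aligner is a linear-gap heuristic adequate for
  ~450-bp upstream regions of congeneric genomes; it is not a
  statistical aligner and can shift island boundaries by a column or
  two, which downstream code tolerates.
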