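# regufoot

Comparative-genomics reconstruction of bacterial transcription-factor
regulons by phylogenetic footprinting and PWM scanning.

## The problem

Gut *Bacteroides* and other *Bacteroidetes* regulate their
polysaccharide-utilization machinery through families of
membrane-anchored transcription factors — hybrid two-component systems
(HTCS) and SusR-like regulators — plus a handful of cytoplasmic sugar
regulators. Their binding sites are unknown for most family members,
and there is usually no experimental binding data at all. What *is*
available is a set of closely related annotated genomes. Two classic
comparative-genomics ideas then make regulon inference possible:

* **Phylogenetic footprinting** — functional sites diverge more slowly
  than the surrounding intergenic DNA, so conserved "islands" in
  alignments of orthologous upstream regions mark candidate binding
  sites.
* **Consistency check** — a candidate site is credible only when sites
  also occur upstream of the gene's orthologs in several other genomes
  that carry the orthologous regulator; sites scattered at random do
  not repeat in orthologous positions.

`regufoot` implements the complete path from annotated genomes to
consistency-checked regulons, for the two motif archetypes of these
regulator families:

* **spaced direct repeats** — two conserved boxes of equal length
  around a non-conserved spacer (HTCS motifs average a 21-bp
  box-to-box distance, e.g. two 16-bp boxes with a 5-bp spacer;
  SusR-type motifs space their boxes 67–77 bp apart);
* **palindromes** — e.g. a 22-bp Crp-like motif with consensus
  `wwwTATGTTnTAnAACATAwww`, discovered by an
  expectation–maximization algorithm whose frequency matrix is forced
  to be exactly reverse-complement symmetric at every step.

## The method in brief

For a position weight matrix built from `n` aligned sites with
background `b` and pseudocount `c`,

    pwm[i, j] = log2( (count[i, j] + c * b[i]) / (n + c) / b[i] )

and the per-column information content is
`IC_j = sum_i f[i, j] * log2(f[i, j] / b[i])` with `f` the
pseudocounted frequencies. Direct-repeat models score only the two
boxes, held at their fixed separation; the spacer is free. Genome
scans use the training-set rule: the threshold is the smallest score
among the sites the PWM was built from. Scanned hits pass the
consistency check when their target operon has conserved support in at
least `min_support` genomes; members are then used to rebuild the PWM,
rescan and re-filter until the accepted set is a fixed point.

Workflow 1 (`run_workflow1()`) chains reciprocal-best-hit orthology at
a 30% Smith-Waterman identity threshold, operon prediction, upstream
extraction (−400..+50 around the translation start), footprinting,
spaced-dyad discovery over a (box, spacer) grid, scanning, and
consistency filtering. Workflow 2 (`run_workflow2()`) starts from
user-supplied candidate co-regulated gene sets and uses the
palindrome-constrained EM instead of the dyad search. Motif models are
compared by Pearson correlation over all offsets and orientations and
clustered by average linkage (`compare_pwms()`, `cluster_motifs()`).

A first-class synthetic benchmark (`generate_collection()`) emulates
the study design: a star phylogeny of annotated genomes at a chosen
divergence, a regulator gene embedded in the locus it controls, sites
sampled from the motif model and planted in the upstream windows of
its target operons, and a ground-truth manifest.

## Worked example

```r
library(regufoot)

## a 5-genome benchmark: one planted regulator with two 16-bp boxes
## around a 5-bp spacer, 6 target operons, divergence 0.2
cfg <- synth_config(seed = 11)
col <- generate_collection(cfg)
man <- col$manifest

reg <- list(genome_id = "G01",
            locus_tag = man$families$G01[man$regulators[[1]]$regulator_family])
res <- run_workflow1(pipeline_config(col$genomes, "footprint_repeat",
                                     regulator = reg,
                                     outdir = tempfile(), seed = 11))
res$model$geometry
#> <motif_geometry> direct repeat: 2 x 16 bp boxes, 5 bp spacer (center distance 21 bp)
res$regulon
#> <regulon> regulator OG0001: 26 member operon(s) in 5 genome(s), 26 site(s)
membership_f1(res$regulon, man$regulators[[1]]$sites)
#> [1] 0.9285714
```

The recovered geometry is the planted one — two 16-bp boxes with a
5-bp spacer, i.e. a 21-bp start-to-start (center-to-center) distance —
and 26 of the 30 planted (genome, operon) memberships are recovered
with no false positives at this seed (F1 0.93; across 20 seeds the
mean F1 is about 0.95–0.97 depending on the seed family).
`consensus(res$model)` prints the motif's IUPAC consensus and
`summary(res$model)` a per-column information-content profile.

The packaged census tables are available via `load_table1()` (36 HTCS
and 5 SusR-like regulators, 16 named HTCS regulons), `load_table2()`
(11 monosaccharide regulons) and `load_network_counts()`;
`crp_consensus()` returns the 22-bp palindromic consensus of the
global sugar regulon.

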