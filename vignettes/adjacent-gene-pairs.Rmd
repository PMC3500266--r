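---
title: "Adjacent gene pairs in co-regulated gene sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjacent gene pairs in co-regulated gene sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjacentome)
library(dplyr)
```

## The phenomenon

In budding yeast and many other eukaryotes, genes that belong to the same
co-regulated set — a *regulon*, such as the ribosome and rRNA biosynthesis
(RRB) genes, the ribosomal protein (RP) genes, or GO-defined stress-response
sets — sit on the chromosomes as immediately adjacent gene pairs far more
often than chance would predict. The pairs occur in every orientation
(divergent, tandem, convergent), the two genes of a pair are more tightly
co-expressed than unpaired members of the same regulon, and the specific
pairings are conserved across divergent fungal lineages, preferentially for
highly expressed genes. `adjacentome` implements the complete quantitative
machinery behind those observations: adjacency detection, a binomial
enrichment test, an offset-normalized expression correlation with bootstrap
nulls, and cross-species pair-conservation scoring — plus a seeded synthetic
data generator so every stage can be exercised and tested without any
external download.

## Adjacency and orientation

Within each chromosome genes are totally ordered by `(start, end, gene_id)`.
This tie rule matters only for overlapping or nested genes, for which no
biological convention exists; any deterministic total order gives a
well-defined notion of "no intervening gene", and ours is reproducible from
the coordinates alone. Two regulon members are *immediately adjacent* when
they occupy consecutive positions in this order — an intervening gene of any
kind breaks adjacency, and chromosome ends break it too (a pair can never
span chromosomes). Maximal streaks of consecutive members form *runs*: a
run of length $L$ contributes $L-1$ pairs and $L$ adjacent genes. The
statistic carried forward is $j$, the number of distinct regulon genes with
at least one adjacent regulon neighbour, so a triplet counts 3 and a
quadruplet 4. Orientation is classified per constituent pair from the
strands in coordinate order: $(-,+)$ divergent, equal strands tandem,
$(+,-)$ convergent. Regulon members absent from the annotation are reported
but do not shrink the regulon size $M$: published regulon sizes are set
memberships, not annotation intersections.

## The enrichment model

Given a regulon of $M$ genes in a genome of $N$ genes, each gene has two
flanking neighbours, each a regulon member with probability $M/N$; by
inclusion–exclusion a gene has at least one regulon neighbour with
probability

$$p = 2\frac{M}{N} - \left(\frac{M}{N}\right)^2 .$$

Modelling the $M$ members independently, the number of adjacent genes is
Binomial$(M, p)$ and the significance of observing $j$ of them adjacent is
the strict upper tail

$$P = 1 - \sum_{k=0}^{j} \binom{M}{k} p^k (1-p)^{M-k} = P(X > j).$$

The independence assumption is approximate (adjacency of neighbours is not
independent, and the $N-1$ neighbour slots ignore chromosome ends), but the
model is the field's standard first-order test and reproduces the published
regulon tables to their printed precision. `adjacency_pvalue()` evaluates
the tail in log space — log-gamma binomial coefficients and a log-sum-exp
over the upper-tail terms — so values spanning $10^{-2}$ to $10^{-14}$ and
far below are computed at full double precision; anything below the normal
floor ($\sim 10^{-300}$) reports as 0. The strictly-greater convention is
deliberate: with $P(X \ge j)$ the small published sets (e.g. an 8-gene set
with 5 adjacent members) do not reproduce, with $P(X > j)$ they do. No
multiple-testing correction is applied, matching the published tables;
reports carry raw p-values.

```{r enrichment}
# the heat-shock-response scale: 18 genes, 4 adjacent, genome of 5797
adjacency_pvalue(18, 4, 5797)
# a regulon the size of the expanded RRB set
adjacency_pvalue(282, 44, 5797)
```

A handful of published rows (the arsenic-response set, and scattered
non-reference rows of the cross-species table) are not consistent with this
formula under any tail convention we examined, most plausibly from different
effective genome sizes or typesetting; we document rather than fit them, and
the genome size $N$ is always an input, never a constant.

## Offset-normalized correlation

Expression similarity is computed relative to a *reference state* rather
than the profile mean. For profiles $X, Y$ over $N$ shared conditions, with
offsets $X_{\mathrm{off}}, Y_{\mathrm{off}}$:

$$S_{X,Y} = \frac{1}{N}\sum_{i=1}^{N}
  \frac{X_i - X_{\mathrm{off}}}{\phi_X}\,
  \frac{Y_i - Y_{\mathrm{off}}}{\phi_Y},
  \qquad
  \phi_G = \sqrt{\frac{1}{N}\sum_{i=1}^N (G_i - G_{\mathrm{off}})^2}.$$

With mean offsets this is algebraically the classical Pearson correlation
(a property the tests verify against `stats::cor()` to $10^{-10}$); with
first-condition offsets — the default for time-courses — it rewards
profiles that move coherently *away from the pre-perturbation baseline*,
which is the natural similarity for stress-response experiments.
$|S| \le 1$ by Cauchy–Schwarz. Conditions missing in either profile are
dropped pairwise (the least destructive rule; the sources are silent on
missing data); a comparison with fewer than 3 shared conditions or a
constant profile is skipped and counted rather than guessed at.

Regulon members with expression data split into three comparison classes:
all pairs of *unpaired* genes; the two partners of each *adjacent pair*; and
all pairs of paired genes excluding each gene's own partner
(*paired, not adjacent*). Group scores are arithmetic means of $S$ over the
class's unordered comparisons.

## Bootstrap significance of group averages

The significance of an elevated paired-subset average is assessed by
resampling: draw at least 10,000 random groupings of genes of the same size
as the paired subset from the regulon members with data, compute each
grouping's mean pairwise $S$, and report the one-sided upper tail

$$p = \frac{1 + \#\{\bar S_{\mathrm{boot}} \ge \bar S_{\mathrm{obs}}\}}{B + 1}.$$

Two choices here were genuinely open. First, each grouping consists of
*distinct* genes, with replacement applying across iterations — resampling
the same gene into one grouping would create degenerate self-comparisons
with $S = 1$. Second, the $+1$ correction keeps $p$ positive and honest at
finite $B$; the published analyses report small one-sided p-values of
exactly this kind. Every report records its seed and iteration count.

## Conservation across a species panel

For each adjacent reference pair and each panel species, the *fate* is
determined through the species' ortholog map and annotation:
`gene_absent` (an ortholog missing), `same_partner` (orthologs of the two
genes immediately adjacent — maintained synteny), `repaired_within_regulon`
(partnership lost but either ortholog adjacent to another regulon member),
else `unpaired`. Orientation is not required to match — conservation of the
*pairing*, not of promoter geometry, is the question — though a strict mode
would be a trivial extension. One-to-many orthologs maintain a pair if
*any* combination is adjacent, matching synteny-browser curation practice.

Fate profiles collapse to three conservation classes: `wide` when the
outgroup species still shows pairing (same or new partner), `minimal` when
no non-reference species does, `intermediate` otherwise. The classes
partition the pair set.

Background synteny maintenance is estimated by resampling adjacent pairs of
the whole reference genome: per iteration $\mathrm{round}(S/2)$ pairs (an
$S$-gene sample corresponds to about $S/2$ pairs) are drawn and scored
maintained if `same_partner` in at least one panel species. The sampling
unit is the *pair*: the conservation question is posed per pair, and
sampling genes would make half the draws uninterpretable singletons. A
query set (a regulon's own pairs) is scored with exactly the same machinery
and compared against the bootstrap distribution, which is what makes the
background and regulon fractions commensurable.

Per-gene expression levels (absolute mRNA abundances in typical use; any
numeric level is accepted, since the published source's units are not
specified) average within conservation classes via
`expression_by_conservation_class()`.

## The synthetic-data generator

Every stage is tested against generated data with planted truth:

* `generate_genome()` lays out non-overlapping genes with uniform lengths
  (500–2000 bp) and gaps (100–1000 bp) over a configurable chromosome
  count — coordinates are structurally realistic but make no attempt at
  real intergenic-distance distributions, which none of the statistics
  consume.
* `plant_regulon()` places a requested run-length multiset (plus unpaired
  singletons) so that the adjacency scan recovers *exactly* the planted
  structure: placement is rejection-sampled with every planted block
  buffered by non-members (cap 1000 retries), strands inside runs are
  solved to satisfy orientation quotas, and a verification pass re-runs
  `find_adjacent_pairs()` and fails loudly rather than trusting the
  construction.
* `generate_expression()` builds each regulon profile as a shared latent
  response plus class-specific Gaussian noise; adjacent partners
  additionally share a pair-specific latent component. The default latent
  is a heat-shock-like repression — a fast monotone decline from baseline 0
  to $-2$ (log2 scale) — because stress repression is the canonical
  condition for these regulons; the shape is pluggable. Background genes
  are pure noise and carry no shared signal.
* `generate_ortholog_panel()` derives each species by breaking the
  reference gene order into blocks (each consecutive link kept independently
  with probability $q$), shuffling blocks over chromosomes, and renaming
  genes through an explicit one-to-one ortholog map, with optional per-gene
  loss. A repair pass prevents a shuffle from accidentally restoring a
  broken link, so the realized maintenance equals the planted link set
  exactly and recovery tests can use a clean Binomial oracle.

What the generator does **not** emulate — real intergenic distances,
sequence content, paralogy and one-to-many orthology from genome
duplications, condition-specific expression offsets, array noise structure
— bounds what green tests mean: they certify the statistics and their
calibration on data whose generating process matches the model, not the
published biological estimates themselves. The published group correlations
(e.g. 0.68 / 0.91 / 0.92 for the RRB classes) and the 67% / 85% / 91%
synteny-maintenance figures require the original microarray compendia and
the sensu-stricto genomes; the pipeline computes the corresponding
statistics whenever a user supplies those inputs in the documented formats.

## Numerical and design choices

* **Tail evaluation.** Upper-tail log-sum-exp rather than
  `1 - lower_sum`, avoiding catastrophic cancellation for tails below
  $10^{-15}$; agreement with direct summation and with `pbinom()` to
  relative $10^{-10}$ over the regulon-scale grid ($M \le 400$,
  $N \le 30{,}000$) is part of the test suite.
* **p-value formatting.** Report files render p-values in scientific
  notation with 2 significant digits, mirroring the published tables;
  computations keep full precision throughout.
* **Degenerate inputs.** Constant profiles, short overlaps, empty
  comparison groups, empty regulon–annotation intersections, and classes
  with no genes are all signalled (NA plus counts, or a typed condition)
  rather than silently dropped.
* **Determinism.** All generators and bootstraps consume an explicit seed
  through an RNG-state-preserving wrapper; pipeline manifests record seeds
  and input checksums, and identical configurations yield byte-identical
  reports.

## Test problem sizes

The shipped suite plants and recovers structure at deliberately modest
scales: random genomes of up to 200 genes (500 replicates) for the
adjacency oracle, a 150-gene genome with a 16-member regulon over 200
expression replicates at 2,000 bootstrap iterations for null calibration,
100 replicates of a 500-gene genome with a 50-member regulon (8 planted
pairs, 20 conditions) for power, and a 1,000-gene genome for synteny
recovery at $q \in \{0.2, 0.67, 0.9\}$ with 10,000 iterations. For the
power study the noise scales are calibrated to the latent response so that
adjacent partners correlate near 0.9, the paired set coheres slightly below
its pairs, and unpaired members near 0.5 under first-condition offsets —
the qualitative structure the published group averages show. These sizes
are the package's chosen trade-off between statistical resolution and a
suite that runs comfortably on a laptop.

## Worked example

```{r example}
gen <- generate_genome(1000, n_chromosomes = 4, seed = 11)
planted <- plant_regulon(gen, M = 50, runs = c(2, 2, 2, 2, 3),
  orientations = c("divergent", "tandem", "convergent",
    "tandem", "divergent", "tandem"),
  seed = 3)

fit <- enrich_regulon(planted$annotation, planted$regulon)
glance(fit)

exprs <- generate_expression(planted, n_conditions = 20, seed = 5)
rep <- coexpression_report(planted$annotation, planted$regulon, exprs,
  iterations = 10000, seed = 9)
tidy(rep)

panel <- generate_ortholog_panel(planted$annotation, planted$regulon,
  n_species = 3, q = 0.67, outgroup = TRUE, seed = 13)
boot <- synteny_maintenance_bootstrap(planted$annotation, panel,
  S = 50, iterations = 10000, seed = 17,
  query_pairs = fit$summary$pairs)
glance(boot)
```

## Known limitations

The binomial test inherits its independence approximation; for regulons
concentrated on few chromosomes a placement-aware permutation null would be
more faithful (the generator provides the machinery to build one, but the
published statistic is the binomial and that is what the package reports).
Gene identity is exact string matching — alias resolution is curation and
out of scope. The conservation machinery consumes precomputed ortholog
maps; it does not infer homology.
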