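---
title: "Methods: coupling of cell-type-specific transcriptome and translatome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling of cell-type-specific transcriptome and translatome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupletrans)
```

`coupletrans` asks, for every gene measured in the same set of cell types
at two system levels — total mRNA (transcriptome) and
polysome/ribosome-associated mRNA (translatome) — whether transcription
and translation behave as a coupled system. This vignette documents the
statistical procedures, the choices that were genuinely open, the
synthetic data the package calibrates itself on, and the known
limitations.

## Data model and aggregation

Inputs are two genes × samples matrices of normalized log2 intensities
(normalization, e.g. RMA of microarray CEL files, happens upstream) and a
sample sheet with `level`, `promoter`, `cell_type`, `replicate` per
sample. Cell-type profiles are built by averaging all replicate samples of
all promoters mapped to a cell type (grand mean). Two promoter universes
are supported: `identical` keeps only promoters whose label occurs at both
levels (four cell types in the default design), `common` keeps every cell
type present at both levels (five). Pooling multiple promoters at the
replicate level, rather than averaging promoter means, treats every array
as one observation and avoids weighting promoters arbitrarily; because the
choice is not forced by anything in the data model, `pooling = "promoter"`
is exposed and tested as an alternative. Genes are restricted to the
intersection of the two matrices, since every downstream statistic needs
paired vectors.

## Per-gene coupling

For gene $g$, coupling is the Pearson correlation $r_g$ between its two
cell-type profiles, and variability per level is the coefficient of
variation $\mathrm{CV} = s/\bar{x}$ (sample sd, $n-1$ denominator; genes
with non-positive mean are reported degenerate and excluded from CV
summaries — on log2 intensity scales in the 4–12 range this is rare).

Significance uses a promoter-subset bootstrap. Each of $n_\text{boot} =
1000$ iterations draws $k$ promoters without replacement, independently
per level, from that level's full promoter pool, averages replicates per
promoter, and pairs the two $k$-vectors in sampled order; the per-gene PCC
over these random cell-type mixtures forms the empirical null. $k$
defaults to the number of cell types in the scenario (4 identical / 5
common); because the source protocol can also be read as drawing as many
promoters as the common scenario uses (8), `boot_unit = "promoter"`
implements that alternative.

**Why classification happens on the Fisher scale.** Because the two
drawn $k$-vectors are paired in a uniformly random order, the null PCC
has, conditional on the drawn values, mean exactly 0 and variance exactly
$1/(k-1)$ — a permutation identity that holds for *any* data (centering
makes $\mathbb{E}[r] = 0$, and the cross terms of
$\mathbb{E}[r^2]$ collapse to $\tfrac1k + \tfrac1{k(k-1)} = \tfrac1{k-1}$).
So with $k = 4$ the per-gene null sd of the raw PCC is
$\approx 0.577$ for *every* gene, and even a perfectly coupled gene
($r = 1$) cannot exceed $Z = \sqrt{3} \approx 1.73 < 1.96$: on the raw
scale the classification would be empty by construction. The Fisher
transform $z = \operatorname{atanh} r$ stretches the tails
($\operatorname{atanh} 0.99 \approx 2.65$ against a null sd near 0.5),
which is what makes the $\pm 1.96$ rule operative; the package therefore
computes observed statistic and null moments on the Fisher scale by
default (`classify_scale = "fisher"`), keeps the raw scale as an option,
and clips $|r|$ at $1-10^{-15}$ so boundary correlations stay finite.
With this choice, the all-null calibration rate
$P(|Z|\ge 1.96) \approx 0.05$ and planted-effect sensitivities above 0.9
are met (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which recompute them).

Genes whose PCC or null sd is undefined (zero variance) are reported as
`degenerate`, never dropped silently.

## Network conservation

Co-expression and co-translation networks are fully connected graphs with
PCC edge weights between gene profiles. The expression conservation score
of gene $g$ is the PCC between its edge-weight row in the two adjacency
matrices. The diagonal is excluded: it equals 1 in both networks and
would only inflate the correlation. Undefined entries (zero-variance
genes) are excluded pairwise; fewer than three usable entries makes the
score undefined. The full-matrix correlation treats the strict upper
triangles the same way. Bootstrap nulls rebuild both networks from random
promoter subsets per iteration, yielding per-gene EC null moments and an
empirical null for the full-matrix correlation, whose one-sided
lower-tail p is $(1 + \#\{\text{null} \le \text{obs}\})/(n_\text{boot}+1)$.

A calibration caveat the package documents deliberately: the bootstrap
varies promoter subsets *conditional on the realized data*, so a gene's
own noise realization is common to all of its null draws. For the
ensemble-level EC score this under-estimates the marginal spread — on
all-null synthetic data EC Z-scores are centred but over-dispersed, and
tail rates exceed the nominal 2.5% per side. The network-level
full-matrix-correlation p-value, by contrast, is approximately
Uniform(0,1) on null data (tested by repeated simulation). Per-gene
conserved/rewired calls should therefore be read as ranking scores rather
than calibrated tests; this behaviour is inherent to the published
procedure and consistent with the very large rewired-gene counts it
reports on real data.

Relevance networks threshold the weighted matrix at $t = 0.9$ (edge iff
PCC $\ge t$). Node properties use `igraph`: degree, betweenness (plus the
per-edge table), harmonic closeness (well-defined on disconnected
graphs), eigenvector centrality computed from the dense symmetric
adjacency spectrum (deterministic, max-normalized, Perron orientation),
alpha centrality with $\alpha = 0.5/\lambda_{\max}$ (half the convergence
bound guarantees invertibility; the factor is configurable) and a unit
exogenous vector, and local/global transitivity. Isolated nodes get 0 for
closeness and centralities by convention.

## Cell-type specificity and motifs

Per gene and level, a one-way fixed-effects ANOVA across cell types
(replicates of all promoters pooled; promoter-level grouping available
via `group_by`) is followed by Benjamini–Hochberg FDR at $q = 0.05$
across genes, independently per level. Tukey HSD post-hoc tests at
$\alpha = 0.05$ run only on ANOVA-significant genes, with the
Tukey–Kramer standard error $\sqrt{(MSW/2)(1/n_i + 1/n_j)}$ for the
mildly unbalanced 2–3-replicate designs. The in-package F and
studentized-range computations are vectorized over genes and verified
against `stats::oneway.test` and `stats::TukeyHSD` in the tests.

Genes differentially expressed at *both* levels get an $m$-bit vector over
the canonical lexicographic cell-type pairs (1 = significant pairwise
difference). The similarity network flips these bits (edge = no
difference), and the labeled motif id is $\sum_p s_p 2^p$ — labeled
because cell-type identity matters (the same isolate-plus-clique shape on
different cell types is a different biological statement), so no
isomorphism collapsing is performed. For $n=4$ cell types there are
$2^6 = 64$ motifs. Occurrence significance permutes each gene's bits
within the gene — preserving its number of significant pairs, the reading
most consistent with shuffling "the 0 and 1 values per gene" — with a
one-sided upper-tail empirical p smoothed by $+1$ to avoid zero. A
consequence worth knowing: genes whose bits are all 0 or all 1 are fixed
points of every shuffle, so motifs populated only by such genes always get
$p = 1$.

## Enrichment

Term overrepresentation uses the upper-tail hypergeometric probability
$P(X \ge k)$ via `phyper` (log-gamma stable), one test per term with at
least one study gene, BH-adjusted. The default population is the full
gene universe of the input matrices; restricting to annotated genes is
the caller's choice by passing a different `population`. The annotation
is consumed as a flat pre-propagated gene→term table; ontology-graph
propagation is out of scope.

## Synthetic data: what it emulates, and what it does not

The generator plants, per gene, a baseline $\sim U(4,12)$ log2 and a
cell-type effect vector with $N(0, \text{effect\_sd}^2)$ entries:
coupled genes reuse the same vector at both levels, uncoupled genes get
the sign-flipped vector on the translatome (an anti-correlated mode
detectable as negative PCC; an independent-profile alternative is a
config switch), null genes have zero effects. Motif genes are drawn from
the null class and receive a single-cell-type shift (default 2.0 log2)
at both levels, making their planted similarity pattern exactly one
isolated node plus a clique. Replicate noise is Gaussian per sample.
Defaults — 5 cell types, 2 promoters per cell type per level (pools of
10, with four shared "identical" promoters), 2–3 replicates per promoter,
effect sd 1.0, noise sd 0.25 (transcriptome) / 0.15 (translatome) —
mirror the real study's design scale and its lower translatome
variability; class fractions 0.15/0.10/0.75 with 10% motif genes give
every downstream stage work to do. Class counts follow the configured
fractions exactly via largest-remainder rounding, and a fixed seed gives
bit-identical output.

What the generator does *not* emulate: probe-level effects and
normalization artifacts, correlated noise between replicates, mean–
variance coupling of microarray intensities, dependence between
annotation terms, or promoters of cell types outside the shared universe
(the real transcriptome pool of 19 promoters covers tissues the
translatome lacks). Passing tests on synthetic data therefore establish
the statistics' internal correctness and calibration under the planted
model, not performance on any particular real dataset.

## Numerical and procedural choices

* Problem sizes in the test and acceptance runs — 2000 all-null genes
  with 200 bootstrap iterations for calibration, 1000 genes for recovery,
  600–1000 genes for network nulls — were chosen as the smallest sizes at
  which the binomial/Monte-Carlo error of the checked rates is well below
  the asserted bands.
* Bootstrap and permutation draws restore the caller's RNG state; stage
  seeds are derived deterministically from one master seed so stage-level
  reruns reproduce full-run outputs byte for byte (the run manifest
  records MD5 checksums).
* Sample sd ($n-1$) is used throughout, including bootstrap null moments.
* Ties in largest-remainder rounding resolve in class declaration order;
  pair ordering is lexicographic everywhere.
* Degenerate cases are values, not errors: zero-variance profiles,
  zero null sds and all-identical ANOVA groups are flagged and propagated.

## Limitations

Per-gene EC significance is over-dispersed (above); ANOVA assumes
homoscedastic Gaussian replicates, which log2 intensities approximate but
do not guarantee; Tukey HSD p-values assume the studentized-range
distribution under balanced-ish designs; the motif permutation preserves
per-gene bit counts but not cross-gene dependence; and the coupling
bootstrap requires promoter pools at least as large as $k$, so designs
with exactly one promoter per cell type leave the null driven by pairing
order alone.
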