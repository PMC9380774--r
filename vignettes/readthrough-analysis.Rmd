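---
title: "Models and methods: termination readthrough, interference, and cleavage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: termination readthrough, interference, and cleavage kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termread)
```

`termread` analyzes what happens when the cleavage and polyadenylation
factor (CPF) fails to act on time: RNA polymerase II transcribes past the
poly(A) site, and in a gene-dense genome that readthrough collides with
neighboring transcription units. This vignette documents the models the
package implements, the parameters that matter, the numerical choices,
and the limits of what a green test establishes.

## The synthetic world

Real nascent RNA-seq from an auxin-degron experiment is large and
lab-specific. The package instead states a compact generative model whose
every parameter is known, and tests the analysis stack against it.

**Genome.** `generate_genome()` lays out `n_genes` non-overlapping genes
along one chromosome. Strands follow a two-state Markov chain with
P(same strand) equal to the codirectional junction target, which makes
realized junction fractions converge on the `strand_scheme` targets; note
that convergent and divergent junctions necessarily alternate along any
strand sequence, so their targets must be (near) equal. Coordinates are
0-based half-open (BED convention); the poly(A) site sits at the 3′
boundary of the gene, so a minus-strand gene stores it at the interval
start.

**Signal.** Each gene draws a baseline body signal
$e_i \sim \mathrm{LogNormal}(\mu, \sigma)$ shared across conditions. A
condition is characterized by a termination-failure fraction
$f \in [0,1]$: at distance $d$ past the poly(A) site the gene leaves
readthrough signal

$$r_i(d) = e_i \, f \, e^{-d/L}$$

on its own strand. Transcription interference acts on initiation: gene
$j$ receives the interference input $I_j$, the mean opposite-strand
readthrough over its promoter window (TSS ± 100 bp), and transcribes at

$$e'_j = \frac{e_j}{1 + \alpha I_j}.$$

This is computed in a single pass from baselines — readthrough curves are
built from $e_i$, not $e'_i$, and there is no fixed-point iteration. The
model is deliberately the simplest monotone, bounded mechanism that
produces the observed phenomenology: suppression of convergent partners
(whose readthrough crosses the neighbor's body and reaches its promoter)
and no self-amplifying cascades. Spike-in genes live on a dedicated
chromosome (mirroring a merged two-species reference), have $f = 0$, and
are exempt from interference, so their expected signal is
condition-invariant by construction.

**Noise.** `sample_counts()` draws per-bin coverage and per-gene counts
as negative binomial with mean `library_scale × expected` and dispersion
$\phi$ (variance $\mu + \phi\mu^2$); a `poisson` flag selects the
$\phi \to 0$ limit. Gene counts integrate the same-strand expected signal
over the gene interval — like a strand-specific featureCounts run — so a
gene invaded by readthrough from a codirectional upstream neighbor
genuinely gains counts. Gene-level and bin-level draws are independent.

**Defaults and why.** Chosen once for a yeast-like world, before any
acceptance measurement, and not revisited:

| parameter | default | rationale |
|---|---|---|
| gene length | 600–2000 bp | budding-yeast ORF scale |
| intergenic gap | N(300, 150), ≥ 50 bp | short yeast intergenic regions |
| expression | LogNormal(3, 1) | ~2 orders of magnitude dynamic range |
| f (−auxin / +auxin) | 0.05 / 0.50 | low basal readthrough; strong defect on depletion |
| decay length L | 1500 bp | readthrough crosses the next gene, terminating within it |
| promoter window | TSS ± 100 bp | compact yeast promoters; no value is dictated by the data |
| interference α | 0.5 | visible but not saturating suppression |
| dispersion φ | 0.05 | typical bulk RNA-seq biological dispersion |
| replicates | 2 | a minimal realistic design; the source design is not stated |
| bin size | 10 bp | matches the coverage-track convention used downstream |

**What the generator does not emulate:** read-level artifacts (mappability,
PCR duplicates, 3′ bias), splicing, polymerase elasticity or collision
mechanics, chromatin context, and the real genome's non-random gene order.
A green test therefore establishes that the statistics recover the stated
model's ground truth at realistic noise — not that the model captures
every property of experimental nascent RNA-seq.

## Normalization

Spike-ins carry the absolute scale. The primary method is a
median-of-ratios restricted to spike-in genes: factor_s = median over
spike-ins of count/geometric-mean, rescaled to geometric mean 1. It is
deterministic, assumption-light, and recovers relative library scale to a
few percent at the default dispersion. An optional RUV-style stage
estimates unwanted factors by SVD of the gene-centered spike-in log
counts (pseudocount 0.5) and regresses them out of all genes; with zero
factors, or spike-ins without between-sample variance, it is the
identity. The number of unwanted factors has no principled default here
(the source analysis does not state one); the argument is explicit.

## Differential expression

The downstream orientation analyses only need per-gene log₂ fold changes and
up/down/ns calls, so the package implements a transparent NB Wald test
rather than wrapping a DE framework:

* log₂FC = log₂((mean₊ + p)/(mean₋ + p)) on normalized counts,
  pseudocount p = 0.5;
* per-gene method-of-moments dispersion, pooled across conditions and
  shrunk toward the trimmed-mean global dispersion with 10 pseudo-degrees
  of freedom ("shrunk" mode; "per_gene" and "pooled" are available);
* delta-method variance of the log₂ mean, Var = (1/μ + φ)/(n ln²2), and a
  normal reference for the Wald statistic. With thousands of genes the
  shrunk dispersion is nearly noise-free, and for the count depths the
  generator produces the 1/μ term is small, so the normal reference holds
  its size (verified by Monte Carlo in the test suite);
* Benjamini–Hochberg adjustment; `up`/`down` at FDR < α with the sign of
  the fold change. No fold-change shrinkage is applied.

A single replicate in any condition refuses p-values (fold changes are
still reported) rather than inventing a dispersion.

## Interference statistics

`opposite_strand_pairs()` pairs each gene's own-strand log₂FC with the
log₂ ratio of opposite-strand signal summed over the same interval —
"corresponding position" is the gene's own interval projected on the
other strand. `window_pairs()` does the same for non-overlapping 1-kb
tiles (the tiling matches a binned multi-track summary; truly sliding
windows would only add autocorrelation). `anticorrelation()` reports
Pearson r by default (no statistic is dictated by the source analysis;
Spearman is a flag).

Two properties of these statistics are worth knowing:

* **Window pairs anticorrelate even without interference.** In a dense
  genome, a tile dominated by readthrough on one strand tends to be
  dominated by unchanged gene body on the other, so the tile statistic
  mixes composition with interference. The package's null-behaved
  statistic is the gene-level pairing, which centers on zero at α = 0.
* **Invasion dilutes the gene-level correlation.** Genes invaded on their
  own strand by a codirectional neighbor gain counts, which adds positive
  fold changes unrelated to opposite-strand suppression. The pure
  interference signal is the ground-truth pairing (own change taken as
  log₂ e′₊/e′₋), which the acceptance suite uses as its oracle.

`classify_orientation()` labels each gene by the unordered pair of its
flanking junction types ({codirectional, convergent, divergent,
chromosome-end}); the class is invariant under mirroring the chromosome
with a strand flip. `orientation_chi2()` runs a Pearson χ² test of
direction × class (no continuity correction) and reports standardized
residuals; by default only significant genes enter, with a flag to
include all genes classed by fold-change sign (used for null
calibration, where significant genes are rare). Expected cells below 1
trigger a warning and an exact-test recommendation flag rather than a
silent fallback.

`readthrough_index()` is the coverage analogue of the qPCR readthrough
level: the fold change in a window downstream of the poly(A) site
normalized to the fold change of the 1-kb genic region upstream of it,
strand-aware.

## Profiles and clustering

`metagene_matrix()` builds rows over poly(A) ± `flank` (default 500 bp,
10-bp bins) for genes at least 200 bp from any neighbor, reversing
minus-strand rows so every row reads 5′→3′; out-of-chromosome bins are
NA. `metagene_average()` gives per-column means with normal-theory 95%
bands (bootstrap optional).

Convergent gene pairs are clustered on the concatenation of both strands'
profiles in both conditions (the joint reading of "before and after"
treatment), in a window anchored at the midpoint between the two
partners' poly(A) sites — per-gene anchoring is a flag, since the
original anchoring is ambiguous. Rows are z-scored by default (raw-CPM
flag available). `kmeans_cluster()` is Lloyd's algorithm with k-means++
starts, best of `n_init` by within-cluster sum of squares; empty clusters
are re-seeded at the farthest point. Two implementation details make its
guarantees real: rows are canonicalized (lexicographically ordered)
before the seeded draws, so the partition is invariant to row
permutation; and a coarser solution's centroids can be supplied as an
additional start, which makes WCSS non-increasing in k. k = 4 follows the
empirical choice in the source analysis; the package treats it as an
argument, not a constant.

`cluster_partner_stats()` summarizes each cluster's partner fold-change
distributions (median, quartiles, Tukey outliers beyond 1.5·IQR) and
compares partners with a pooled-variance two-sample Student's t-test
(Welch is a flag), skipping clusters with fewer than two pairs.

## qPCR

The ΔΔCt machinery assumes perfect amplification efficiency (one Ct per
doubling), as the 2^(−ΔΔCt) formula implies; the efficiency is exposed as
a parameter defaulting to 2. The spike-in reference Ct is the arithmetic
mean of the spike-in amplicons per condition and replicate, and missing
spike-in measurements are an error, not an imputation.

## Cleavage kinetics

Percent cleaved is computed against the t = 0 intensity,
Y = (1 − S_t/S_0)·100, and deliberately not clipped to [0, 100]: noise can
push it outside, and clipping before fitting would bias the plateau. The
global fit shares Y_max and Y_0 across complexes ("globally restrained")
with one rate constant per complex, by `nls` (port algorithm, k bounded
below at 1e-6 min⁻¹). Starting values are robust and data-driven: Y_0
from the earliest timepoint, Y_max from the latest, k from the slope of
log(Y_max − Y) against time. If `nls` fails, a Nelder–Mead fall-back on
the residual sum of squares is reported with a non-convergence flag. A
fitted amplitude near zero (flat data) triggers an explicit
unidentifiability warning.

The half-time solves Y(t₅₀) = Y_max/2 analytically:

$$t_{50} = \frac{1}{k}\ln\!\frac{2\,(Y_{max} - Y_0)}{Y_{max}},$$

defined only for Y_0 < Y_max/2 (otherwise half-maximum is already passed
at t = 0, and the function errors rather than extrapolating backwards).

Uncertainty is by case-resampling bootstrap of replicates within each
(complex, timepoint) cell with percentile 95% intervals; with single
replicates it falls back to residual resampling and says so. The ±
values printed in the source literature do not state their method, so the
package labels its intervals explicitly as bootstrap percentiles.

```{r}
k <- c(cpf = 0.455292, cpf_no_mpe1 = 0.0458347)
tc <- simulate_cleavage_timecourse(83.42, 0.8474, k,
                                   c(0, 0.5, 1, 2, 4, 8, 16, 32, 64, 90),
                                   noise_sd = 0)
fit <- fit_global_plateau(tc)
fit$t50
```

## Numerical conventions, in one place

* Coordinates 0-based half-open everywhere in memory; GFF3 (1-based
  closed) and bedGraph (0-based half-open) conversions happen only at the
  file boundary, via rtracklayer.
* Bin membership is by bin midpoint; all grids share the origin, so
  equal-bin-size tracks align exactly.
* Pseudocount 0.5 wherever a log or ratio meets a zero count.
* Running-mean smoothing truncates and renormalizes edge windows, so a
  constant track is a fixed point; CPM is computed after smoothing,
  jointly over both strands, and sums to exactly 1e6.
* One global seed; every stochastic stage derives its own sub-stream
  deterministically, and no generator touches the caller's RNG state.

## Limitations

* The interference model is phenomenological: no polymerase collisions,
  no elongation dynamics, no chromatin. α and L are effective parameters.
* The NB Wald test is a substitute for a full DE framework; it matches
  the scale of the downstream orientation analyses, not DESeq2's output
  numerically.
* Genome-scale counts from the real experiment (numbers of affected
  genes, convergent pairs, cluster sizes) depend on the real annotation
  and data and are out of scope; the package reproduces the structure of
  those analyses, with its synthetic world's ground truth as the
  reference.
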