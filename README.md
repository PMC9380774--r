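# termread

Strand-specific analysis of transcription termination readthrough and its
consequences, for researchers studying mRNA 3′-end processing by the yeast
cleavage and polyadenylation factor (CPF).

When CPF fails to cleave a nascent transcript at the poly(A) site — for
example after auxin-induced depletion of an activating subunit such as
Mpe1 — RNA polymerase II reads through the termination site. In a compact
genome this readthrough invades downstream genes: it inflates the
nascent-RNA signal of codirectional neighbors and interferes with
transcription of convergent neighbors on the opposite strand. `termread`
implements the quantitative analyses needed to measure these effects from
strand-specific nascent RNA-seq style data, together with the companion
in vitro assay analyses, and ships a synthetic-data generator with known
ground truth so that every stage is testable without external data.

## What it computes

**Genomics (counts and coverage in, statistics out)**

* Spike-in median-of-ratios size factors (`spikein_size_factors()`), with
  an optional RUV-style SVD factor-removal stage
  (`ruv_like_factor_removal()`).
* Strand-specific per-gene log₂ fold changes and a negative-binomial Wald
  test with Benjamini–Hochberg FDR calls (`de_test()`).
* Transcription-interference statistics: per-gene own-strand vs
  opposite-strand paired changes (`opposite_strand_pairs()`), 1-kb
  genome-tiling window pairs (`window_pairs()`), their correlation
  (`anticorrelation()`), gene-orientation classes
  (`classify_orientation()`), a χ² test of direction × orientation
  (`orientation_chi2()`), and a per-gene readthrough index
  (`readthrough_index()`).
* Metagene profiles in a 1-kb window at poly(A) sites with 95% confidence
  bands (`metagene_matrix()`, `metagene_average()`), k-means clustering
  (k-means++ / Lloyd, seed-deterministic and permutation-invariant) of
  convergent gene pairs (`convergent_pair_matrix()`, `kmeans_cluster()`),
  and per-cluster partner comparisons with Student's t-tests
  (`cluster_partner_stats()`).

**Assays**

* Spike-in normalized ΔΔCt qPCR:
  ΔCt = Ct − mean(spike-in Cts), ΔΔCt = ΔCt₊ₐᵤₓ − ΔCt₋ₐᵤₓ,
  fold change = 2^(−ΔΔCt) (`spike_ct()`, `fold_change()`,
  `readthrough_level()`).
* Cleavage kinetics under the exponential plateau model
  Y(t) = Y_max − (Y_max − Y_0)·e^(−kt), fitted globally (shared Y_max,
  Y_0; one k per CPF variant) with `fit_global_plateau()`, the analytic
  half-time t₅₀ = ln(2(Y_max − Y_0)/Y_max)/k (`t50()`), and bootstrap
  confidence intervals (`bootstrap_ci()`). The packaged 42-nt precleaved
  CYC1 substrate (with its AAGAA polyadenylation signal) is available via
  `cyc1_substrates()`.

**Synthetic world** — `sim_config()` + `simulate_dataset()` generate a
yeast-like chromosome of codirectional/convergent/divergent genes, two
conditions differing only in the termination-failure fraction f,
exponential readthrough decay past the poly(A) site, single-pass
interference e′ = e/(1 + αI) on opposite-strand promoters,
negative-binomial count noise, and condition-invariant spike-ins, all
bit-reproducible under one seed. I/O uses standard text formats: GFF3 or
BED6 annotations, strand-split bedGraph coverage, TSV/CSV tables.

## Worked example

```r
library(termread)

cfg <- sim_config(n_genes = 300, seed = 42)   # default interference alpha 0.5
rep <- run_pipeline(cfg, seed = 42)
print(rep)
#> termread pipeline report (seed 42 )
#>   DE: up = 50 , down = 93 , ns = 157 
#>   strand anticorrelation: gene r = -0.082 , window r = -0.538 , chi2 p = 1.4e-06 
#>   convergent pairs: 78 in clusters 29/18/12/19
```

Reading the numbers: of 300 simulated genes, 50 gain nascent signal upon
the simulated depletion (mostly genes invaded by readthrough from a
codirectional upstream neighbor) and 93 lose signal (mostly genes whose
promoters receive opposite-strand readthrough); the χ² test detects the
association between direction and gene orientation (p ≈ 1e-6); strand
changes anticorrelate; and the 78 convergent gene pairs split into four
profile clusters.

```r
k <- c(cpf = 0.455292, cpf_no_mpe1 = 0.0458347)   # min^-1
tc <- simulate_cleavage_timecourse(83.42, 0.8474, k,
                                   c(0, 0.5, 1, 2, 4, 8, 16, 32, 64, 90),
                                   noise_sd = 0)
fit <- fit_global_plateau(tc)
print(fit)
#> plateau_fit ( nls ): Y_max = 83.42 , Y_0 = 0.8474 
#>                     k       t50 R2
#> cpf         0.4552920  1.499998  1
#> cpf_no_mpe1 0.0458347 14.899999  1
```

The joint fit recovers the shared plateau parameters and per-complex rate
constants exactly on noiseless data; the derived half-times (1.5 vs
14.9 min) quantify a ~10-fold slowdown of the cleavage reaction when the
activating subunit is absent.

## Acceptance script

`scripts/acceptance.R` regenerates the package's headline quantity from
scratch — it simulates noiseless cleavage time courses for the two rate
constants above, runs the joint global plateau fit, and reports the
fitted t₅₀ ratio (slower/faster complex) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
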