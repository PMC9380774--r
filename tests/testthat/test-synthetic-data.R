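# The synthetic-data generator: genome layout, expected signal model,
# count noise, and the assay generators.

test_that("junction labeling follows the strand definitions", {
  a <- make_annotation(c(0, 300), c(200, 500), c("+", "+"))
  expect_equal(a$junctions$type, "codirectional")
  a <- make_annotation(c(0, 300), c(200, 500), c("+", "-"))
  expect_equal(a$junctions$type, "convergent")
  a <- make_annotation(c(0, 300), c(200, 500), c("-", "+"))
  expect_equal(a$junctions$type, "divergent")
})

test_that("generate_genome is deterministic and hits junction targets", {
  cfg <- sim_config(n_genes = 150, seed = 11)
  a1 <- generate_genome(cfg)
  a2 <- generate_genome(cfg)
  expect_identical(a1, a2)
  fr <- junction_fractions(a1)
  expect_true(all(abs(fr - cfg$strand_scheme[names(fr)]) <= 0.1))
  # no same-strand overlaps, sorted, polyA inside interval
  g <- a1$genes
  expect_true(all(g$start < g$end))
  expect_true(all(g$polyA_site >= g$start & g$polyA_site <= g$end))
})

test_that("infeasible packing is rejected with an explicit error", {
  cfg <- tiny_config()
  cfg$chrom_length <- 5000L  # cannot hold 60 genes of >= 600 bp
  expect_error(generate_genome(cfg), "infeasible packing")
})

test_that("expected coverage obeys the model limits", {
  # f = 0 in both conditions: no signal beyond any poly(A) site
  cfg <- tiny_config(termination_failure = c(minus_auxin = 0,
                                             plus_auxin = 0))
  ann <- generate_genome(cfg)
  sim <- simulate_expected_coverage(ann, cfg, "plus_auxin")
  cov <- sim$coverage
  genic <- lapply(cov$tracks, function(tr)
    list(plus = logical(length(tr$plus)),
         minus = logical(length(tr$minus))))
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    idx <- termread:::bins_in_interval(g$start, g$end, cfg$bin_size,
                                       length(genic[[g$chrom]]$plus))
    key <- if (g$strand == "+") "plus" else "minus"
    genic[[g$chrom]][[key]][idx] <- TRUE
  }
  for (chrom in names(cov$tracks)) {
    expect_true(all(cov$tracks[[chrom]]$plus[!genic[[chrom]]$plus] == 0))
    expect_true(all(cov$tracks[[chrom]]$minus[!genic[[chrom]]$minus] == 0))
  }

  # alpha = 0: effective expression equals baseline exactly
  cfg0 <- tiny_config(interference_alpha = 0)
  ann0 <- generate_genome(cfg0)
  s0 <- simulate_expected_coverage(ann0, cfg0, "plus_auxin")
  expect_identical(s0$truth$e, s0$truth$e_prime)
})

test_that("readthrough decays exponentially from the poly(A) site", {
  expect_equal(readthrough_signal(10, 0.5, 1500, 1500), 10 * 0.5 * exp(-1),
               tolerance = 1e-12)
  # and the simulated track matches the closed form at bin midpoints
  ann <- make_annotation(0, 1000, "+", chrom_length = 20000)
  cfg <- sim_config(n_genes = 2, seed = 1, interference_alpha = 0,
                    termination_failure = c(minus_auxin = 0.5))
  sim <- simulate_expected_coverage(ann, cfg, "minus_auxin")
  e <- sim$truth$e[1]
  tr <- sim$coverage$tracks$chrI$plus
  d <- (150 + 0.5) * 10 - 1000  # midpoint of bin 151, past the pA at 1000
  expect_equal(tr[151], readthrough_signal(e, 0.5, d, 1500),
               tolerance = 1e-12)
})

test_that("gene-body signal is conserved across conditions when alpha=0", {
  cfg <- tiny_config(interference_alpha = 0)
  ann <- generate_genome(cfg)
  sm <- simulate_expected_coverage(ann, cfg, "minus_auxin")
  sp <- simulate_expected_coverage(ann, cfg, "plus_auxin")
  expect_equal(sum(sm$truth$e_prime), sum(sp$truth$e_prime),
               tolerance = 1e-12)
})

test_that("count sampling: Poisson limit, depth scaling, determinism", {
  # Poisson mode: mean of many draws concentrates at mu (CLT bound)
  draws <- withr::with_seed(1, termread:::nb_draw(1e4, 100, 0.05,
                                                  poisson = TRUE))
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / 1e4))

  cfg <- tiny_config(n_replicates = 1)
  ann <- generate_genome(cfg)
  conds <- names(cfg$termination_failure)
  exp_cov <- lapply(conds, function(cc)
    simulate_expected_coverage(ann, cfg, cc)$coverage)
  names(exp_cov) <- conds
  o1 <- sample_counts(exp_cov, ann, cfg)
  o2 <- sample_counts(exp_cov, ann, cfg)
  expect_identical(o1$counts$counts, o2$counts$counts)

  # doubling library_scale doubles spike-in count means
  cfg2 <- cfg; cfg2$library_scale <- 2; cfg2$seed <- 99L
  o3 <- sample_counts(exp_cov, ann, cfg2)
  sp1 <- o1$counts$counts[o1$counts$gene_info$is_spikein, ]
  sp3 <- o3$counts$counts[o3$counts$gene_info$is_spikein, ]
  expect_equal(mean(sp3) / mean(sp1), 2, tolerance = 0.15)
})

test_that("invalid dispersion is rejected", {
  expect_error(tiny_config(nb_dispersion = 0), "phi")
  expect_error(tiny_config(nb_dispersion = -1), "phi")
})

test_that("cleavage time-course generator matches the plateau model", {
  tc <- simulate_cleavage_timecourse(83.42, 0.8474, c(cpf = 0.455292),
                                     timepoints = c(0, 1.5, 30),
                                     noise_sd = 0)
  expect_equal(tc$pct_cleaved[tc$time_min == 0], 0.8474)
  expect_equal(tc$pct_cleaved[tc$time_min == 30], 83.42,
               tolerance = 1e-4)
  # k chosen by inverting the half-time expression for t50 = 1.5 min:
  # Y(1.5) = Y_max / 2
  expect_equal(tc$pct_cleaved[tc$time_min == 1.5], 83.42 / 2,
               tolerance = 1e-4)
  expect_error(simulate_cleavage_timecourse(50, 60, 1, 0:3),
               "y_0 < y_max")
  expect_identical(
    simulate_cleavage_timecourse(80, 1, 0.3, 0:5, noise_sd = 2,
                                 n_rep = 3, seed = 5),
    simulate_cleavage_timecourse(80, 1, 0.3, 0:5, noise_sd = 2,
                                 n_rep = 3, seed = 5))
})

test_that("qPCR generator encodes fold changes in Ct space", {
  tab <- simulate_qpcr(c(rtA = 1, rtB = 0.25, rtC = 2),
                       spikein_cts = c(act1 = 15, adh1 = 16, gpd3 = 17),
                       noise_sd_ct = 0)
  fc <- fold_change(tab)
  expect_equal(fc$fold_change[match(c("rtA", "rtB", "rtC"),
                                    fc$amplicon)],
               c(1, 0.25, 2), tolerance = 1e-12)
  expect_equal(fc$ddct[fc$amplicon == "rtB"], 2, tolerance = 1e-12)
  expect_identical(simulate_qpcr(c(a = 2), c(s = 15), noise_sd_ct = 0.3,
                                 seed = 4),
                   simulate_qpcr(c(a = 2), c(s = 15), noise_sd_ct = 0.3,
                                 seed = 4))
})

test_that("ground-truth strand-paired changes anticorrelate only under
           interference", {
  # alpha > 0 with elevated +auxin failure: negative correlation
  gp <- ground_truth_pairs(sim_config(n_genes = 250, seed = 8))
  expect_lt(anticorrelation(gp)$estimate, -0.2)
  # alpha = 0: own ground-truth change is exactly zero for every gene
  cfg0 <- sim_config(n_genes = 250, seed = 8, interference_alpha = 0)
  gp0 <- ground_truth_pairs(cfg0)
  expect_true(all(gp0$own_lfc == 0))
})
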