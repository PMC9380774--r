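# Spike-in normalization and the RUV-style factor removal stage.

test_that("median-of-ratios size factors scale with spike-in depth", {
  # 4 target genes + 3 spikes, sample B = 2x sample A on all spike-ins
  spikes_a <- c(100, 200, 400)
  counts <- rbind(cbind(A = c(10, 20, 30, 40), B = c(12, 18, 33, 41)),
                  cbind(spikes_a, 2 * spikes_a))
  gi <- data.frame(gene_id = c(paste0("g", 1:4), paste0("spike", 1:3)),
                   chrom = "chrI", strand = "+",
                   is_spikein = rep(c(FALSE, TRUE), c(4, 3)))
  samples <- data.frame(sample = c("minus_auxin_rep1", "plus_auxin_rep1"),
                        condition = c("minus_auxin", "plus_auxin"))
  tab <- count_table(counts, gi, samples)
  fac <- spikein_size_factors(tab)
  expect_equal(unname(fac[2] / fac[1]), 2, tolerance = 1e-12)
  expect_equal(unname(prod(fac)), 1, tolerance = 1e-12)  # geomean 1

  # identical samples: all factors exactly 1
  tab2 <- count_table(cbind(counts[, 1], counts[, 1]), gi, samples)
  expect_equal(unname(spikein_size_factors(tab2)), c(1, 1))
})

test_that("the factor is the median of the spike-in ratios", {
  # three spike-ins with sample ratios {1.8, 2.0, 2.2}: median 2.0
  a <- c(100, 100, 100)
  b <- c(180, 200, 220)
  gi <- data.frame(gene_id = paste0("spike", 1:3), chrom = "s",
                   strand = "+", is_spikein = TRUE)
  samples <- data.frame(sample = c("x_rep1", "y_rep1"),
                        condition = c("x", "y"))
  tab <- count_table(cbind(a, b), gi, samples)
  fac <- spikein_size_factors(tab)
  expect_equal(unname(fac[2] / fac[1]), 2, tolerance = 1e-9)
})

test_that("all-zero spike-ins in a sample are an error", {
  gi <- data.frame(gene_id = c("g1", "spike1"), chrom = "c",
                   strand = "+", is_spikein = c(FALSE, TRUE))
  samples <- data.frame(sample = c("a_rep1", "b_rep1"),
                        condition = c("a", "b"))
  tab <- count_table(rbind(c(5, 5), c(10, 0)), gi, samples)
  expect_error(spikein_size_factors(tab), "zero")
})

test_that("mean spike-in log-ratio is zero after normalization", {
  sim <- simulate_dataset(tiny_config())
  ct <- estimate_size_factors(sim$counts, "spikein")
  norm <- normalized_counts(ct)
  sp <- norm[ct$gene_info$is_spikein, ]
  sp <- sp[rowSums(sp == 0) == 0, ]
  lr <- median(log(sp[, 1] / sp[, 2]))
  # noiseless-input exactness is over the same genes the factors used;
  # here with NB noise the median log-ratio should sit near 0
  expect_lt(abs(lr), 0.2)
})

test_that("recovered factors track the true library scale within 5%", {
  # typical (mean absolute) deviation at the default NB dispersion,
  # averaged over seeds so no single draw decides the outcome
  devs <- vapply(1:8, function(s) {
    cfg <- sim_config(n_genes = 80, n_spikeins = 60, seed = s,
                      library_scale = c(1, 1.6, 0.7, 1.2))
    sim <- simulate_dataset(cfg)
    fac <- spikein_size_factors(sim$counts)
    truth <- sim$samples$library_scale
    truth <- truth / exp(mean(log(truth)))
    mean(abs(fac / truth - 1))
  }, numeric(1))
  expect_lt(mean(devs), 0.05)
})

test_that("RUV-style removal: identity cases and rank-1 offset removal", {
  sim <- simulate_dataset(tiny_config())
  ct <- estimate_size_factors(sim$counts, "spikein")
  logc <- log2(normalized_counts(ct) + 0.5)
  expect_equal(ruv_like_factor_removal(ct, n_factors = 0), logc)
  expect_error(ruv_like_factor_removal(ct, n_factors = 10), "n_factors")

  # spike-ins with zero between-sample variance: adjustment is identity
  gi <- data.frame(gene_id = c(paste0("g", 1:3), "spike1", "spike2"),
                   chrom = "c", strand = "+",
                   is_spikein = rep(c(FALSE, TRUE), c(3, 2)))
  samples <- data.frame(sample = paste0(c("a", "a", "b", "b"),
                                        "_rep", c(1, 2, 1, 2)),
                        condition = rep(c("a", "b"), each = 2))
  counts <- rbind(matrix(rpois(12, 50), 3), matrix(20, 2, 4))
  tab <- count_table(counts, gi, samples)
  expect_equal(ruv_like_factor_removal(tab, 1),
               log2(normalized_counts(tab) + 0.5))

  # a common additive log2 offset in one sample is removed (n_factors=1);
  # large counts keep the pseudocount's distortion below the tolerance
  counts2 <- matrix(rep(2^(22:25), 4), ncol = 4)
  counts2[, 2] <- counts2[, 2] * 4  # +2 in log2, all genes
  gi2 <- data.frame(gene_id = paste0(c("g", "g", "spike", "spike"),
                                     1:4),
                    chrom = "c", strand = "+",
                    is_spikein = c(FALSE, FALSE, TRUE, TRUE))
  tab2 <- count_table(counts2, gi2, samples)
  adj <- ruv_like_factor_removal(tab2, 1)
  spread <- apply(adj, 1, function(v) max(v) - min(v))
  expect_true(all(spread < 1e-6))
})
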