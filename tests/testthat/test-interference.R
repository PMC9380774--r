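# Orientation classes, strand pairing, anticorrelation, chi-squared, and
# the readthrough index.

test_that("orientation classes follow the flanking junctions", {
  # three plus-strand genes: middle gene codirectional on both sides
  a <- make_annotation(c(0, 300, 600), c(200, 500, 800),
                       c("+", "+", "+"))
  cls <- classify_orientation(a)
  expect_equal(cls$class[2], "codirectional|codirectional")
  # -,+,-: middle plus gene faces its left neighbor 5'-to-5' (divergent)
  # and its right neighbor 3'-to-3' (convergent)
  a2 <- make_annotation(c(0, 300, 600), c(200, 500, 800),
                        c("-", "+", "-"))
  cls2 <- classify_orientation(a2)
  expect_equal(cls2$left[2], "divergent")
  expect_equal(cls2$right[2], "convergent")
  expect_equal(cls2$class[2], "convergent|divergent")
  # chromosome ends
  expect_true(grepl("chromosome-end", cls$class[1]))
  expect_true(grepl("chromosome-end", cls$class[3]))
})

test_that("orientation classes are invariant under mirroring with
           strand flip", {
  cfg <- tiny_config()
  ann <- generate_genome(cfg)
  g <- ann$genes[ann$genes$chrom == "chrI", ]
  L <- ann$chrom_lengths[["chrI"]]
  mirrored <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = L - g$end, end = L - g$start,
    strand = ifelse(g$strand == "+", "-", "+"),
    polyA_site = L - g$polyA_site,
    is_spikein = g$is_spikein, stringsAsFactors = FALSE)
  ann_m <- termread:::new_genome_annotation(
    mirrored, stats::setNames(L, "chrI"))
  c1 <- classify_orientation(ann)
  c1 <- c1[c1$gene_id %in% g$gene_id, ]
  c2 <- classify_orientation(ann_m)
  expect_equal(c2$class[match(c1$gene_id, c2$gene_id)], c1$class)
})

test_that("chi-squared test: uniform table and hand-computed 2x2", {
  de <- data.frame(gene_id = paste0("g", 1:40),
                   log2fc = rep(c(1, -1), 20),
                   direction = rep(c("up", "down"), 20))
  cls <- data.frame(gene_id = paste0("g", 1:40),
                    class = rep(c("A", "A", "B", "B"), 10))
  res <- orientation_chi2(de, cls)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$dof, 1)

  # [[30,10],[10,30]]: chi2 = n(ad-bc)^2 / product of margins = 20
  de2 <- data.frame(gene_id = paste0("g", 1:80),
                    log2fc = rep(c(1, -1), c(40, 40)),
                    direction = rep(c("up", "down"), c(40, 40)))
  cls2 <- data.frame(gene_id = paste0("g", 1:80),
                     class = c(rep("A", 30), rep("B", 10),
                               rep("A", 10), rep("B", 30)))
  res2 <- orientation_chi2(de2, cls2)
  expect_equal(res2$statistic, 20, tolerance = 1e-12)
  expect_equal(res2$dof, 1)
})

test_that("anticorrelation statistic and degeneracy handling", {
  pairs <- data.frame(own_lfc = c(1, -2, 0.5, 3),
                      opp_lfc = -c(1, -2, 0.5, 3))
  res <- anticorrelation(pairs)
  expect_equal(res$estimate, -1)
  # independent noise: |r| < 0.1 in at least 95% of seeds at n = 500
  hits <- vapply(1:20, function(s) {
    d <- withr::with_seed(s, data.frame(own_lfc = rnorm(500),
                                        opp_lfc = rnorm(500)))
    abs(anticorrelation(d)$estimate) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  flat <- data.frame(own_lfc = c(1, 1, 1), opp_lfc = c(1, 2, 3))
  expect_warning(res0 <- anticorrelation(flat), "zero variance")
  expect_true(res0$degenerate)
})

test_that("window pairs tile the genome and vanish without change", {
  cov <- make_coverage(rep(1, 1000), minus = rep(2, 1000))  # 10 kb
  covc <- list(minus_auxin = cov, plus_auxin = cov)
  wp <- window_pairs(covc, window = 1000)
  expect_equal(nrow(wp), 10)
  expect_true(all(wp$plus_lfc == 0) && all(wp$minus_lfc == 0))
})

test_that("opposite-strand pairing uses the gene's own interval", {
  # one plus gene; opposite-strand signal quadruples in +auxin
  ann <- make_annotation(c(0, 300), c(200, 500), c("+", "+"),
                         chrom_length = 500)
  ref <- make_coverage(rep(10, 50), minus = rep(5, 50), bin_size = 10)
  trt <- make_coverage(rep(10, 50), minus = rep(20, 50), bin_size = 10)
  de <- data.frame(gene_id = c("g01", "g02"), log2fc = c(0.5, 0.5))
  gp <- opposite_strand_pairs(de, ann,
                              list(minus_auxin = ref, plus_auxin = trt))
  # sums: 20 bins x 5 -> 100 vs 20 bins x 20 -> 400
  expect_equal(gp$opp_lfc[1], log2(400.5 / 100.5))
  expect_equal(gp$own_lfc, c(0.5, 0.5))
})

test_that("interference simulations give opposite-sign convergent pairs", {
  cfg <- sim_config(n_genes = 250, seed = 13)
  gp <- ground_truth_pairs(cfg)
  ann <- generate_genome(cfg)
  cp <- convergent_pairs(ann)
  own <- stats::setNames(gp$own_lfc, gp$gene_id)
  opp <- stats::setNames(gp$opp_lfc, gp$gene_id)
  # convergent partners: own change down, opposite-strand change up
  sign_ok <- own[cp$plus_gene] < 0 & opp[cp$plus_gene] > 0
  expect_gt(mean(sign_ok, na.rm = TRUE), 0.5)
})

test_that("anticorrelation strengthens with interference alpha", {
  rs <- vapply(c(0, 0.25, 0.5, 1), function(alpha) {
    cfg <- sim_config(n_genes = 250, seed = 21,
                      interference_alpha = alpha)
    gp <- ground_truth_pairs(cfg)
    if (all(gp$own_lfc == 0)) 0 else anticorrelation(gp)$estimate
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("readthrough index compares downstream to upstream fold change", {
  # plus gene [0, 1000); upstream fold change 2, downstream 4
  ann <- make_annotation(0, 1000, "+", chrom_length = 2000)
  ref <- make_coverage(c(rep(100, 100), rep(10, 100)),
                       minus = rep(0, 200), bin_size = 10)
  trt <- make_coverage(c(rep(200, 100), rep(40, 100)),
                       minus = rep(0, 200), bin_size = 10)
  ri <- readthrough_index(list(minus_auxin = ref, plus_auxin = trt), ann,
                          downstream_window = 500, upstream_window = 1000,
                          pseudocount = 0)
  expect_equal(ri$index[1], 2, tolerance = 1e-12)

  # null: no change between conditions -> index 1
  ri0 <- readthrough_index(list(minus_auxin = ref, plus_auxin = ref), ann)
  expect_equal(ri0$index[1], 1, tolerance = 1e-6)

  # minus-strand gene: downstream extends to lower coordinates
  ann2 <- make_annotation(1000, 1900, "-", chrom_length = 2000)
  ref2 <- make_coverage(rep(0, 200),
                        minus = c(rep(10, 100), rep(100, 100)),
                        bin_size = 10)
  trt2 <- make_coverage(rep(0, 200),
                        minus = c(rep(40, 100), rep(200, 100)),
                        bin_size = 10)
  ri2 <- readthrough_index(list(minus_auxin = ref2, plus_auxin = trt2),
                           ann2, downstream_window = 500,
                           upstream_window = 900, pseudocount = 0)
  expect_equal(ri2$index[1], 2, tolerance = 1e-12)
})
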