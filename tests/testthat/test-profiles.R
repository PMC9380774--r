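# Metagene matrices, averages, k-means, and partner statistics.

test_that("metagene rows are anchored, filtered, and strand-flipped", {
  # well-separated genes on flat unit coverage -> all-ones rows
  ann <- make_annotation(c(1000, 3000), c(2000, 4000), c("+", "+"),
                         chrom_length = 6000)
  cov <- make_coverage(rep(1, 600), minus = rep(1, 600))
  m <- metagene_matrix(cov, ann, flank = 500, bin = 10,
                       min_neighbor_distance = 200)
  expect_equal(dim(m), c(2, 100))
  expect_true(all(m == 1))
  expect_equal(attr(m, "anchor_col"), 50)

  # a gene 150 bp from its neighbor is excluded at min distance 200
  ann2 <- make_annotation(c(1000, 2150), c(2000, 3000), c("+", "+"),
                          chrom_length = 6000)
  m2 <- metagene_matrix(cov, ann2, flank = 500, bin = 10,
                        min_neighbor_distance = 200)
  expect_equal(nrow(m2), 0)

  # minus-strand step function mirrors the plus-strand equivalent
  step_plus <- make_coverage(
    c(rep(0, 100), rep(2, 100), rep(0, 400)),
    minus = c(rep(0, 220), rep(2, 100), rep(0, 280)))
  ann_p <- make_annotation(1000, 2000, "+", chrom_length = 6000)
  ann_m <- make_annotation(2200, 3200, "-", chrom_length = 6000)
  mp <- metagene_matrix(step_plus, ann_p, flank = 500, bin = 10)
  mm <- metagene_matrix(step_plus, ann_m, flank = 500, bin = 10)
  expect_equal(as.numeric(mm[1, ]), as.numeric(mp[1, ]))
})

test_that("window bins beyond the chromosome are NA-padded", {
  ann <- make_annotation(0, 300, "+", chrom_length = 400)
  cov <- make_coverage(rep(1, 40))
  m <- metagene_matrix(cov, ann, flank = 500, bin = 10,
                       min_neighbor_distance = 0)
  expect_true(any(is.na(m)))
  expect_true(all(m[1, !is.na(m[1, ])] == 1))
})

test_that("metagene averages and confidence bands", {
  m <- rbind(rep(0, 10), rep(2, 10))
  attr(m, "positions") <- seq_len(10)
  avg <- metagene_average(m)
  expect_equal(avg$mean, rep(1, 10))
  ident <- rbind(rep(3, 10), rep(3, 10))
  attr(ident, "positions") <- seq_len(10)
  avg2 <- metagene_average(ident)
  expect_equal(avg2$upper - avg2$lower, rep(0, 10))
})

test_that("k-means separates well-separated blobs and is seed-stable", {
  x <- withr::with_seed(2, rbind(matrix(rnorm(60, 0), ncol = 2),
                                 matrix(rnorm(60, 8), ncol = 2)))
  rownames(x) <- sprintf("r%02d", seq_len(nrow(x)))
  r1 <- kmeans_cluster(x, k = 2, seed = 9)
  truth <- rep(1:2, each = 30)
  agree <- max(mean(r1$assignments == truth),
               mean(r1$assignments == 3 - truth))
  expect_equal(agree, 1)

  r2 <- kmeans_cluster(x, k = 2, seed = 9)
  expect_identical(r1$assignments, r2$assignments)
  expect_equal(r1$wcss, r2$wcss, tolerance = 1e-12)

  # agreement with the reference implementation on separated data
  km <- stats::kmeans(x, centers = 2, nstart = 5)
  agree_ref <- max(mean((r1$assignments == km$cluster)),
                   mean((r1$assignments == 3 - km$cluster)))
  expect_equal(agree_ref, 1)

  # permutation invariance up to label renaming
  perm <- withr::with_seed(4, sample(nrow(x)))
  rp <- kmeans_cluster(x[perm, ], k = 2, seed = 9)
  tab <- table(r1$assignments[perm], rp$assignments)
  expect_equal(sum(tab > 0), 2)  # one-to-one label mapping
})

test_that("WCSS is non-increasing in k when seeded from the coarser fit", {
  x <- withr::with_seed(6, matrix(rnorm(200), ncol = 4))
  r2 <- kmeans_cluster(x, k = 2, seed = 3)
  # extend the k=2 centroids with the two worst-fit points
  d2 <- termread:::dist2_to_centers(x, r2$centers)
  worst <- order(d2[cbind(seq_len(nrow(x)), r2$assignments)],
                 decreasing = TRUE)[1:2]
  init4 <- rbind(r2$centers, x[worst, ])
  r4 <- kmeans_cluster(x, k = 4, seed = 3, init_centers = init4)
  expect_lte(r4$wcss, r2$wcss + 1e-10)
})

test_that("convergent pair matrix concatenates strands and conditions", {
  sim <- simulate_dataset(tiny_config())
  covc <- condition_coverage(sim$coverage, sim$samples)
  pm <- convergent_pair_matrix(covc, sim$annotation, flank = 300,
                               bin = 10)
  expect_equal(ncol(pm$matrix), 4 * 60)  # 2 conditions x 2 strands
  expect_equal(nrow(pm$matrix), nrow(pm$pairs))
  # z-scored rows: mean 0, sd 1 (or all-zero degenerate rows)
  mu <- rowMeans(pm$matrix)
  expect_true(all(abs(mu) < 1e-8))
})

test_that("cluster partner statistics: quartiles, outliers, t-test", {
  de <- data.frame(gene_id = c(paste0("p", 1:5), paste0("m", 1:5)),
                   log2fc = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  pairs <- data.frame(pair_id = paste0("pair", 1:5),
                      plus_gene = paste0("p", 1:5),
                      minus_gene = paste0("m", 1:5))
  asg <- stats::setNames(rep(1L, 5), pairs$pair_id)
  st <- cluster_partner_stats(de, pairs, asg)
  plus_row <- st[st$strand == "plus", ]
  expect_equal(plus_row$median, 3)
  expect_equal(plus_row$q1, 2)
  expect_equal(plus_row$q3, 4)
  expect_equal(plus_row$n_outliers, 0)
  # identical partner distributions: t = 0, p = 1
  expect_equal(plus_row$t_statistic, 0)
  expect_equal(plus_row$t_p_value, 1)
})

test_that("interference skews fold changes against the weaker convergent
           partner", {
  # ground-truth ordering: the lower-expressed partner of a convergent
  # pair is suppressed by the stronger partner's readthrough more than
  # it suppresses back
  cfg <- sim_config(n_genes = 300, seed = 17)
  ann <- generate_genome(cfg)
  sm <- simulate_expected_coverage(ann, cfg, "minus_auxin")
  sp <- simulate_expected_coverage(ann, cfg, "plus_auxin")
  lfc <- stats::setNames(log2(sp$truth$e_prime / sm$truth$e_prime),
                         sp$truth$gene_id)
  e <- stats::setNames(sm$truth$e, sm$truth$gene_id)
  cp <- convergent_pairs(ann)
  weaker <- ifelse(e[cp$plus_gene] < e[cp$minus_gene],
                   cp$plus_gene, cp$minus_gene)
  stronger <- ifelse(e[cp$plus_gene] < e[cp$minus_gene],
                     cp$minus_gene, cp$plus_gene)
  expect_lt(median(lfc[weaker] - lfc[stronger], na.rm = TRUE), 0)
})
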