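# Metagene profiles at poly(A) sites, k-means clustering of convergent
# gene pairs, and per-cluster partner comparisons.

neighbor_distances <- function(annotation) {
  genes <- annotation$genes
  out <- rep(Inf, nrow(genes))
  for (chrom in unique(genes$chrom)) {
    idx <- which(genes$chrom == chrom)
    g <- genes[idx, ]
    o <- order(g$start)
    idx <- idx[o]; g <- g[o, ]
    n <- nrow(g)
    left <- c(Inf, g$start[-1] - g$end[-n])
    right <- c(g$start[-1] - g$end[-n], Inf)
    out[idx] <- pmax(0, pmin(left, right))
  }
  out
}

#' Metagene matrix anchored at poly(A) sites
#'
#' One row per gene passing the neighbor-distance filter, columns covering
#' `[polyA - flank, polyA + flank)` in `bin`-bp steps, oriented 5' to 3'
#' (minus-strand rows are reversed). Bins outside the chromosome are NA.
#' The anchor (poly(A) site) sits at the boundary between columns
#' `flank/bin` and `flank/bin + 1`.
#'
#' @param coverage a `stranded_coverage` whose bin size equals `bin`.
#' @param annotation a `genome_annotation`.
#' @param flank half-window in bp.
#' @param bin column width in bp.
#' @param min_neighbor_distance genes closer than this to a neighboring
#'   gene (either side, any strand) are excluded.
#' @return numeric matrix with gene_id rownames and attributes `anchor_col`
#'   (last upstream column index), `bin`, `flank`, `positions` (column
#'   midpoints relative to the anchor).
#' @export
metagene_matrix <- function(coverage, annotation, flank = 500, bin = 10,
                            min_neighbor_distance = 200) {
  stopifnot(inherits(coverage, "stranded_coverage"))
  if (coverage$bin_size != bin)
    stop("coverage bin size (", coverage$bin_size,
         ") must equal the requested bin (", bin, ")")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  genes <- annotation$genes
  keep <- !genes$is_spikein &
    neighbor_distances(annotation) >= min_neighbor_distance
  genes <- genes[keep, ]
  n_col <- as.integer(2 * flank / bin)
  mat <- matrix(NA_real_, nrow(genes), n_col,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tr <- coverage$tracks[[g$chrom]]
    nb <- length(tr$plus)
    # column j covers [pA - flank + (j-1)*bin, ... + bin); use the bin
    # whose midpoint falls there (grids are aligned since bin sizes match)
    col_start <- g$polyA_site - flank + (seq_len(n_col) - 1) * bin
    bin_idx <- floor((col_start + bin / 2) / bin) + 1
    ok <- bin_idx >= 1 & bin_idx <= nb
    vals <- rep(NA_real_, n_col)
    key <- if (g$strand == "+") "plus" else "minus"
    vals[ok] <- tr[[key]][bin_idx[ok]]
    if (g$strand == "-") vals <- rev(vals)
    mat[i, ] <- vals
  }
  structure(mat, anchor_col = as.integer(flank / bin), bin = bin,
            flank = flank,
            positions = (seq_len(n_col) - 0.5) * bin - flank)
}

#' Column-wise metagene average with 95% confidence band
#'
#' @param mat a matrix from [metagene_matrix()] (>= 2 rows).
#' @param conf confidence level.
#' @param method `"normal"` (mean +/- z * SE) or `"bootstrap"`
#'   (percentile over row resamples).
#' @param n_boot,seed bootstrap controls.
#' @return data.frame: position, mean, lower, upper, n (rows used per
#'   column); columns where every row is missing are NA and flagged in the
#'   `all_missing` attribute.
#' @export
metagene_average <- function(mat, conf = 0.95,
                             method = c("normal", "bootstrap"),
                             n_boot = 1000, seed = 1) {
  method <- match.arg(method)
  if (nrow(mat) < 2) stop("need at least 2 rows")
  n <- colSums(!is.na(mat))
  m <- suppressWarnings(colMeans(mat, na.rm = TRUE))
  m[n == 0] <- NA_real_
  if (method == "normal") {
    s <- apply(mat, 2, stats::sd, na.rm = TRUE)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    half <- z * s / sqrt(pmax(n, 1))
    lower <- m - half; upper <- m + half
  } else {
    qs <- with_seed(seed, {
      boots <- replicate(n_boot, {
        idx <- sample.int(nrow(mat), replace = TRUE)
        suppressWarnings(colMeans(mat[idx, , drop = FALSE], na.rm = TRUE))
      })
      apply(boots, 1, stats::quantile,
            probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    })
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  out <- data.frame(position = attr(mat, "positions"), mean = m,
                    lower = lower, upper = upper, n = n)
  attr(out, "all_missing") <- which(n == 0)
  out
}

#' Convergent gene pairs of an annotation
#'
#' @param annotation a `genome_annotation`.
#' @return data.frame: pair_id, chrom, plus_gene, minus_gene (the left,
#'   plus-strand partner and the right, minus-strand partner), anchor
#'   (midpoint of the two poly(A) sites).
#' @export
convergent_pairs <- function(annotation) {
  j <- annotation$junctions[annotation$junctions$type == "convergent", ]
  g <- annotation$genes
  pa <- stats::setNames(g$polyA_site, g$gene_id)
  out <- data.frame(pair_id = sprintf("pair%04d", seq_len(nrow(j))),
                    chrom = j$chrom,
                    plus_gene = j$left_gene,
                    minus_gene = j$right_gene,
                    anchor = round((pa[j$left_gene] +
                                      pa[j$right_gene]) / 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Feature matrix for clustering convergent gene pairs
#'
#' For each convergent pair, extracts the coverage profile in a window
#' centered on the midpoint between the two partners' poly(A) sites
#' (`anchor = "midpoint"`; `"plus"`/`"minus"` anchor at one partner's
#' site instead), for both strands in every condition, and concatenates
#' the blocks into one feature vector. Rows are z-scored by default.
#'
#' @param cov_by_condition named list of per-condition
#'   `stranded_coverage` (bin size must equal `bin`).
#' @param annotation a `genome_annotation`.
#' @param flank half-window (bp).
#' @param bin bin width (bp).
#' @param zscore z-score each row over its features (rows with zero
#'   variance become all-zero).
#' @param anchor `"midpoint"`, `"plus"`, or `"minus"`.
#' @return list: `matrix` (pairs x features, NA-free rows only), `pairs`
#'   (the matching rows of [convergent_pairs()]), `blocks` (feature-block
#'   labels).
#' @export
convergent_pair_matrix <- function(cov_by_condition, annotation,
                                   flank = 500, bin = 10, zscore = TRUE,
                                   anchor = c("midpoint", "plus",
                                              "minus")) {
  anchor <- match.arg(anchor)
  pairs <- convergent_pairs(annotation)
  if (!nrow(pairs)) stop("no convergent pairs in annotation")
  g <- annotation$genes
  pa <- stats::setNames(g$polyA_site, g$gene_id)
  centers <- switch(anchor,
                    midpoint = pairs$anchor,
                    plus = pa[pairs$plus_gene],
                    minus = pa[pairs$minus_gene])
  n_col <- as.integer(2 * flank / bin)
  blocks <- list()
  for (cond in names(cov_by_condition)) {
    cov <- cov_by_condition[[cond]]
    if (cov$bin_size != bin)
      stop("coverage bin size must equal bin (", bin, ")")
    for (strand in c("plus", "minus")) {
      blk <- matrix(NA_real_, nrow(pairs), n_col)
      for (i in seq_len(nrow(pairs))) {
        tr <- cov$tracks[[pairs$chrom[i]]]
        col_start <- centers[i] - flank + (seq_len(n_col) - 1) * bin
        bin_idx <- floor((col_start + bin / 2) / bin) + 1
        ok <- bin_idx >= 1 & bin_idx <= length(tr$plus)
        blk[i, ok] <- tr[[strand]][bin_idx[ok]]
      }
      blocks[[paste(cond, strand, sep = ".")]] <- blk
    }
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- pairs$pair_id
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  pairs <- pairs[complete, , drop = FALSE]
  if (zscore) {
    mu <- rowMeans(mat)
    s <- apply(mat, 1, stats::sd)
    mat <- sweep(mat, 1, mu)
    mat <- sweep(mat, 1, ifelse(s > 0, s, 1), "/")
  }
  list(matrix = mat, pairs = pairs,
       blocks = rep(names(blocks), each = n_col))
}

# Squared Euclidean distances from each row of x to each center row.
dist2_to_centers <- function(x, centers) {
  cross <- x %*% t(centers)
  sweep(sweep(-2 * cross, 2, rowSums(centers^2), "+"), 1,
        rowSums(x^2), "+")
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(dist2_to_centers(x, centers[seq_len(j - 1), ,
                                            drop = FALSE]), 1, min)
    d2 <- pmax(d2, 0)
    if (sum(d2) == 0) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
  }
  centers
}

lloyd <- function(x, centers, max_iter) {
  k <- nrow(centers)
  assign_prev <- rep(0L, nrow(x))
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(assign, k) == 0)) {
      # empty cluster: re-seed at the point farthest from its center
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
      centers[j, ] <- x[far, ]
      assign[far] <- j
    }
    if (all(assign == assign_prev)) break
    assign_prev <- assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  d2 <- dist2_to_centers(x, centers)
  wcss <- sum(pmax(d2[cbind(seq_len(nrow(x)), assign)], 0))
  list(assignments = assign, centers = centers, wcss = wcss, iter = iter)
}

#' k-means clustering (Lloyd's algorithm with k-means++ starts)
#'
#' Deterministic for a fixed seed: runs `n_init` k-means++ initializations
#' (plus an optional user-supplied start, e.g. the centroids of a coarser
#' solution, which makes the within-cluster sum of squares non-increasing
#' in k) and keeps the best by WCSS. Empty clusters are re-seeded at the
#' point currently farthest from its assigned center.
#'
#' @param x numeric matrix (rows = objects).
#' @param k number of clusters (k <= nrow(x)).
#' @param seed integer seed.
#' @param n_init number of random initializations.
#' @param max_iter Lloyd iteration cap.
#' @param init_centers optional k x ncol(x) matrix used as an additional
#'   starting point.
#' @return list of class `cluster_result`: k, assignments (named by
#'   rownames), centers, wcss, sizes, iter.
#' @export
kmeans_cluster <- function(x, k = 4, seed = 1, n_init = 10,
                           max_iter = 100, init_centers = NULL) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k must be <= number of rows")
  # canonicalize row order so the seeded k-means++ draws depend on the
  # data values only: permuting the input rows cannot change the partition
  ord <- do.call(order, as.data.frame(x))
  xs <- x[ord, , drop = FALSE]
  runs <- with_seed(derive_seed(seed, "cluster"), {
    r <- lapply(seq_len(n_init), function(i)
      lloyd(xs, kmeanspp_init(xs, k), max_iter))
    if (!is.null(init_centers)) {
      stopifnot(nrow(init_centers) == k, ncol(init_centers) == ncol(x))
      r <- c(r, list(lloyd(xs, as.matrix(init_centers), max_iter)))
    }
    r
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "wcss"))]]
  assignments <- integer(nrow(x))
  assignments[ord] <- best$assignments
  assignments <- stats::setNames(assignments, rownames(x))
  structure(list(k = k, assignments = assignments,
                 centers = best$centers, wcss = best$wcss,
                 sizes = tabulate(best$assignments, k),
                 iter = best$iter),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means: k =", x$k, ", sizes =",
      paste(x$sizes, collapse = "/"),
      ", WCSS =", signif(x$wcss, 6), "\n")
  invisible(x)
}

#' Per-cluster partner statistics for convergent pairs
#'
#' For each cluster and strand: median, quartiles, and Tukey outliers
#' (beyond 1.5 IQR) of the partners' log2 fold changes, plus a two-sided
#' two-sample Student's t-test (pooled variance by default; `var_equal =
#' FALSE` gives Welch) between the plus- and minus-strand partner
#' distributions. Clusters with fewer than 2 pairs skip the test.
#'
#' @param deresult a `de_result` (source of per-gene log2FC).
#' @param pairs convergent pairs data.frame (from
#'   [convergent_pair_matrix()] or [convergent_pairs()]).
#' @param assignments cluster assignment per pair (named by pair_id, as in
#'   a `cluster_result`).
#' @param var_equal pooled-variance Student's t (TRUE) or Welch (FALSE).
#' @return data.frame, one row per (cluster, strand) with the boxplot
#'   statistics; per-cluster t-test results are attached in rows where
#'   `strand == "plus"` (`t_statistic`, `t_p_value`).
#' @export
cluster_partner_stats <- function(deresult, pairs, assignments,
                                  var_equal = TRUE) {
  lfc <- stats::setNames(deresult$log2fc, deresult$gene_id)
  pairs$cluster <- assignments[pairs$pair_id]
  rows <- list()
  for (cl in sort(unique(pairs$cluster))) {
    p <- pairs[pairs$cluster == cl, ]
    vals <- list(plus = as.numeric(lfc[p$plus_gene]),
                 minus = as.numeric(lfc[p$minus_gene]))
    tt <- if (nrow(p) >= 2 &&
              stats::sd(c(vals$plus, vals$minus)) > 0) {
      stats::t.test(vals$plus, vals$minus, var.equal = var_equal)
    } else NULL
    if (is.null(tt) && nrow(p) < 2)
      message("cluster ", cl, ": <2 pairs, t-test skipped")
    for (strand in c("plus", "minus")) {
      v <- vals[[strand]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, strand = strand, n = length(v),
        median = q[2], q1 = q[1], q3 = q[3],
        n_outliers = sum(v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr),
        t_statistic = if (strand == "plus" && !is.null(tt))
          unname(tt$statistic) else NA_real_,
        t_p_value = if (strand == "plus" && !is.null(tt))
          tt$p.value else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
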