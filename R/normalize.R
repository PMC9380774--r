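# Spike-in based between-sample normalization. Primary method is a
# median-of-ratios over the spike-in genes (deterministic, assumption-light
# substitute for RUVg); an optional RUV-style SVD factor-removal stage is
# provided for log-scale batch structure.

#' Spike-in median-of-ratios size factors
#'
#' For each sample, the size factor is the median over spike-in genes of
#' `count / geometric mean of that gene across samples` (genes with a zero
#' count in any sample are excluded from the reference). Factors are
#' rescaled to have geometric mean 1, so identical samples get factor 1
#' and only relative sequencing depth is removed.
#'
#' @param table a `count_table` with at least one spike-in gene.
#' @return named numeric vector of per-sample size factors (> 0).
#' @export
spikein_size_factors <- function(table) {
  stopifnot(inherits(table, "count_table"))
  sp <- table$counts[table$gene_info$is_spikein, , drop = FALSE]
  if (!nrow(sp)) stop("no spike-in genes in count table")
  zero_samples <- colSums(sp) == 0
  if (any(zero_samples))
    stop("all spike-in counts are zero in sample(s): ",
         paste(colnames(sp)[zero_samples], collapse = ", "))
  usable <- rowSums(sp == 0) == 0
  if (!any(usable))
    stop("no spike-in gene has nonzero counts in every sample")
  sp <- sp[usable, , drop = FALSE]
  ref <- apply(sp, 1, geometric_mean)
  fac <- apply(sp / ref, 2, stats::median)
  fac <- fac / geometric_mean(fac)
  fac
}

#' Attach size factors to a count table
#'
#' @param table a `count_table`.
#' @param method `"spikein"` (median-of-ratios over spike-ins) or
#'   `"none"` (all factors 1).
#' @return the table with `size_factors` set.
#' @export
estimate_size_factors <- function(table, method = c("spikein", "none")) {
  method <- match.arg(method)
  table$size_factors <- switch(method,
    spikein = spikein_size_factors(table),
    none = stats::setNames(rep(1, ncol(table$counts)),
                           colnames(table$counts)))
  table
}

#' RUV-style removal of unwanted variation (optional stage)
#'
#' Estimates `n_factors` unwanted factors from the singular value
#' decomposition of the gene-centered spike-in log2 counts (pseudocount
#' 0.5) and regresses them out of every gene's log2 counts. With
#' `n_factors = 0`, or when the spike-ins carry no between-sample
#' variation, the adjustment is the identity.
#'
#' @param table a `count_table` (size factors applied first if present).
#' @param n_factors number of unwanted factors, `< n_samples`.
#' @param pseudocount added before taking log2.
#' @return matrix of adjusted log2 counts (genes x samples).
#' @export
ruv_like_factor_removal <- function(table, n_factors = 1,
                                    pseudocount = 0.5) {
  stopifnot(inherits(table, "count_table"))
  n_samples <- ncol(table$counts)
  if (n_factors >= n_samples)
    stop("n_factors must be < number of samples (", n_samples, ")")
  logc <- log2(normalized_counts(table) + pseudocount)
  if (n_factors == 0) return(logc)
  sp <- logc[table$gene_info$is_spikein, , drop = FALSE]
  centered <- sweep(sp, 1, rowMeans(sp))
  sv <- svd(centered)
  keep <- sv$d > max(sv$d[1], 1) * 1e-10
  k <- min(n_factors, sum(keep))
  if (k == 0) return(logc)  # spike-ins have no between-sample variance
  W <- sv$v[, seq_len(k), drop = FALSE]  # samples x k
  # Regress each gene's (centered) log profile on W and remove the fit.
  centered_all <- sweep(logc, 1, rowMeans(logc))
  beta <- centered_all %*% W  # W has orthonormal columns
  logc - beta %*% t(W)
}
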