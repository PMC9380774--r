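# Strand-specific differential expression between conditions: per-gene
# log2 fold change and a negative-binomial Wald test with
# method-of-moments dispersion shrunk toward the global mean. This is a
# deliberately simple, fully implemented substitute for a DESeq2 call:
# downstream orientation analyses only need log2FC and up/down/ns calls.

#' Per-gene log2 fold change between conditions
#'
#' `log2((mean_treated + pseudocount) / (mean_reference + pseudocount))`
#' on size-factor-normalized counts. Counts are strand-specific upstream
#' (each gene was quantified on its own strand), so this is the
#' strand-specific fold change.
#'
#' @param table a `count_table` with size factors set.
#' @param conditions length-2 character: reference first, treated second.
#' @param pseudocount added to both means.
#' @return named numeric vector of log2 fold changes.
#' @export
gene_log2fc <- function(table, conditions = c("minus_auxin", "plus_auxin"),
                        pseudocount = 0.5) {
  stopifnot(inherits(table, "count_table"), length(conditions) == 2)
  cond <- table$samples$condition
  if (!all(conditions %in% cond))
    stop("condition(s) missing from table: ",
         paste(setdiff(conditions, cond), collapse = ", "))
  norm <- normalized_counts(table)
  m_ref <- rowMeans(norm[, cond == conditions[1], drop = FALSE])
  m_trt <- rowMeans(norm[, cond == conditions[2], drop = FALSE])
  stats::setNames(log2((m_trt + pseudocount) / (m_ref + pseudocount)),
                  rownames(norm))
}

# Method-of-moments NB dispersion per gene, pooled across conditions and
# shrunk toward the global mean dispersion with `prior_df` pseudo-degrees
# of freedom.
mom_dispersion <- function(norm, cond, conditions, mode, prior_df = 10) {
  per_cond <- lapply(conditions, function(cc) {
    x <- norm[, cond == cc, drop = FALSE]
    list(m = rowMeans(x),
         v = apply(x, 1, stats::var),
         df = ncol(x) - 1)
  })
  num <- Reduce(`+`, lapply(per_cond, function(p)
    p$df * (p$v - p$m) / pmax(p$m, 1e-8)^2))
  df_tot <- sum(vapply(per_cond, `[[`, numeric(1), "df"))
  phi_g <- pmax(num / df_tot, 0)
  prior <- mean(phi_g[is.finite(phi_g)], trim = 0.05)
  switch(mode,
         per_gene = phi_g,
         pooled = rep(prior, length(phi_g)),
         shrunk = (df_tot * phi_g + prior_df * prior) /
           (df_tot + prior_df))
}

#' Negative-binomial Wald test for differential expression
#'
#' Tests `log2FC = 0` per gene using the delta-method variance of the log2
#' mean under NB noise, `Var(log2 mean) = (1/mu + phi) / (n log(2)^2)`,
#' with a method-of-moments dispersion estimate shrunk toward the global
#' trimmed-mean dispersion (`dispersion_mode = "shrunk"`, the default).
#' With a single replicate in any condition no dispersion can be
#' estimated; p-values are refused (NA) and only fold changes are
#' reported.
#'
#' @param table a `count_table` with size factors set.
#' @param conditions reference and treated condition labels.
#' @param dispersion_mode `"shrunk"`, `"per_gene"`, or `"pooled"`.
#' @param pseudocount pseudocount for fold changes and variance floors.
#' @return data.frame: gene_id, strand, is_spikein, base_mean, log2fc,
#'   p_value.
#' @export
nb_test <- function(table, conditions = c("minus_auxin", "plus_auxin"),
                    dispersion_mode = c("shrunk", "per_gene", "pooled"),
                    pseudocount = 0.5) {
  dispersion_mode <- match.arg(dispersion_mode)
  stopifnot(inherits(table, "count_table"))
  cond <- table$samples$condition
  if (!all(conditions %in% cond))
    stop("condition(s) missing from table: ",
         paste(setdiff(conditions, cond), collapse = ", "))
  norm <- normalized_counts(table)
  n_per <- vapply(conditions, function(cc) sum(cond == cc), integer(1))
  lfc <- gene_log2fc(table, conditions, pseudocount)
  base_mean <- rowMeans(norm[, cond %in% conditions, drop = FALSE])
  out <- data.frame(gene_id = table$gene_info$gene_id,
                    strand = table$gene_info$strand,
                    is_spikein = table$gene_info$is_spikein,
                    base_mean = base_mean,
                    log2fc = as.numeric(lfc),
                    p_value = NA_real_,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  if (any(n_per < 2)) {
    message("single replicate in a condition: p-values refused, ",
            "log2 fold changes only")
    return(out)
  }
  phi <- mom_dispersion(norm, cond, conditions, dispersion_mode)
  vars <- sapply(conditions, function(cc) {
    x <- norm[, cond == cc, drop = FALSE]
    m <- pmax(rowMeans(x), pseudocount)
    (1 / m + phi) / (ncol(x) * log(2)^2)
  })
  se <- sqrt(rowSums(vars))
  z <- out$log2fc / se
  out$p_value <- 2 * stats::pnorm(-abs(z))
  out
}

#' Benjamini-Hochberg adjustment and direction calls
#'
#' @param p_values numeric p-values.
#' @param log2fc matching log2 fold changes.
#' @param alpha FDR threshold for calling a gene up or down.
#' @return data.frame: p_value, fdr, direction (`up`/`down`/`ns`).
#' @export
bh_fdr <- function(p_values, log2fc, alpha = 0.05) {
  stopifnot(length(p_values) == length(log2fc))
  fdr <- stats::p.adjust(p_values, method = "BH")
  direction <- ifelse(is.na(fdr) | fdr >= alpha, "ns",
                      ifelse(log2fc > 0, "up", "down"))
  data.frame(p_value = p_values, fdr = fdr, direction = direction,
             stringsAsFactors = FALSE)
}

#' Full differential-expression stage
#'
#' Chains [nb_test()] and [bh_fdr()]; spike-in genes are excluded from the
#' multiple-testing universe (their FDR and direction are NA/ns).
#'
#' @inheritParams nb_test
#' @param alpha FDR threshold.
#' @return data.frame of class `de_result`: gene_id, strand, is_spikein,
#'   base_mean, log2fc, p_value, fdr, direction.
#' @export
de_test <- function(table, conditions = c("minus_auxin", "plus_auxin"),
                    alpha = 0.05,
                    dispersion_mode = c("shrunk", "per_gene", "pooled"),
                    pseudocount = 0.5) {
  res <- nb_test(table, conditions, dispersion_mode, pseudocount)
  res$fdr <- NA_real_
  res$direction <- "ns"
  tgt <- !res$is_spikein
  adj <- bh_fdr(res$p_value[tgt], res$log2fc[tgt], alpha)
  res$fdr[tgt] <- adj$fdr
  res$direction[tgt] <- adj$direction
  attr(res, "alpha") <- alpha
  attr(res, "conditions") <- conditions
  class(res) <- c("de_result", "data.frame")
  res
}
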