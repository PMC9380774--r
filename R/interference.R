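# Opposite-strand and gene-orientation statistics for transcription
# interference: strand-paired log2 changes, their correlation, the
# orientation chi-squared test, and the readthrough index.

# Mean of per-condition coverage tracks normalized by size factors.
#' Average normalized coverage per condition
#'
#' @param coverage named list of per-sample raw `stranded_coverage`.
#' @param samples data.frame with `sample` and `condition`.
#' @param size_factors named per-sample factors (default 1).
#' @return named list of `stranded_coverage`, one per condition.
#' @export
condition_coverage <- function(coverage, samples, size_factors = NULL) {
  sf <- size_factors %||% stats::setNames(rep(1, nrow(samples)),
                                          samples$sample)
  out <- lapply(split(samples$sample, samples$condition), function(ss) {
    tmpl <- coverage[[ss[1]]]
    tracks <- lapply(names(tmpl$tracks), function(chrom) {
      acc <- list(plus = 0, minus = 0)
      for (s in ss) {
        tr <- coverage[[s]]$tracks[[chrom]]
        acc$plus <- acc$plus + tr$plus / sf[[s]]
        acc$minus <- acc$minus + tr$minus / sf[[s]]
      }
      list(plus = acc$plus / length(ss), minus = acc$minus / length(ss))
    })
    names(tracks) <- names(tmpl$tracks)
    stranded_coverage(tracks, tmpl$bin_size, tmpl$chrom_lengths)
  })
  out
}

strand_sum <- function(cov, chrom, strand, from, to) {
  tr <- cov$tracks[[chrom]]
  if (is.null(tr)) return(NA_real_)
  idx <- bins_in_interval(from, to, cov$bin_size, length(tr$plus))
  if (!length(idx)) return(NA_real_)
  sum(tr[[if (strand == "+") "plus" else "minus"]][idx])
}

#' Strand-paired log2 changes per gene
#'
#' For every (non-spike-in) gene, pairs its own-strand log2 fold change
#' (from the DE result) with the log2 ratio of normalized opposite-strand
#' signal summed over the same interval between the two conditions. Genes
#' whose interval holds no coverage bins are excluded and recorded in the
#' `excluded` attribute.
#'
#' @param deresult a `de_result`.
#' @param annotation a `genome_annotation`.
#' @param cov_by_condition list of per-condition `stranded_coverage`
#'   (from [condition_coverage()]).
#' @param conditions reference and treated condition labels.
#' @param pseudocount pseudocount for the opposite-strand ratio.
#' @return data.frame of class `strand_pair_set`: gene_id, strand,
#'   own_lfc, opp_lfc.
#' @export
opposite_strand_pairs <- function(deresult, annotation, cov_by_condition,
                                  conditions = c("minus_auxin",
                                                 "plus_auxin"),
                                  pseudocount = 0.5) {
  stopifnot(all(conditions %in% names(cov_by_condition)))
  genes <- annotation$genes[!annotation$genes$is_spikein, ]
  de <- deresult[match(genes$gene_id, deresult$gene_id), ]
  opp <- ifelse(genes$strand == "+", "-", "+")
  ref <- cov_by_condition[[conditions[1]]]
  trt <- cov_by_condition[[conditions[2]]]
  s_ref <- mapply(strand_sum, chrom = genes$chrom, strand = opp,
                  from = genes$start, to = genes$end,
                  MoreArgs = list(cov = ref))
  s_trt <- mapply(strand_sum, chrom = genes$chrom, strand = opp,
                  from = genes$start, to = genes$end,
                  MoreArgs = list(cov = trt))
  keep <- !is.na(s_ref) & !is.na(s_trt)
  out <- data.frame(gene_id = genes$gene_id[keep],
                    strand = genes$strand[keep],
                    own_lfc = de$log2fc[keep],
                    opp_lfc = log2((s_trt[keep] + pseudocount) /
                                     (s_ref[keep] + pseudocount)),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- genes$gene_id[!keep]
  class(out) <- c("strand_pair_set", "data.frame")
  out
}

#' Strand-paired log2 changes in genome-tiling windows
#'
#' Tiles each chromosome with non-overlapping windows (a chromosome
#' shorter than the window yields a single truncated tile) and computes
#' the per-strand log2 fold change of summed normalized signal in each
#' tile.
#'
#' @param cov_by_condition list of per-condition `stranded_coverage`.
#' @param window tile width in bp (default 1 kb).
#' @param conditions reference and treated condition labels.
#' @param pseudocount pseudocount for the ratios.
#' @param exclude_chroms chromosomes to drop (e.g. the spike-in
#'   chromosome).
#' @return data.frame of class `strand_pair_set`: chrom, start, end,
#'   plus_lfc, minus_lfc.
#' @export
window_pairs <- function(cov_by_condition, window = 1000,
                         conditions = c("minus_auxin", "plus_auxin"),
                         pseudocount = 0.5, exclude_chroms = "spikes") {
  ref <- cov_by_condition[[conditions[1]]]
  trt <- cov_by_condition[[conditions[2]]]
  chroms <- setdiff(names(ref$tracks), exclude_chroms)
  rows <- lapply(chroms, function(chrom) {
    len <- ref$chrom_lengths[[chrom]]
    starts <- seq(0L, max(0L, len - 1L), by = window)
    ends <- pmin(starts + window, len)
    lfc <- function(strand) {
      r <- mapply(strand_sum, from = starts, to = ends,
                  MoreArgs = list(cov = ref, chrom = chrom,
                                  strand = strand))
      t <- mapply(strand_sum, from = starts, to = ends,
                  MoreArgs = list(cov = trt, chrom = chrom,
                                  strand = strand))
      log2((t + pseudocount) / (r + pseudocount))
    }
    data.frame(chrom = chrom, start = starts, end = ends,
               plus_lfc = lfc("+"), minus_lfc = lfc("-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[stats::complete.cases(out[, c("plus_lfc", "minus_lfc")]), ]
  rownames(out) <- NULL
  class(out) <- c("strand_pair_set", "data.frame")
  out
}

#' Correlation between strand-paired log2 changes
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value,
#' between the two paired columns of a `strand_pair_set` (gene pairs:
#' own vs opposite strand; window pairs: plus vs minus strand).
#'
#' @param pairs a `strand_pair_set`, or anything with two numeric columns
#'   named either `own_lfc`/`opp_lfc` or `plus_lfc`/`minus_lfc`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list: estimate (r), p_value, n, method, degenerate (TRUE when
#'   a side has zero variance, in which case r is NA).
#' @export
anticorrelation <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cols <- if (all(c("own_lfc", "opp_lfc") %in% names(pairs)))
    c("own_lfc", "opp_lfc") else c("plus_lfc", "minus_lfc")
  x <- pairs[[cols[1]]]; y <- pairs[[cols[2]]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one strand: correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_, n = length(x),
                method = method, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method, degenerate = FALSE)
}

#' Per-gene orientation class
#'
#' Each gene is classified by the unordered pair of its two flanking
#' junction relations, drawn from codirectional/convergent/divergent, with
#' `chromosome-end` for a missing neighbor. The classification is
#' invariant under mirroring the chromosome with a strand flip.
#'
#' @param annotation a `genome_annotation`.
#' @param include_spikeins keep spike-in genes (default FALSE).
#' @return data.frame: gene_id, left, right, class.
#' @export
classify_orientation <- function(annotation, include_spikeins = FALSE) {
  genes <- annotation$genes
  if (!include_spikeins) genes <- genes[!genes$is_spikein, ]
  j <- annotation$junctions
  left <- j$type[match(genes$gene_id, j$right_gene)]
  right <- j$type[match(genes$gene_id, j$left_gene)]
  left[is.na(left)] <- "chromosome-end"
  right[is.na(right)] <- "chromosome-end"
  cls <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"),
                left, right, USE.NAMES = FALSE)
  data.frame(gene_id = genes$gene_id, left = left, right = right,
             class = cls, stringsAsFactors = FALSE)
}

#' Chi-squared test of direction vs gene orientation
#'
#' Pearson chi-squared test of independence between the DE direction call
#' and the orientation class, with standardized residuals indicating which
#' cells drive the association (e.g. a positive residual for up-regulated
#' genes in codirectional arrangements under readthrough invasion). By
#' default only significant genes (`up`/`down`) enter the table;
#' `include_ns = TRUE` instead classifies every gene by the sign of its
#' fold change.
#'
#' @param deresult a `de_result`.
#' @param classes output of [classify_orientation()].
#' @param include_ns include non-significant genes, classed by log2FC sign.
#' @param min_expected below this expected cell count a warning is issued
#'   and `exact_recommended` is set.
#' @return list of class `contingency_result`: observed, expected,
#'   statistic, dof, p_value, stdres, exact_recommended.
#' @export
orientation_chi2 <- function(deresult, classes, include_ns = FALSE,
                             min_expected = 1) {
  m <- merge(as.data.frame(deresult)[, c("gene_id", "log2fc", "direction")],
             classes[, c("gene_id", "class")], by = "gene_id")
  if (include_ns) {
    dir <- ifelse(m$log2fc > 0, "up", "down")
  } else {
    m <- m[m$direction %in% c("up", "down"), ]
    dir <- m$direction
  }
  tab <- table(direction = dir, class = m$class)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 direction classes and 2 orientation classes")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  exact_recommended <- any(ct$expected < min_expected)
  if (exact_recommended)
    warning("expected cell count < ", min_expected,
            "; consider an exact test")
  structure(list(observed = ct$observed, expected = ct$expected,
                 statistic = unname(ct$statistic),
                 dof = unname(ct$parameter),
                 p_value = ct$p.value, stdres = ct$stdres,
                 exact_recommended = exact_recommended),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("chi-squared test of independence: X2 =", round(x$statistic, 3),
      ", dof =", x$dof, ", p =", signif(x$p_value, 3), "\n")
  print(x$observed)
  invisible(x)
}

#' Per-gene readthrough index
#'
#' Ratio of the between-condition fold change in a window downstream of
#' the poly(A) site to the fold change in the 1-kb genic region upstream
#' of it, strand-aware (for a minus-strand gene the downstream window
#' extends to lower coordinates). An index of ~1 means no specific
#' readthrough; genes with zero upstream signal in both conditions are
#' flagged with an undefined (NA) index.
#'
#' @param cov_by_condition list of per-condition `stranded_coverage`.
#' @param annotation a `genome_annotation`.
#' @param downstream_window bp downstream of the poly(A) site.
#' @param upstream_window bp upstream (genic side) of the poly(A) site.
#' @param conditions reference and treated condition labels.
#' @param pseudocount pseudocount for the fold changes.
#' @return data.frame: gene_id, strand, fc_downstream, fc_upstream, index,
#'   undefined.
#' @export
readthrough_index <- function(cov_by_condition, annotation,
                              downstream_window = 500,
                              upstream_window = 1000,
                              conditions = c("minus_auxin", "plus_auxin"),
                              pseudocount = 0.5) {
  genes <- annotation$genes[!annotation$genes$is_spikein, ]
  ref <- cov_by_condition[[conditions[1]]]
  trt <- cov_by_condition[[conditions[2]]]
  fc_win <- function(from, to, chrom, strand) {
    a <- strand_sum(ref, chrom, strand, from, to)
    b <- strand_sum(trt, chrom, strand, from, to)
    c(ref = a, trt = b,
      fc = (b + pseudocount) / (a + pseudocount))
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      down <- fc_win(g$polyA_site, g$polyA_site + downstream_window,
                     g$chrom, g$strand)
      up <- fc_win(g$polyA_site - upstream_window, g$polyA_site,
                   g$chrom, g$strand)
    } else {
      down <- fc_win(g$polyA_site - downstream_window, g$polyA_site,
                     g$chrom, g$strand)
      up <- fc_win(g$polyA_site, g$polyA_site + upstream_window,
                   g$chrom, g$strand)
    }
    undef <- isTRUE(up[["ref"]] == 0 && up[["trt"]] == 0) ||
      is.na(up[["fc"]]) || is.na(down[["fc"]])
    data.frame(gene_id = g$gene_id, strand = g$strand,
               fc_downstream = down[["fc"]], fc_upstream = up[["fc"]],
               index = if (undef) NA_real_ else
                 down[["fc"]] / up[["fc"]],
               undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
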