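# Negative-binomial sampling of gene counts and observed coverage.

#' Construct a count table
#'
#' @param counts integer matrix, genes x samples (dimnames required).
#' @param gene_info data.frame with gene_id, chrom, strand, is_spikein
#'   matching the rows of `counts`.
#' @param samples data.frame with `sample` and `condition` columns matching
#'   the columns of `counts`.
#' @param size_factors optional named per-sample factors (> 0).
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, gene_info, samples, size_factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(gene_info),
            ncol(counts) == nrow(samples),
            all(counts >= 0),
            all(c("gene_id", "strand", "is_spikein") %in% names(gene_info)),
            all(c("sample", "condition") %in% names(samples)))
  if (!any(gene_info$is_spikein))
    stop("count table must contain at least one spike-in gene")
  rownames(counts) <- gene_info$gene_id
  colnames(counts) <- samples$sample
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  }
  structure(list(counts = counts, gene_info = gene_info,
                 samples = samples, size_factors = size_factors),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", sum(x$gene_info$is_spikein), "spike-ins );",
      if (is.null(x$size_factors)) "unnormalized" else "size factors set",
      "\n")
  invisible(x)
}

#' Size-factor-normalized counts
#'
#' @param table a `count_table` with size factors set (all 1 otherwise).
#' @return numeric matrix of counts divided by per-sample size factors.
#' @export
normalized_counts <- function(table) {
  stopifnot(inherits(table, "count_table"))
  sf <- table$size_factors %||% rep(1, ncol(table$counts))
  sweep(table$counts, 2, sf, "/")
}

nb_draw <- function(n, mu, phi, poisson = FALSE) {
  if (poisson) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu,
                                                       size = 1 / phi)
}

#' Sample observed counts and coverage from expected signal
#'
#' Draws, for each sample, (i) per-gene counts (the featureCounts-style
#' strand-specific quantification over the gene interval, including any
#' readthrough invading it on the same strand) and (ii) per-bin observed
#' coverage. Both are negative binomial with mean
#' `library_scale * expected` and dispersion `phi = nb_dispersion`
#' (variance mu + phi mu^2); `poisson = TRUE` selects the phi -> 0 limit.
#' Spike-in genes have condition-independent expected signal, so their
#' count means differ between samples only through `library_scale`.
#'
#' @param expected named list of `simulate_expected_coverage()` coverage
#'   objects, one per condition (names must match
#'   `config$termination_failure`).
#' @param annotation the `genome_annotation` the signal was simulated from.
#' @param config the [sim_config()].
#' @param poisson use Poisson noise (dispersion-free limit).
#' @return list with `counts` (a `count_table`), `coverage` (named list of
#'   raw `stranded_coverage`, one per sample), and `samples` (data.frame:
#'   sample, condition, library_scale).
#' @export
sample_counts <- function(expected, annotation, config, poisson = FALSE) {
  validate_sim_config(config)
  conds <- names(config$termination_failure)
  stopifnot(all(conds %in% names(expected)))
  genes <- annotation$genes
  bs <- config$bin_size

  samples <- expand.grid(rep = seq_len(config$n_replicates),
                         condition = conds, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_rep%d", samples$condition, samples$rep)
  ls <- rep_len(config$library_scale, nrow(samples))
  samples <- data.frame(sample = samples$sample,
                        condition = samples$condition,
                        library_scale = ls, stringsAsFactors = FALSE)

  # Expected per-gene signal: sum of same-strand expected coverage over the
  # gene interval (captures invading readthrough on the gene's own strand).
  gene_mu <- sapply(conds, function(cond) {
    cov <- expected[[cond]]
    vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      tr <- cov$tracks[[g$chrom]]
      idx <- bins_in_interval(g$start, g$end, bs, length(tr$plus))
      key <- if (g$strand == "+") "plus" else "minus"
      sum(tr[[key]][idx])
    }, numeric(1))
  })

  phi <- config$nb_dispersion
  with_seed(derive_seed(config$seed, "counts"), {
    counts <- matrix(0L, nrow(genes), nrow(samples))
    coverage <- vector("list", nrow(samples))
    names(coverage) <- samples$sample
    for (s in seq_len(nrow(samples))) {
      cond <- samples$condition[s]
      counts[, s] <- nb_draw(nrow(genes), samples$library_scale[s] *
                               gene_mu[, cond], phi, poisson)
      tracks <- lapply(expected[[cond]]$tracks, function(tr) {
        list(plus = as.numeric(nb_draw(length(tr$plus),
                                       samples$library_scale[s] * tr$plus,
                                       phi, poisson)),
             minus = as.numeric(nb_draw(length(tr$minus),
                                        samples$library_scale[s] * tr$minus,
                                        phi, poisson)))
      })
      coverage[[s]] <- stranded_coverage(tracks, bs,
                                         annotation$chrom_lengths)
    }
    ct <- count_table(counts, genes[, c("gene_id", "chrom", "strand",
                                        "is_spikein")],
                      samples[, c("sample", "condition")])
    list(counts = ct, coverage = coverage, samples = samples)
  })
}

#' Run the full generator: genome, expected signal, observed data
#'
#' Convenience wrapper chaining [generate_genome()],
#' [simulate_expected_coverage()] for every condition, and
#' [sample_counts()].
#'
#' @param config a [sim_config()].
#' @param poisson passed to [sample_counts()].
#' @return list with `annotation`, `expected` (per-condition coverage),
#'   `truth` (row-bound ground-truth data.frame), `counts`, `coverage`
#'   (per-sample observed), and `samples`.
#' @export
simulate_dataset <- function(config, poisson = FALSE) {
  ann <- generate_genome(config)
  conds <- names(config$termination_failure)
  sim <- lapply(conds, function(cond)
    simulate_expected_coverage(ann, config, cond))
  names(sim) <- conds
  expected <- lapply(sim, `[[`, "coverage")
  truth <- do.call(rbind, lapply(sim, `[[`, "truth"))
  rownames(truth) <- NULL
  obs <- sample_counts(expected, ann, config, poisson = poisson)
  list(annotation = ann, expected = expected, truth = truth,
       counts = obs$counts, coverage = obs$coverage, samples = obs$samples)
}
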