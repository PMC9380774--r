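# End-to-end orchestration over the synthetic world: simulate ->
# normalize -> differential expression -> interference statistics ->
# profiles/clustering, with a machine-readable summary and optional
# on-disk outputs. One global seed deterministically derives all
# per-stage seeds, so identical config + seed gives identical output.

#' Run the full synthetic readthrough analysis pipeline
#'
#' @param config a [sim_config()]; its seed is overridden by `seed`.
#' @param seed global seed.
#' @param out_dir if non-NULL, write stage outputs there (GFF3 annotation,
#'   per-sample bedGraph pairs, counts TSV, DE TSV, pair TSVs, and
#'   `summary.json`).
#' @param stages named logical toggles for the optional stages
#'   (`interference`, `profiles`); a toggled-off stage is absent from the
#'   report.
#' @param k number of k-means clusters for convergent pairs.
#' @param alpha FDR threshold for DE calls.
#' @return list of class `termread_report` with elements `config_summary`,
#'   `sizes`, `size_factors`, `de`, and (when enabled) `interference` and
#'   `profiles`, plus `objects` carrying the full intermediate objects.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         out_dir = NULL,
                         stages = c(interference = TRUE, profiles = TRUE),
                         k = 4, alpha = 0.05) {
  config$seed <- as.integer(seed)
  validate_sim_config(config)
  sim <- simulate_dataset(config)
  ct <- estimate_size_factors(sim$counts, "spikein")
  de <- de_test(ct, alpha = alpha)
  covc <- condition_coverage(sim$coverage, sim$samples,
                             ct$size_factors)
  report <- list(
    config_summary = list(n_genes = config$n_genes,
                          n_spikeins = config$n_spikeins,
                          n_replicates = config$n_replicates,
                          alpha = alpha, seed = seed),
    sizes = list(junction_fractions =
                   as.list(junction_fractions(sim$annotation))),
    size_factors = as.list(ct$size_factors),
    de = list(n_up = sum(de$direction == "up"),
              n_down = sum(de$direction == "down"),
              n_ns = sum(de$direction == "ns" & !de$is_spikein)))
  objects <- list(config = config, annotation = sim$annotation,
                  truth = sim$truth, counts = ct, de = de,
                  condition_coverage = covc)

  if (isTRUE(stages[["interference"]])) {
    gene_pairs <- opposite_strand_pairs(de, sim$annotation, covc)
    win_pairs <- window_pairs(covc)
    ac_gene <- anticorrelation(gene_pairs)
    ac_win <- anticorrelation(win_pairs)
    classes <- classify_orientation(sim$annotation)
    chi2 <- tryCatch(suppressWarnings(orientation_chi2(de, classes)),
                     error = function(e) NULL)
    report$interference <- list(
      gene_r = ac_gene$estimate, gene_p = ac_gene$p_value,
      window_r = ac_win$estimate, window_p = ac_win$p_value,
      chi2_statistic = if (is.null(chi2)) NA else chi2$statistic,
      chi2_p = if (is.null(chi2)) NA else chi2$p_value)
    objects$gene_pairs <- gene_pairs
    objects$window_pairs <- win_pairs
    objects$chi2 <- chi2
  }

  if (isTRUE(stages[["profiles"]])) {
    mg <- lapply(covc, function(cov)
      metagene_average(metagene_matrix(cov, sim$annotation,
                                       bin = config$bin_size)))
    cpm_mat <- convergent_pair_matrix(covc, sim$annotation,
                                      bin = config$bin_size)
    kk <- min(k, nrow(cpm_mat$matrix))
    clust <- kmeans_cluster(cpm_mat$matrix, k = kk, seed = seed)
    partner <- cluster_partner_stats(de, cpm_mat$pairs,
                                     clust$assignments)
    report$profiles <- list(n_convergent_pairs = nrow(cpm_mat$pairs),
                            cluster_sizes = as.list(clust$sizes),
                            wcss = clust$wcss)
    objects$metagene <- mg
    objects$pair_matrix <- cpm_mat
    objects$clusters <- clust
    objects$partner_stats <- partner
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_annotation(sim$annotation, file.path(out_dir, "genes.gff3"))
    write_counts(ct, file.path(out_dir, "counts.tsv"))
    for (s in names(sim$coverage))
      write_bedgraph(sim$coverage[[s]], file.path(out_dir, s))
    utils::write.table(as.data.frame(de),
                       file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(objects$gene_pairs))
      utils::write.table(as.data.frame(objects$gene_pairs),
                         file.path(out_dir, "gene_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(objects$partner_stats))
      utils::write.table(objects$partner_stats,
                         file.path(out_dir, "cluster_partner_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "objects")],
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report$objects <- objects
  class(report) <- "termread_report"
  report
}

#' @export
print.termread_report <- function(x, ...) {
  cat("termread pipeline report (seed", x$config_summary$seed, ")\n")
  cat("  DE: up =", x$de$n_up, ", down =", x$de$n_down,
      ", ns =", x$de$n_ns, "\n")
  if (!is.null(x$interference))
    cat("  strand anticorrelation: gene r =",
        round(x$interference$gene_r, 3), ", window r =",
        round(x$interference$window_r, 3), ", chi2 p =",
        signif(x$interference$chi2_p, 3), "\n")
  if (!is.null(x$profiles))
    cat("  convergent pairs:", x$profiles$n_convergent_pairs,
        "in clusters", paste(unlist(x$profiles$cluster_sizes),
                             collapse = "/"), "\n")
  invisible(x)
}
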