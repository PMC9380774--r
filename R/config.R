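#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic nascent RNA-seq
#' world: a compact yeast-like chromosome populated with genes in
#' codirectional, convergent, and divergent arrangements, two conditions
#' (`minus_auxin`, `plus_auxin`) differing only in the termination-failure
#' rate, exponential readthrough decay past the poly(A) site, optional
#' transcription interference on opposite-strand promoters, and
#' negative-binomial count noise with condition-invariant spike-ins.
#'
#' Coordinates are 0-based, half-open throughout (BED convention); a
#' minus-strand gene stores its poly(A) site at the interval start.
#'
#' @param n_genes number of genes on the main chromosome.
#' @param chrom_length main chromosome length in bp; `NULL` sizes it
#'   automatically to fit the genes with ~15% slack.
#' @param gene_length_range min/max gene length (bp), drawn uniformly.
#' @param intergap_mean,intergap_sd intergenic gap distribution (bp), normal
#'   truncated at 50 bp. Yeast-like default: mean 300 bp.
#' @param strand_scheme target fractions of codirectional/convergent/divergent
#'   junctions. Convergent and divergent junctions alternate along any strand
#'   sequence, so their targets must be (near) equal; strands are assigned by
#'   a two-state Markov chain with P(same strand) = codirectional fraction.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   per-gene baseline body signal e_i (arbitrary coverage units).
#' @param termination_failure named fraction f of polymerases reading through
#'   the poly(A) site, per condition, each in \[0,1\].
#' @param readthrough_decay_L exponential decay length of readthrough signal
#'   (bp): at distance d past the poly(A) site the readthrough signal is
#'   e_i * f * exp(-d/L).
#' @param interference_alpha strength (>= 0) of transcription interference:
#'   a gene whose promoter window receives opposite-strand readthrough I has
#'   its effective expression reduced to e / (1 + alpha * I).
#' @param promoter_window half-width (bp) of the promoter window around the
#'   TSS over which interfering readthrough is averaged.
#' @param nb_dispersion negative-binomial dispersion phi > 0
#'   (variance = mu + phi * mu^2).
#' @param library_scale per-sample sequencing-depth factor; scalar or one
#'   value per sample (conditions x replicates).
#' @param n_spikeins number of condition-invariant spike-in genes, placed on
#'   a dedicated `spikes` chromosome (mirroring a merged two-species
#'   reference).
#' @param n_replicates replicates per condition.
#' @param bin_size coverage bin size (bp).
#' @param seed integer seed; all generators are bit-reproducible given it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       chrom_length = NULL,
                       gene_length_range = c(600, 2000),
                       intergap_mean = 300,
                       intergap_sd = 150,
                       strand_scheme = c(codirectional = 0.5,
                                         convergent = 0.25,
                                         divergent = 0.25),
                       expression_meanlog = 3,
                       expression_sdlog = 1,
                       termination_failure = c(minus_auxin = 0.05,
                                               plus_auxin = 0.5),
                       readthrough_decay_L = 1500,
                       interference_alpha = 0.5,
                       promoter_window = 100,
                       nb_dispersion = 0.05,
                       library_scale = 1,
                       n_spikeins = 20,
                       n_replicates = 2,
                       bin_size = 10,
                       seed = 1) {
  if (is.null(chrom_length)) {
    chrom_length <- ceiling(
      1.15 * (n_genes * (mean(gene_length_range) + intergap_mean) +
                intergap_mean))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              chrom_length = as.integer(chrom_length),
              gene_length_range = as.integer(gene_length_range),
              intergap_mean = intergap_mean,
              intergap_sd = intergap_sd,
              strand_scheme = strand_scheme,
              expression_meanlog = expression_meanlog,
              expression_sdlog = expression_sdlog,
              termination_failure = termination_failure,
              readthrough_decay_L = readthrough_decay_L,
              interference_alpha = interference_alpha,
              promoter_window = promoter_window,
              nb_dispersion = nb_dispersion,
              library_scale = library_scale,
              n_spikeins = as.integer(n_spikeins),
              n_replicates = as.integer(n_replicates),
              bin_size = as.integer(bin_size),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (n_genes < 2) stop("n_genes must be >= 2")
    if (chrom_length <= 0) stop("chrom_length must be positive")
    if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
        gene_length_range[1] > gene_length_range[2])
      stop("gene_length_range must be a positive (min, max) pair")
    if (intergap_mean <= 0 || intergap_sd < 0)
      stop("intergenic gap distribution must have positive mean, sd >= 0")
    ss <- strand_scheme
    if (length(ss) != 3 || any(ss < 0) || abs(sum(ss) - 1) > 1e-6 ||
        !all(c("codirectional", "convergent", "divergent") %in% names(ss)))
      stop("strand_scheme must be named fractions summing to 1")
    if (abs(ss[["convergent"]] - ss[["divergent"]]) > 0.05)
      stop("convergent and divergent junction targets must be (near) equal: ",
           "they alternate along any strand sequence")
    if (is.null(names(termination_failure)) ||
        length(termination_failure) < 1 ||
        any(termination_failure < 0 | termination_failure > 1))
      stop("termination_failure must be a named vector with values in [0,1]")
    if (readthrough_decay_L <= 0) stop("readthrough_decay_L must be > 0")
    if (interference_alpha < 0) stop("interference_alpha must be >= 0")
    if (promoter_window <= 0) stop("promoter_window must be > 0")
    if (nb_dispersion <= 0) stop("nb_dispersion (phi) must be > 0")
    if (any(library_scale <= 0)) stop("library_scale must be > 0")
    if (n_spikeins < 1) stop("n_spikeins must be >= 1")
    if (n_replicates < 1) stop("n_replicates must be >= 1")
    if (bin_size < 1) stop("bin_size must be >= 1")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes on", x$chrom_length, "bp;",
      x$n_spikeins, "spike-ins;", x$n_replicates, "replicates x",
      length(x$termination_failure), "conditions\n")
  cat("  f =", paste(names(x$termination_failure),
                     x$termination_failure, sep = "=", collapse = ", "),
      "| L =", x$readthrough_decay_L, "bp | alpha =",
      x$interference_alpha, "| phi =", x$nb_dispersion,
      "| seed =", x$seed, "\n")
  invisible(x)
}
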