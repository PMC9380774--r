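# Stranded binned coverage container and expected-signal simulation.

#' Construct a stranded coverage object
#'
#' Per-chromosome, per-strand binned signal. Bin `i` (1-based index) covers
#' the half-open interval `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param tracks named list (one element per chromosome) of lists with
#'   numeric vectors `plus` and `minus` of equal length.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param normalization `"raw"` or `"CPM"`.
#' @return an object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(tracks, bin_size, chrom_lengths,
                              normalization = "raw") {
  stopifnot(is.list(tracks), length(tracks) >= 1, !is.null(names(tracks)))
  for (chrom in names(tracks)) {
    tr <- tracks[[chrom]]
    if (!all(c("plus", "minus") %in% names(tr)))
      stop("track for ", chrom, " must have plus and minus strands")
    if (length(tr$plus) != length(tr$minus))
      stop("plus/minus bin grids differ for ", chrom)
    if (!all(is.finite(tr$plus)) || !all(is.finite(tr$minus)))
      stop("coverage values must be finite")
    if (any(tr$plus < 0) || any(tr$minus < 0))
      stop("coverage values must be >= 0")
  }
  structure(list(tracks = tracks,
                 bin_size = as.integer(bin_size),
                 chrom_lengths = chrom_lengths,
                 normalization = match.arg(normalization, c("raw", "CPM"))),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  nb <- sum(vapply(x$tracks, function(t) length(t$plus), integer(1)))
  cat("stranded_coverage:", length(x$tracks), "chromosome(s),",
      nb, "bins/strand total, bin_size =", x$bin_size,
      "bp,", x$normalization, "\n")
  invisible(x)
}

coverage_total <- function(cov) {
  sum(vapply(cov$tracks,
             function(t) sum(t$plus) + sum(t$minus), numeric(1)))
}

n_bins_for <- function(chrom_length, bin_size) {
  as.integer(ceiling(chrom_length / bin_size))
}

# 1-based bin indices whose midpoints fall inside [from, to) (0-based bp).
bins_in_interval <- function(from, to, bin_size, n_bins) {
  mids_lo <- ceiling((from - bin_size / 2) / bin_size) + 1
  mids_hi <- ceiling((to - bin_size / 2) / bin_size)
  lo <- max(1L, as.integer(mids_lo))
  hi <- min(n_bins, as.integer(mids_hi))
  if (lo > hi) integer(0) else lo:hi
}

#' Readthrough signal at a distance past the poly(A) site
#'
#' Under the generator's model a gene with baseline body signal `e` and
#' termination-failure fraction `f` leaves readthrough signal
#' `e * f * exp(-d / L)` at distance `d` bp past its poly(A) site, on its
#' own strand.
#'
#' @param e baseline body signal (coverage units).
#' @param f termination-failure fraction in \[0,1\].
#' @param d distance past the poly(A) site (bp, >= 0).
#' @param L exponential decay length (bp).
#' @return readthrough signal (coverage units); vectorized.
#' @export
readthrough_signal <- function(e, f, d, L) {
  stopifnot(all(d >= 0), L > 0)
  e * f * exp(-d / L)
}

#' Simulate expected stranded coverage for one condition
#'
#' Computes the noise-free expected signal implied by the generator model:
#' constant signal `e'_i` over each gene body, exponentially decaying
#' readthrough `e_i * f * exp(-d/L)` downstream of each poly(A) site on the
#' gene's own strand, and transcription interference applied in a single
#' pass from baselines: the interference input `I_j` is the mean
#' opposite-strand readthrough over the promoter window (TSS +/-
#' `promoter_window` bp) and `e'_j = e_j / (1 + alpha * I_j)`. Spike-in
#' genes have `f = 0` and are exempt from interference, making their
#' expected signal condition-invariant.
#'
#' Baseline expression `e_i` is drawn from the configured log-normal using a
#' seed derived only from `config$seed`, so all conditions share the same
#' baselines.
#'
#' @param annotation a `genome_annotation` from [generate_genome()].
#' @param config the [sim_config()] used to generate it.
#' @param condition name of a condition in `config$termination_failure`.
#' @return list with `coverage` (a raw `stranded_coverage`) and `truth`
#'   (data.frame: gene_id, condition, e, e_prime, f, interference_input).
#' @export
simulate_expected_coverage <- function(annotation, config, condition) {
  validate_sim_config(config)
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!condition %in% names(config$termination_failure))
    stop("unknown condition: ", condition)
  f_cond <- config$termination_failure[[condition]]
  genes <- annotation$genes
  e <- with_seed(derive_seed(config$seed, "expression"),
                 stats::rlnorm(nrow(genes), config$expression_meanlog,
                               config$expression_sdlog))
  f_gene <- ifelse(genes$is_spikein, 0, f_cond)

  bs <- config$bin_size
  L <- config$readthrough_decay_L
  empty_tracks <- lapply(annotation$chrom_lengths, function(len) {
    nb <- n_bins_for(len, bs)
    list(plus = numeric(nb), minus = numeric(nb))
  })

  # Pass 1: readthrough-only tracks from baseline e.
  rt <- empty_tracks
  d_max <- 12 * L  # exp(-12) ~ 6e-6: negligible beyond this
  for (i in seq_len(nrow(genes))) {
    if (f_gene[i] == 0) next
    g <- genes[i, ]
    nb <- length(rt[[g$chrom]]$plus)
    if (g$strand == "+") {
      idx <- bins_in_interval(g$polyA_site, g$polyA_site + d_max, bs, nb)
      d <- (idx - 0.5) * bs - g$polyA_site
    } else {
      idx <- bins_in_interval(g$polyA_site - d_max, g$polyA_site, bs, nb)
      d <- g$polyA_site - (idx - 0.5) * bs
    }
    keep <- d >= 0
    idx <- idx[keep]; d <- d[keep]
    if (!length(idx)) next
    key <- if (g$strand == "+") "plus" else "minus"
    rt[[g$chrom]][[key]][idx] <-
      rt[[g$chrom]][[key]][idx] + readthrough_signal(e[i], f_gene[i], d, L)
  }

  # Interference input: mean opposite-strand readthrough over the promoter.
  pw <- config$promoter_window
  I <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$is_spikein) next
    tss <- if (g$strand == "+") g$start else g$end
    nb <- length(rt[[g$chrom]]$plus)
    idx <- bins_in_interval(tss - pw, tss + pw, bs, nb)
    if (!length(idx)) next
    opp <- if (g$strand == "+") "minus" else "plus"
    I[i] <- mean(rt[[g$chrom]][[opp]][idx])
  }
  e_prime <- ifelse(genes$is_spikein, e,
                    e / (1 + config$interference_alpha * I))

  # Pass 2: full expected signal = gene bodies at e' plus readthrough.
  tracks <- rt
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    nb <- length(tracks[[g$chrom]]$plus)
    idx <- bins_in_interval(g$start, g$end, bs, nb)
    if (!length(idx)) next
    key <- if (g$strand == "+") "plus" else "minus"
    tracks[[g$chrom]][[key]][idx] <- tracks[[g$chrom]][[key]][idx] + e_prime[i]
  }

  list(coverage = stranded_coverage(tracks, bs, annotation$chrom_lengths),
       truth = data.frame(gene_id = genes$gene_id,
                          condition = condition,
                          e = e,
                          e_prime = e_prime,
                          f = f_gene,
                          interference_input = I,
                          stringsAsFactors = FALSE))
}
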