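# Generators for the in vitro cleavage time courses and qPCR Ct tables.

#' Simulate cleavage time courses under the exponential-plateau model
#'
#' Generates replicate percent-cleaved values
#' `Y(t) = Y_max - (Y_max - Y_0) * exp(-k t) + N(0, noise_sd)` for one or
#' more complexes (one rate constant each), together with the synthetic
#' band intensities they would have been quantified from
#' (`intensity = (1 - Y/100) * intensity_t0`).
#'
#' @param y_max plateau (% of initial substrate cleaved), shared.
#' @param y_0 value at t = 0 (%), shared; must satisfy 0 <= y_0 < y_max <= 100.
#' @param k per-complex rate constants (min^-1), optionally named.
#' @param timepoints times in minutes (>= 0).
#' @param noise_sd Gaussian noise sd in percentage points.
#' @param n_rep replicates per timepoint.
#' @param seed integer seed.
#' @return data.frame of class `time_course_set` with columns complex,
#'   replicate, time_min, pct_cleaved, intensity, intensity_t0.
#' @export
simulate_cleavage_timecourse <- function(y_max, y_0, k, timepoints,
                                         noise_sd = 0, n_rep = 1, seed = 1) {
  if (!(y_0 >= 0 && y_0 < y_max && y_max <= 100))
    stop("parameters must satisfy 0 <= y_0 < y_max <= 100")
  if (any(k <= 0)) stop("rate constants k must be > 0")
  if (any(timepoints < 0)) stop("timepoints must be >= 0")
  if (is.null(names(k))) names(k) <- sprintf("complex%d", seq_along(k))
  grid <- expand.grid(time_min = timepoints,
                      replicate = seq_len(n_rep),
                      complex = names(k),
                      stringsAsFactors = FALSE)
  mu <- y_max - (y_max - y_0) * exp(-k[grid$complex] * grid$time_min)
  y <- with_seed(derive_seed(seed, "kinetics"),
                 mu + stats::rnorm(nrow(grid), 0, noise_sd))
  out <- data.frame(complex = grid$complex,
                    replicate = grid$replicate,
                    time_min = grid$time_min,
                    pct_cleaved = as.numeric(y),
                    intensity = (1 - as.numeric(y) / 100) * 100,
                    intensity_t0 = 100,
                    stringsAsFactors = FALSE)
  class(out) <- c("time_course_set", "data.frame")
  out
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Builds Ct values for target amplicons in two conditions assuming perfect
#' amplification efficiency (Ct drops by one cycle per doubling of
#' template): the +auxin Ct of a target equals its -auxin Ct minus
#' log2(fold change), and a condition-wide Ct shift (e.g. different cDNA
#' input) is added to targets and spike-ins alike so that spike-in
#' normalization is actually exercised. At `noise_sd_ct = 0` the qpcr
#' module recovers the input fold changes exactly.
#'
#' @param true_fold_changes named vector of per-amplicon fold changes
#'   (+auxin over -auxin), > 0.
#' @param spikein_cts named vector of baseline spike-in Ct values (one per
#'   spike-in amplicon).
#' @param noise_sd_ct Gaussian Ct noise (cycles).
#' @param n_replicates biological replicates per condition.
#' @param base_ct baseline -auxin Ct of every target amplicon.
#' @param condition_shift named per-condition Ct offset applied to all
#'   amplicons (cancels under spike-in normalization).
#' @param conditions condition labels (reference first).
#' @param seed integer seed.
#' @return data.frame of class `qpcr_table` (amplicon, condition,
#'   replicate, ct) with attribute `spike_amplicons`.
#' @export
simulate_qpcr <- function(true_fold_changes, spikein_cts,
                          noise_sd_ct = 0, n_replicates = 3,
                          base_ct = 22,
                          condition_shift = c(minus_auxin = 0,
                                              plus_auxin = 0.7),
                          conditions = c("minus_auxin", "plus_auxin"),
                          seed = 1) {
  if (any(true_fold_changes <= 0)) stop("fold changes must be > 0")
  if (is.null(names(true_fold_changes)) || is.null(names(spikein_cts)))
    stop("true_fold_changes and spikein_cts must be named")
  stopifnot(length(conditions) == 2,
            all(conditions %in% names(condition_shift)))
  rows <- list()
  for (cond in conditions) {
    shift <- condition_shift[[cond]]
    for (r in seq_len(n_replicates)) {
      tgt <- rep(base_ct + shift, length(true_fold_changes)) -
        if (cond == conditions[2]) log2(true_fold_changes) else 0
      rows[[length(rows) + 1]] <- data.frame(
        amplicon = c(names(true_fold_changes), names(spikein_cts)),
        condition = cond, replicate = r,
        ct = c(tgt, spikein_cts + shift),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$ct <- with_seed(derive_seed(seed, "qpcr"),
                      out$ct + stats::rnorm(nrow(out), 0, noise_sd_ct))
  rownames(out) <- NULL
  attr(out, "spike_amplicons") <- names(spikein_cts)
  class(out) <- c("qpcr_table", "data.frame")
  out
}
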