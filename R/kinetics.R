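# Quantitation and global fitting of in vitro cleavage time courses under
# the exponential plateau model Y(t) = Y_max - (Y_max - Y_0) exp(-k t),
# with Y_max and Y_0 shared ("globally restrained") across complexes and
# one rate constant k per complex; analytic half-time
# t50 = ln(2 (Y_max - Y_0) / Y_max) / k, the time at which Y = Y_max / 2.

#' Percent of substrate cleaved
#'
#' `Y_t = (1 - substrate_t / substrate_t0) * 100`, per row of a time
#' course. Values are not clipped to \[0, 100\]: noise can push them
#' outside and clipping would bias the fit.
#'
#' @param timecourse data.frame with columns `intensity` and
#'   `intensity_t0` (plus any identifiers).
#' @return the data.frame with a `pct_cleaved` column (re)computed.
#' @export
percent_cleaved <- function(timecourse) {
  stopifnot(all(c("intensity", "intensity_t0") %in% names(timecourse)))
  if (any(is.na(timecourse$intensity_t0) | timecourse$intensity_t0 <= 0))
    stop("initial substrate intensity (intensity_t0) must be > 0")
  timecourse$pct_cleaved <-
    (1 - timecourse$intensity / timecourse$intensity_t0) * 100
  timecourse
}

plateau_y <- function(t, y_max, y_0, k) y_max - (y_max - y_0) * exp(-k * t)

# Start values: Y_0 from the earliest timepoint, Y_max from the latest,
# k from the slope of log(Y_max - Y) vs t.
plateau_start <- function(df) {
  t_split <- split(df$pct_cleaved, df$time_min)
  means <- vapply(t_split, mean, numeric(1))
  y0 <- means[[1]]
  ymax <- max(means[[length(means)]], y0 + 1)
  ks <- vapply(split(df, df$complex), function(d) {
    resid <- pmax(ymax * 1.001 - d$pct_cleaved, 1e-6)
    sl <- stats::coef(stats::lm(log(resid) ~ d$time_min))[2]
    max(-sl, 1e-4)
  }, numeric(1))
  list(y_max = min(ymax, 100), y_0 = max(y0, 0), k = unname(ks))
}

#' Global exponential-plateau fit of cleavage time courses
#'
#' Joint least squares over all complexes with shared `Y_max` and `Y_0`
#' and a per-complex rate constant `k` (bounded below at `k_lower`).
#' `nls` (port algorithm) is tried first; if it fails to converge the
#' best `optim` iterate is reported with `converged = FALSE` via an error
#' carrying the fit, unless `allow_fallback = TRUE`.
#'
#' @param timecourse data.frame with columns complex, time_min,
#'   pct_cleaved (see [percent_cleaved()] and
#'   [simulate_cleavage_timecourse()]).
#' @param k_lower lower bound on the rate constants (min^-1).
#' @param allow_fallback on `nls` failure return the best `optim` iterate
#'   (flagged) instead of erroring.
#' @return object of class `plateau_fit`: y_max, y_0, k (named per
#'   complex), t50 (named), r2 (named per complex), converged, method,
#'   data.
#' @export
fit_global_plateau <- function(timecourse, k_lower = 1e-6,
                               allow_fallback = TRUE) {
  df <- timecourse
  stopifnot(all(c("complex", "time_min", "pct_cleaved") %in% names(df)))
  df$complex <- as.character(df$complex)
  complexes <- unique(df$complex)
  for (cx in complexes)
    if (length(unique(df$time_min[df$complex == cx])) < 3)
      stop("need >= 3 distinct timepoints per complex (", cx, ")")
  cid <- factor(df$complex, levels = complexes)
  start <- plateau_start(df)
  K <- length(complexes)
  fit_env <- list(y = df$pct_cleaved, t = df$time_min,
                  cid = as.integer(cid))
  nls_fit <- tryCatch({
    stats::nls(y ~ ymax - (ymax - y0) * exp(-k[cid] * t),
               data = fit_env,
               start = list(ymax = start$y_max, y0 = start$y_0,
                            k = start$k),
               algorithm = "port",
               lower = c(0, -Inf, rep(k_lower, K)),
               upper = c(100, Inf, rep(Inf, K)),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE))
  }, error = function(e) e)
  if (inherits(nls_fit, "error")) {
    # fall back to direct SSE minimization and flag non-convergence
    sse <- function(p) {
      pred <- plateau_y(df$time_min, p[1], p[2],
                        pmax(p[3:(K + 2)], k_lower)[as.integer(cid)])
      sum((df$pct_cleaved - pred)^2)
    }
    op <- stats::optim(c(start$y_max, start$y_0, start$k), sse,
                       method = "Nelder-Mead",
                       control = list(maxit = 5000))
    pars <- list(ymax = op$par[1], y0 = op$par[2],
                 k = pmax(op$par[3:(K + 2)], k_lower))
    converged <- FALSE
    method <- "optim"
    if (!allow_fallback)
      stop(structure(class = c("plateau_fit_error", "error", "condition"),
                     list(message = paste("nls did not converge:",
                                          conditionMessage(nls_fit)),
                          call = sys.call(), best = pars)))
  } else {
    cf <- stats::coef(nls_fit)
    pars <- list(ymax = cf[["ymax"]], y0 = cf[["y0"]],
                 k = unname(cf[grep("^k", names(cf))]))
    converged <- nls_fit$convInfo$isConv
    method <- "nls"
  }
  names(pars$k) <- complexes
  if (any(pars$k <= k_lower * (1 + 1e-6)))
    warning("rate constant at lower bound for: ",
            paste(complexes[pars$k <= k_lower * (1 + 1e-6)],
                  collapse = ", "))
  if (pars$ymax - pars$y0 < 1e-3 * max(1, pars$ymax))
    warning("fitted amplitude (Y_max - Y_0) is ~0: ",
            "rate constants are unidentifiable (flat data)")
  r2 <- vapply(complexes, function(cx) {
    d <- df[df$complex == cx, ]
    pred <- plateau_y(d$time_min, pars$ymax, pars$y0, pars$k[[cx]])
    1 - sum((d$pct_cleaved - pred)^2) /
      max(sum((d$pct_cleaved - mean(d$pct_cleaved))^2), 1e-12)
  }, numeric(1))
  fit <- structure(list(y_max = unname(pars$ymax),
                        y_0 = unname(pars$y0),
                        k = pars$k, r2 = r2,
                        converged = converged, method = method,
                        data = df),
                   class = "plateau_fit")
  fit$t50 <- tryCatch(t50(fit), error = function(e)
    stats::setNames(rep(NA_real_, K), complexes))
  fit
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("plateau_fit (", x$method, if (!x$converged) ", NOT converged",
      "): Y_max =", round(x$y_max, 3), ", Y_0 =", round(x$y_0, 4), "\n")
  print(data.frame(k = x$k, t50 = x$t50, R2 = round(x$r2, 4)))
  invisible(x)
}

#' Analytic half-time of the exponential plateau model
#'
#' Solves `Y(t) = Y_max / 2` for t:
#' `t50 = -ln((Y_max / 2) / (Y_max - Y_0)) / k
#'      = ln(2 (Y_max - Y_0) / Y_max) / k`.
#' Requires `Y_0 < Y_max / 2` (otherwise half of the maximum is already
#' cleaved at t = 0 and the half-time is undefined).
#'
#' @param fit a `plateau_fit`, or a named numeric k vector when `y_max`
#'   and `y_0` are given explicitly.
#' @param y_max,y_0 plateau parameters (%); taken from `fit` when omitted.
#' @return named numeric vector of t50 values (same time units as 1/k).
#' @export
t50 <- function(fit, y_max = NULL, y_0 = NULL) {
  if (inherits(fit, "plateau_fit")) {
    k <- fit$k
    y_max <- y_max %||% fit$y_max
    y_0 <- y_0 %||% fit$y_0
  } else {
    k <- fit
    if (is.null(y_max) || is.null(y_0))
      stop("y_max and y_0 are required when not passing a plateau_fit")
  }
  if (any(k <= 0)) stop("k must be > 0")
  if (y_0 >= y_max / 2)
    stop("t50 undefined: Y_0 (", y_0, ") >= Y_max/2 (", y_max / 2,
         "), half-maximum already passed at t = 0")
  log(2 * (y_max - y_0) / y_max) / k
}

#' Bootstrap confidence intervals for a global plateau fit
#'
#' Case resampling of replicates within each (complex, timepoint) cell
#' (falling back to residual resampling, with a message, when any cell
#' has a single replicate), refitting, and percentile intervals for
#' `Y_max`, `Y_0`, each rate constant, and each t50.
#'
#' @param timecourse the fitted data (complex, replicate, time_min,
#'   pct_cleaved).
#' @param fit the `plateau_fit` for it.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return data.frame: parameter, estimate, lower, upper; attribute
#'   `resampling` records the scheme used.
#' @export
bootstrap_ci <- function(timecourse, fit, n_boot = 1000, seed = 1,
                         level = 0.95) {
  stopifnot(inherits(fit, "plateau_fit"), n_boot >= 100)
  df <- timecourse
  df$complex <- as.character(df$complex)
  cell <- interaction(df$complex, df$time_min, drop = TRUE)
  case_ok <- all(table(cell) >= 2)
  if (!case_ok)
    message("single replicate in some timepoints: ",
            "using residual resampling")
  pred <- plateau_y(df$time_min, fit$y_max, fit$y_0,
                    fit$k[df$complex])
  resid <- df$pct_cleaved - pred
  param_names <- c("y_max", "y_0", paste0("k.", names(fit$k)),
                   paste0("t50.", names(fit$k)))
  draws <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      db <- df
      if (case_ok) {
        idx <- unlist(lapply(split(seq_len(nrow(df)), cell),
                             function(ii) ii[sample.int(length(ii),
                                                        replace = TRUE)]),
                      use.names = FALSE)
        db <- df[idx, ]
      } else {
        db$pct_cleaved <- pred + sample(resid, replace = TRUE)
      }
      fb <- tryCatch(fit_global_plateau(db), error = function(e) NULL)
      if (is.null(fb))
        return(rep(NA_real_, length(param_names)))
      t50b <- tryCatch(t50(fb), error = function(e)
        stats::setNames(rep(NA_real_, length(fb$k)), names(fb$k)))
      c(fb$y_max, fb$y_0, fb$k[names(fit$k)], t50b[names(fit$k)])
    }, numeric(length(param_names)))
  })
  rownames(draws) <- param_names
  a <- (1 - level) / 2
  qs <- t(apply(draws, 1, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE))
  est <- c(fit$y_max, fit$y_0, fit$k, fit$t50)
  out <- data.frame(parameter = param_names, estimate = unname(est),
                    lower = qs[, 1], upper = qs[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "resampling") <- if (case_ok) "case" else "residual"
  attr(out, "n_boot") <- n_boot
  out
}

#' Packaged CYC1 RNA substrate sequences
#'
#' The fluorescently labeled CYC1 3'-end substrates used in the cleavage
#' and polyadenylation assays: the 42-nt precleaved form (5' cleavage
#' product, 5' 6-FAM label) and the full uncleaved form with the 3'
#' extension (5' 6-FAM, 3' Alexa647). Both contain the AAGAA
#' polyadenylation signal.
#'
#' @return data.frame: id, sequence, length, pas (the PAS motif),
#'   pas_start (1-based position of the motif), labels.
#' @export
cyc1_substrates <- function() {
  fa <- system.file("extdata", "cyc1_substrates.fa", package = "termread",
                    mustWork = TRUE)
  seqs <- Biostrings::readRNAStringSet(fa)
  ids <- sub(" .*", "", names(seqs))
  labels <- sub("^[^ ]+ ?", "", names(seqs))
  pas <- "AAGAA"
  pas_start <- vapply(seq_along(seqs), function(i) {
    m <- Biostrings::matchPattern(pas, seqs[[i]])
    if (length(m) == 0) NA_integer_ else BiocGenerics::start(m)[1]
  }, integer(1))
  data.frame(id = ids, sequence = as.character(seqs),
             length = Biostrings::width(seqs), pas = pas,
             pas_start = pas_start, labels = labels,
             stringsAsFactors = FALSE, row.names = NULL)
}
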