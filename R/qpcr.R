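# Spike-in normalized delta-delta-Ct qPCR analysis:
#   Ct_spike-in = mean of the spike-in amplicon Cts (per condition and
#                 replicate)
#   dCt  = Ct_target - Ct_spike-in
#   ddCt = dCt(+auxin) - dCt(-auxin)
#   fold change = 2^(-ddCt)   (perfect efficiency; exposed as a parameter)
# and the readthrough level as the ratio of the downstream amplicon's fold
# change to that of the genic region 1 kb upstream.

qpcr_groups <- function(table) {
  cols <- intersect(c("condition", "fraction", "replicate"), names(table))
  interaction(table[cols], drop = TRUE, lex.order = TRUE)
}

#' Spike-in reference Ct per condition/replicate
#'
#' Arithmetic mean of the spike-in amplicons' Ct values within each
#' (condition, \[fraction,\] replicate) group. Every spike-in amplicon
#' must be measured in every group.
#'
#' @param table a qPCR table (amplicon, condition, replicate, ct, and
#'   optionally fraction).
#' @param spike_amplicons character vector of spike-in amplicon names
#'   (default: the table's `spike_amplicons` attribute).
#' @return data.frame of group keys plus `ct_spikein`.
#' @export
spike_ct <- function(table, spike_amplicons = attr(table,
                                                   "spike_amplicons")) {
  if (is.null(spike_amplicons) || !length(spike_amplicons))
    stop("spike_amplicons must be provided (none attached to table)")
  stopifnot(all(c("amplicon", "condition", "replicate", "ct") %in%
                  names(table)))
  sp <- table[table$amplicon %in% spike_amplicons, , drop = FALSE]
  grp <- qpcr_groups(sp)
  n_per <- tapply(sp$amplicon, grp, function(a)
    length(unique(a)))
  if (any(n_per < length(spike_amplicons)))
    stop("missing spike-in amplicon(s) in group(s): ",
         paste(names(n_per)[n_per < length(spike_amplicons)],
               collapse = ", "))
  agg <- stats::aggregate(sp["ct"], by = sp[intersect(
    c("condition", "fraction", "replicate"), names(sp))], FUN = mean)
  names(agg)[names(agg) == "ct"] <- "ct_spikein"
  agg
}

#' Spike-in normalized fold changes (2^-ddCt)
#'
#' @param table a qPCR table (see [spike_ct()]).
#' @param spike_amplicons spike-in amplicon names.
#' @param conditions reference and treated condition labels.
#' @param efficiency amplification factor per cycle (2 = perfect).
#' @return data.frame: amplicon (plus fraction if present), dct_ref,
#'   dct_trt, ddct, fold_change.
#' @export
fold_change <- function(table,
                        spike_amplicons = attr(table, "spike_amplicons"),
                        conditions = c("minus_auxin", "plus_auxin"),
                        efficiency = 2) {
  stopifnot(length(conditions) == 2, efficiency > 1)
  present <- unique(table$condition)
  if (!all(conditions %in% present))
    stop("condition(s) missing from table: ",
         paste(setdiff(conditions, present), collapse = ", "))
  ref <- spike_ct(table, spike_amplicons)
  keys <- intersect(c("condition", "fraction", "replicate"), names(table))
  tgt <- table[!table$amplicon %in% spike_amplicons, , drop = FALSE]
  tgt <- merge(tgt, ref, by = keys)
  tgt$dct <- tgt$ct - tgt$ct_spikein
  by_cols <- c("amplicon", intersect("fraction", names(tgt)))
  mean_dct <- function(cond) {
    d <- tgt[tgt$condition == cond, , drop = FALSE]
    stats::aggregate(d["dct"], by = d[by_cols], FUN = mean)
  }
  a <- mean_dct(conditions[1]); names(a)[names(a) == "dct"] <- "dct_ref"
  b <- mean_dct(conditions[2]); names(b)[names(b) == "dct"] <- "dct_trt"
  out <- merge(a, b, by = by_cols)
  out$ddct <- out$dct_trt - out$dct_ref
  out$fold_change <- efficiency^(-out$ddct)
  out
}

#' Readthrough level from qPCR fold changes
#'
#' Normalizes the fold change at a position downstream of the poly(A)
#' site to the fold change of the genic region 1 kb upstream:
#' `readthrough = fc_downstream / fc_upstream`. A value > 1 in the
#' treated condition indicates readthrough transcription.
#'
#' @param fc_downstream,fc_upstream positive fold changes (vectorized).
#' @return the ratio(s).
#' @export
readthrough_level <- function(fc_downstream, fc_upstream) {
  if (any(fc_downstream <= 0) || any(fc_upstream <= 0))
    stop("fold changes must be > 0")
  fc_downstream / fc_upstream
}
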