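#' Root-mean-square error between moment series
#'
#' Per-DoF (column-wise) RMSE between estimated and reference joint
#' moments.
#'
#' @param M_est,M_ref `nPt x nDoF` moment matrices, Nm.
#' @return numeric vector of per-DoF RMSE, Nm.
#' @export
moment_rmse <- function(M_est, M_ref) {
  M_est <- as.matrix(M_est); M_ref <- as.matrix(M_ref)
  if (!all(dim(M_est) == dim(M_ref))) {
    stop_trunksyn("argument_error", "moment matrices differ in shape")
  }
  if (anyNA(M_est) || anyNA(M_ref)) {
    stop_trunksyn("data_error", "NaN in moment matrices")
  }
  sqrt(colMeans((M_est - M_ref)^2))
}

# circular shift by a possibly fractional number of samples (positive =
# forward in time/delay); linear interpolation between neighbors, exact for
# whole-sample shifts
circ_shift <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0) return(x)
  pos <- (seq_len(n) - 1 - s) %% n
  lo <- floor(pos); frac <- pos - lo
  (1 - frac) * x[(lo %% n) + 1] + frac * x[((lo + 1) %% n) + 1]
}

#' Apply an electromechanical delay to a time-normalized cycle signal
#'
#' Circularly shifts a gait-cycle signal forward in time by `delay_ms`,
#' converting the delay to (possibly fractional) samples via the cycle's
#' true duration; fractional shifts use linear interpolation so that delay
#' grids finer than the sampling interval remain distinguishable. Gait is
#' treated as periodic, so the shift wraps around the cycle; whole-sample
#' shifts are exact.
#'
#' @param x signal sampled over one time-normalized gait cycle.
#' @param delay_ms delay in milliseconds, `0 <= delay < cycle duration`.
#' @param cycle_duration_s true duration of the cycle in seconds.
#' @return the delayed signal (same length).
#' @export
apply_emd <- function(x, delay_ms, cycle_duration_s) {
  if (delay_ms < 0) stop_trunksyn("argument_error", "delay must be >= 0")
  if (delay_ms / 1000 >= cycle_duration_s) {
    stop_trunksyn("argument_error", "delay must be shorter than the cycle")
  }
  circ_shift(x, delay_ms / 1000 / cycle_duration_s * length(x))
}

#' Pearson correlation between two mean curves
#'
#' @param x,y equal-length non-constant numeric vectors (typically ensemble
#'   mean curves of an estimated activation and a measured excitation).
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_mean_curves <- function(x, y) {
  if (length(x) != length(y)) {
    stop_trunksyn("argument_error", "curves differ in length")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_trunksyn("data_error", "correlation undefined for a constant curve")
  }
  stats::cor(x, y)
}

#' Sweep electromechanical delays and return the best-correlating one
#'
#' Applies each candidate delay to the measured excitation curve and
#' correlates it with the estimated activation curve; returns the delay
#' giving the highest Pearson r (ties broken toward the smallest delay).
#' The default grid, 100 to 165 ms in 5 ms steps, spans reported erector
#' spinae delays.
#'
#' @param estimated_mean estimated activation mean curve (nPt samples).
#' @param measured_mean measured excitation mean curve (nPt samples).
#' @param delays_ms candidate delays in ms (default `seq(100, 165, by = 5)`).
#' @param cycle_duration_s true cycle duration, seconds.
#' @return list with `delay_ms`, `r`, and the full `r_by_delay` vector.
#' @export
emd_sweep <- function(estimated_mean, measured_mean,
                      delays_ms = seq(100, 165, by = 5),
                      cycle_duration_s = 1.1) {
  if (length(delays_ms) == 0) {
    stop_trunksyn("argument_error", "delay grid must be nonempty")
  }
  rs <- vapply(delays_ms, function(d) {
    pearson_mean_curves(estimated_mean,
                        apply_emd(measured_mean, d, cycle_duration_s))
  }, 0)
  best <- which.max(rs)   # which.max returns the first (smallest-delay) tie
  list(delay_ms = delays_ms[best], r = rs[best],
       r_by_delay = stats::setNames(rs, delays_ms))
}

#' Summarize a sweep of estimation results across gait cycles
#'
#' Aggregates per-cycle metrics over a configuration grid (number of
#' synergies x allowable activation) into the two standard report tables:
#' mean +/- sd moment RMSE per DoF, and best Pearson r (with its delay) per
#' muscle and side. Strong correlation is flagged at r > 0.7.
#'
#' @param rmse_df data.frame with columns `n_syn`, `allow_a`, `cycle`,
#'   `dof`, `rmse`.
#' @param corr_df optional data.frame with columns `n_syn`, `allow_a`,
#'   `muscle`, `side`, `r`, `delay_ms`.
#' @return list with data.frames `rmse` (columns `n_syn`, `allow_a`, `dof`,
#'   `mean`, `sd`) and, when supplied, `correlation` (adds `strong`
#'   logical).
#' @export
summarize_sweep <- function(rmse_df, corr_df = NULL) {
  if (nrow(rmse_df) == 0) {
    stop_trunksyn("argument_error", "no results to summarize")
  }
  agg_m <- stats::aggregate(rmse ~ n_syn + allow_a + dof, rmse_df, mean)
  agg_s <- stats::aggregate(rmse ~ n_syn + allow_a + dof, rmse_df,
                            function(v) if (length(v) > 1) stats::sd(v) else 0)
  names(agg_m)[4] <- "mean"; agg_m$sd <- agg_s$rmse
  out <- list(rmse = agg_m)
  if (!is.null(corr_df) && nrow(corr_df)) {
    corr_df$strong <- corr_df$r > 0.7
    out$correlation <- corr_df
  }
  out
}

#' Group-mean activation recovery correlations
#'
#' For each muscle group, the Pearson correlation between the group-mean
#' estimated and ground-truth activation curves. Groups whose ground truth
#' is essentially inactive (peak below `min_activation`) have no defined
#' curve shape and are excluded; a flat estimate against a varying truth
#' scores 0.
#'
#' @param a_est,a_true `nPt x nMusc` activation matrices.
#' @param groups list of member-column index vectors, one per muscle group.
#' @param min_activation truth peak below which a group is considered
#'   inactive and skipped (default 0.01).
#' @return named numeric vector of correlations for the active groups.
#' @export
recovery_correlation <- function(a_est, a_true, groups,
                                 min_activation = 0.01) {
  out <- vapply(groups, function(g) {
    truth <- rowMeans(a_true[, g, drop = FALSE])
    if (max(truth) < min_activation || stats::sd(truth) == 0) {
      return(NA_real_)
    }
    est <- rowMeans(a_est[, g, drop = FALSE])
    if (stats::sd(est) == 0) 0 else stats::cor(est, truth)
  }, 0)
  out[!is.na(out)]
}
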