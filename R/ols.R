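#' Per-subject least-squares trajectory fit
#'
#' Fits the straight-line biomarker trajectory by ordinary least squares to
#' the measurements taken at or before `t` and returns the prediction at `t`
#' together with its leverage, `lev(t) = 1/s + (t - vbar)^2 / sum((v - vbar)^2)`,
#' so that `Var(Xhat(t)) = sigma2 * lev(t)`. (This leverage plays the role of
#' the trajectory-variance multiplier in the conditional-score sufficient
#' statistic; it is distinct from the treatment indicator.)
#'
#' @param meas_times measurement times (years from entry), strictly increasing.
#' @param meas_values observed biomarker values.
#' @param t prediction time.
#' @param fit_to measurements with `time <= fit_to` enter the fit; defaults
#'   to `t` (the prefix rule used inside the conditional score).
#' @return A list with `bhat0`, `bhat1`, `xhat` (prediction at `t`),
#'   `leverage` (at `t`) and `s` (number of measurements used).
#' @examples
#' ols_trajectory(c(0, 1), c(1, 3), 1)  # slope 2, prediction 3, leverage 1
#' @export
ols_trajectory <- function(meas_times, meas_values, t, fit_to = t) {
  stopifnot(length(meas_times) == length(meas_values))
  use <- meas_times <= fit_to + 1e-12
  v <- meas_times[use]; d <- meas_values[use]
  s <- length(v)
  if (s < 2L) {
    stop("InsufficientMeasurements: need at least two measurements at or before t",
         call. = FALSE)
  }
  vbar <- mean(v)
  svv <- sum((v - vbar)^2)
  if (svv <= 0) stop("singular design: measurement times are identical", call. = FALSE)
  b1 <- sum((d - mean(d)) * (v - vbar)) / svv
  b0 <- mean(d) - b1 * vbar
  list(bhat0 = b0, bhat1 = b1, xhat = b0 + b1 * t,
       leverage = 1 / s + (t - vbar)^2 / svv, s = s)
}

#' Pooled measurement-error variance estimate
#'
#' Pools each subject's residual sum of squares from the least-squares line
#' through all of their retained measurements, using `m - 2` degrees of
#' freedom per subject; only subjects with more than two measurements
#' contribute.
#'
#' @param snapshot a `trial_snapshot`.
#' @param subgroup 1 or 2.
#' @return The pooled variance estimate.
#' @export
pooled_sigma2 <- function(snapshot, subgroup) {
  su <- snapshot$subjects
  ids <- su$subject_id[su$subgroup == as.integer(subgroup)]
  me <- snapshot$measurements[snapshot$measurements$subject_id %in% ids, ]
  parts <- dplyr::summarise(
    dplyr::group_by(me, .data$subject_id),
    m = dplyr::n(),
    rss = {
      v <- .data$time_years; d <- .data$biomarker
      if (dplyr::n() > 2L) {
        vv <- sum((v - mean(v))^2)
        if (vv > 0) sum((d - mean(d))^2) - sum((d - mean(d)) * (v - mean(v)))^2 / vv else NA_real_
      } else NA_real_
    },
    .groups = "drop"
  )
  keep <- parts$m > 2L & !is.na(parts$rss)
  df <- sum(parts$m[keep] - 2L)
  if (df <= 0) {
    stop("NoResidualDf: no subject has more than two retained measurements",
         call. = FALSE)
  }
  max(sum(parts$rss[keep]) / df, 0)
}
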