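#' Biomarker visit schedule
#'
#' Visits occur at entry and every 2 weeks for the first 12 weeks (three
#' 4-week months), then every 4 weeks, truncated at the follow-up horizon.
#'
#' @param horizon follow-up horizon in years (visits at offsets `<= horizon`).
#' @param params optional `joint_model_params` carrying alternative schedule
#'   settings.
#' @return Numeric vector of visit offsets in years, starting at 0 (unless
#'   `horizon < 0` which is an error; `horizon = 0` gives just the entry
#'   visit).
#' @examples
#' measurement_schedule(12 * 7 / 365.25) * 365.25 / 7  # weeks 0, 2, ..., 12
#' @export
measurement_schedule <- function(horizon, params = NULL) {
  if (length(horizon) != 1L || is.na(horizon) || horizon < 0) {
    stop("`horizon` must be a single non-negative number of years", call. = FALSE)
  }
  early <- if (is.null(params)) 12 else params$visit_weeks_early
  gap <- if (is.null(params)) 4 else params$visit_gap_weeks
  hw <- horizon / .week + 1e-9  # tolerate representation error at visit times
  wks <- seq(0, early, by = 2)
  if (hw > early) {
    wks <- c(wks, seq(early + gap, by = gap,
                      length.out = max(0, ceiling((hw - early) / gap))))
  }
  wks[wks <= hw] * .week
}

# piecewise cumulative hazard multiplier: int_0^t h0(s) exp(a s) ds pieces
# g(a, t0, t1) = (exp(a t1) - exp(a t0)) / a, with the a -> 0 linear limit
.haz_g <- function(a, t0, t1) {
  out <- ifelse(abs(a) < 1e-9, t1 - t0, (exp(a * t1) - exp(a * t0)) / a)
  out
}

#' Cumulative hazard of the working joint model
#'
#' `H(t) = exp(gamma b0 + theta psi) * int_0^t h0(s) exp(gamma b1 s) ds` with
#' the piecewise-constant baseline hazard. Vectorised over subjects.
#'
#' @param t event time(s), years from entry.
#' @param b0,b1 latent random effects.
#' @param psi treatment indicator (0/1).
#' @param subgroup subgroup label (1 or 2).
#' @param params a [joint_model_params()].
#' @return Cumulative hazard values.
#' @export
cumulative_hazard <- function(t, b0, b1, psi, subgroup, params) {
  n <- max(length(t), length(b0))
  t <- rep_len(t, n); b0 <- rep_len(b0, n); b1 <- rep_len(b1, n)
  psi <- rep_len(psi, n); subgroup <- rep_len(subgroup, n)
  g <- params$gamma[subgroup, 1]
  th <- params$theta[subgroup]
  c1 <- params$baseline[subgroup, 1]
  c2 <- params$baseline[subgroup, 2]
  knot <- params$hazard_knot
  a <- g * b1
  k <- exp(g * b0 + th * psi)
  t1 <- pmin(t, knot)
  H <- k * c1 * .haz_g(a, 0, t1)
  over <- t > knot
  if (any(over)) {
    H[over] <- H[over] + (k * c2)[over] * .haz_g(a[over], knot, t[over])
  }
  H
}

#' Draw latent event times from the working joint model
#'
#' Inverts the cumulative hazard in closed form within each constant-hazard
#' piece (`H` is exponential in `t` within a piece). When `gamma * b1 < 0`
#' the total hazard `H(Inf)` can be finite, in which case a draw may be
#' `Inf` (a cured subject); callers censor such subjects.
#'
#' @inheritParams cumulative_hazard
#' @return Event times in years from entry (possibly `Inf`). Uses the current
#'   RNG state.
#' @examples
#' set.seed(1)
#' p <- joint_model_params(gamma = 0, baseline = c(0.5, 0.5))
#' mean(sample_event_time(rep(0, 1e4), 0, 0, 1, p))  # ~ 1 / 0.5
#' @export
sample_event_time <- function(b0, b1, psi, subgroup, params) {
  n <- max(length(b0), length(b1), length(psi), length(subgroup))
  b0 <- rep_len(b0, n); b1 <- rep_len(b1, n)
  psi <- rep_len(psi, n); subgroup <- rep_len(subgroup, n)
  g <- params$gamma[subgroup, 1]
  th <- params$theta[subgroup]
  c1 <- params$baseline[subgroup, 1]
  c2 <- params$baseline[subgroup, 2]
  knot <- params$hazard_knot
  a <- g * b1
  k <- exp(g * b0 + th * psi)
  u <- stats::rexp(n)

  lin <- abs(a) < 1e-9
  H1 <- k * c1 * .haz_g(a, 0, knot)     # hazard mass of piece 1
  t_out <- numeric(n)

  in1 <- u <= H1
  # piece 1: exp(a t) = 1 + a u / (k c1)
  arg1 <- 1 + a * u / (k * c1)
  t_out[in1 & lin] <- (u / (k * c1))[in1 & lin]
  i1 <- in1 & !lin
  t_out[i1] <- log(arg1[i1]) / a[i1]

  # piece 2: exp(a t) = exp(a knot) + a (u - H1) / (k c2)
  u2 <- u - H1
  arg2 <- exp(a * knot) + a * u2 / (k * c2)
  i2l <- !in1 & lin
  t_out[i2l] <- knot + (u2 / (k * c2))[i2l]
  i2 <- !in1 & !lin
  t2 <- rep(Inf, sum(i2))
  ok <- arg2[i2] > 0     # a < 0 with exhausted hazard => never
  t2[ok] <- log(arg2[i2][ok]) / a[i2][ok]
  t_out[i2] <- t2
  t_out
}

#' Simulate a trial cohort from the working joint model
#'
#' Patients arrive deterministically at `recruit_rate` per week; subgroup
#' membership is Bernoulli(`lambda`); treatment alternates 1:1 within
#' subgroup in arrival order. Random effects are bivariate normal, biomarker
#' measurements follow the visit schedule with i.i.d. Gaussian error, the
#' latent event time comes from the proportional-hazards model and loss to
#' follow-up is exponential and independent. Measurements are generated up to
#' each subject's own (latent) end of follow-up; analysis-time snapshots
#' truncate further.
#'
#' @param params a [joint_model_params()].
#' @param n_patients number of patients.
#' @param theta optional length-2 override of `params$theta`.
#' @return An object of class `trial_data`: a list with tibbles `subjects`
#'   (one row per patient: `subject_id`, `subgroup`, `arm`, `recruit_years`,
#'   `b0`, `b1`, `latent_event_years`, `ltfu_years`) and `measurements`
#'   (`subject_id`, `time_years`, `biomarker`), plus the parameters used.
#' @examples
#' set.seed(7)
#' tr <- simulate_trial(joint_model_params(), 50)
#' tr$subjects
#' @export
simulate_trial <- function(params, n_patients, theta = NULL) {
  stopifnot(inherits(params, "joint_model_params"), n_patients >= 1)
  if (!is.null(theta)) {
    params$theta <- rep_len(as.numeric(theta), 2L)
  }
  n <- as.integer(n_patients)
  recruit <- (seq_len(n) - 1L) / params$recruit_rate * .week
  subgroup <- ifelse(stats::runif(n) < params$lambda, 1L, 2L)
  arm <- integer(n)
  for (j in 1:2) {
    idx <- which(subgroup == j)
    arm[idx] <- (seq_along(idx) - 1L) %% 2L   # control first, then alternate
  }

  # random effects per subgroup
  b0 <- numeric(n); b1 <- numeric(n)
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  for (j in 1:2) {
    idx <- which(subgroup == j)
    cv <- matrix(c(params$phi[j, 1], params$phi[j, 2],
                   params$phi[j, 2], params$phi[j, 3]), 2L)
    L <- t(chol(cv + diag(1e-12, 2L)))
    bj <- z[idx, , drop = FALSE] %*% t(L)
    b0[idx] <- params$mu[j, 1] + bj[, 1]
    b1[idx] <- params$mu[j, 2] + bj[, 2]
  }

  latent <- sample_event_time(b0, b1, arm, subgroup, params)
  ltfu <- if (params$censor_rate > 0) stats::rexp(n, params$censor_rate) else rep(Inf, n)

  fu <- pmin(latent, ltfu)
  fu_cap <- pmin(fu, 150)   # schedule horizon guard for immortal subjects
  sched <- measurement_schedule(max(fu_cap), params)
  s_n <- findInterval(fu_cap + 1e-12, sched)
  s_n <- pmax(s_n, 1L)      # entry visit always observed
  id_rep <- rep.int(seq_len(n), s_n)
  v <- sched[sequence(s_n)]
  sd_meas <- sqrt(params$sigma2[subgroup, 1])[id_rep]
  d_obs <- b0[id_rep] + b1[id_rep] * v + stats::rnorm(length(v), 0, sd_meas)

  subjects <- tibble::tibble(
    subject_id = seq_len(n), subgroup = subgroup, arm = arm,
    recruit_years = recruit, b0 = b0, b1 = b1,
    latent_event_years = latent, ltfu_years = ltfu
  )
  measurements <- tibble::tibble(
    subject_id = id_rep, time_years = v, biomarker = d_obs
  )
  structure(list(subjects = subjects, measurements = measurements,
                 params = params),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Simulated trial cohort: %d patients (%d in S1), %d biomarker measurements\n",
              nrow(x$subjects), sum(x$subjects$subgroup == 1L),
              nrow(x$measurements)))
  invisible(x)
}

#' Administratively censored view of a trial at a calendar time
#'
#' @param trial a `trial_data` object.
#' @param calendar_time analysis calendar time, years since trial start.
#' @param analysis_index analysis number (1 = interim, 2 = final).
#' @return An object of class `trial_snapshot`: subjects recruited by
#'   `calendar_time` with observed time `time_years` (years from entry),
#'   event indicator `event`, and the biomarker measurements that predate the
#'   observed time; carries `analysis`, `calendar_time` and the maximum
#'   follow-up `tau`.
#' @export
snapshot_at_time <- function(trial, calendar_time, analysis_index = 1L) {
  stopifnot(inherits(trial, "trial_data"))
  su <- trial$subjects[trial$subjects$recruit_years <= calendar_time, ]
  if (nrow(su) == 0L) stop("no patients recruited by this calendar time", call. = FALSE)
  admin <- calendar_time - su$recruit_years
  t_obs <- pmin(su$latent_event_years, su$ltfu_years, admin)
  event <- as.integer(su$latent_event_years <= pmin(su$ltfu_years, admin))
  su$time_years <- t_obs
  su$event <- event
  me <- trial$measurements[trial$measurements$subject_id %in% su$subject_id, ]
  keep <- me$time_years <= t_obs[match(me$subject_id, su$subject_id)] + 1e-12
  me <- me[keep, ]
  structure(list(subjects = su, measurements = me,
                 analysis = as.integer(analysis_index),
                 calendar_time = calendar_time, tau = max(t_obs),
                 params = trial$params),
            class = "trial_snapshot")
}

#' Snapshot the trial when a target number of events has occurred
#'
#' Finds the calendar time at which the `d`-th event occurs in the trigger
#' population (`"1"`, `"2"` or `"F"` for the full population) and
#' administratively censors everyone at that time. Events are counted
#' irrespective of how many biomarker measurements a patient has.
#'
#' @param trial a `trial_data` object.
#' @param trigger_subgroup `"1"`, `"2"` or `"F"`.
#' @param d required number of events (>= 1).
#' @param analysis_index analysis number stored in the snapshot.
#' @return A `trial_snapshot` (see [snapshot_at_time()]).
#' @export
snapshot_at_event_count <- function(trial, trigger_subgroup, d,
                                    analysis_index = 1L) {
  stopifnot(inherits(trial, "trial_data"), d >= 1)
  trigger_subgroup <- as.character(trigger_subgroup)
  if (!trigger_subgroup %in% c("1", "2", "F")) {
    stop('`trigger_subgroup` must be "1", "2" or "F"', call. = FALSE)
  }
  su <- trial$subjects
  sel <- if (trigger_subgroup == "F") rep(TRUE, nrow(su)) else
    su$subgroup == as.integer(trigger_subgroup)
  ev <- sel & is.finite(su$latent_event_years) &
    su$latent_event_years <= su$ltfu_years
  cal <- sort(su$recruit_years[ev] + su$latent_event_years[ev])
  if (length(cal) < d) {
    stop(sprintf(
      "InsufficientEvents: only %d events ever occur in subgroup %s (need %d); increase n_patients",
      length(cal), trigger_subgroup, d), call. = FALSE)
  }
  # nudge past the triggering event so it is counted despite rounding
  snapshot_at_time(trial, cal[d] + 1e-9, analysis_index)
}

#' @export
print.trial_snapshot <- function(x, ...) {
  cat(sprintf(
    "Trial snapshot (analysis %d) at calendar time %.3f y: %d patients, %d events, tau = %.3f y\n",
    x$analysis, x$calendar_time, nrow(x$subjects), sum(x$subjects$event),
    x$tau))
  invisible(x)
}

#' Count observed events in a snapshot
#'
#' @param snapshot a `trial_snapshot`.
#' @param subgroup `"1"`, `"2"` or `"F"`.
#' @return Integer event count.
#' @export
n_events <- function(snapshot, subgroup = "F") {
  su <- snapshot$subjects
  sel <- if (identical(as.character(subgroup), "F")) rep(TRUE, nrow(su)) else
    su$subgroup == as.integer(subgroup)
  sum(su$event[sel])
}

#' Calibrate the loss-to-follow-up rate
#'
#' Solves (by bisection on Monte-Carlo draws of the latent event time) for
#' the exponential dropout rate at which a target fraction of patients is
#' lost to follow-up before their event, under the given parameters with no
#' treatment effect.
#'
#' @param params a [joint_model_params()].
#' @param target target fraction lost to follow-up before the event.
#' @param n_draws Monte-Carlo sample size.
#' @return The calibrated rate (per year).
#' @export
calibrate_censor_rate <- function(params = joint_model_params(),
                                  target = 0.10, n_draws = 2e5) {
  params$theta <- c(0, 0)
  subgroup <- ifelse(stats::runif(n_draws) < params$lambda, 1L, 2L)
  b <- matrix(stats::rnorm(2L * n_draws), ncol = 2L)
  b0 <- numeric(n_draws); b1 <- numeric(n_draws)
  for (j in 1:2) {
    idx <- which(subgroup == j)
    cv <- matrix(c(params$phi[j, 1], params$phi[j, 2],
                   params$phi[j, 2], params$phi[j, 3]), 2L)
    L <- t(chol(cv + diag(1e-12, 2L)))
    bj <- b[idx, , drop = FALSE] %*% t(L)
    b0[idx] <- params$mu[j, 1] + bj[, 1]
    b1[idx] <- params$mu[j, 2] + bj[, 2]
  }
  psi <- rep(0:1, length.out = n_draws)
  tt <- sample_event_time(b0, b1, psi, subgroup, params)
  # P(C < T | T finite) = E[1 - exp(-rho T)] with C ~ Exp(rho); subjects whose
  # event would never occur are eventually censored whatever the rate, so the
  # target fraction is defined among subjects with a finite latent event time
  tt <- tt[is.finite(tt)]
  frac <- function(rho) mean(1 - exp(-rho * tt))
  stats::uniroot(function(r) frac(r) - target, c(1e-6, 10), tol = 1e-6)$root
}
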