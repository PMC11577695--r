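#' Joint model parameters for trial simulation
#'
#' Bundles all parameters of the working joint model used to simulate trial
#' data: a linear latent biomarker trajectory `X(v) = b0 + b1 v` with
#' bivariate-normal random effects `(b0, b1)` and Gaussian measurement error,
#' and a proportional-hazards survival model
#' `h_j(t) = h0_j(t) exp(gamma_j X(t) + theta_j psi)` with a piecewise-constant
#' baseline hazard with a single knot at `t = 1` year. Defaults are calibrated
#' to a metastatic breast cancer setting with circulating tumour DNA as the
#' longitudinal biomarker and HER2 status defining the two subgroups.
#'
#' Time is measured in years throughout; a week is `7/365.25` years and the
#' "monthly" part of the visit schedule uses a 4-week month.
#'
#' @param gamma association between the latent biomarker value and the log
#'   hazard, per biomarker unit; scalar or length-2 (one per subgroup).
#' @param theta log-hazard treatment effects, length-2 `(theta1, theta2)`;
#'   negative values mean the experimental arm benefits.
#' @param sigma2 biomarker measurement-error variance; scalar or length-2.
#' @param baseline baseline hazard constants (events/year), a length-2 vector
#'   `c(c1, c2)` used for both subgroups or a 2x2 matrix with one row per
#'   subgroup; the first column applies for `t <= hazard_knot`, the second
#'   after.
#' @param hazard_knot knot of the piecewise baseline hazard, years.
#' @param mu random-effect means `c(mu0, mu1)` (intercept; slope per year),
#'   shared by both subgroups or a 2x2 matrix with one row per subgroup.
#' @param phi random-effect covariance entries `c(phi1, phi12, phi2)` so that
#'   `Var(b0) = phi1`, `Cov(b0, b1) = phi12`, `Var(b1) = phi2`; shared or a
#'   2x3 matrix with one row per subgroup.
#' @param lambda prevalence of subgroup S1 in the full population, in (0,1).
#' @param recruit_rate recruitment rate, patients per week (deterministic
#'   arrivals, one every `1/recruit_rate` weeks).
#' @param censor_rate hazard of loss to follow-up (per year), independent of
#'   the event process. The default was calibrated so that roughly 10% of
#'   patients are lost to follow-up before their event under the null
#'   defaults; see [calibrate_censor_rate()].
#' @param visit_weeks_early,visit_gap_weeks biomarker visits occur every
#'   `2` weeks up to `visit_weeks_early` (default 12 weeks, i.e. the first
#'   three months) and every `visit_gap_weeks` (default 4) thereafter.
#'
#' @return An object of class `joint_model_params` (a named list with
#'   per-subgroup matrices `gamma`, `theta`, `sigma2`, `baseline`, `mu`,
#'   `phi`, plus `hazard_knot`, `lambda`, `recruit_rate`, `censor_rate` and
#'   the visit-schedule settings).
#' @examples
#' p <- joint_model_params()
#' p_alt <- joint_model_params(theta = c(-0.5, 0))
#' @export
joint_model_params <- function(gamma = 0.8,
                               theta = c(0, 0),
                               sigma2 = 0.25,
                               baseline = c(0.0085, 0.0142),
                               hazard_knot = 1,
                               mu = c(4.23, 1.81),
                               phi = c(2.5, 1.7, 5),
                               lambda = 2 / 3,
                               recruit_rate = 2,
                               censor_rate = 0.0917,
                               visit_weeks_early = 12,
                               visit_gap_weeks = 4) {
  as_rows <- function(x, k, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(2L, k))) {
        stop(sprintf("`%s` must be length %d or a 2x%d matrix", nm, k, k),
             call. = FALSE)
      }
      return(x)
    }
    if (k == 1L && length(x) == 2L) return(matrix(x, nrow = 2L))  # per subgroup
    if (length(x) == 1L) x <- rep(x, k)
    if (length(x) != k) {
      stop(sprintf("`%s` must have length %d (or 1)", nm, k), call. = FALSE)
    }
    matrix(rep(x, each = 2L), nrow = 2L)
  }
  gamma <- as_rows(gamma, 1L, "gamma")
  sigma2 <- as_rows(sigma2, 1L, "sigma2")
  baseline <- as_rows(baseline, 2L, "baseline")
  mu <- as_rows(mu, 2L, "mu")
  phi <- as_rows(phi, 3L, "phi")
  if (length(theta) == 1L) theta <- rep(theta, 2L)
  stopifnot(length(theta) == 2L)

  if (!(lambda > 0 && lambda < 1)) {
    stop("`lambda` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(baseline <= 0)) stop("baseline hazard constants must be > 0", call. = FALSE)
  if (any(sigma2 < 0)) stop("`sigma2` must be >= 0", call. = FALSE)
  if (censor_rate < 0) stop("`censor_rate` must be >= 0", call. = FALSE)
  if (recruit_rate <= 0) stop("`recruit_rate` must be > 0", call. = FALSE)
  for (j in 1:2) {
    cv <- matrix(c(phi[j, 1], phi[j, 2], phi[j, 2], phi[j, 3]), 2L)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop("random-effect covariance must be positive semi-definite",
           call. = FALSE)
    }
  }

  structure(
    list(gamma = gamma, theta = as.numeric(theta), sigma2 = sigma2,
         baseline = baseline, hazard_knot = hazard_knot, mu = mu, phi = phi,
         lambda = lambda, recruit_rate = recruit_rate,
         censor_rate = censor_rate,
         visit_weeks_early = visit_weeks_early,
         visit_gap_weeks = visit_gap_weeks),
    class = "joint_model_params"
  )
}

#' @export
print.joint_model_params <- function(x, ...) {
  cat("Joint model parameters (time unit: years)\n")
  cat(sprintf("  gamma: %s   theta: (%.3g, %.3g)   sigma2: %s\n",
              paste(signif(x$gamma[, 1], 3), collapse = "/"),
              x$theta[1], x$theta[2],
              paste(signif(x$sigma2[, 1], 3), collapse = "/")))
  cat(sprintf("  baseline hazard: %.4g then %.4g (knot %.3g y)\n",
              x$baseline[1, 1], x$baseline[1, 2], x$hazard_knot))
  cat(sprintf("  random effects: mu = (%.3g, %.3g), phi = (%.3g, %.3g, %.3g)\n",
              x$mu[1, 1], x$mu[1, 2], x$phi[1, 1], x$phi[1, 2], x$phi[1, 3]))
  cat(sprintf("  lambda = %.4g, recruit %.3g/week, LTFU rate %.4g/y\n",
              x$lambda, x$recruit_rate, x$censor_rate))
  invisible(x)
}

#' Design configuration for the enrichment trial
#'
#' Collects the pre-trial design targets: familywise error rate, power, the
#' design effect magnitude, subgroup prevalence, the target interim selection
#' probabilities that determine the threshold `zeta` and interim information,
#' and the selection-rule variant. Error is spent with the quadratic spending
#' functions `f(t) = min(alpha t^2, alpha)` and `g(t) = min(beta t^2, beta)`
#' of the information fraction `t = I_F / Imax`.
#'
#' @param alpha familywise error rate (one-sided).
#' @param beta one minus the target (conditional) power.
#' @param delta design treatment effect on the log-hazard scale; its
#'   magnitude (hazard reduction) is what drives the design, so either sign
#'   is accepted.
#' @param lambda prevalence of subgroup S1 in the full population.
#' @param p_select_1 target probability of selecting S1 at the interim under
#'   the design alternative.
#' @param p_select_F target probability of continuing in the full population
#'   under the design alternative.
#' @param omega `"full"` allows selection of either subgroup or F
#'   (`{1, 2, F, none}`); `"conventional"` never enriches the complement
#'   subgroup (`{1, F, none}`).
#' @return An object of class `design_config`.
#' @examples
#' design_config()
#' @export
design_config <- function(alpha = 0.025, beta = 0.1, delta = -0.5,
                          lambda = 2 / 3, p_select_1 = 0.6, p_select_F = 0.2,
                          omega = c("full", "conventional")) {
  omega <- match.arg(omega)
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1,
            lambda > 0, lambda < 1)
  if (p_select_1 < 0 || p_select_F < 0 || p_select_1 + p_select_F >= 1) {
    stop("selection targets must be non-negative with p_select_1 + p_select_F < 1",
         call. = FALSE)
  }
  if (p_select_1 < 0.5) {
    warning("p_select_1 below 0.5: asymptotic behaviour of the estimator ",
            "after selection may be poor", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, delta = abs(delta), lambda = lambda,
         p_select_1 = p_select_1, p_select_F = p_select_F, omega = omega),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat(sprintf(
    "Enrichment design config: alpha %.4g, power %.4g, |delta| %.3g, lambda %.4g\n",
    x$alpha, 1 - x$beta, x$delta, x$lambda))
  cat(sprintf("  selection targets P(W=1) = %.3g, P(W=F) = %.3g; omega = %s\n",
              x$p_select_1, x$p_select_F, x$omega))
  invisible(x)
}

#' Read or write model parameters as YAML
#'
#' The YAML file mirrors the fields of [joint_model_params()] /
#' [design_config()]; round trips preserve values.
#'
#' @param path file path.
#' @param params,config objects to write.
#' @return `read_params_yaml()` returns a `joint_model_params`;
#'   `read_design_yaml()` a `design_config`.
#' @export
read_params_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("baseline", "mu", "phi", "gamma", "sigma2")) {
    if (!is.null(x[[nm]]) && is.list(x[[nm]])) {
      x[[nm]] <- do.call(rbind, x[[nm]])
    }
  }
  do.call(joint_model_params, x)
}

#' @rdname read_params_yaml
#' @export
write_params_yaml <- function(params, path) {
  x <- unclass(params)
  for (nm in names(x)) {
    if (is.matrix(x[[nm]])) x[[nm]] <- apply(x[[nm]], 1, identity, simplify = FALSE)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname read_params_yaml
#' @export
read_design_yaml <- function(path) {
  do.call(design_config, yaml::read_yaml(path))
}

#' @rdname read_params_yaml
#' @export
write_design_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# one week in years; the visit schedule's "month" is 4 weeks
.week <- 7 / 365.25
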