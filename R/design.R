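# Pre-trial design computation for the two-stage enrichment trial:
# threshold selection rule, joint densities of (interim Z, selection),
# quadratic error spending, boundary equations and the maximum-information
# search. All Z-statistics follow the benefit-positive convention
# z = -theta_hat * sqrt(I); under the design alternative the drift in S1 is
# |delta| * sqrt(I1).

.gl_env <- new.env(parent = emptyenv())

# cached Gauss-Legendre nodes/weights on (a, b)
.gl <- function(n, a, b) {
  key <- as.character(n)
  if (is.null(.gl_env[[key]])) {
    .gl_env[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  g <- .gl_env[[key]]
  list(x = a + (b - a) * g$x, w = (b - a) * g$w)
}

.drift <- function(theta, info) -theta * sqrt(info)

#' Solve the threshold rule for zeta and the interim information
#'
#' Under the design alternative (drift `|delta| sqrt(I1)` in S1, no effect in
#' S2, independent interim statistics) the two selection-probability
#' equations `P(select S1) = p1` and `P(continue in F) = pF` have the closed
#' form `zeta = qnorm(p1 / (p1 + pF))` and
#' `I1 = ((zeta + qnorm(p1 + pF)) / |delta|)^2`. A 2-d numeric solve of the
#' same equations is available as a cross-check.
#'
#' @param delta design treatment effect (its magnitude is used).
#' @param p_select_1 target probability of selecting S1.
#' @param p_select_F target probability of selecting F.
#' @param method `"closed_form"` (default) or `"numeric"`.
#' @return A list with `zeta` and `info_interim`.
#' @examples
#' solve_threshold_and_info(-0.5, 0.6, 0.2)  # zeta 0.674, info 9.19
#' @export
solve_threshold_and_info <- function(delta, p_select_1, p_select_F,
                                     method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  p1 <- p_select_1; pF <- p_select_F
  if (p1 <= 0 || pF <= 0 || p1 + pF >= 1) {
    stop("need p_select_1, p_select_F > 0 with sum < 1", call. = FALSE)
  }
  if (method == "closed_form") {
    zeta <- stats::qnorm(p1 / (p1 + pF))
    info <- ((zeta + stats::qnorm(p1 + pF)) / abs(delta))^2
    return(list(zeta = zeta, info_interim = info))
  }
  f <- function(par) {
    zeta <- par[1]; info <- exp(par[2])
    dr <- abs(delta) * sqrt(info)
    c(stats::pnorm(zeta - dr, lower.tail = FALSE) * stats::pnorm(zeta) - p1,
      stats::pnorm(zeta - dr, lower.tail = FALSE) *
        stats::pnorm(zeta, lower.tail = FALSE) - pF)
  }
  sol <- .newton_root(f, list(c(0.5, log(9))), tol = 1e-12)
  if (is.null(sol)) stop("threshold solve failed", call. = FALSE)
  list(zeta = sol$par[1], info_interim = exp(sol$par[2]))
}

#' Interim selection probabilities under the threshold rule
#'
#' The interim statistics are independent with `Z_j ~ N(-theta_j sqrt(I_j), 1)`;
#' the rule selects every subgroup whose statistic exceeds `zeta` (both: full
#' population; neither: stop for futility). The conventional variant never
#' enriches S2 (its selection event is folded into stopping).
#'
#' @param theta1,theta2 treatment effects on the model (log-hazard) scale.
#' @param zeta selection threshold.
#' @param I1,I2 interim information levels.
#' @param omega `"full"` or `"conventional"`.
#' @return A tibble with columns `w` (`"1"`, `"2"`, `"F"`, `"none"`) and
#'   `prob`.
#' @export
selection_probabilities <- function(theta1, theta2, zeta, I1, I2,
                                    omega = c("full", "conventional")) {
  omega <- match.arg(omega)
  stopifnot(I1 > 0, I2 > 0)
  q1 <- stats::pnorm(zeta - .drift(theta1, I1), lower.tail = FALSE)
  q2 <- stats::pnorm(zeta - .drift(theta2, I2), lower.tail = FALSE)
  p <- c(`1` = q1 * (1 - q2), `2` = (1 - q1) * q2, F = q1 * q2,
         none = (1 - q1) * (1 - q2))
  if (omega == "conventional") {
    p["none"] <- p["none"] + p["2"]
    p <- p[c("1", "F", "none")]
  }
  tibble::tibble(w = names(p), prob = unname(p))
}

#' Joint density of the interim statistic and the selection decision
#'
#' For `w = "1"` or `"2"` the density is the (sub-probability) truncated
#' normal `P(other <= zeta) * phi(z - drift_w)` on `z > zeta`. For `w = "F"`
#' the full-population statistic is the weighted sum
#' `Z_F = c1 Z_1 + c2 Z_2` with `c_j` determined by the prevalence-weighted
#' information combination, and its joint density with selection is the
#' convolution truncated to `Z_1 > zeta, Z_2 > zeta`. For `w = "none"` the
#' function returns the constant selection probability (there is no statistic
#' to integrate over; passing `w = "none"` to a z-integral is a contract
#' violation).
#'
#' @param z evaluation points.
#' @param w `"1"`, `"2"`, `"F"` or `"none"`.
#' @inheritParams selection_probabilities
#' @param lambda prevalence of S1, needed for `w = "F"`.
#' @return Density values (same length as `z`).
#' @export
joint_density_zw <- function(z, w, theta1, theta2, zeta, I1, I2,
                             lambda = NULL) {
  w <- as.character(w)
  d1 <- .drift(theta1, I1); d2 <- .drift(theta2, I2)
  if (w == "1") {
    return(ifelse(z > zeta, stats::pnorm(zeta - d2) * stats::dnorm(z - d1), 0))
  }
  if (w == "2") {
    return(ifelse(z > zeta, stats::pnorm(zeta - d1) * stats::dnorm(z - d2), 0))
  }
  if (w == "none") {
    return(rep(stats::pnorm(zeta - d1) * stats::pnorm(zeta - d2), length(z)))
  }
  if (w != "F") stop('`w` must be one of "1", "2", "F", "none"', call. = FALSE)
  if (is.null(lambda)) stop('`lambda` is required for w = "F"', call. = FALSE)
  IF <- 1 / (lambda^2 / I1 + (1 - lambda)^2 / I2)
  c1 <- lambda * sqrt(IF / I1)
  c2 <- (1 - lambda) * sqrt(IF / I2)
  # U = c1 Z1 ~ N(c1 d1, c1^2), V = c2 Z2; truncate to Z1 > zeta, Z2 > zeta
  vapply(z, function(zz) {
    lo <- c1 * zeta
    hi <- zz - c2 * zeta
    if (hi <= lo) return(0)
    g <- .gl(80L, lo, hi)
    sum(g$w * stats::dnorm(g$x, c1 * d1, c1) *
          stats::dnorm(zz - g$x, c2 * d2, c2))
  }, numeric(1))
}

# P(Z_w(1) > b, W = w; Theta) for w in {"1","2","F"}
.stage1_tail <- function(b, w, theta1, theta2, zeta, I1, I2, lambda) {
  d1 <- .drift(theta1, I1); d2 <- .drift(theta2, I2)
  if (w == "1") {
    return(stats::pnorm(zeta - d2) *
             stats::pnorm(max(b, zeta) - d1, lower.tail = FALSE))
  }
  if (w == "2") {
    return(stats::pnorm(zeta - d1) *
             stats::pnorm(max(b, zeta) - d2, lower.tail = FALSE))
  }
  IF <- 1 / (lambda^2 / I1 + (1 - lambda)^2 / I2)
  c1 <- lambda * sqrt(IF / I1)
  c2 <- (1 - lambda) * sqrt(IF / I2)
  up <- max(d1, 0) + 9
  if (up <= zeta) return(0)
  g <- .gl(160L, zeta, up)
  thr <- pmax(zeta, (b - c1 * g$x) / c2)
  sum(g$w * stats::dnorm(g$x - d1) * stats::pnorm(thr - d2, lower.tail = FALSE))
}

#' Conditional density of the second-stage statistic
#'
#' Under the canonical joint distribution of sequentially computed
#' standardized statistics, `Z(2) | Z(1) = z1` is normal with mean
#' `drift2 (1 - r) + sqrt(r) z1` and variance `1 - r`, where
#' `r = I(1)/I(2)` and `drift2 = eta sqrt(I(2))` for benefit effect `eta`.
#'
#' @param z2,z1 statistic values.
#' @param eta benefit-scale effect (`-theta`).
#' @param info1,info2 information at the two analyses (`info1 < info2`).
#' @return Density values.
#' @export
stage2_conditional_density <- function(z2, z1, eta, info1, info2) {
  if (!(info1 > 0 && info2 > info1)) {
    stop("need 0 < info1 < info2", call. = FALSE)
  }
  r <- info1 / info2
  m <- eta * sqrt(info2) * (1 - r) + sqrt(r) * z1
  stats::dnorm(z2, m, sqrt(1 - r))
}

#' Quadratic error spending
#'
#' `f(t) = min(alpha t^2, alpha)` and `g(t) = min(beta t^2, beta)` of the
#' full-population information fraction `t = I_F / Imax`.
#'
#' @param alpha,beta total one-sided type-1/type-2 error.
#' @param IF1,IF2 full-population information at the two analyses.
#' @param Imax maximum (planning) information.
#' @return List with `alpha1`, `alpha2`, `beta1`, `beta2`.
#' @examples
#' spend(0.025, 0.1, 5, 10, 10)
#' @export
spend <- function(alpha, beta, IF1, IF2, Imax) {
  stopifnot(IF1 > 0, IF2 >= IF1, Imax > 0)
  f <- function(t, tot) tot * min(t, 1)^2
  a1 <- f(IF1 / Imax, alpha)
  a2 <- f(IF2 / Imax, alpha) - a1
  b1 <- f(IF1 / Imax, beta)
  b2 <- f(IF2 / Imax, beta) - b1
  list(alpha1 = a1, alpha2 = a2, beta1 = b1, beta2 = b2)
}

#' Stage-1 efficacy and futility boundaries
#'
#' `b1` solves the spent type-1 error equation under the global null: the sum
#' over selectable populations of the joint tail mass `P(Z_w(1) > b1, W = w)`.
#' `a1` solves the spent type-2 error equation under the design alternative
#' for the `w = 1` path. Because power is defined conditionally on selecting
#' S1 while the joint density of (statistic, selection) integrates to the
#' selection probability, the type-2 mass spent is
#' `beta1 * P(W = 1; theta_alt)`; without this normalisation the attained
#' conditional power would be `1 - beta / P(W = 1)` rather than `1 - beta`.
#' Stopping for futility without selecting anything rejects no hypothesis, so
#' the `w = none` path never contributes to the rejection sum.
#'
#' @param alpha1,beta1 error spent at the interim.
#' @param zeta selection threshold.
#' @param theta_alt length-2 design-alternative effects (model scale),
#'   typically `c(-delta, 0)`.
#' @param I1,I2 interim informations for the two subgroups.
#' @param lambda prevalence of S1.
#' @param omega selection-rule variant.
#' @return List with `a1`, `b1`.
#' @export
solve_stage1_boundaries <- function(alpha1, beta1, zeta, theta_alt, I1, I2,
                                    lambda, omega = c("full", "conventional")) {
  omega <- match.arg(omega)
  ws <- if (omega == "full") c("1", "2", "F") else c("1", "F")
  total <- function(b) {
    sum(vapply(ws, .stage1_tail, numeric(1), b = b, theta1 = 0, theta2 = 0,
               zeta = zeta, I1 = I1, I2 = I2, lambda = lambda))
  }
  if (alpha1 <= total(8)) {
    b1 <- 8
    if (alpha1 < total(8)) warning("alpha1 too small; b1 capped at 8", call. = FALSE)
  } else {
    if (alpha1 > total(zeta)) {
      stop("InfeasibleSpend: alpha1 exceeds the attainable rejection mass",
           call. = FALSE)
    }
    b1 <- stats::uniroot(function(b) total(b) - alpha1,
                         c(min(zeta, 0), 8), tol = 1e-10)$root
  }
  # beta equation for the w = 1 density under the alternative (closed form);
  # the spent mass is beta1 * P(W = 1) so that power is conditional on W = 1
  dr1 <- .drift(theta_alt[1], I1)
  dr2 <- .drift(theta_alt[2], I2)
  sel2 <- stats::pnorm(zeta - dr2)
  psel1 <- stats::pnorm(zeta - dr1, lower.tail = FALSE) * sel2
  if (beta1 <= 0) {
    a1 <- zeta
  } else {
    arg <- beta1 * psel1 / sel2 + stats::pnorm(zeta - dr1)
    if (arg >= 1) {
      stop("InfeasibleSpend: beta1 exceeds the attainable futility mass",
           call. = FALSE)
    }
    a1 <- dr1 + stats::qnorm(arg)
  }
  list(a1 = a1, b1 = b1)
}

#' Stage-2 boundaries given the stage-1 boundaries
#'
#' `b2` solves
#' `sum_w int_{a1}^{b1} f(z, w; Theta_G) P(Z_w(2) > b2 | z) dz = alpha2`,
#' the conditional second-stage tail weighted by the stage-1 joint density;
#' `a2` solves the analogous type-2 equation under the design alternative for
#' the `w = 1` path, spending `beta2 * P(W = 1; theta_alt)` so that power is
#' conditional on selecting S1 (see [solve_stage1_boundaries()]). Conditional
#' laws follow the canonical joint distribution with information ratios
#' `r_w = I_w(1) / I_w(2)`.
#'
#' @param alpha2,beta2 error spent at the final analysis.
#' @param a1,b1 stage-1 boundaries.
#' @param zeta selection threshold.
#' @param theta_alt design-alternative effects (model scale).
#' @param infos_stage1,infos_stage2 named numeric vectors with entries
#'   `"1"`, `"2"`, `"F"`: information at each analysis per population.
#' @param lambda prevalence of S1.
#' @param omega selection-rule variant.
#' @return List with `a2`, `b2`.
#' @export
solve_stage2_boundaries <- function(alpha2, beta2, a1, b1, zeta, theta_alt,
                                    infos_stage1, infos_stage2, lambda,
                                    omega = c("full", "conventional")) {
  omega <- match.arg(omega)
  ws <- if (omega == "full") c("1", "2", "F") else c("1", "F")
  if (any(infos_stage2[ws] <= infos_stage1[ws])) {
    stop("stage-2 information must exceed stage-1 information", call. = FALSE)
  }
  if (b1 <= a1) stop("need a1 < b1", call. = FALSE)
  g <- .gl(96L, a1, b1)
  dens_G <- lapply(ws, function(w) {
    joint_density_zw(g$x, w, 0, 0, zeta, infos_stage1[["1"]],
                     infos_stage1[["2"]], lambda)
  })
  names(dens_G) <- ws
  r <- infos_stage1[ws] / infos_stage2[ws]

  tail2 <- function(b2) {
    s <- 0
    for (w in ws) {
      rw <- r[[w]]
      s <- s + sum(g$w * dens_G[[w]] *
                     stats::pnorm((b2 - sqrt(rw) * g$x) / sqrt(1 - rw),
                                  lower.tail = FALSE))
    }
    s
  }
  if (alpha2 <= tail2(8)) {
    b2 <- 8
    if (alpha2 < tail2(8)) warning("alpha2 too small; b2 capped at 8", call. = FALSE)
  } else if (alpha2 >= tail2(-8)) {
    stop("InfeasibleSpend: alpha2 exceeds the attainable mass", call. = FALSE)
  } else {
    b2 <- stats::uniroot(function(b) tail2(b) - alpha2, c(-8, 8),
                         tol = 1e-10)$root
  }

  dens_A1 <- joint_density_zw(g$x, "1", theta_alt[1], theta_alt[2], zeta,
                              infos_stage1[["1"]], infos_stage1[["2"]], lambda)
  r1 <- r[["1"]]
  dr2A <- .drift(theta_alt[1], infos_stage2[["1"]])
  psel1 <- stats::pnorm(zeta - .drift(theta_alt[1], infos_stage1[["1"]]),
                        lower.tail = FALSE) *
    stats::pnorm(zeta - .drift(theta_alt[2], infos_stage1[["2"]]))
  beta2_mass <- beta2 * psel1
  low2 <- function(a2) {
    sum(g$w * dens_A1 *
          stats::pnorm((a2 - (dr2A * (1 - r1) + sqrt(r1) * g$x)) / sqrt(1 - r1)))
  }
  if (beta2_mass <= low2(-8)) {
    a2 <- -8
  } else if (beta2_mass >= low2(8)) {
    a2 <- 8
  } else {
    a2 <- stats::uniroot(function(a) low2(a) - beta2_mass, c(-8, 8),
                         tol = 1e-10)$root
  }
  list(a2 = a2, b2 = b2)
}

#' Predict information from event counts
#'
#' Information is approximately proportional to the number of observed
#' events, so a future information level is predicted by linear scaling:
#' `I_target = d_target * I_interim / d_interim`.
#'
#' @param info_interim observed information.
#' @param d_interim observed event count (>= 1).
#' @param d_target future event count.
#' @return Predicted information.
#' @export
predict_information <- function(info_interim, d_interim, d_target) {
  stopifnot(d_interim >= 1)
  d_target * info_interim / d_interim
}

#' Maximum-information search
#'
#' Finds the maximum information `Imax` such that the stage-2 boundaries
#' meet (`a2 = b2`) along the information path the trial actually realizes
#' when information accrues in proportion to events: at the interim,
#' `I_1 = d1/m1`, `I_2 = ((1-lambda)/lambda) I_1` and (by the
#' prevalence-weighted combination) `I_F = I_1/lambda`; at the final
#' analysis every selectable population has observed `d(2)` of its own
#' events and so reaches information `d(2)/m1 = Imax`. Error is spent on
#' the full-population information fraction, which reaches 1 at the final
#' analysis. The total event target is `d(2) = ceiling(m1 * Imax)`
#' (equivalently `ceiling(mF * lambda * Imax)` via the ratio identity
#' `mF = m1/lambda`).
#'
#' @param config a [design_config()].
#' @param m length-3 events-per-information constants `(m1, m2, mF)` from
#'   [calibrate_information_rate()] (`m1` drives the solve; the others are
#'   carried for reporting and interim event predictions).
#' @param d1_interim planned interim event count in S1; defaults to
#'   `ceiling(m1 * I1)` with `I1` from the threshold solve.
#' @return List with `Imax`, `d_total`, `d1_interim`, `zeta`,
#'   `info_interim`, and the planning boundaries/spends at the solution.
#' @export
solve_imax <- function(config, m, d1_interim = NULL) {
  stopifnot(inherits(config, "design_config"), length(m) == 3L, all(m > 0))
  ti <- solve_threshold_and_info(config$delta, config$p_select_1,
                                 config$p_select_F)
  if (is.null(d1_interim)) d1_interim <- ceiling(m[1] * ti$info_interim)
  lam <- config$lambda
  d1j <- c(`1` = d1_interim, `2` = (1 - lam) * d1_interim / lam,
           F = d1_interim / lam)
  I1j <- d1j / m[1]   # per-event information scale shared by 1, 2 and F
  names(I1j) <- c("1", "2", "F")
  theta_alt <- c(-config$delta, 0)

  eval_at <- function(Imax) {
    I2j <- c(`1` = Imax, `2` = Imax, F = Imax)
    sp <- spend(config$alpha, config$beta, I1j[["F"]], Imax, Imax)
    s1 <- solve_stage1_boundaries(sp$alpha1, sp$beta1, ti$zeta, theta_alt,
                                  I1j[["1"]], I1j[["2"]], lam,
                                  omega = config$omega)
    s2 <- suppressWarnings(
      solve_stage2_boundaries(sp$alpha2, sp$beta2, s1$a1, s1$b1, ti$zeta,
                              theta_alt, I1j, I2j, lam, omega = config$omega))
    list(diff = s2$a2 - s2$b2, s1 = s1, s2 = s2, sp = sp, I2j = I2j)
  }
  lo <- I1j[["F"]] * 1.02
  hi <- I1j[["F"]] * 2
  k <- 0
  while (eval_at(hi)$diff < 0 && k < 12) {
    hi <- hi * 1.6
    k <- k + 1
  }
  if (eval_at(hi)$diff < 0) {
    stop("Imax search failed: no sign change in bracket", call. = FALSE)
  }
  Imax <- stats::uniroot(function(x) eval_at(x)$diff, c(lo, hi),
                         tol = 1e-6)$root
  at <- eval_at(Imax)
  list(Imax = Imax, d_total = ceiling(m[1] * Imax),
       d1_interim = d1_interim, zeta = ti$zeta,
       info_interim = ti$info_interim,
       boundaries = structure(
         list(a1 = at$s1$a1, b1 = at$s1$b1, a2 = at$s2$a2, b2 = at$s2$b2,
              alpha1 = at$sp$alpha1, alpha2 = at$sp$alpha2,
              beta1 = at$sp$beta1, beta2 = at$sp$beta2),
         class = "trial_boundaries"),
       infos_stage1 = I1j, infos_stage2 = at$I2j)
}

#' @export
print.trial_boundaries <- function(x, ...) {
  cat(sprintf("Boundaries: stage 1 (a1 = %.4f, b1 = %.4f), stage 2 (a2 = %.4f, b2 = %.4f)\n",
              x$a1, x$b1, x$a2, x$b2))
  cat(sprintf("  spent error: alpha (%.5f, %.5f), beta (%.5f, %.5f)\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  invisible(x)
}

#' Plan a full enrichment trial design
#'
#' Composes the design pipeline: solve the threshold rule for
#' `(zeta, I1(1))`, calibrate the events-per-information constants by
#' simulation under the design alternative, set the interim event target
#' `d1(1) = ceiling(m1 I1(1))`, and search for the maximum information /
#' total event target `d(2)`.
#'
#' @param config a [design_config()].
#' @param params a [joint_model_params()]; its treatment effects are replaced
#'   by the design alternative `(-delta, 0)` for calibration.
#' @param method analysis method to calibrate for.
#' @param n_calibration number of patients per calibration replicate.
#' @param n_replicates number of calibration replicates.
#' @param calibration optionally, a precomputed [calibrate_information_rate()]
#'   result (skips simulation).
#' @return An object of class `design_plan`.
#' @export
plan_design <- function(config, params, method = "condscore",
                        n_calibration = 1600, n_replicates = 150,
                        calibration = NULL) {
  stopifnot(inherits(config, "design_config"),
            inherits(params, "joint_model_params"))
  ti <- solve_threshold_and_info(config$delta, config$p_select_1,
                                 config$p_select_F)
  if (is.null(calibration)) {
    params_alt <- params
    params_alt$lambda <- config$lambda
    calibration <- calibrate_information_rate(
      params_alt, method = method, n_patients = n_calibration,
      n_replicates = n_replicates, theta = c(-config$delta, 0),
      info_target = ti$info_interim)
  }
  m <- c(calibration$m1, calibration$m2, calibration$mF)
  im <- solve_imax(config, m)
  d1 <- im$d1_interim
  structure(
    list(zeta = ti$zeta, info_interim = ti$info_interim,
         m1 = m[1], m2 = m[2], mF = m[3],
         d1_interim = d1,
         d2_interim_pred = (1 - config$lambda) * d1 / config$lambda,
         dF_interim_pred = d1 / config$lambda,
         d_total = im$d_total, imax = im$Imax,
         boundaries = im$boundaries,
         infos_stage1 = im$infos_stage1, infos_stage2 = im$infos_stage2,
         method = method, config = config, calibration = calibration),
    class = "design_plan")
}

#' @export
print.design_plan <- function(x, ...) {
  cat(sprintf("Enrichment design plan (%s analysis)\n", x$method))
  cat(sprintf("  zeta = %.4f, interim information target I1(1) = %.3f\n",
              x$zeta, x$info_interim))
  cat(sprintf("  m-constants: m1 = %.3f, m2 = %.3f, mF = %.3f\n",
              x$m1, x$m2, x$mF))
  cat(sprintf("  events: d1(1) = %d (predict d2(1) ~ %.0f, dF(1) ~ %.0f); d(2) = %d\n",
              x$d1_interim, x$d2_interim_pred, x$dF_interim_pred, x$d_total))
  cat(sprintf("  Imax = %.3f\n", x$imax))
  invisible(x)
}

#' Tidy a design plan
#'
#' @param x a `design_plan`.
#' @param ... unused.
#' @return One-row tibble of the planned quantities.
#' @export
tidy.design_plan <- function(x, ...) {
  tibble::tibble(
    method = x$method, zeta = x$zeta, info_interim = x$info_interim,
    m1 = x$m1, m2 = x$m2, mF = x$mF,
    d1_interim = x$d1_interim, d_total = x$d_total, imax = x$imax,
    a1 = x$boundaries$a1, b1 = x$boundaries$b1,
    a2 = x$boundaries$a2, b2 = x$boundaries$b2
  )
}

#' Export a design plan as JSON
#'
#' @param plan a `design_plan`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to file).
#' @export
plan_json <- function(plan, path = NULL) {
  x <- list(zeta = plan$zeta, info_interim = plan$info_interim,
            m1 = plan$m1, m2 = plan$m2, mF = plan$mF,
            d1_interim = plan$d1_interim,
            d2_interim_pred = plan$d2_interim_pred,
            dF_interim_pred = plan$dF_interim_pred,
            d_total = plan$d_total, imax = plan$imax,
            boundaries = unclass(plan$boundaries))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
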