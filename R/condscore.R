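# Multi-stage conditional-score estimation for the joint model.
#
# The estimator removes the subject-level random effects by conditioning on
# the per-subject least-squares trajectory prediction Xhat(t), whose
# measurement-error variance is sigma2 * leverage(t). Risk sets and event
# sums only admit subjects whose second measurement predates t (the
# regression needs two points), per the at-risk/counting processes.

# Precompute everything about a (snapshot, subgroup) that the score needs:
# event times, per-event design matrices of Xhat, leverage, at-risk flags.
.cs_build <- function(snapshot, subgroup) {
  su <- snapshot$subjects[snapshot$subjects$subgroup == as.integer(subgroup), ]
  me <- snapshot$measurements[snapshot$measurements$subject_id %in% su$subject_id, ]
  f <- factor(me$subject_id, levels = su$subject_id)
  vlist <- split(me$time_years, f)
  dlist <- split(me$biomarker, f)
  n <- nrow(su)

  # per-subject prefix OLS statistics for every usable prefix length s >= 2
  pre <- vector("list", n)
  for (i in seq_len(n)) {
    v <- vlist[[i]]; d <- dlist[[i]]
    o <- order(v); v <- v[o]; d <- d[o]
    m <- length(v)
    if (m < 2L) { pre[i] <- list(NULL); vlist[[i]] <- v; next }
    s <- seq_len(m)
    vbar <- cumsum(v) / s
    dbar <- cumsum(d) / s
    svv <- cumsum(v^2) - s * vbar^2
    svd_ <- cumsum(v * d) - s * vbar * dbar
    slope <- ifelse(s >= 2L & svv > 1e-12, svd_ / svv, NA_real_)
    pre[[i]] <- list(b1 = slope, b0 = dbar - slope * vbar, vbar = vbar,
                     svv = svv)
    vlist[[i]] <- v
  }

  m_at <- vapply(seq_len(n), function(i) {
    if (is.null(pre[[i]])) return(0L)
    findInterval(su$time_years[i] + 1e-12, vlist[[i]])
  }, integer(1))
  is_event <- su$event == 1L & m_at >= 2L
  ord <- order(su$time_years[is_event], su$subject_id[is_event])
  ev_rows <- which(is_event)[ord]
  te <- su$time_years[ev_rows]
  d_ev <- length(te)

  Xhat <- matrix(0, d_ev, n)
  lev <- matrix(0, d_ev, n)
  risk <- matrix(0, d_ev, n)
  if (d_ev > 0L) {
    for (i in seq_len(n)) {
      if (is.null(pre[[i]])) next
      s <- findInterval(te + 1e-12, vlist[[i]])
      ok <- s >= 2L & su$time_years[i] >= te - 1e-12
      if (!any(ok)) next
      si <- s[ok]
      bad <- is.na(pre[[i]]$b1[si])
      if (any(bad)) { ok[ok][bad] <- FALSE; si <- si[!bad] }
      if (!any(ok)) next
      Xhat[ok, i] <- pre[[i]]$b0[si] + pre[[i]]$b1[si] * te[ok]
      lev[ok, i] <- 1 / si + (te[ok] - pre[[i]]$vbar[si])^2 / pre[[i]]$svv[si]
      risk[ok, i] <- 1
    }
  }
  ev_col <- match(ev_rows, seq_len(n))
  list(te = te, d = d_ev, n = n, psi = as.numeric(su$arm),
       Xhat = Xhat, lev = lev, risk = risk,
       ev_idx = cbind(seq_len(d_ev), ev_col),
       subject_id = su$subject_id)
}

# Conditional score U(gamma, theta) and per-event contributions xi (d x 2).
.cs_score <- function(par, D, sigma2) {
  g <- par[1]; th <- par[2]
  dd <- D$d; nn <- D$n
  if (dd == 0L) return(list(U = c(0, 0), xi = matrix(0, 0, 2)))
  S <- D$Xhat
  S[D$ev_idx] <- S[D$ev_idx] + g * sigma2 * D$lev[D$ev_idx]
  eta <- g * S - (0.5 * g * g * sigma2) * D$lev
  eta <- eta + rep(th * D$psi, each = dd)
  E0 <- D$risk * exp(pmin(eta, 700))
  den <- .rowSums(E0, dd, nn)
  ES <- .rowSums(E0 * S, dd, nn) / den
  Epsi <- drop(E0 %*% D$psi) / den
  xi1 <- S[D$ev_idx] - ES
  xi2 <- D$psi[D$ev_idx[, 2]] - Epsi
  list(U = c(sum(xi1), sum(xi2)), xi = cbind(xi1, xi2))
}

.num_jac <- function(f, par, h_rel = 1e-5) {
  p <- length(par)
  J <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    h <- h_rel * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

# Damped Newton root finder with restart list; f returns the score vector.
.newton_root <- function(f, starts, tol, max_iter = 50L) {
  for (st in starts) {
    par <- st
    U <- tryCatch(f(par), error = function(e) NULL)
    if (is.null(U) || any(!is.finite(U))) next
    for (it in seq_len(max_iter)) {
      if (max(abs(U)) < tol) return(list(par = par, U = U))
      J <- .num_jac(f, par)
      if (any(!is.finite(J))) break
      step <- tryCatch(solve(J, -U), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        parn <- par + lam * step
        Un <- tryCatch(f(parn), error = function(e) NULL)
        if (!is.null(Un) && all(is.finite(Un)) && sum(Un^2) < sum(U^2)) break
        lam <- lam / 2
        if (lam < 2^-20) break
      }
      if (lam < 2^-20) break
      par <- parn; U <- Un
    }
    if (!is.null(U) && all(is.finite(U)) && max(abs(U)) < tol) {
      return(list(par = par, U = U))
    }
  }
  NULL
}

new_score_fit <- function(gamma_hat, theta_hat, sigma2_hat, A, B, info, z,
                          d, n, method, subgroup) {
  structure(list(gamma_hat = gamma_hat, theta_hat = theta_hat,
                 sigma2_hat = sigma2_hat, A = A, B = B, info = info, z = z,
                 d = d, n = n, method = method, subgroup = subgroup),
            class = "score_fit")
}

#' Conditional score vector
#'
#' Evaluates the two-component conditional score (components for the
#' biomarker association `gamma` and the treatment effect `theta`) at the
#' given parameter values, summing over the observed event times of
#' measurement-eligible subjects in the subgroup.
#'
#' @param gamma,theta parameter values.
#' @param sigma2 measurement-error variance used in the sufficient statistic.
#' @param snapshot a `trial_snapshot`.
#' @param subgroup 1 or 2.
#' @return Numeric length-2 score vector.
#' @export
score_vector <- function(gamma, theta, sigma2, snapshot, subgroup) {
  D <- .cs_build(snapshot, subgroup)
  .cs_score(c(gamma, theta), D, sigma2)$U
}

#' Fit the joint model by the conditional-score method
#'
#' Finds `(gamma_hat, theta_hat)` as the root of the conditional score with
#' the pooled plug-in estimate of the measurement-error variance, then forms
#' the sandwich information for the treatment effect:
#' `I = 1 / Var(theta_hat) = n * ([A^-1 B A^-T]_22)^-1` with `A` the
#' per-patient average numeric Jacobian of the score and `B` the per-patient
#' average outer product of the per-subject score contributions. The
#' standardized statistic uses the benefit-positive convention
#' `z = -theta_hat * sqrt(I)` (negative log-hazard effects mean benefit).
#'
#' @param snapshot a `trial_snapshot`.
#' @param subgroup 1 or 2.
#' @param fix_gamma optionally hold `gamma` fixed at this value and solve the
#'   treatment-effect component only (used mainly for method comparisons).
#' @param tol_scale convergence requires `max |U| < tol_scale * d`.
#' @return A `score_fit` object; see [tidy.score_fit()] and
#'   [glance.score_fit()].
#' @export
solve_score <- function(snapshot, subgroup, fix_gamma = NULL,
                        tol_scale = 1e-8) {
  sigma2_hat <- pooled_sigma2(snapshot, subgroup)
  D <- .cs_build(snapshot, subgroup)
  if (D$d < 1L) {
    stop("RootNotFound: no eligible events in subgroup ", subgroup, call. = FALSE)
  }
  if (D$d < 20L) {
    warning(sprintf(
      "only %d events in subgroup %s: conditional-score asymptotics need about 20 events per subgroup",
      D$d, subgroup), call. = FALSE)
  }
  tol <- tol_scale * D$d

  if (is.null(fix_gamma)) {
    f <- function(p) .cs_score(p, D, sigma2_hat)$U
    sol <- .newton_root(f, list(c(0, 0), c(0, 0.5), c(0, -0.5)), tol)
    if (is.null(sol)) {
      stop("RootNotFound: conditional score has no root (few events or large measurement error)",
           call. = FALSE)
    }
    par <- sol$par
    J <- .num_jac(f, par)
    A <- J / D$n
    xi <- .cs_score(par, D, sigma2_hat)$xi
    B <- crossprod(xi) / D$n
    Ainv <- solve(A)
    v22 <- (Ainv %*% B %*% t(Ainv))[2, 2] / D$n
    if (!is.finite(v22) || v22 <= 0) {
      stop("RootNotFound: sandwich variance not positive", call. = FALSE)
    }
    info <- 1 / v22
    new_score_fit(par[1], par[2], sigma2_hat, A, B, info,
                  -par[2] * sqrt(info), D$d, D$n, "condscore",
                  as.integer(subgroup))
  } else {
    f1 <- function(th) .cs_score(c(fix_gamma, th), D, sigma2_hat)$U[2]
    g1 <- function(th) c(f1(th[1]))
    sol <- .newton_root(function(p) g1(p), list(0, 0.5, -0.5), tol)
    if (is.null(sol)) stop("RootNotFound: no root in theta", call. = FALSE)
    th <- sol$par[1]
    h <- 1e-5 * max(1, abs(th))
    a22 <- (f1(th + h) - f1(th - h)) / (2 * h) / D$n
    xi <- .cs_score(c(fix_gamma, th), D, sigma2_hat)$xi
    b22 <- sum(xi[, 2]^2) / D$n
    v <- b22 / (a22^2) / D$n
    info <- 1 / v
    new_score_fit(fix_gamma, th, sigma2_hat, NULL, NULL, info,
                  -th * sqrt(info), D$d, D$n, "condscore_fixed_gamma",
                  as.integer(subgroup))
  }
}

#' Combine subgroup estimates into the full-population estimate
#'
#' The full-population effect is the prevalence-weighted combination
#' `theta_F = lambda * theta_1 + (1 - lambda) * theta_2` with information
#' `I_F = (lambda^2 / I_1 + (1 - lambda)^2 / I_2)^-1` and
#' `z_F = -theta_F * sqrt(I_F)`.
#'
#' @param fit1,fit2 `score_fit` objects for subgroups 1 and 2.
#' @param lambda prevalence of subgroup 1.
#' @return A `score_fit` for the full population (`subgroup = "F"`).
#' @examples
#' f1 <- enrichjm:::new_score_fit(NA, -0.5, NA, NULL, NULL, 9, 1.5, 40, 100, "x", 1L)
#' f2 <- enrichjm:::new_score_fit(NA, -0.5, NA, NULL, NULL, 9, 1.5, 20, 50, "x", 2L)
#' combine_subgroups(f1, f2, 2/3)$theta_hat  # -0.5
#' @export
combine_subgroups <- function(fit1, fit2, lambda) {
  if (!(lambda > 0 && lambda < 1)) stop("lambda must be in (0,1)", call. = FALSE)
  stopifnot(fit1$info > 0, fit2$info > 0)
  theta_F <- lambda * fit1$theta_hat + (1 - lambda) * fit2$theta_hat
  info_F <- 1 / (lambda^2 / fit1$info + (1 - lambda)^2 / fit2$info)
  out <- new_score_fit(NA_real_, theta_F, NA_real_, NULL, NULL, info_F,
                       -theta_F * sqrt(info_F), fit1$d + fit2$d,
                       fit1$n + fit2$n, paste0(fit1$method, "_combined"), "F")
  out
}

#' @export
print.score_fit <- function(x, ...) {
  cat(sprintf("<score_fit %s, subgroup %s>\n", x$method, x$subgroup))
  cat(sprintf("  theta_hat = %.4f  (info %.3f, z = %.3f)\n",
              x$theta_hat, x$info, x$z))
  if (is.finite(x$gamma_hat %||% NA)) {
    cat(sprintf("  gamma_hat = %.4f  sigma2_hat = %.4f\n",
                x$gamma_hat, x$sigma2_hat %||% NA))
  }
  cat(sprintf("  %d events / %d subjects\n", x$d, x$n))
  invisible(x)
}

#' Tidy a fitted treatment-effect estimate
#'
#' @param x a `score_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter.
#' @export
tidy.score_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "theta"),
    estimate = c(x$gamma_hat, x$theta_hat),
    statistic = c(NA_real_, x$z),
    std.error = c(NA_real_, 1 / sqrt(x$info))
  )
}

#' @rdname tidy.score_fit
#' @export
glance.score_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, subgroup = as.character(x$subgroup),
    theta_hat = x$theta_hat, gamma_hat = x$gamma_hat,
    sigma2_hat = x$sigma2_hat %||% NA_real_,
    info = x$info, z = x$z, n_events = x$d, n_subjects = x$n
  )
}

#' Export a fit as JSON
#'
#' @param fit a `score_fit`.
#' @param path optional file path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
score_fit_json <- function(fit, path = NULL) {
  x <- list(gamma_hat = fit$gamma_hat, theta_hat = fit$theta_hat,
            sigma2_hat = fit$sigma2_hat, info = fit$info, z = fit$z,
            d = fit$d, n = fit$n)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
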