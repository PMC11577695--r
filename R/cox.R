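# Comparator analyses: the plain Cox model ignoring the biomarker, and the
# Cox model treating the observed biomarker as an error-free time-varying
# covariate (last observation carried forward). Both are fit by Newton on
# the partial-likelihood score and return score_fit objects so that the
# enrichment-design machinery is method-agnostic.

#' Plain Cox model treatment-effect fit
#'
#' Fits `h(t) = h0(t) exp(theta * psi)` by maximum partial likelihood within
#' the subgroup; every subject is eligible (no minimum number of biomarker
#' measurements). Information is the observed partial-likelihood information
#' at the estimate and `z = -theta_hat * sqrt(info)`.
#'
#' @param snapshot a `trial_snapshot`.
#' @param subgroup 1 or 2.
#' @return A `score_fit`.
#' @export
cox_fit <- function(snapshot, subgroup) {
  su <- snapshot$subjects[snapshot$subjects$subgroup == as.integer(subgroup), ]
  tt <- su$time_years; ev <- su$event == 1L; psi <- as.numeric(su$arm)
  d <- sum(ev)
  if (d < 1L) stop("no events in subgroup ", subgroup, call. = FALSE)

  # risk sums by decreasing time; Breslow handling for tied times
  o <- order(-tt, su$subject_id)
  tt_o <- tt[o]; psi_o <- psi[o]
  score_info <- function(theta) {
    w <- exp(theta * psi_o)
    a0 <- cumsum(w)
    a1 <- cumsum(w * psi_o)
    # for each event, risk set = subjects with time >= te
    idx <- findInterval(-tt[ev] + 1e-15, -tt_o)  # last position with tt_o >= te
    idx <- pmax(idx, 1L)
    e1 <- a1[idx] / a0[idx]
    U <- sum(psi[ev] - e1)
    info <- sum(e1 - e1^2)   # psi binary: E[psi^2] = E[psi]
    c(U, info)
  }
  theta <- 0
  for (it in 1:50) {
    si <- score_info(theta)
    if (abs(si[1]) < 1e-10 * max(1, d)) break
    if (si[2] <= 1e-12 || abs(theta) >= 10) {
      # monotone likelihood (e.g. all events on one arm): bounded fallback
      warning("monotone partial likelihood; treatment effect truncated",
              call. = FALSE)
      theta <- sign(theta + si[1]) * 10
      break
    }
    step <- si[1] / si[2]
    step <- max(min(step, 2), -2)
    theta <- theta + step
  }
  si <- score_info(theta)
  info <- si[2]
  new_score_fit(NA_real_, theta, NA_real_, NULL, NULL, info,
                -theta * sqrt(info), d, nrow(su), "cox",
                as.integer(subgroup))
}

# Build per-event LOCF covariate matrix for the time-varying-covariate Cox.
.tvc_build <- function(snapshot, subgroup) {
  su <- snapshot$subjects[snapshot$subjects$subgroup == as.integer(subgroup), ]
  me <- snapshot$measurements[snapshot$measurements$subject_id %in% su$subject_id, ]
  f <- factor(me$subject_id, levels = su$subject_id)
  vlist <- split(me$time_years, f)
  dlist <- split(me$biomarker, f)
  n <- nrow(su)
  has_meas <- lengths(vlist) >= 1L
  if (any(!has_meas)) {
    warning(sum(!has_meas), " subject(s) without biomarker measurements excluded from risk sets",
            call. = FALSE)
  }
  is_event <- su$event == 1L & has_meas &
    vapply(seq_len(n), function(i) {
      length(vlist[[i]]) > 0L && vlist[[i]][1] <= su$time_years[i] + 1e-12
    }, logical(1))
  ord <- order(su$time_years[is_event], su$subject_id[is_event])
  ev_rows <- which(is_event)[ord]
  te <- su$time_years[ev_rows]
  d_ev <- length(te)
  Dmat <- matrix(0, d_ev, n)
  risk <- matrix(0, d_ev, n)
  if (d_ev > 0L) {
    for (i in seq_len(n)) {
      if (!has_meas[i]) next
      o <- order(vlist[[i]])
      v <- vlist[[i]][o]; dd <- dlist[[i]][o]
      s <- findInterval(te + 1e-12, v)
      ok <- s >= 1L & su$time_years[i] >= te - 1e-12
      if (!any(ok)) next
      Dmat[ok, i] <- dd[s[ok]]
      risk[ok, i] <- 1
    }
  }
  list(te = te, d = d_ev, n = n, psi = as.numeric(su$arm),
       D = Dmat, risk = risk, ev_idx = cbind(seq_len(d_ev), match(ev_rows, seq_len(n))))
}

.tvc_score <- function(par, B) {
  g <- par[1]; th <- par[2]
  dd <- B$d; nn <- B$n
  eta <- g * B$D + rep(th * B$psi, each = dd)
  w <- B$risk * exp(pmin(eta, 700))
  den <- .rowSums(w, dd, nn)
  eD <- .rowSums(w * B$D, dd, nn) / den
  ePsi <- drop(w %*% B$psi) / den
  eDD <- .rowSums(w * B$D * B$D, dd, nn) / den
  ePP <- ePsi                      # psi binary
  eDP <- drop((w * B$D) %*% B$psi) / den
  xi1 <- B$D[B$ev_idx] - eD
  xi2 <- B$psi[B$ev_idx[, 2]] - ePsi
  U <- c(sum(xi1), sum(xi2))
  H <- matrix(c(sum(eDD - eD^2), sum(eDP - eD * ePsi),
                sum(eDP - eD * ePsi), sum(ePP - ePsi^2)), 2L)
  list(U = U, H = H, xi = cbind(xi1, xi2))
}

#' Cox model with the biomarker as a time-varying covariate
#'
#' Fits `h(t) = h0(t) exp(gamma * D(t) + theta * psi)` where `D(t)` is the
#' last observed biomarker value at or before `t` (LOCF), by Newton on the
#' two-parameter partial-likelihood score with its analytic Hessian. The
#' treatment-effect information is the inverse of the `(theta, theta)` entry
#' of the inverted observed information.
#'
#' @param snapshot a `trial_snapshot`.
#' @param subgroup 1 or 2.
#' @param fix_gamma optionally hold `gamma` fixed (at 0 this reproduces
#'   [cox_fit()] exactly).
#' @return A `score_fit`.
#' @export
cox_tvc_fit <- function(snapshot, subgroup, fix_gamma = NULL) {
  B <- .tvc_build(snapshot, subgroup)
  if (B$d < 1L) stop("no eligible events in subgroup ", subgroup, call. = FALSE)
  if (is.null(fix_gamma)) {
    par <- c(0, 0)
    for (it in 1:100) {
      sc <- .tvc_score(par, B)
      if (max(abs(sc$U)) < 1e-9 * max(1, B$d)) break
      step <- tryCatch(solve(sc$H, sc$U), error = function(e) NULL)
      if (is.null(step)) stop("singular information in time-varying Cox fit", call. = FALSE)
      step <- pmin(pmax(step, -2), 2)
      par <- par + step
    }
    sc <- .tvc_score(par, B)
    Hinv <- solve(sc$H)
    info <- 1 / Hinv[2, 2]
    new_score_fit(par[1], par[2], NA_real_, NULL, NULL, info,
                  -par[2] * sqrt(info), B$d, B$n, "cox_tvc",
                  as.integer(subgroup))
  } else {
    th <- 0
    for (it in 1:100) {
      sc <- .tvc_score(c(fix_gamma, th), B)
      if (abs(sc$U[2]) < 1e-10 * max(1, B$d)) break
      th <- th + max(min(sc$U[2] / sc$H[2, 2], 2), -2)
    }
    sc <- .tvc_score(c(fix_gamma, th), B)
    info <- sc$H[2, 2]
    new_score_fit(fix_gamma, th, NA_real_, NULL, NULL, info,
                  -th * sqrt(info), B$d, B$n, "cox_tvc_fixed_gamma",
                  as.integer(subgroup))
  }
}

#' Fit one subgroup of a snapshot with a chosen analysis method
#'
#' @param snapshot a `trial_snapshot`.
#' @param subgroup 1 or 2.
#' @param method `"condscore"`, `"cox"` or `"cox_tvc"`.
#' @return A `score_fit`.
#' @export
fit_snapshot <- function(snapshot, subgroup,
                         method = c("condscore", "cox", "cox_tvc")) {
  method <- match.arg(method)
  switch(method,
         condscore = solve_score(snapshot, subgroup),
         cox = cox_fit(snapshot, subgroup),
         cox_tvc = cox_tvc_fit(snapshot, subgroup))
}
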