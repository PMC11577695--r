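# Shared fixtures and independent oracles for the test suite. Oracles use
# survival::coxph on counting-process (start, stop, event) data so that they
# share no code with the package's own Newton solvers.

base_params <- function(...) joint_model_params(...)

# Construct a trial_snapshot directly from per-subject fields (no simulation).
manual_snapshot <- function(subgroup, arm, time_years, event,
                            meas = NULL, recruit_years = NULL) {
  n <- length(time_years)
  if (is.null(recruit_years)) recruit_years <- rep(0, n)
  su <- tibble::tibble(
    subject_id = seq_len(n), subgroup = as.integer(subgroup),
    arm = as.integer(arm), recruit_years = recruit_years,
    b0 = NA_real_, b1 = NA_real_,
    latent_event_years = NA_real_, ltfu_years = NA_real_,
    time_years = time_years, event = as.integer(event))
  me <- if (is.null(meas)) {
    tibble::tibble(subject_id = integer(), time_years = numeric(),
                   biomarker = numeric())
  } else {
    meas
  }
  structure(list(subjects = su, measurements = me, analysis = 1L,
                 calendar_time = max(recruit_years + time_years),
                 tau = max(time_years), params = NULL),
            class = "trial_snapshot")
}

# Treatment-only Cox partial-likelihood fit on risk sets restricted to
# subjects whose second biomarker measurement predates t (entry time = v2).
oracle_cox_restricted <- function(snapshot, subgroup) {
  su <- snapshot$subjects[snapshot$subjects$subgroup == as.integer(subgroup), ]
  me <- snapshot$measurements[snapshot$measurements$subject_id %in% su$subject_id, ]
  v2 <- vapply(su$subject_id, function(id) {
    v <- sort(me$time_years[me$subject_id == id])
    if (length(v) >= 2) v[2] else NA_real_
  }, numeric(1))
  keep <- !is.na(v2) & v2 < su$time_years
  d <- data.frame(start = v2[keep], stop = su$time_years[keep],
                  event = su$event[keep], psi = su$arm[keep])
  survival::coxph(survival::Surv(start, stop, event) ~ psi, data = d,
                  ties = "breslow")
}

# Cox fit with a per-subject linear-trajectory covariate evaluated exactly at
# each event time (episode-split at event times); risk sets restricted to
# v2 <= t as above. With sigma2 = 0 the OLS prefix prediction equals the true
# line, so this is the reference for the conditional score in that limit.
oracle_cox_trajectory <- function(snapshot, subgroup) {
  su <- snapshot$subjects[snapshot$subjects$subgroup == as.integer(subgroup), ]
  me <- snapshot$measurements[snapshot$measurements$subject_id %in% su$subject_id, ]
  fits <- lapply(su$subject_id, function(id) {
    v <- me$time_years[me$subject_id == id]
    d <- me$biomarker[me$subject_id == id]
    o <- order(v)
    list(v = v[o], d = d[o])
  })
  v2 <- vapply(fits, function(f) if (length(f$v) >= 2) f$v[2] else NA_real_,
               numeric(1))
  te <- sort(su$time_years[su$event == 1 & !is.na(v2) & v2 <= su$time_years])
  rows <- list()
  for (i in seq_along(fits)) {
    if (is.na(v2[i])) next
    cuts <- te[te > v2[i] & te <= su$time_years[i]]
    if (length(cuts) == 0) next
    lo <- c(v2[i], head(cuts, -1))
    for (k in seq_along(cuts)) {
      t_ev <- cuts[k]
      use <- fits[[i]]$v <= t_ev + 1e-12
      cf <- stats::coef(stats::lm(fits[[i]]$d[use] ~ fits[[i]]$v[use]))
      rows[[length(rows) + 1]] <- data.frame(
        start = lo[k], stop = t_ev,
        event = as.integer(su$event[i] == 1 &&
                             abs(su$time_years[i] - t_ev) < 1e-12),
        x = cf[1] + cf[2] * t_ev, psi = su$arm[i])
    }
  }
  d <- do.call(rbind, rows)
  survival::coxph(survival::Surv(start, stop, event) ~ x + psi, data = d,
                  ties = "breslow")
}

# LOCF time-varying-covariate Cox via counting-process intervals split at
# measurement times (entry at the first measurement).
oracle_cox_locf <- function(snapshot, subgroup) {
  su <- snapshot$subjects[snapshot$subjects$subgroup == as.integer(subgroup), ]
  me <- snapshot$measurements[snapshot$measurements$subject_id %in% su$subject_id, ]
  rows <- list()
  for (i in seq_len(nrow(su))) {
    id <- su$subject_id[i]
    v <- me$time_years[me$subject_id == id]
    d <- me$biomarker[me$subject_id == id]
    o <- order(v); v <- v[o]; d <- d[o]
    if (length(v) == 0 || v[1] > su$time_years[i]) next
    ends <- c(v[-1], su$time_years[i])
    for (s in seq_along(v)) {
      if (ends[s] <= v[s]) next
      stop_s <- min(ends[s], su$time_years[i])
      if (stop_s <= v[s]) next
      rows[[length(rows) + 1]] <- data.frame(
        start = v[s], stop = stop_s,
        event = as.integer(su$event[i] == 1 &&
                             abs(stop_s - su$time_years[i]) < 1e-12),
        x = d[s], psi = su$arm[i])
      if (stop_s >= su$time_years[i]) break
    }
  }
  dd <- do.call(rbind, rows)
  survival::coxph(survival::Surv(start, stop, event) ~ x + psi, data = dd,
                  ties = "breslow")
}

# Gaussian-level Monte Carlo of the two-stage procedure at a planned design:
# interim statistics drawn from their exact joint law, threshold selection,
# planned stage-1 boundaries, canonical-joint-distribution transition to the
# final statistic, rejection above b2. Returns the rejected population label
# per replicate ("none" if none).
mc_two_stage <- function(n, theta, zeta, im, cfg, I_F1 = NULL) {
  I1 <- unname(im$infos_stage1[["1"]])
  I2 <- unname(im$infos_stage1[["2"]])
  lam <- cfg$lambda
  if (is.null(I_F1)) I_F1 <- 1 / (lam^2 / I1 + (1 - lam)^2 / I2)
  z1 <- rnorm(n, -theta[1] * sqrt(I1))
  z2 <- rnorm(n, -theta[2] * sqrt(I2))
  zF <- lam * sqrt(I_F1 / I1) * z1 + (1 - lam) * sqrt(I_F1 / I2) * z2
  w <- ifelse(z1 > zeta & z2 > zeta, "F",
              ifelse(z1 > zeta, "1", ifelse(z2 > zeta, "2", "none")))
  a1 <- im$boundaries$a1; b1 <- im$boundaries$b1; b2 <- im$boundaries$b2
  zw1 <- ifelse(w == "1", z1, ifelse(w == "2", z2, zF))
  rej <- rep("none", n)
  sel <- w != "none"
  rej[sel & zw1 > b1] <- w[sel & zw1 > b1]
  cont <- which(sel & zw1 <= b1 & zw1 >= a1)
  if (length(cont)) {
    thw <- c(`1` = theta[1], `2` = theta[2],
             F = lam * theta[1] + (1 - lam) * theta[2])
    I1w <- c(`1` = I1, `2` = I2, F = I_F1)
    I2w <- c(`1` = unname(im$infos_stage2[["1"]]),
             `2` = unname(im$infos_stage2[["2"]]),
             F = unname(im$infos_stage2[["F"]]))
    wi <- w[cont]
    r <- I1w[wi] / I2w[wi]
    m2 <- -thw[wi] * sqrt(I2w[wi]) * (1 - r) + sqrt(r) * zw1[cont]
    znd <- rnorm(length(cont), m2, sqrt(1 - r))
    rej[cont[znd > b2]] <- wi[znd > b2]
  }
  rej
}
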