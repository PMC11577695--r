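test_that("at gamma = 0 the treatment score equals the restricted Cox partial score", {
  set.seed(21)
  p <- base_params()
  tr <- simulate_trial(p, 300, theta = c(-0.3, 0))
  sn <- snapshot_at_event_count(tr, "1", 40, 1L)

  # direct partial score for the treatment indicator over risk sets
  # restricted to subjects with two measurements by t (independent of the
  # package's matrix machinery)
  direct_score <- function(theta) {
    su <- sn$subjects[sn$subjects$subgroup == 1L, ]
    me <- sn$measurements
    v2 <- vapply(su$subject_id, function(id) {
      v <- sort(me$time_years[me$subject_id == id])
      if (length(v) >= 2) v[2] else Inf
    }, numeric(1))
    ev_idx <- which(su$event == 1 & v2 <= su$time_years)
    U <- 0
    for (i in ev_idx) {
      te <- su$time_years[i]
      risk <- su$time_years >= te & v2 <= te
      w <- exp(theta * su$arm[risk])
      U <- U + su$arm[i] - sum(su$arm[risk] * w) / sum(w)
    }
    U
  }
  for (th in c(0, -0.4, 0.3)) {
    expect_equal(score_vector(0, th, 0.25, sn, 1)[2], direct_score(th),
                 tolerance = 1e-10)
  }
})

test_that("the score has mean zero at the generating parameters", {
  set.seed(22)
  p <- base_params()
  reps <- 60
  u <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    tr <- simulate_trial(p, 400, theta = c(-0.5, 0))
    sn <- snapshot_at_event_count(tr, "1", 40, 1L)
    u[r, ] <- score_vector(0.8, -0.5, 0.25, sn, 1)
  }
  for (j in 1:2) {
    se <- sd(u[, j]) / sqrt(reps)
    expect_lt(abs(mean(u[, j])), 3 * se)
  }
})

test_that("with noiseless biomarkers the solve matches the exact-trajectory Cox fit", {
  set.seed(23)
  p <- base_params(sigma2 = 0)
  tr <- simulate_trial(p, 260, theta = c(-0.4, 0))
  sn <- snapshot_at_event_count(tr, "1", 45, 1L)
  fit <- suppressWarnings(solve_score(sn, 1))
  orc <- oracle_cox_trajectory(sn, 1)
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-12)
  expect_equal(fit$theta_hat, unname(coef(orc)["psi"]), tolerance = 1e-4)
  expect_equal(fit$gamma_hat, unname(coef(orc)["x"]), tolerance = 1e-4)
})

test_that("with gamma fixed at zero the solve matches the restricted Cox fit", {
  set.seed(24)
  p <- base_params()
  tr <- simulate_trial(p, 300, theta = c(-0.4, 0))
  sn <- snapshot_at_event_count(tr, "1", 45, 1L)
  fit <- suppressWarnings(solve_score(sn, 1, fix_gamma = 0))
  orc <- oracle_cox_restricted(sn, 1)
  expect_equal(fit$theta_hat, unname(coef(orc)), tolerance = 1e-4)
  expect_equal(fit$z, -fit$theta_hat * sqrt(fit$info))
})

test_that("the estimator recovers the generating treatment effect", {
  set.seed(25)
  p <- base_params()
  reps <- 40
  th <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    tr <- simulate_trial(p, 700, theta = c(-0.5, 0))
    sn <- snapshot_at_event_count(tr, "1", 60, 1L)
    f <- tryCatch(suppressWarnings(solve_score(sn, 1)),
                  error = function(e) NULL)
    if (!is.null(f)) th[r] <- f$theta_hat
  }
  th <- th[!is.na(th)]
  expect_gt(length(th), 30)
  expect_lt(abs(mean(th) + 0.5), 3 * sd(th) / sqrt(length(th)))
})

test_that("subgroup combination follows the prevalence-weighted formulas", {
  mk <- function(theta, info) {
    enrichjm:::new_score_fit(NA_real_, theta, NA_real_, NULL, NULL, info,
                             -theta * sqrt(info), 40, 100, "x", 1L)
  }
  f <- combine_subgroups(mk(-0.4, 9), mk(-0.4, 5), 2 / 3)
  expect_equal(f$theta_hat, -0.4)
  expect_equal(f$info, 1 / ((4 / 9) / 9 + (1 / 9) / 5))

  # equal informations at lambda = 2/3 give I_F = 9 I / 5
  f2 <- combine_subgroups(mk(-0.2, 7), mk(0.1, 7), 2 / 3)
  expect_equal(f2$info, 9 * 7 / 5)
  expect_equal(f2$theta_hat, 2 / 3 * -0.2 + 1 / 3 * 0.1)
  expect_equal(f2$z, -f2$theta_hat * sqrt(f2$info))

  # boundary behaviour: lambda near 1 recovers subgroup 1
  f3 <- combine_subgroups(mk(-0.3, 8), mk(0.5, 2), 1 - 1e-9)
  expect_equal(f3$theta_hat, -0.3, tolerance = 1e-6)
  expect_equal(f3$info, 8, tolerance = 1e-5)
  expect_error(combine_subgroups(mk(0, 1), mk(0, 1), 1.2), "lambda")

  # zero effect maps to zero statistic
  expect_equal(combine_subgroups(mk(0, 4), mk(0, 4), 0.5)$z, 0)
})

test_that("information grows in proportion to the event count", {
  set.seed(26)
  p <- base_params()
  tr <- simulate_trial(p, 1500, theta = c(-0.5, 0))
  grid <- seq(30, 210, by = 20)
  d <- info <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    sn <- snapshot_at_event_count(tr, "1", grid[k], 1L)
    f <- tryCatch(suppressWarnings(solve_score(sn, 1)),
                  error = function(e) NULL)
    if (is.null(f)) next
    d[k] <- grid[k]; info[k] <- f$info
  }
  ok <- !is.na(d)
  expect_gt(sum(ok), 7)
  expect_gt(cor(d[ok], info[ok])^2, 0.98)
})

test_that("information is invariant to the per-patient normalisation of A and B", {
  set.seed(27)
  p <- base_params()
  tr <- simulate_trial(p, 300, theta = c(-0.5, 0))
  sn <- snapshot_at_event_count(tr, "1", 40, 1L)
  f <- suppressWarnings(solve_score(sn, 1))
  # per-patient averages (package convention) and raw sums give the same
  # information: n [(A^-1 B A^-T)_22]^-1 with averages equals
  # [(As^-1 Bs As^-T)_22]^-1 with As = nA, Bs = nB
  As <- f$n * f$A
  Bs <- f$n * f$B
  info_sum <- 1 / (solve(As) %*% Bs %*% t(solve(As)))[2, 2]
  expect_equal(unname(info_sum), f$info, tolerance = 1e-10)
})

test_that("fits tidy into one row per parameter and export as JSON", {
  set.seed(28)
  p <- base_params()
  tr <- simulate_trial(p, 300, theta = c(-0.5, 0))
  sn <- snapshot_at_event_count(tr, "1", 35, 1L)
  f <- suppressWarnings(solve_score(sn, 1))
  td <- tidy(f)
  expect_equal(td$term, c("gamma", "theta"))
  expect_equal(td$estimate, c(f$gamma_hat, f$theta_hat))
  gl <- glance(f)
  expect_equal(gl$info, f$info)
  expect_equal(gl$n_events, f$d)
  js <- jsonlite::fromJSON(score_fit_json(f))
  expect_equal(js$theta_hat, f$theta_hat)
  expect_equal(js$d, f$d)
})

test_that("too few measurement-eligible events raises the advisory warning", {
  set.seed(29)
  p <- base_params()
  tr <- simulate_trial(p, 400, theta = c(0, 0))
  sn <- snapshot_at_event_count(tr, "1", 10, 1L)
  expect_warning(try(solve_score(sn, 1), silent = TRUE), "20 events")
})
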