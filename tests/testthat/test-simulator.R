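test_that("visit schedule is fortnightly for three months then four-weekly", {
  wk <- 7 / 365.25
  expect_equal(measurement_schedule(12 * wk) / wk, seq(0, 12, by = 2))
  expect_equal(measurement_schedule(24 * wk) / wk,
               c(seq(0, 12, by = 2), 16, 20, 24))
  expect_equal(measurement_schedule(1 * wk), 0)
  expect_equal(measurement_schedule(0), 0)
  expect_error(measurement_schedule(-1), "non-negative")
})

test_that("event sampling reduces to the exponential when gamma = 0", {
  set.seed(101)
  p <- base_params(gamma = 0, baseline = c(0.5, 0.5))
  tt <- sample_event_time(rep(0, 2e4), 0, 0, 1, p)
  se <- 2 / sqrt(2e4)   # sd of Exp(0.5) is 2
  expect_lt(abs(mean(tt) - 2), 3 * se)

  # piecewise-exponential survivor function against Kaplan-Meier
  p2 <- base_params(gamma = 0)
  tt2 <- sample_event_time(rep(0, 1e4), 0, 0, 1, p2)
  km <- survival::survfit(survival::Surv(tt2, rep(1, 1e4)) ~ 1)
  s_true <- exp(-(p2$baseline[1, 1] * pmin(km$time, 1) +
                    p2$baseline[1, 2] * pmax(km$time - 1, 0)))
  expect_lt(max(abs(km$surv - s_true)), 0.02)
})

test_that("the integrated hazard of sampled event times is standard exponential", {
  set.seed(102)
  p <- base_params()
  b0 <- 4.23; b1 <- 1.81
  tt <- sample_event_time(rep(b0, 3000), b1, 0, 1, p)
  H <- cumulative_hazard(tt, b0, b1, 0, 1, p)
  # closed-form cumulative hazard agrees with numeric quadrature
  haz <- function(s) {
    c0 <- ifelse(s <= 1, p$baseline[1, 1], p$baseline[1, 2])
    c0 * exp(p$gamma[1, 1] * (b0 + b1 * s))
  }
  for (t0 in c(0.3, 0.9, 1.7)) {
    expect_equal(cumulative_hazard(t0, b0, b1, 0, 1, p),
                 stats::integrate(haz, 0, t0, rel.tol = 1e-10)$value,
                 tolerance = 1e-6)
  }
  expect_gt(stats::ks.test(H, "pexp")$p.value, 0.01)
})

test_that("a negative hazard trend produces the closed-form cure fraction", {
  set.seed(103)
  p <- base_params()
  b0 <- 2; b1 <- -2    # gamma * b1 < 0: bounded total hazard
  n <- 2e4
  tt <- sample_event_time(rep(b0, n), b1, 0, 1, p)
  a <- p$gamma[1, 1] * b1
  k <- exp(p$gamma[1, 1] * b0)
  H_inf <- k * (p$baseline[1, 1] * (exp(a) - 1) / a +
                  p$baseline[1, 2] * (0 - exp(a)) / a)
  p_cure <- exp(-H_inf)
  se <- sqrt(p_cure * (1 - p_cure) / n)
  expect_lt(abs(mean(!is.finite(tt)) - p_cure), 3 * se)
})

test_that("simulated cohorts match the generating model", {
  set.seed(104)
  p <- base_params()
  tr <- simulate_trial(p, 6000, theta = c(-0.5, 0))
  su <- tr$subjects

  expect_lt(abs(mean(su$subgroup == 1) - 2 / 3),
            3 * sqrt(2 / 9 / 6000) + 1e-9)
  # 1:1 allocation within each subgroup by alternation
  expect_lte(abs(sum(su$arm[su$subgroup == 1]) - sum(su$subgroup == 1) / 2), 1)
  # recruitment at 2/week, deterministic
  expect_equal(diff(su$recruit_years[1:3]), rep(3.5 / 365.25, 2))

  me <- tr$measurements
  key <- match(me$subject_id, su$subject_id)
  resid <- me$biomarker - (su$b0[key] + su$b1[key] * me$time_years)
  expect_lt(abs(var(resid) - 0.25) / 0.25, 0.05)
})

test_that("loss to follow-up matches the calibrated 10% target", {
  set.seed(105)
  p <- base_params()
  tr <- simulate_trial(p, 8000)
  su <- tr$subjects
  fin <- is.finite(su$latent_event_years)
  frac <- mean(su$ltfu_years[fin] < su$latent_event_years[fin])
  expect_lt(abs(frac - 0.10), 0.02)
})

test_that("event-count snapshots censor administratively and count exactly d events", {
  set.seed(106)
  p <- base_params()
  tr <- simulate_trial(p, 600, theta = c(-0.5, 0))
  sn <- snapshot_at_event_count(tr, "1", 30, 1L)

  expect_equal(n_events(sn, 1), 30)
  su <- sn$subjects
  raw <- tr$subjects[match(su$subject_id, tr$subjects$subject_id), ]
  admin <- sn$calendar_time - su$recruit_years
  expect_equal(su$time_years,
               pmin(raw$latent_event_years, raw$ltfu_years, admin))
  expect_equal(su$event,
               as.integer(raw$latent_event_years <=
                            pmin(raw$ltfu_years, admin)))
  expect_equal(sn$tau, max(su$time_years))
  # retained measurements never post-date the observed time
  key <- match(sn$measurements$subject_id, su$subject_id)
  expect_true(all(sn$measurements$time_years <= su$time_years[key] + 1e-9))

  # d = 1 gives the earliest event calendar time
  sn1 <- snapshot_at_event_count(tr, "1", 1, 1L)
  ev <- raw_ev <- tr$subjects
  ok <- ev$subgroup == 1 & is.finite(ev$latent_event_years) &
    ev$latent_event_years <= ev$ltfu_years
  expect_equal(sn1$calendar_time,
               min(ev$recruit_years[ok] + ev$latent_event_years[ok]),
               tolerance = 1e-6)

  expect_error(snapshot_at_event_count(tr, "1", 1e5, 1L), "InsufficientEvents")
})

test_that("interim events in the complement track the prevalence ratio", {
  set.seed(107)
  p <- base_params()
  reps <- 40
  ratio <- numeric(reps)
  for (r in seq_len(reps)) {
    tr <- simulate_trial(p, 500, theta = c(-0.5, 0))
    sn <- snapshot_at_event_count(tr, "1", 40, 1L)
    ratio[r] <- n_events(sn, 2) / 40
  }
  want <- (1 - p$lambda) / p$lambda
  expect_lt(abs(mean(ratio) - want), 3 * sd(ratio) / sqrt(reps))
})
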