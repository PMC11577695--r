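test_that("the threshold solve reproduces the worked design example", {
  s <- solve_threshold_and_info(-0.5, 0.6, 0.2)
  expect_equal(s$zeta, qnorm(0.75))
  expect_lt(abs(s$zeta - 0.674), 0.001)
  expect_lt(abs(s$info_interim - 9.19), 0.01)

  sn <- solve_threshold_and_info(-0.5, 0.6, 0.2, method = "numeric")
  expect_equal(sn$zeta, s$zeta, tolerance = 1e-6)
  expect_equal(sn$info_interim, s$info_interim, tolerance = 1e-6)

  expect_equal(solve_threshold_and_info(-0.5, 0.3, 0.3)$zeta, 0)
  expect_error(solve_threshold_and_info(-0.5, 0.7, 0.4), "sum < 1")
})

test_that("selection probabilities partition and hit the design targets", {
  zeta <- qnorm(0.75)
  pG <- selection_probabilities(0, 0, zeta, 9, 9)
  expect_equal(pG$prob[pG$w == "none"], 0.5625)
  expect_equal(pG$prob[pG$w == "F"], 0.0625)
  expect_equal(sum(pG$prob), 1)

  s <- solve_threshold_and_info(-0.5, 0.6, 0.2)
  pA <- selection_probabilities(-0.5, 0, s$zeta, s$info_interim, 5)
  expect_equal(pA$prob[pA$w == "1"], 0.6, tolerance = 1e-9)
  expect_equal(pA$prob[pA$w == "F"], 0.2, tolerance = 1e-9)

  # arbitrary configuration still partitions
  pX <- selection_probabilities(-0.4, 0.2, 0.3, 7, 3)
  expect_equal(sum(pX$prob), 1)
  pC <- selection_probabilities(-0.4, 0.2, 0.3, 7, 3, omega = "conventional")
  expect_equal(sum(pC$prob), 1)
  expect_setequal(pC$w, c("1", "F", "none"))
  expect_equal(pC$prob[pC$w == "1"], pX$prob[pX$w == "1"])
  expect_equal(pC$prob[pC$w == "F"], pX$prob[pX$w == "F"])
})

test_that("joint selection densities integrate to the selection probabilities", {
  zeta <- qnorm(0.75)
  for (th in list(c(0, 0), c(-0.5, 0), c(-0.3, 0.2))) {
    I1 <- 9.19; I2 <- 4.6; lam <- 2 / 3
    pr <- selection_probabilities(th[1], th[2], zeta, I1, I2)
    i1 <- integrate(function(z) joint_density_zw(z, "1", th[1], th[2], zeta,
                                                 I1, I2, lam),
                    zeta, Inf, rel.tol = 1e-10)$value
    expect_equal(i1, pr$prob[pr$w == "1"], tolerance = 1e-8)
    iF <- integrate(function(z) joint_density_zw(z, "F", th[1], th[2], zeta,
                                                 I1, I2, lam),
                    -Inf, Inf, rel.tol = 1e-8)$value
    expect_equal(iF, pr$prob[pr$w == "F"], tolerance = 1e-6)
    expect_equal(joint_density_zw(1.5, "none", th[1], th[2], zeta, I1, I2),
                 pr$prob[pr$w == "none"])
  }
  expect_equal(joint_density_zw(0.2, "1", 0, 0, 0.67, 9, 9, 2 / 3), 0)
})

test_that("the full-population selection density matches Monte Carlo draws", {
  set.seed(41)
  zeta <- qnorm(0.75); I1 <- 9.19; I2 <- 4.6; lam <- 2 / 3
  th <- c(-0.4, -0.1)
  n <- 1e5
  z1 <- rnorm(n, 0.4 * sqrt(I1))
  z2 <- rnorm(n, 0.1 * sqrt(I2))
  IF <- 1 / (lam^2 / I1 + (1 - lam)^2 / I2)
  zF <- lam * sqrt(IF / I1) * z1 + (1 - lam) * sqrt(IF / I2) * z2
  sel <- z1 > zeta & z2 > zeta
  pF <- integrate(function(z) joint_density_zw(z, "F", th[1], th[2], zeta,
                                               I1, I2, lam),
                  -Inf, Inf, rel.tol = 1e-8)$value
  grid <- seq(min(zF[sel]) - 0.5, max(zF[sel]) + 0.5, length.out = 600)
  dens <- joint_density_zw(grid, "F", th[1], th[2], zeta, I1, I2, lam) / pF
  cdf_grid <- cumsum(dens) * diff(grid)[1]
  cdf <- stats::approxfun(grid, pmin(cdf_grid / max(cdf_grid), 1),
                          yleft = 0, yright = 1)
  ks <- stats::ks.test(zF[sel], cdf)
  expect_gt(ks$p.value, 0.01)
})

test_that("the stage-2 conditional law is the group-sequential increment law", {
  d <- stage2_conditional_density(0.3, 0, 0, 5, 20)
  expect_equal(d, dnorm(0.3, 0, sqrt(1 - 5 / 20)))
  # information-ratio limit: independence
  d2 <- stage2_conditional_density(1.1, 3, 0.5, 1e-9, 25)
  expect_equal(d2, dnorm(1.1, 0.5 * 5, 1), tolerance = 1e-4)
  # conditional mean interpolates between drift and observed statistic
  r <- 9 / 36
  expect_equal(stage2_conditional_density(0.5 * 6 * (1 - r) + sqrt(r) * 1.2,
                                          1.2, 0.5, 9, 36),
               dnorm(0, 0, sqrt(1 - r)))
  expect_error(stage2_conditional_density(0, 0, 0, 10, 5), "info1 < info2")
})

test_that("quadratic spending allocates error by squared information fraction", {
  s <- spend(0.025, 0.1, 5, 10, 10)
  expect_equal(s$alpha1, 0.025 * 0.25)
  expect_equal(s$alpha1 + s$alpha2, 0.025)
  expect_equal(s$beta1 + s$beta2, 0.1)
  # cap at Imax
  s2 <- spend(0.025, 0.1, 8, 30, 10)
  expect_equal(s2$alpha1 + s2$alpha2, 0.025)
  # equal informations spend nothing extra
  s3 <- spend(0.025, 0.1, 7, 7, 10)
  expect_equal(s3$alpha2, 0)
  expect_equal(s3$beta2, 0)
})

test_that("stage-1 boundaries reproduce their spent error", {
  zeta <- qnorm(0.75)
  I1 <- 9.19; I2 <- 0.5 * 9.19; lam <- 2 / 3
  s <- solve_stage1_boundaries(0.004, 0.016, zeta, c(-0.5, 0), I1, I2, lam)
  tail_at <- function(b) {
    sum(vapply(c("1", "2", "F"), enrichjm:::.stage1_tail, numeric(1),
               b = b, theta1 = 0, theta2 = 0, zeta = zeta, I1 = I1, I2 = I2,
               lambda = lam))
  }
  expect_equal(tail_at(s$b1), 0.004, tolerance = 1e-8)

  # futility boundary: P(zeta < Z1 < a1, Z2 <= zeta; Theta_A) = beta1 * P(W=1)
  set.seed(42)
  n <- 2e5
  z1 <- rnorm(n, 0.5 * sqrt(I1)); z2 <- rnorm(n, 0)
  psel <- mean(z1 > zeta & z2 <= zeta)
  hit <- mean(z1 > zeta & z2 <= zeta & z1 < s$a1)
  se <- sqrt(hit * (1 - hit) / n)
  expect_lt(abs(hit - 0.016 * psel), 3 * se + 1e-5)

  # vanishing spend pushes the efficacy boundary to the cap
  expect_warning(
    s0 <- solve_stage1_boundaries(1e-20, 0.016, zeta, c(-0.5, 0), I1, I2, lam),
    "capped")
  expect_equal(s0$b1, 8)
  expect_error(
    solve_stage1_boundaries(0.9, 0.016, zeta, c(-0.5, 0), I1, I2, lam),
    "InfeasibleSpend")
})

test_that("two-stage rejection probability under the global null equals alpha", {
  # Gaussian-level Monte Carlo of the whole procedure at the planned path
  cfg <- design_config()
  m <- c(5, 2.5, 7.5)
  im <- solve_imax(cfg, m)
  expect_lt(abs(im$boundaries$a2 - im$boundaries$b2), 1e-4)

  set.seed(43)
  zeta <- im$zeta
  I1 <- im$infos_stage1[["1"]]; I2 <- im$infos_stage1[["2"]]
  IFc <- 1 / (cfg$lambda^2 / I1 + (1 - cfg$lambda)^2 / I2)
  n <- 1e5
  rej <- mc_two_stage(n, c(0, 0), zeta, im, cfg, I_F1 = IFc)
  p_rej <- mean(rej != "none")
  se <- sqrt(p_rej * (1 - p_rej) / n)
  expect_lt(abs(p_rej - cfg$alpha), 3 * se)
})

test_that("strong familywise control holds when the combined effect is null", {
  # theta_F = 0 with opposite subgroup effects: benefit drifts (+0.6, -1.2)
  cfg <- design_config()
  im <- solve_imax(cfg, c(5, 2.5, 7.5))
  set.seed(44)
  n <- 1e5
  I1 <- im$infos_stage1[["1"]]; I2 <- im$infos_stage1[["2"]]
  theta <- c(-0.6 / sqrt(I1), 1.2 / sqrt(I2))   # model scale
  IFc <- 1 / (cfg$lambda^2 / I1 + (1 - cfg$lambda)^2 / I2)
  rej <- mc_two_stage(n, theta, im$zeta, im, cfg, I_F1 = IFc)
  thF <- cfg$lambda * theta[1] + (1 - cfg$lambda) * theta[2]
  true_nulls <- c("2", "F")[c(theta[2] >= 0, thF >= -1e-9)]
  p_bad <- mean(rej %in% true_nulls)
  expect_lt(p_bad, cfg$alpha + 3 * sqrt(cfg$alpha * (1 - cfg$alpha) / n))
})

test_that("information prediction scales linearly in events", {
  expect_equal(predict_information(9, 45, 45), 9)
  expect_equal(predict_information(9, 45, 90), 18)
  expect_equal(predict_information(7.5, 50, 20), 3)
  expect_error(predict_information(9, 0, 10))
})

test_that("relaxing the power requirement lowers the event target monotonically", {
  m <- c(5, 2.5, 7.5)
  d <- vapply(c(0.05, 0.1, 0.2),
              function(b) solve_imax(design_config(beta = b), m)$d_total,
              numeric(1))
  expect_true(all(diff(d) < 0))
  # the planning information sequence reaches Imax in every population
  im <- solve_imax(design_config(), m)
  expect_equal(unname(im$infos_stage2[["F"]]), im$Imax)
  expect_equal(im$d_total, ceiling(m[1] * im$Imax))
})
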