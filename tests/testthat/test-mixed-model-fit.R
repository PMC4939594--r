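test_that("arm means are exact, including the counting identity for z", {
  d <- manual_design(2, 12, 5L)
  p <- crt_params(beta1 = 0.5, beta2 = 0.8, sigma_u2 = 0, sigma_e2 = 0)
  tr <- simulate_trial(d, p)
  am <- arm_means(tr)
  expect_equal(am$ybar_I, 0.5 + 0.8 * 5 / 6)
  expect_equal(am$ybar_C, 0.8 * 1 / 6)
  expect_equal(am$zbar_I - am$zbar_C, (2 * 5 - 6) / 6)
  bal <- arm_means(simulate_trial(manual_design(2, 12, 3L), p))
  expect_equal(bal$zbar_I, 0.5)
  expect_equal(bal$zbar_C, 0.5)
})

test_that("the toy trial reproduces every hand-computed quantity", {
  tr <- toy_trial()
  vc <- reml_components(tr, adjusted = TRUE)
  expect_equal(vc$sigma_e2, 2)
  expect_equal(vc$sigma_u2, 0, tolerance = 1e-10)
  vc_u <- reml_components(tr, adjusted = FALSE)
  expect_equal(vc_u$sigma_u2, 1.5)

  fa <- crt_lmm(tr)
  expect_equal(fa$beta1_hat, 3)
  expect_equal(fa$beta2_hat, 2)
  expect_equal(fa$se_beta1, 1, tolerance = 1e-10)
  expect_equal(fa$t_stat, 3, tolerance = 1e-10)
  expect_identical(fa$df, 1L)

  fu <- crt_lmm(tr, adjusted = FALSE)
  expect_equal(fu$beta1_hat, 3)
  expect_equal(fu$se_beta1, sqrt(2.5))
  expect_identical(fu$df, 2L)
  expect_equal(fu$sigma_u2_hat, 1.5)
})

test_that("noise-free fits interpolate the fixed effects exactly", {
  d <- manual_design(3, 12, 5L)
  p <- crt_params(beta1 = 0.5, beta2 = 0.8, sigma_u2 = 0, sigma_e2 = 0)
  tr <- simulate_trial(d, p)
  fa <- crt_lmm(tr)
  expect_equal(fa$beta1_hat, 0.5, tolerance = 1e-12)
  expect_equal(fa$beta2_hat, 0.8, tolerance = 1e-12)
  # ignoring the covariate shifts the estimate by beta2 (zbar_I - zbar_C)
  fu <- crt_lmm(tr, adjusted = FALSE)
  expect_equal(fu$beta1_hat, 0.5 + 0.8 * 2 / 3, tolerance = 1e-12)
})

test_that("estimator identities hold on random trials", {
  set.seed(101)
  for (rep in 1:20) {
    tr <- random_trial()
    d <- tr$design
    am <- arm_means(tr)
    fu <- crt_lmm(tr, adjusted = FALSE)
    expect_equal(fu$beta1_hat, am$ybar_I - am$ybar_C, tolerance = 1e-10)
    # GLS equals OLS on cluster means for both models
    ybar <- colMeans(tr$y)
    ols <- unname(coef(lm(ybar ~ d$x + d$z)))
    fa <- crt_lmm(tr)
    expect_equal(unname(coef(fa)), ols, tolerance = 1e-10)
    if (d$k == d$n2 / 4)   # balanced z: orthogonality
      expect_equal(fa$beta1_hat, am$ybar_I - am$ybar_C, tolerance = 1e-10)
  }
})

test_that("closed-form REML agrees with a numerically optimized REML oracle", {
  set.seed(202)
  checked <- 0L
  for (rep in 1:40) {
    tr <- random_trial()
    fa <- crt_lmm(tr)
    if (fa$sigma_u2_hat < 1e-3) next   # boundary fits have no interior REML
    orc <- oracle_reml(tr)
    expect_equal(fa$beta1_hat, orc$beta[2], tolerance = 1e-6)
    expect_equal(fa$beta2_hat, orc$beta[3], tolerance = 1e-6)
    expect_equal(fa$se_beta1, orc$se_beta1, tolerance = 1e-6)
    expect_equal(fa$sigma_u2_hat, orc$sigma_u2, tolerance = 1e-6)
    expect_equal(fa$sigma_e2_hat, orc$sigma_e2, tolerance = 1e-6)
    fu <- crt_lmm(tr, adjusted = FALSE)
    orc_u <- oracle_reml(tr, adjusted = FALSE)
    expect_equal(fu$beta1_hat, orc_u$beta[2], tolerance = 1e-6)
    expect_equal(fu$se_beta1, orc_u$se_beta1, tolerance = 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 15L)
})

test_that("closed-form REML matches nlme::lme to its optimizer precision", {
  set.seed(203)
  checked <- 0L
  for (rep in 1:15) {
    tr <- random_trial()
    fa <- crt_lmm(tr)
    if (fa$sigma_u2_hat < 1e-3) next
    lf <- nlme::lme(y ~ x + z, random = ~ 1 | cluster,
                    data = as.data.frame(tr), method = "REML")
    expect_equal(fa$beta1_hat, unname(nlme::fixef(lf)["x"]), tolerance = 1e-5)
    expect_equal(fa$se_beta1, sqrt(stats::vcov(lf)["x", "x"]),
                 tolerance = 1e-4)
    expect_equal(fa$sigma_u2_hat, unname(nlme::getVarCov(lf)[1, 1]),
                 tolerance = 1e-3)
    expect_equal(fa$sigma_e2_hat, lf$sigma^2, tolerance = 1e-4)
    checked <- checked + 1L
  }
  expect_gte(checked, 8L)
})

test_that("the unadjusted model absorbs the covariate into the cluster variance", {
  # sigma_u*2 >= sigma_u2 on average when beta2 != 0
  d <- manual_design(5, 12, 3L)
  p <- crt_params(beta1 = 0.5, beta2 = 0.8, rho = 0.1)
  fits <- crtimbalance:::sim_condition_fits(d, p, 5000, seed = 303)
  expect_gt(mean(fits$unadjusted$sigma_u2), mean(fits$adjusted$sigma_u2))
  d_mean <- mean(fits$unadjusted$sigma_u2 - fits$adjusted$sigma_u2)
  # analytic inflation of the between mean square: beta2^2 * RSS_z / (n2 - 2)
  expect_gt(d_mean, 0.5 * 0.8^2 * (12 / 4) * (1 - (0^2)) / 10)
})

test_that("degenerate and collinear fits raise informative errors", {
  d <- manual_design(4, 8, 4L)          # x == z
  tr <- simulate_trial(d, crt_params(beta2 = 0.5, rho = 0.1), seed = 1)
  expect_error(crt_lmm(tr), "collinear")
  expect_silent(crt_lmm(tr, adjusted = FALSE))
  d1 <- manual_design(1, 8, 2L)
  tr1 <- simulate_trial(d1, crt_params(beta2 = 0.5, rho = 0.1), seed = 1)
  expect_error(crt_lmm(tr1), "n1 = 1")
  expect_error(reml_components(tr1), "n1 = 1")
})

test_that("fit objects expose a coherent test decision", {
  tr <- simulate_trial(crt_design(30, 0.05, q = 0.5),
                       crt_params(beta2 = 0.5, rho = 0.05), seed = 5)
  f <- crt_lmm(tr, alpha = 0.05)
  expect_equal(f$t_stat, f$beta1_hat / f$se_beta1)
  expect_identical(f$df, f$n2 - 3L)
  expect_identical(f$reject, f$p_value < 0.05)
  expect_true(f$p_value >= 0 && f$p_value <= 1)
  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("treatment effect", out)))
})
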