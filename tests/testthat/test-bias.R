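test_that("BCP normalization divides by viewpoint and fragment length", {
  frags <- fragment_map("c", c(0, 2000, 7000), c(2000, 7000, 12000))
  vp <- viewpoint_set("v1", 0, 2000)
  pr <- bcp_profile(c(3, 10, 0), 1:3, frags, vp[1, ])
  expect_equal(pr$F[2], 10 / (2000 * 5000))   # 1.0e-6 count/bp^2
  expect_equal(pr$F[3], 0)
  expect_true(pr$self[1])                     # viewpoint's own fragment
  expect_false(any(pr$self[2:3]))

  # unit lengths: F equals the raw count
  frags1 <- fragment_map("c", 0:3, 1:4)
  vp1 <- viewpoint_set("v1", 0, 1)
  pr1 <- bcp_profile(c(0, 7, 2, 5), 1:4, frags1, vp1[1, ])
  expect_equal(pr1$F, c(0, 7, 2, 5))
})

test_that("deletion-condition separations use deleted coordinates", {
  # pair straddling a [100, 400) deletion is shortened by 300
  expect_equal(deletion_separation(50, 500, c(100, 400)), 150)
  # pair on one side is unchanged
  expect_equal(deletion_separation(500, 800, c(100, 400)), 300)
  expect_equal(deletion_separation(10, 90, c(100, 400)), 80)
})

test_that("log-log decay fit recovers noiseless and noisy power laws", {
  pr <- power_law_profile(nu = -1.5, n = 100)
  fit <- fit_loglog_decay(pr)
  s_eval <- exp(seq(log(2e4), log(5e6), length.out = 20))
  expect_lt(max(abs(log(predict_decay(fit, s_eval)) - (-1.5 * log(s_eval)))),
            1e-3)

  # lognormal noise, fixed seed: slope at 100 kb within 0.1 of the truth
  set.seed(42)
  prn <- power_law_profile(nu = -1.5, n = 300)
  prn$F <- prn$F * exp(rnorm(300, sd = 0.2))
  fitn <- fit_loglog_decay(prn)
  expect_lt(abs(decay_slope(fitn, 1e5) - (-1.5)), 0.1)

  # constant input: slope ~ 0 everywhere
  prc <- power_law_profile(nu = 0, n = 100)
  fitc <- fit_loglog_decay(prc)
  expect_lt(max(abs(decay_slope(fitc, s_eval))), 1e-6)

  # too few points names the viewpoint
  few <- power_law_profile(n = 10)
  attr(few, "viewpoint") <- "vpX"
  expect_error(fit_loglog_decay(few), "vpX")
})

test_that("inter-viewpoint BCP uses each viewpoint's smoothed decay", {
  vps <- viewpoint_set(c("a", "b", "c"), c(0, 1e6, 3e6) ,
                       c(1e4, 1.01e6, 3.01e6))
  fit1 <- fit_loglog_decay(power_law_profile(-1.5, amplitude = 1))
  fit2 <- fit_loglog_decay(power_law_profile(-1.5, amplitude = 2))
  pm_same <- interviewpoint_bcp(list(fit1, fit1, fit1), vps)
  expect_equal(pm_same$F, t(pm_same$F))            # identical fits: symmetric
  expect_equal(sum(!is.na(pm_same$F)), 3 * 2)      # n(n-1) defined entries

  # fits differing by factor 2 everywhere: F_IJ / F_JI = 2
  pm <- interviewpoint_bcp(list(fit2, fit1, fit1), vps)
  expect_equal(pm$F[1, 2] / pm$F[2, 1], 2, tolerance = 1e-9)
  expect_equal(pm$F[1, 3] / pm$F[3, 1], 2, tolerance = 1e-9)
})

test_that("bias solver has the no-bias fixed point and refuses n < 4", {
  pm <- make_pair_matrix(C = rep(1, 5), K = rep(1, 5))
  bf <- solve_bias_factors(pm)
  expect_equal(unname(bf$C), rep(1, 5), tolerance = 1e-10)
  expect_equal(unname(bf$K), rep(1, 5), tolerance = 1e-10)

  pm3 <- make_pair_matrix(C = rep(1, 3), K = rep(1, 3))
  expect_error(solve_bias_factors(pm3), "4 viewpoints")
  expect_no_error(solve_bias_factors(make_pair_matrix(rep(1, 4), rep(1, 4))))
})

test_that("bias solver recovers known factors exactly on noiseless input", {
  set.seed(7)
  C <- exp(runif(6, log(0.5), log(2)))
  K <- exp(runif(6, log(0.5), log(2)))
  pm <- make_pair_matrix(C, K, seed = 3)
  bf <- solve_bias_factors(pm)
  # reconstruction to numerical precision
  expect_lt(max(abs(log(bf$Fhat / pm$F)), na.rm = TRUE), 1e-10)
  # gauge-aligned recovery: correlation 1, slope 1
  expect_gt(cor(log(bf$C), log(C)), 0.9999)
  expect_gt(cor(log(bf$K), log(K)), 0.9999)
  expect_equal(unname(coef(lm(log(bf$C) ~ log(C)))[2]), 1, tolerance = 1e-8)
  # corrected matrix is symmetric
  expect_equal(bf$P, t(bf$P), tolerance = 1e-12)
})

test_that("solutions are gauge-invariant up to the declared normalization", {
  set.seed(11)
  C <- exp(runif(5, log(0.5), log(2)))
  K <- exp(runif(5, log(0.5), log(2)))
  pm1 <- make_pair_matrix(C, K, seed = 5)
  pm2 <- make_pair_matrix(C, K * 3.7, seed = 5)   # rescale all K
  bf1 <- solve_bias_factors(pm1)
  bf2 <- solve_bias_factors(pm2)
  expect_equal(bf1$K, bf2$K, tolerance = 1e-9)    # gauge absorbs the scale
  expect_equal(bf1$C, bf2$C, tolerance = 1e-9)
  pm3 <- make_pair_matrix(C * 1.9, K, seed = 5)   # rescale all C
  bf3 <- solve_bias_factors(pm3)
  expect_equal(bf1$C, bf3$C, tolerance = 1e-9)
  # P absorbs the compensating rescale
  expect_equal(bf3$P / bf1$P, matrix(1.9^2, 5, 5) + (bf1$P * 0),
               tolerance = 1e-9)
})

test_that("relative asymmetry is bounded, symmetric and NA-safe", {
  M <- matrix(c(NA, 2, 5, 8, NA, 1, 0, 3, NA), 3, 3, byrow = TRUE)
  A <- relative_asymmetry(M)
  expect_equal(A[1, 2], abs(2 - 8) / (2 + 8))   # 0.6
  expect_equal(A[1, 3], 1)                      # 5 vs 0: maximal
  expect_equal(A, t(A))
  S <- matrix(c(NA, 2, 2, NA), 2, 2)
  expect_equal(relative_asymmetry(S)[1, 2], 0)  # symmetric input: zero
  Z <- matrix(0, 2, 2)
  expect_true(is.na(relative_asymmetry(Z)[1, 2]))  # both zero: undefined
})
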