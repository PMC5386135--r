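test_that("ivw equals the hand-computed weighted through-origin slope", {
  s <- orient_summaries(data.frame(variant = 1:2, beta_x = c(0.1, 0.2),
                                   se_x = 0.01, beta_y = c(0.01, 0.02),
                                   se_y = 0.05))
  expect_equal(suppressWarnings(ivw(s))$beta, 0.1, tolerance = 1e-12)
  expect_error(ivw(s[1, ]), "at least 2")
})

test_that("estimators agree exactly on degenerate equal-ratio inputs", {
  k <- 6
  s <- orient_summaries(data.frame(variant = 1:k,
                                   beta_x = seq(0.05, 0.3, length.out = k),
                                   se_x = 0.01,
                                   beta_y = 0.25 * seq(0.05, 0.3,
                                                       length.out = k),
                                   se_y = 0.02))
  suppressWarnings({
    expect_equal(ivw(s)$beta, 0.25, tolerance = 1e-10)
    eg <- mr_egger(s)
    expect_equal(eg$slope$beta, 0.25, tolerance = 1e-10)
    expect_equal(eg$intercept$beta, 0, tolerance = 1e-10)
    expect_equal(weighted_median(s, n_boot = 10)$beta, 0.25,
                 tolerance = 1e-10)
  })
})

test_that("mr_egger recovers an injected constant pleiotropic offset", {
  s <- synthetic_summaries(k = 30, gamma = 0.25, alpha = 0.03, noise = FALSE)
  eg <- mr_egger(s)
  expect_equal(eg$intercept$beta, 0.03, tolerance = 1e-10)
  expect_equal(eg$slope$beta, 0.25, tolerance = 1e-10)
  expect_error(mr_egger(s[1:2, ]), "at least 3")
  flat <- s; flat$beta_x <- 0.1
  expect_error(mr_egger(flat), "no spread")
})

test_that("directional pleiotropy biases ivw but not the egger slope", {
  # averaged over independent draws so the test checks the property, not
  # one realization of a calibrated z-statistic
  res <- sapply(1:8, function(i) {
    s <- synthetic_summaries(k = 100, gamma = 0, alpha = 0.02, se_y = 0.005,
                             seed = 40 + i)
    eg <- mr_egger(s)
    c(ivw = suppressWarnings(ivw(s))$beta,
      slope_z = eg$slope$beta / eg$slope$se,
      intercept = eg$intercept$beta)
  })
  expect_gt(mean(res["ivw", ]), 0.05)            # drifted off the null
  expect_lt(abs(mean(res["slope_z", ])), 1.2)    # consistent with zero
  expect_gt(mean(res["intercept", ]), 0.015)     # pleiotropy detected
})

test_that("balanced InSIDE pleiotropy leaves the egger slope consistent", {
  set.seed(6)
  k <- 100
  bx <- runif(k, 0.05, 0.25)
  alpha <- rnorm(k, 0, 0.02)     # mean-zero, independent of bx
  s <- orient_summaries(data.frame(variant = 1:k, beta_x = bx, se_x = 1e-4,
                                   beta_y = 0.1 * bx + alpha, se_y = 0.02))
  eg <- mr_egger(s)
  expect_lt(abs(eg$slope$beta - 0.1), 3 * eg$slope$se)
})

test_that("weighted median interpolates the weighted ECDF", {
  s <- orient_summaries(data.frame(variant = 1:3, beta_x = 0.1, se_x = 0.01,
                                   beta_y = 0.1 * c(1, 2, 3), se_y = 0.1))
  expect_equal(suppressWarnings(weighted_median(s, n_boot = 10))$beta, 2,
               tolerance = 1e-10)
  # invariance: duplicating a variant while halving its weight leaves the
  # weighted ECDF, and hence the estimate, unchanged
  s2 <- orient_summaries(data.frame(
    variant = 1:4, beta_x = 0.1, se_x = 0.01,
    beta_y = 0.1 * c(1, 2, 2, 3),
    se_y = c(0.1, 0.1 * sqrt(2), 0.1 * sqrt(2), 0.1)))
  expect_equal(suppressWarnings(weighted_median(s2, n_boot = 10))$beta, 2,
               tolerance = 1e-10)
})

test_that("weighted median holds with up to half the weight invalid", {
  set.seed(8)
  k <- 50
  bx <- runif(k, 0.1, 0.3)
  by <- 0.1 * bx
  bad <- 1:20                       # ~40% of weight, strongly pleiotropic
  by[bad] <- by[bad] + 0.08
  s <- orient_summaries(data.frame(variant = 1:k, beta_x = bx, se_x = 1e-3,
                                   beta_y = by + rnorm(k, 0, 0.002),
                                   se_y = 0.01))
  wm <- weighted_median(s, n_boot = 200, seed = 9)
  expect_lt(abs(wm$beta - 0.1), 0.02)
})

test_that("orientation is a no-op for downstream estimators", {
  s <- synthetic_summaries(k = 20, gamma = 0.2, alpha = 0.01, seed = 10)
  flipped <- s
  flipped$beta_x[3] <- -flipped$beta_x[3]
  flipped$beta_y[3] <- -flipped$beta_y[3]
  flipped$oriented <- NULL
  suppressWarnings({
    expect_equal(ivw(flipped)$beta, ivw(s)$beta, tolerance = 1e-12)
    expect_equal(mr_egger(flipped)$slope$beta, mr_egger(s)$slope$beta,
                 tolerance = 1e-12)
    expect_equal(weighted_median(flipped, n_boot = 10, seed = 2)$beta,
                 weighted_median(s, n_boot = 10, seed = 2)$beta,
                 tolerance = 1e-12)
  })
})

test_that("zero-strength variants are dropped from the weighted median", {
  s <- synthetic_summaries(k = 10, gamma = 0.3, noise = FALSE)
  s$beta_x[1] <- 0; s$beta_y[1] <- 0
  expect_warning(wm <- weighted_median(s, n_boot = 10), "beta_x = 0")
  expect_equal(wm$beta, 0.3, tolerance = 1e-8)
})

test_that("per-variant summaries estimate gamma when instruments are valid", {
  cfg <- scenario_config(n_trios = 10000L, n_variants = 15L, q_x = 0.1,
                         gamma = 0.2, v_o = 0, v_p = 0, seed = 103L)
  co <- simulate_trio_cohort(cfg)
  s <- suppressMessages(per_variant_summaries(co, adjust_offspring = TRUE))
  expect_equal(nrow(s), 15L)
  expect_true(all(s$beta_x >= 0))
  i <- suppressWarnings(ivw(s))
  expect_lt(abs(i$beta - 0.2), 3 * i$se)
})

test_that("same-trait design: unadjusted summaries violate InSIDE", {
  # matched maternal/offspring panels with v_o = q_x: every variant picks up
  # the transmitted leak, the common ratio becomes gamma + 0.5, and the
  # egger slope tracks that ratio rather than gamma
  set.seed(11)
  cfg <- scenario_config(n_trios = 20000L, n_variants = 12L, q_x = 0.05,
                         gamma = 0, v_o = 0.05,
                         variant_weights = runif(12, 0.5, 2), seed = 107L)
  co <- simulate_trio_cohort(cfg)
  s_un <- suppressMessages(per_variant_summaries(co, adjust_offspring = FALSE))
  i_un <- suppressWarnings(ivw(s_un))
  expect_equal(i_un$beta, 0.5, tolerance = 0.12)
  eg <- mr_egger(s_un)
  expect_gt(eg$slope$beta - 3 * eg$slope$se, 0)   # does NOT recover gamma = 0
  # offspring adjustment restores validity
  s_ad <- suppressMessages(per_variant_summaries(co, adjust_offspring = TRUE))
  i_ad <- suppressWarnings(ivw(s_ad))
  expect_lt(abs(i_ad$beta), 3 * i_ad$se)
})

test_that("external exposure weights are accepted", {
  co <- simulate_trio_cohort(mid_config(q_x = 0.05, gamma = 0.1, seed = 109L))
  ext <- data.frame(beta_x = rep(0.05, 15), se_x = rep(0.01, 15))
  s <- per_variant_summaries(co, external_beta_x = ext)
  expect_equal(unique(s$beta_x), 0.05)
})

test_that("minus-0.5 correction is a pure shift with metadata", {
  est <- manual_estimate(0.60, 0.37, 0.82)
  corr <- minus_half_correction(est, applicability = "same trait, additive")
  expect_equal(corr$beta, 0.10)
  expect_equal(corr$ci_low, -0.13)
  expect_equal(corr$ci_high, 0.32)
  expect_equal(corr$se, est$se)
  expect_identical(attr(corr, "applicability"), "same trait, additive")
  expect_equal(minus_half_correction(manual_estimate(0.5, 0.3, 0.7))$beta, 0)
})

test_that("the corrected same-trait unadjusted estimate recovers gamma", {
  # closed form: unadjusted plim is gamma + 0.5 when v_o = q_x
  expect_equal(expected_unadjusted_estimate(0.1, 0.02, 0.02) - 0.5, 0.1)
  cfg <- scenario_config(n_trios = 10000L, n_variants = 15L, q_x = 0.02,
                         gamma = 0.1, v_o = 0.02, seed = 113L)
  betas <- vapply(1:40, function(i) {
    co <- simulate_trio_cohort(cfg, i - 1L)
    est <- estimate_all_strategies(co, strategies = "unadjusted")[[1]]
    minus_half_correction(est)$beta
  }, 0)
  expect_lt(abs(mean(betas) - 0.1), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("summary tables round-trip through delimited text", {
  s <- synthetic_summaries(k = 8, gamma = 0.15, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_summaries(s, path)
  back <- read_variant_summaries(path)
  expect_equal(back$beta_y, s$beta_y, tolerance = 1e-12)
  expect_error(read_variant_summaries(
    withr::local_tempfile(lines = "a\tb\t1\t2", fileext = ".tsv")),
    "columns")
})
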