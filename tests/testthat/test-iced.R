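test_that("covariance summary uses n-1 denominators and enforces contracts", {
  s <- summarize_two_timepoint(data.frame(value_t1 = c(0, 1, 2),
                                          value_t2 = c(0, 1, 2)))
  expect_equal(s$s11, 1); expect_equal(s$s22, 1); expect_equal(s$s12, 1)
  expect_equal(s$n, 3L)
  expect_error(summarize_two_timepoint(data.frame(value_t1 = c(0, 1),
                                                  value_t2 = c(1, 0))),
               "insufficient")
  expect_error(summarize_two_timepoint(data.frame(value_t1 = c(0, 1, NA),
                                                  value_t2 = c(1, 0, 1))),
               "missing")
  expect_error(cov_summary(1, 1, 2, 10), "positive semi-definite")
})

test_that("sample covariance of generated data matches the moment oracle", {
  d <- simulate_dataset(sim_config(1, 10000, "r1", sigma_b2 = 2,
                                   sigma_e2 = 1, seed = 31))
  s <- summarize_two_timepoint(d)
  expect_lt(abs(s$s12 - 2), 0.07)
})

test_that("constrained fit recovers the symmetric interior solution", {
  f <- fit_iced(cov_summary(2, 2, 1, 1000), ci_level = NA)
  expect_equal(f$components$sigma_b2, 1, tolerance = 1e-10)
  expect_equal(f$components$sigma_e2, 1, tolerance = 1e-10)
  expect_equal(f$icc, 0.5, tolerance = 1e-10)
  expect_equal(f$indices$chisq, 0)
  expect_equal(f$indices$df, 1L)
  # grid-search oracle agrees on an asymmetric matrix
  g <- grid_fit_oracle(2.3, 1.9, 0.8)
  f2 <- fit_iced(cov_summary(2.3, 1.9, 0.8, 500), ci_level = NA)
  expect_equal(f2$components$sigma_b2, g$sigma_b2, tolerance = 0.02)
  expect_equal(f2$components$sigma_e2, g$sigma_e2, tolerance = 0.02)
  # and the closed form matches to near machine precision
  expect_equal(f2$components$sigma_b2, 0.8, tolerance = 1e-9)
  expect_equal(f2$components$sigma_e2, (2.3 + 1.9) / 2 - 0.8, tolerance = 1e-9)
})

test_that("independent occasions give zero between-subjects variance", {
  f <- fit_iced(cov_summary(1, 1, 0, 100), ci_level = NA)
  expect_equal(f$components$sigma_b2, 0, tolerance = 1e-9)
  expect_equal(f$components$sigma_e2, 1, tolerance = 1e-9)
  expect_equal(f$icc, 0, tolerance = 1e-9)
})

test_that("the unconstrained model is saturated: exact fit, CFI 1, df 0", {
  set.seed(13)
  for (i in 1:10) {
    A <- matrix(rnorm(8), 4, 2); S <- crossprod(A) / 4
    f <- suppressWarnings(
      fit_iced(cov_summary(S[1, 1], S[2, 2], S[1, 2], 200),
               constrained = FALSE))
    expect_lt(f$indices$chisq, 1e-8)
    expect_identical(f$indices$df, 0L)
    expect_equal(f$indices$cfi, 1)
    # reproduces S exactly
    expect_equal(f$components$sigma_b2, S[1, 2], tolerance = 1e-12)
    expect_equal(f$components$sigma_e1_2, S[1, 1] - S[1, 2], tolerance = 1e-12)
  }
})

test_that("baseline model matches its closed form and limits", {
  expect_equal(fit_baseline(cov_summary(1, 1, 0, 100))$chisq, 0)
  b <- fit_baseline(cov_summary(2, 2, 1, 1000))
  expect_equal(b$chisq, 999 * (-log(1 - 0.25)), tolerance = 1e-10)
  expect_identical(b$df, 1L)
  # chisq grows without bound as the cross-occasion correlation approaches 1
  expect_gt(fit_baseline(cov_summary(2, 2, 1.99, 1000))$chisq, b$chisq * 10)
})

test_that("CFI follows the incremental-fit definition and conventions", {
  expect_equal(compute_cfi(list(chisq = 0, df = 0),
                           list(chisq = 100, df = 1)), 1)
  expect_equal(compute_cfi(list(chisq = 5, df = 5),
                           list(chisq = 100, df = 1)), 1)
  expect_equal(compute_cfi(list(chisq = 50, df = 1),
                           list(chisq = 500, df = 1)), 1 - 49 / 499)
  expect_equal(compute_cfi(list(chisq = 0, df = 0),
                           list(chisq = 0.5, df = 1)), 1)  # both excesses zero
})

test_that("ICC and ICC2 formulas cover the worked cases", {
  expect_equal(icc_from_components(list(sigma_b2 = 1, sigma_e2 = 1)), 0.5)
  expect_equal(icc_from_components(list(sigma_b2 = 1, sigma_e2 = 0)), 1)
  expect_equal(icc_from_components(list(sigma_b2 = 9, sigma_e2 = 1)), 0.9)
  expect_warning(out <- icc_from_components(list(sigma_b2 = 0, sigma_e2 = 0)),
                 "undefined")
  expect_true(is.na(out))
  vc <- list(sigma_b2 = 1, sigma_e2 = 1)
  expect_equal(icc2_from_components(vc, 2), 2 / 3)
  expect_equal(icc2_from_components(vc, 3), 0.75)
  expect_equal(icc2_from_components(vc, 1), 0.5)
  expect_error(icc2_from_components(vc, 0), "n_measures")
  # ICC2 >= ICC for N >= 2, increasing in N, -> 1
  iccs <- vapply(c(1, 2, 3, 10, 1e6), function(n) icc2_from_components(vc, n),
                 numeric(1))
  expect_true(all(diff(iccs) > 0))
  expect_equal(iccs[5], 1, tolerance = 1e-5)
})

test_that("estimates are scale equivariant; stability indices are invariant", {
  d <- simulate_dataset(sim_config(1, 400, "r1", sigma_b2 = 1,
                                   sigma_e2 = 0.5, seed = 17))
  f1 <- fit_iced(summarize_two_timepoint(d), ci_level = NA)
  for (c_ in c(0.001, 1000)) {
    d2 <- d; d2$value_t1 <- d2$value_t1 * c_; d2$value_t2 <- d2$value_t2 * c_
    f2 <- fit_iced(summarize_two_timepoint(d2), ci_level = NA)
    expect_equal(f2$components$sigma_b2, f1$components$sigma_b2 * c_^2,
                 tolerance = 1e-6)
    expect_equal(f2$icc, f1$icc, tolerance = 1e-8)
    expect_equal(f2$indices$chisq, f1$indices$chisq, tolerance = 1e-6)
    expect_equal(f2$indices$cfi, f1$indices$cfi, tolerance = 1e-8)
  }
})

test_that("profile-likelihood interval behaves at boundaries and with n", {
  # error-free data: degenerate flagged interval
  d0 <- simulate_dataset(sim_config(1, 100, "r1", sigma_b2 = 1, sigma_e2 = 0,
                                    seed = 3))
  f0 <- fit_iced(summarize_two_timepoint(d0))
  expect_equal(as.numeric(f0$icc_ci), c(1, 1))
  # wider interval at smaller n, both containing the point estimate
  dbig <- simulate_dataset(sim_config(1, 7000, "r1", sigma_b2 = 1,
                                      sigma_e2 = 1, seed = 4))
  dsmall <- simulate_dataset(sim_config(1, 700, "r1", sigma_b2 = 1,
                                        sigma_e2 = 1, seed = 4))
  fb <- fit_iced(summarize_two_timepoint(dbig))
  fs <- fit_iced(summarize_two_timepoint(dsmall))
  expect_gt(diff(fs$icc_ci), diff(fb$icc_ci))
  expect_true(fb$icc_ci[1] < fb$icc && fb$icc < fb$icc_ci[2])
  expect_true(fs$icc_ci[1] < fs$icc && fs$icc < fs$icc_ci[2])
})

test_that("negative variance estimates warn and clip the ICC", {
  expect_warning(f <- fit_iced(cov_summary(1, 1, -0.3, 200), ci_level = NA),
                 "negative variance")
  expect_equal(f$icc, 0)
  expect_lt(f$components$sigma_b2, 0)
  # strict non-negative mode stays in the parameter space
  f2 <- fit_iced(cov_summary(1, 1, -0.3, 200), allow_negative = FALSE,
                 ci_level = NA)
  expect_gte(f2$components$sigma_b2, 0)
})

test_that("equal-error comparison is null on symmetric input and detects
           occasion-dependent error", {
  sym <- compare_error_constraints(cov_summary(2, 2, 1, 2000))
  expect_equal(sym$delta_cfi, 0)
  expect_false(sym$flag)
  # occasion-2 error four times occasion-1: flag should fire essentially always
  hits <- 0; null_hits <- 0
  for (s in 1:20) {
    d <- simulate_dataset(sim_config(1, 2000, "r1", sigma_b2 = 1,
                                     sigma_e2 = 1, error_timepoint_ratio = 4,
                                     seed = 300 + s))
    hits <- hits + compare_error_constraints(d)$flag
    d0 <- simulate_dataset(sim_config(1, 2000, "r1", sigma_b2 = 1,
                                      sigma_e2 = 1, seed = 400 + s))
    null_hits <- null_hits + compare_error_constraints(d0)$flag
  }
  expect_gte(hits, 19)
  expect_lte(null_hits, 3)
})
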