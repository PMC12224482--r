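test_that("degrees of freedom follow the 3G - p identity for all four models", {
  d <- sim_groups(rep(1, 3), rep(1, 3), 30, 1)
  expect_identical(fit_multigroup(d, "site", "constrained")$df, 7L)
  expect_identical(fit_multigroup(d, "site", "b_varying")$df, 5L)
  expect_identical(fit_multigroup(d, "site", "e_varying")$df, 5L)
  expect_identical(fit_multigroup(d, "site", "unconstrained")$df, 3L)
  d21 <- sim_groups(rep(1, 21), rep(1, 21), 10, 2)
  expect_identical(fit_multigroup(d21, "site", "unconstrained")$df, 21L)
  expect_identical(fit_multigroup(d21, "site", "constrained")$df, 61L)
})

test_that("the unconstrained multigroup model separates into per-group fits", {
  d <- sim_groups(c(1, 2), c(0.5, 1), 80, 3)
  mg <- fit_multigroup(d, "site", "unconstrained")
  chisq_sep <- 0
  for (g in unique(d$site)) {
    f <- fit_iced(summarize_two_timepoint(d[d$site == g, ]), ci_level = NA)
    row <- mg$per_group[mg$per_group$group == g, ]
    expect_equal(row$sigma_b2, f$components$sigma_b2, tolerance = 1e-6)
    expect_equal(row$sigma_e2, f$components$sigma_e2, tolerance = 1e-6)
    chisq_sep <- chisq_sep + f$indices$chisq
  }
  expect_equal(mg$chisq, chisq_sep, tolerance = 1e-6)
})

test_that("constrained multigroup chi-square is calibrated under the null", {
  set.seed(55)
  chisqs <- replicate(150, {
    d <- sim_groups(rep(1, 3), rep(1, 3), 200, sample.int(10000, 1))
    fit_multigroup(d, "site", "constrained")$chisq
  })
  # mean of a chi-squared(7) is 7; SE of the mean over 150 draws ~ 0.31
  expect_lt(abs(mean(chisqs) - 7), 1)
})

test_that("nested models never fit better than their relaxations", {
  for (s in 1:4) {
    d <- sim_groups(geom_ladder(0.5, 3, 4), geom_ladder(0.5, 2, 4), 150, s)
    ch <- vapply(c("constrained", "b_varying", "e_varying", "unconstrained"),
                 function(m) fit_multigroup(d, "site", m)$chisq, numeric(1))
    expect_gte(ch["constrained"], ch["b_varying"] - 1e-7)
    expect_gte(ch["constrained"], ch["e_varying"] - 1e-7)
    expect_gte(ch["b_varying"], ch["unconstrained"] - 1e-7)
    expect_gte(ch["e_varying"], ch["unconstrained"] - 1e-7)
  }
})

test_that("group relabelling leaves fit statistics unchanged", {
  d <- sim_groups(c(1, 1, 1), geom_ladder(0.5, 4, 3), 200, 9)
  res1 <- model_comparison_series(d, "site")
  relabel <- c(site01 = "Z", site02 = "A", site03 = "M")
  d2 <- d; d2$site <- unname(relabel[d$site])
  res2 <- model_comparison_series(d2, "site")
  expect_equal(res1$delta_cfi, res2$delta_cfi, tolerance = 1e-9)
  expect_equal(res1$cfi, res2$cfi, tolerance = 1e-9)
})

test_that("undersized groups are excluded with a warning and recorded", {
  d <- sim_groups(c(1, 1), c(1, 1), 50, 4)
  d <- rbind(d, within(d[1:2, ], {
    site <- "site99"; participant_id <- paste0("x", 1:2)
  }))
  expect_warning(mg <- fit_multigroup(d, "site", "constrained"), "site99")
  expect_identical(mg$excluded_groups, "site99")
  expect_identical(mg$n_groups, 2L)
})

test_that("error-variance heterogeneity is attributed to the error component", {
  # sigma_e2 spread 4-fold across 5 groups, sigma_b2 equal: C and E flag, A not
  flags <- sapply(1:20, function(s) {
    d <- sim_groups(rep(1, 5), geom_ladder(0.5, 4, 5), 500, s)
    model_comparison_series(d, "site")$flags
  })
  expect_gte(mean(flags["C", ]), 0.9)
  expect_gte(mean(flags["E", ]), 0.9)
  expect_lte(mean(flags["A", ]), 0.1)
})

test_that("between-subjects heterogeneity is attributed to that component", {
  flags <- sapply(1:8, function(s) {
    d <- sim_groups(geom_ladder(0.5, 4, 5), rep(0.25, 5), 500, 100 + s)
    model_comparison_series(d, "site")$flags
  })
  expect_gte(mean(flags["A", ]), 0.9)
  expect_gte(mean(flags["E", ]), 0.9)
  expect_lte(mean(flags["C", ]), 0.1)
})

test_that("homogeneous groups rarely raise any flag", {
  flags <- sapply(1:10, function(s) {
    d <- sim_groups(rep(1, 5), rep(0.5, 5), 500, 200 + s)
    model_comparison_series(d, "site")$flags
  })
  expect_lte(max(rowMeans(flags)), 0.1)
})

test_that("comparison grid completes, summarises flags, and tolerates
           an empty region list", {
  cfg <- small_config(n_sites = 4, n_per_site = 150, n_regions = 3,
                      site_error_spread = 6, seed = 61)
  d <- simulate_dataset(cfg)
  g <- comparison_grid(d, "site")
  expect_equal(nrow(g$grid), 3 * 5)  # regions x comparisons
  expect_true(all(g$grid$available))
  cfrac <- g$summary$fraction_flagged[g$summary$comparison == "C"]
  expect_gte(cfrac, 2 / 3)
  empty <- comparison_grid(d[0, ], "site")
  expect_identical(nrow(empty$grid), 0L)
})

test_that("scanner manufacturer works as the grouping variable unchanged", {
  cfg <- small_config(n_sites = 6, n_per_site = 100, n_regions = 1,
                      site_error_spread = 3, seed = 77)
  d <- simulate_dataset(cfg)
  res <- model_comparison_series(d, "scanner")
  expect_identical(res$fits$constrained$n_groups,
                   length(unique(d$scanner)))
  expect_true(all(res$available))
})
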