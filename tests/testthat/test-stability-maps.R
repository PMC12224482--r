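test_that("region map covers every measure x region x group cell", {
  cfg <- small_config(n_sites = 5, n_per_site = 30, n_regions = 8, seed = 41)
  d <- simulate_dataset(cfg)
  tab <- fit_region_map(d, grouping = "site", ci_level = NA)
  expect_s3_class(tab, "stability_table")
  expect_equal(nrow(tab), 40L)
  expect_equal(anyDuplicated(tab[c("measure", "region", "group")]), 0L)
  pooled <- fit_region_map(d, grouping = "pooled", ci_level = NA)
  expect_equal(nrow(pooled), 8L)
})

test_that("a high-stability region is recovered from pooled data", {
  d <- simulate_dataset(sim_config(1, 7000, "r1", sigma_b2 = 0.9,
                                   sigma_e2 = 0.1, seed = 43))
  tab <- fit_region_map(d, grouping = "pooled", ci_level = NA)
  expect_lt(abs(tab$icc - 0.9), 0.03)
})

test_that("constant-valued regions come back as degenerate, not as errors", {
  d <- simulate_dataset(sim_config(1, 20, c("flat", "ok"), sigma_b2 = 1,
                                   sigma_e2 = 1, seed = 44))
  d$value_t1[d$region == "flat"] <- 3
  d$value_t2[d$region == "flat"] <- 3
  tab <- fit_region_map(d, grouping = "pooled", ci_level = NA)
  expect_identical(tab$status[tab$region == "flat"], "degenerate")
  expect_identical(tab$status[tab$region == "ok"], "ok")
})

test_that("region order does not change the (sorted) map", {
  cfg <- small_config(n_sites = 2, n_per_site = 40, n_regions = 4, seed = 45)
  d <- simulate_dataset(cfg)
  shuffled <- d[rev(seq_len(nrow(d))), ]
  t1 <- fit_region_map(d, grouping = "site", ci_level = NA)
  t2 <- fit_region_map(shuffled, grouping = "site", ci_level = NA)
  expect_equal(as.data.frame(t1), as.data.frame(t2), tolerance = 1e-10)
})

test_that("map summaries report mean and range over usable rows", {
  tab <- data.frame(measure = "thickness", region = c("a", "b", "c"),
                    group = "pooled", icc = c(0.5, 0.7, 0.9),
                    icc2 = c(0.6, 0.8, 0.95),
                    status = c("ok", "ok", "ok"))
  s <- summarize_map(tab)
  expect_equal(s$mean_icc, 0.7)
  expect_equal(c(s$min_icc, s$max_icc), c(0.5, 0.9))
  one <- summarize_map(tab[1, ])
  expect_equal(one$mean_icc, one$min_icc)
  tab$status <- c("non_converged", "degenerate", "insufficient_data")
  expect_warning(empty <- summarize_map(tab), "no usable fits")
  expect_identical(nrow(empty), 0L)
})

test_that("map summary tracks the generator's per-region ICC ladder", {
  cfg <- small_config(n_sites = 2, n_per_site = 2000, n_regions = 6, seed = 47)
  d <- simulate_dataset(cfg)
  s <- summarize_map(fit_region_map(d, grouping = "pooled", ci_level = NA))
  expect_lt(abs(s$mean_icc - mean(seq(0.55, 0.90, length.out = 6))), 0.02)
  expect_lt(abs(s$min_icc - 0.55), 0.05)
  expect_lt(abs(s$max_icc - 0.90), 0.03)
})

test_that("dispersion decomposition attributes heterogeneity to the right
           axis", {
  # between-subjects variance varies 4-fold over regions; error flat
  regions <- sprintf("r%02d", 1:6)
  b2 <- stats::setNames(geom_ladder(0.5, 4, 6), regions)
  cfg <- sim_config(4, 800, regions, sigma_b2 = b2, sigma_e2 = 0.3, seed = 51)
  tab <- fit_region_map(simulate_dataset(cfg), grouping = "site",
                        ci_level = NA)
  disp <- dispersion_decomposition(tab)
  region_row <- disp[disp$axis == "region", ]
  expect_gt(region_row$ratio_b_over_e, 5)
  # homogeneous generator: neither axis shows structured dispersion
  cfg0 <- sim_config(4, 800, regions, sigma_b2 = 0.5, sigma_e2 = 0.3,
                     seed = 52)
  tab0 <- fit_region_map(simulate_dataset(cfg0), grouping = "site",
                         ci_level = NA)
  disp0 <- dispersion_decomposition(tab0)
  expect_lt(disp0$ratio_b_over_e[disp0$axis == "region"],
            region_row$ratio_b_over_e / 10)
  # degenerate: identical medians on both axes -> undefined ratios
  flat <- data.frame(measure = "m", region = rep(c("a", "b"), 2),
                     group = rep(c("s1", "s2"), each = 2),
                     sigma_b2 = 1, sigma_e2 = 1, status = "ok")
  dflat <- dispersion_decomposition(flat)
  expect_true(all(is.na(dflat$ratio_b_over_e)))
  expect_error(dispersion_decomposition(flat[1:2, ]), ">= 2")
})

test_that("rank-order stability matches the ANOVA mean-squares oracle", {
  set.seed(71)
  for (i in 1:5) {
    m <- matrix(rnorm(24), 6, 4)
    got <- rank_order_stability(m)
    want <- icc_anova_oracle(m)
    expect_equal(got$icc_2_1, want$icc_2_1, tolerance = 1e-10)
    expect_equal(got$icc_3_1, want$icc_3_1, tolerance = 1e-10)
  }
})

test_that("a constant rater shift preserves consistency but not absolute
           agreement", {
  m <- cbind(1:6, 1:6 + 2)
  ro <- rank_order_stability(m)
  expect_equal(ro$icc_3_1, 1)
  expect_lt(ro$icc_2_1, 1)
  ident <- rank_order_stability(cbind(1:6, 1:6, 1:6))
  expect_equal(ident$icc_2_1, 1)
  expect_equal(ident$icc_3_1, 1)
  expect_true(is.na(rank_order_stability(matrix(2, 3, 3))$icc_2_1))
})

test_that("transposing targets and raters changes ICC(3,1) in general", {
  set.seed(72)
  m <- matrix(rnorm(12), 4, 3) + outer(rep(1, 4), c(0, 2, 5))
  a <- rank_order_stability(m)$icc_3_1
  b <- rank_order_stability(t(m))$icc_3_1
  expect_gt(abs(a - b), 1e-6)
})

test_that("estimate matrix pivots a site map and drops incomplete targets", {
  cfg <- small_config(n_sites = 3, n_per_site = 30, n_regions = 4, seed = 73)
  tab <- fit_region_map(simulate_dataset(cfg), grouping = "site",
                        ci_level = NA)
  m <- estimate_matrix(tab, "icc", targets = "region")
  expect_equal(dim(m), c(4L, 3L))
  m2 <- estimate_matrix(tab, "sigma_b2", targets = "site")
  expect_equal(dim(m2), c(3L, 4L))
  tab2 <- tab[-1, ]  # knock out one cell -> its target row is dropped
  expect_message(m3 <- estimate_matrix(tab2, "icc", targets = "region"),
                 "dropping 1")
  expect_equal(nrow(m3), 3L)
})

test_that("lobe aggregation means thickness, sums volume, conserves totals", {
  mapping <- c(lh_a = "lh_front", lh_b = "lh_front")
  d <- data.frame(participant_id = rep(c("p1", "p2"), each = 4),
                  site = "site01", scanner = "Siemens",
                  measure = rep(rep(c("thickness", "volume"), each = 2), 2),
                  region = rep(c("lh_a", "lh_b"), 4),
                  value_t1 = c(2, 3, 10, 20, 2.4, 3.6, 12, 24),
                  value_t2 = c(2, 3, 10, 20, 2.4, 3.6, 12, 24))
  agg <- aggregate_lobes(d, mapping)
  th <- agg[agg$measure == "thickness", ]
  expect_equal(th$value_t1[th$participant_id == "p1"], 2.5)
  expect_equal(th$value_t1[th$participant_id == "p2"], 3.0)
  vol <- agg[agg$measure == "volume", ]
  expect_equal(sort(vol$value_t1), c(30, 36))
  expect_equal(sum(vol$value_t1), sum(d$value_t1[d$measure == "volume"]))
  expect_error(aggregate_lobes(d, mapping[1]), "lh_b")
})

test_that("the shipped lobe mapping covers all 68 regions with 5 lobes per
           hemisphere", {
  mapping <- read_lobe_mapping()
  expect_setequal(names(mapping), dk_regions())
  expect_equal(length(unique(mapping[startsWith(names(mapping), "lh_")])), 5L)
  expect_equal(length(unique(mapping[startsWith(names(mapping), "rh_")])), 5L)
})

test_that("lobe-level stability is at least that of the worst member region", {
  regions <- c("lh_a", "lh_b", "lh_c")
  mapping <- stats::setNames(rep("lh_front", 3), regions)
  b2 <- stats::setNames(c(0.3, 0.5, 0.8), regions)
  hits <- 0
  for (s in 1:20) {
    cfg <- sim_config(1, 1000, regions, sigma_b2 = b2, sigma_e2 = 0.4,
                      seed = 500 + s)
    d <- simulate_dataset(cfg)
    member <- fit_region_map(d, grouping = "pooled", ci_level = NA)
    lobe <- fit_region_map(aggregate_lobes(d, mapping), grouping = "pooled",
                           ci_level = NA)
    hits <- hits + (lobe$icc >= min(member$icc))
  }
  expect_gte(hits, 18)
})
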