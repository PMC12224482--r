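# Multigroup fixture: one single-site generator per group so that both
# variance components can differ across groups (the package config keys
# sigma_b2 by region, matching the single-population generative model).
sim_groups <- function(b_levels, e_levels, n, seed) {
  out <- lapply(seq_along(b_levels), function(g) {
    d <- simulate_dataset(sim_config(
      n_sites = 1, n_per_site = n, regions = "r1",
      sigma_b2 = b_levels[g], sigma_e2 = e_levels[g],
      seed = seed * 1000L + g))
    d$site <- sprintf("site%02d", g)
    d$participant_id <- paste0(d$site, "_", d$participant_id)
    d
  })
  do.call(rbind, out)
}

# Geometric ladder spanning `spread`-fold around a centre.
geom_ladder <- function(centre, spread, k) {
  centre * exp(seq(-log(spread) / 2, log(spread) / 2, length.out = k))
}

# Two-way ANOVA mean-squares oracle for the single-rater intraclass
# correlations, via stats::aov on the long form of the matrix.
icc_anova_oracle <- function(m) {
  long <- data.frame(y = as.vector(m),
                     target = factor(rep(seq_len(nrow(m)), ncol(m))),
                     rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- summary(stats::aov(y ~ target + rater, data = long))[[1]][, "Mean Sq"]
  bms <- ms[1]; jms <- ms[2]; ems <- ms[3]
  n <- nrow(m); k <- ncol(m)
  list(icc_2_1 = (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n),
       icc_3_1 = (bms - ems) / (bms + (k - 1) * ems))
}

# Brute-force grid oracle for the constrained single-group ML fit.
grid_fit_oracle <- function(s11, s22, s12, span = 3, steps = 400) {
  total <- (s11 + s22) / 2
  bs <- seq(-total, span * total, length.out = steps)
  es <- seq(1e-6, span * total, length.out = steps)
  best <- c(NA, NA); best_f <- Inf
  for (b in bs) for (e in es) {
    f <- icedstab:::fml_discrepancy(s11, s22, s12, b + e, b + e, b)
    if (is.finite(f) && f < best_f) { best_f <- f; best <- c(b, e) }
  }
  list(sigma_b2 = best[1], sigma_e2 = best[2], fml = best_f)
}
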