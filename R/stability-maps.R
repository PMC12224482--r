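#' Batch stability map across measures, regions, and groups
#'
#' Fits the constrained two-timepoint model to every measure x region x group
#' slice of a dataset and collects components, ICC/ICC2, profile-likelihood CI
#' bounds, and fit indices into a long table. Per-slice failures never abort
#' the batch; they are downgraded to a `status` code (`ok`, `non_converged`,
#' `insufficient_data`, `degenerate`).
#'
#' @param dataset A dataset data frame (columns `participant_id`, `site`,
#'   `scanner`, `measure`, `region`, `value_t1`, `value_t2`).
#' @param measures Measures to fit (default: all present).
#' @param grouping `"pooled"` (one fit per measure x region), `"site"`, or
#'   `"scanner"`.
#' @param ci_level Level for the ICC profile-likelihood interval (`NA` skips;
#'   markedly faster for large grids).
#' @param n_measures N used for the construct-level ICC2 (default 2).
#' @return A data frame of class `stability_table`: one row per measure x
#'   region x group with `sigma_b2`, `sigma_e2`, `icc`, `icc2`, `ci_low`,
#'   `ci_high`, `chisq`, `df`, `cfi`, `n`, `status`.
#' @seealso [summarize_map()], [dispersion_decomposition()],
#'   [estimate_matrix()]
#' @export
fit_region_map <- function(dataset, measures = NULL,
                           grouping = c("pooled", "site", "scanner"),
                           ci_level = 0.95, n_measures = 2) {
  grouping <- match.arg(grouping)
  if (is.null(measures)) measures <- unique(dataset$measure)
  stopifnot(all(measures %in% dataset$measure))
  dataset <- dataset[dataset$measure %in% measures, , drop = FALSE]

  group_col <- if (grouping == "pooled") NULL else grouping
  keys <- unique(dataset[c("measure", "region",
                           if (!is.null(group_col)) group_col)])
  if (is.null(group_col)) keys$group <- "pooled" else {
    names(keys)[names(keys) == group_col] <- "group"
  }
  keys <- keys[order(keys$measure, keys$region, keys$group), , drop = FALSE]

  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- dataset$measure == keys$measure[i] & dataset$region == keys$region[i]
    if (!is.null(group_col)) {
      sel <- sel & dataset[[group_col]] == keys$group[i]
    }
    slice <- dataset[sel, , drop = FALSE]
    rows[[i]] <- fit_map_row(slice, keys$measure[i], keys$region[i],
                             keys$group[i], ci_level, n_measures)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  attr(out, "grouping") <- grouping
  out
}

fit_map_row <- function(slice, measure, region, group, ci_level, n_measures) {
  row <- data.frame(measure = measure, region = region, group = group,
                    sigma_b2 = NA_real_, sigma_e2 = NA_real_,
                    icc = NA_real_, icc2 = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    chisq = NA_real_, df = NA_integer_, cfi = NA_real_,
                    n = nrow(slice), status = "insufficient_data",
                    stringsAsFactors = FALSE)
  fit <- tryCatch(
    suppressWarnings(fit_iced(summarize_two_timepoint(slice),
                              ci_level = ci_level, n_measures = n_measures)),
    error = function(e) NULL)
  if (is.null(fit)) return(row)
  row$status <- fit$status
  row$sigma_b2 <- fit$components$sigma_b2
  row$sigma_e2 <- fit$components$sigma_e2
  row$icc <- fit$icc
  row$icc2 <- fit$icc2
  row$ci_low <- fit$icc_ci[1]
  row$ci_high <- fit$icc_ci[2]
  row$chisq <- fit$indices$chisq
  row$df <- fit$indices$df
  row$cfi <- fit$indices$cfi
  if (fit$status == "degenerate" || (is.na(fit$icc) && fit$status == "ok")) {
    row$status <- "degenerate"
  }
  row
}

#' Summarise a stability map per measure
#'
#' Mean and range (min, max) of ICC and ICC2 over the successfully fitted rows
#' of a [fit_region_map()] table, the form in which stability maps are usually
#' reported.
#'
#' @param table A `stability_table`.
#' @return A data frame with one row per measure: `n_ok`, `mean_icc`,
#'   `min_icc`, `max_icc`, `mean_icc2`, `min_icc2`, `max_icc2`. Measures with
#'   no usable rows are dropped with a warning.
#' @export
summarize_map <- function(table) {
  stopifnot(is.data.frame(table), all(c("measure", "icc", "status") %in%
                                        names(table)))
  ok <- table[table$status == "ok" & !is.na(table$icc), , drop = FALSE]
  missing <- setdiff(unique(table$measure), unique(ok$measure))
  if (length(missing)) {
    warning("no usable fits for measure(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(ok)) {
    return(data.frame(measure = character(), n_ok = integer(),
                      mean_icc = numeric(), min_icc = numeric(),
                      max_icc = numeric(), mean_icc2 = numeric(),
                      min_icc2 = numeric(), max_icc2 = numeric()))
  }
  out <- do.call(rbind, lapply(split(ok, ok$measure), function(d) {
    data.frame(measure = d$measure[1], n_ok = nrow(d),
               mean_icc = mean(d$icc), min_icc = min(d$icc),
               max_icc = max(d$icc),
               mean_icc2 = mean(d$icc2), min_icc2 = min(d$icc2),
               max_icc2 = max(d$icc2), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Dispersion of variance-component estimates across regions vs across sites
#'
#' Quantifies which axis drives heterogeneity in a site-grouped stability map.
#' For the region axis, the per-region median (over sites) of each variance
#' component is taken and the variance of those medians across regions is
#' computed; the site axis swaps the roles. The ratio of the two component
#' variances on each axis says whether between-subjects or error variance
#' estimates disperse more along that axis.
#'
#' @param table A site-grouped `stability_table` covering at least 2 regions
#'   and 2 sites.
#' @return A data frame with one row per axis (`region`, `site`):
#'   `var_median_sigma_b2`, `var_median_sigma_e2`, `ratio_b_over_e`,
#'   `ratio_e_over_b`. Zero component variances yield `NA` ratios.
#' @export
dispersion_decomposition <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("region", "group", "sigma_b2", "sigma_e2", "status") %in%
                  names(table)))
  ok <- table[table$status == "ok", , drop = FALSE]
  if (length(unique(ok$region)) < 2 || length(unique(ok$group)) < 2) {
    stop("dispersion decomposition needs >= 2 regions and >= 2 groups",
         call. = FALSE)
  }
  med_by <- function(axis) {
    sp <- split(ok, ok[[axis]])
    data.frame(b = vapply(sp, function(d) stats::median(d$sigma_b2), numeric(1)),
               e = vapply(sp, function(d) stats::median(d$sigma_e2), numeric(1)))
  }
  one_axis <- function(axis) {
    m <- med_by(axis)
    vb <- stats::var(m$b); ve <- stats::var(m$e)
    data.frame(axis = if (axis == "region") "region" else "site",
               var_median_sigma_b2 = vb, var_median_sigma_e2 = ve,
               ratio_b_over_e = if (isTRUE(ve > 0)) vb / ve else NA_real_,
               ratio_e_over_b = if (isTRUE(vb > 0)) ve / vb else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_axis("region"), one_axis("group"))
  rownames(out) <- NULL
  out
}

#' Estimate matrix for rank-order stability
#'
#' Pivots a site-grouped stability table into a complete targets x raters
#' matrix of one estimate, for [rank_order_stability()]. The "by region" view
#' asks how stable regional estimates are across sites (targets = regions,
#' raters = sites); "by site" swaps the axes. Rows with any missing cell are
#' deleted with a message.
#'
#' @param table A site- (or scanner-) grouped `stability_table`.
#' @param estimate One of `"icc"`, `"sigma_b2"`, `"sigma_e2"`.
#' @param targets `"region"` or `"site"`.
#' @param measure Optional measure to restrict to (required when the table
#'   covers several).
#' @return A numeric matrix (targets in rows, raters in columns).
#' @export
estimate_matrix <- function(table, estimate = c("icc", "sigma_b2", "sigma_e2"),
                            targets = c("region", "site"), measure = NULL) {
  estimate <- match.arg(estimate)
  targets <- match.arg(targets)
  if (!is.null(measure)) table <- table[table$measure == measure, , drop = FALSE]
  if (length(unique(table$measure)) > 1) {
    stop("table covers several measures; pass `measure`", call. = FALSE)
  }
  ok <- table[table$status == "ok", , drop = FALSE]
  rows <- if (targets == "region") "region" else "group"
  cols <- if (targets == "region") "group" else "region"
  m <- stats::xtabs(stats::reformulate(paste(rows, cols, sep = "+"),
                                       response = estimate),
                    data = ok, na.action = stats::na.pass)
  m <- as.matrix(m)
  present <- stats::xtabs(stats::reformulate(paste(rows, cols, sep = "+")),
                          data = ok)
  m[as.matrix(present) == 0] <- NA
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " incomplete row(s) from the ",
            targets, " matrix")
    m <- m[complete, , drop = FALSE]
  }
  m
}

#' Rank-order stability: single-rater intraclass correlations
#'
#' Shrout-Fleiss ICC(2,1) (absolute agreement; penalises systematic rater
#' shifts) and ICC(3,1) (consistency; does not) from the two-way ANOVA mean
#' squares of a complete targets x raters matrix:
#' \deqn{ICC(3,1) = \frac{BMS - EMS}{BMS + (k-1) EMS}} \deqn{ICC(2,1) =
#' \frac{BMS - EMS}{BMS + (k-1) EMS + k (JMS - EMS)/n}} with BMS/JMS/EMS the
#' target, rater and residual mean squares, n targets and k raters.
#'
#' @param m Numeric matrix, targets in rows (>= 2), raters in columns (>= 2),
#'   no missing cells.
#' @return List with `icc_2_1` and `icc_3_1`, both in `[-1, 1]`; `NA` when the
#'   between-target variance is zero.
#' @examples
#' m <- cbind(1:5, 1:5 + 2)   # constant rater shift
#' rank_order_stability(m)    # icc_3_1 = 1, icc_2_1 < 1
#' @export
rank_order_stability <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete (no missing cells)", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters", call. = FALSE)
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  bms <- k * sum((row_means - grand)^2) / (n - 1)
  jms <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- m - outer(row_means, rep(1, k)) - outer(rep(1, n), col_means) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  if (bms <= .Machine$double.eps * max(1, grand^2)) {
    return(list(icc_2_1 = NA_real_, icc_3_1 = NA_real_))
  }
  icc31 <- (bms - ems) / (bms + (k - 1) * ems)
  icc21 <- (bms - ems) / (bms + (k - 1) * ems + k * (jms - ems) / n)
  list(icc_2_1 = icc21, icc_3_1 = icc31)
}

#' Read the shipped region-to-lobe mapping
#'
#' Loads a YAML mapping of region labels to lobes. The shipped file follows
#' the FreeSurfer lobe grouping of the Desikan-Killiany parcels (5 lobes per
#' hemisphere, hemispheres kept separate); it is editable data, not code.
#'
#' @param path Path to a YAML file of `lobe: [regions...]` blocks per
#'   hemisphere; defaults to the shipped mapping.
#' @return Named character vector, region label -> lobe label.
#' @export
read_lobe_mapping <- function(path = system.file("extdata",
                                                 "lobe_mapping.yaml",
                                                 package = "icedstab")) {
  x <- yaml::read_yaml(path)
  out <- character()
  for (hemi in names(x)) {
    for (lobe in names(x[[hemi]])) {
      regs <- paste0(hemi, "_", unlist(x[[hemi]][[lobe]]))
      out[regs] <- paste0(hemi, "_", lobe)
    }
  }
  out
}

#' Aggregate regions into lobes
#'
#' Collapses a region-resolution dataset to lobe resolution, per participant
#' and timepoint: cortical thickness is averaged over member regions
#' (unweighted by default) and extensive measures (surface area, volume) are
#' summed, so total volume is conserved exactly.
#'
#' @param dataset A dataset data frame.
#' @param mapping Named character vector region -> lobe (see
#'   [read_lobe_mapping()]); must cover every region present.
#' @param mean_measures Measures aggregated by mean (all others are summed).
#' @param weights Optional named vector of per-region weights for the mean
#'   (e.g. surface areas); unweighted by default.
#' @return A dataset data frame with lobes in the `region` column.
#' @export
aggregate_lobes <- function(dataset, mapping, mean_measures = "thickness",
                            weights = NULL) {
  missing <- setdiff(unique(dataset$region), names(mapping))
  if (length(missing)) {
    stop("regions not covered by the lobe mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dataset$lobe <- unname(mapping[dataset$region])
  w <- if (is.null(weights)) rep(1, nrow(dataset)) else {
    if (!all(unique(dataset$region) %in% names(weights))) {
      stop("weights must cover every region", call. = FALSE)
    }
    unname(weights[dataset$region])
  }
  is_mean <- dataset$measure %in% mean_measures
  wv <- ifelse(is_mean, w, 1)
  key <- paste(dataset$participant_id, dataset$measure, dataset$lobe,
               sep = "\r")
  first <- !duplicated(key)
  num1 <- rowsum(dataset$value_t1 * wv, key)
  num2 <- rowsum(dataset$value_t2 * wv, key)
  den <- rowsum(wv, key)
  out <- data.frame(participant_id = dataset$participant_id[first],
                    site = dataset$site[first],
                    scanner = dataset$scanner[first],
                    measure = dataset$measure[first],
                    region = dataset$lobe[first],
                    stringsAsFactors = FALSE)
  k <- key[first]
  div <- ifelse(out$measure %in% mean_measures, den[k, 1], 1)
  out$value_t1 <- num1[k, 1] / div
  out$value_t2 <- num2[k, 1] / div
  out <- out[order(out$measure, out$region, out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
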