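#' Read and validate a two-timepoint dataset CSV
#'
#' Parses a dataset written by [write_dataset()] (RFC-4180 CSV with a header)
#' and enforces the schema contract: all seven documented columns present,
#' values numeric and complete, each (participant, measure, region) key unique,
#' each participant in exactly one site, each site on exactly one scanner.
#'
#' @param path CSV path.
#' @return A validated dataset data frame.
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  validate_dataset(ds, where = path)
}

#' @rdname read_dataset
#' @param dataset A dataset data frame.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' Validate a dataset data frame against the schema contract
#'
#' @param dataset Candidate data frame.
#' @param where Label used in error messages (e.g. a file path).
#' @return The dataset, invisibly usable, after validation.
#' @export
validate_dataset <- function(dataset, where = "dataset") {
  required <- c("participant_id", "site", "scanner", "measure", "region",
                "value_t1", "value_t2")
  missing <- setdiff(required, names(dataset))
  if (length(missing)) {
    stop("schema error in ", where, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("value_t1", "value_t2")) {
    if (!is.numeric(dataset[[col]])) {
      stop("schema error in ", where, ": column ", col, " is not numeric",
           call. = FALSE)
    }
    if (anyNA(dataset[[col]])) {
      stop("schema error in ", where, ": missing values in ", col,
           " (complete cases required)", call. = FALSE)
    }
  }
  key <- paste(dataset$participant_id, dataset$measure, dataset$region,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- dataset[duplicated(key), c("participant_id", "measure", "region")]
    stop("schema error in ", where, ": duplicated (participant, measure, ",
         "region) key(s), e.g. ", paste(unlist(dup[1, ]), collapse = " / "),
         call. = FALSE)
  }
  p_sites <- unique(dataset[c("participant_id", "site")])
  if (anyDuplicated(p_sites$participant_id)) {
    stop("schema error in ", where,
         ": a participant belongs to more than one site", call. = FALSE)
  }
  s_scan <- unique(dataset[c("site", "scanner")])
  if (anyDuplicated(s_scan$site)) {
    stop("schema error in ", where,
         ": a site maps to more than one scanner manufacturer", call. = FALSE)
  }
  dataset
}

#' Rescale extensive measures before fitting
#'
#' Multiplies the values of selected measures by a constant (default .001) so
#' that surface area and volume, whose native units give variances several
#' orders of magnitude above cortical thickness, fit on a comparable numeric
#' scale. ICC, ICC2, chi-squared and CFI are scale-equivariant, so this
#' changes no reported stability quantity - only the conditioning of the
#' optimisation and the units of the variance components.
#'
#' @param dataset A dataset data frame.
#' @param measures Measures to rescale.
#' @param constant Positive multiplier.
#' @return The rescaled dataset.
#' @export
rescale_measures <- function(dataset, measures = c("area", "volume"),
                             constant = 0.001) {
  stopifnot(is.numeric(constant), constant > 0)
  sel <- dataset$measure %in% measures
  dataset$value_t1[sel] <- dataset$value_t1[sel] * constant
  dataset$value_t2[sel] <- dataset$value_t2[sel] * constant
  dataset
}

#' Pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Exactly one of
#' `input` (a dataset CSV path or data frame) or `simulation` (a
#' [sim_config()]) must be supplied.
#'
#' @param input Dataset CSV path or data frame.
#' @param simulation A [sim_config()] to generate the input instead.
#' @param measures Measures to analyse (default: all present).
#' @param grouping Grouping variable for the site-level analyses: `"site"` or
#'   `"scanner"`.
#' @param rescale Measures to rescale and the constant (see
#'   [rescale_measures()]); set `rescale_measures = character()` to disable.
#' @param rescale_constant Positive multiplier for the rescaled measures.
#' @param rescale_measures Character vector of measures to rescale.
#' @param delta_cfi_threshold Flag threshold for model comparisons.
#' @param holdout Number of participants withheld as an exploratory subset
#'   before the final fits (0 disables).
#' @param ci_level Level for ICC profile-likelihood intervals.
#' @param seed Integer seed governing simulation and the holdout draw.
#' @param out_dir Output directory for tables and the manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL, measures = NULL,
                            grouping = c("site", "scanner"),
                            rescale_measures = c("area", "volume"),
                            rescale_constant = 0.001,
                            delta_cfi_threshold = 0.02, holdout = 0,
                            ci_level = 0.95, seed = 1L, out_dir = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(input) == is.null(simulation)) {
    stop("config error: supply exactly one of `input` or `simulation`",
         call. = FALSE)
  }
  stopifnot(rescale_constant > 0,
            delta_cfi_threshold > 0, delta_cfi_threshold < 1,
            holdout >= 0, ci_level > 0, ci_level < 1)
  structure(list(input = input, simulation = simulation, measures = measures,
                 grouping = grouping, rescale_measures = rescale_measures,
                 rescale_constant = rescale_constant,
                 delta_cfi_threshold = delta_cfi_threshold,
                 holdout = as.integer(holdout), ci_level = ci_level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full stability-analysis pipeline
#'
#' Orchestrates, in order: data simulation or ingestion, rescaling of
#' extensive measures, optional exploratory holdout, the pooled and
#' site-grouped stability maps, map summaries, the dispersion decomposition,
#' the multigroup model-comparison grid, rank-order stability of the estimate
#' maps, and the design-planning report (required timepoints and attenuation
#' per region). Every number in every table is produced by one of the exported
#' module functions; this layer only sequences and writes them.
#'
#' @param config A [pipeline_config()].
#' @return A manifest list (also written as `manifest.json` when `out_dir` is
#'   set) recording the package version, seed, configuration, stage row
#'   counts, and every output file. The result tables themselves are attached
#'   under `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (!is.null(config$simulation)) {
    simulate_dataset(config$simulation)
  } else if (is.character(config$input)) {
    read_dataset(config$input)
  } else {
    validate_dataset(config$input)
  }
  if (!is.null(config$measures)) {
    unknown <- setdiff(config$measures, unique(dataset$measure))
    if (length(unknown)) {
      stop("config error: unknown measure(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    dataset <- dataset[dataset$measure %in% config$measures, , drop = FALSE]
  }
  log_info <- function(...) message("[icedstab] ", ...)
  log_info("dataset: ", length(unique(dataset$participant_id)),
           " participants, ", length(unique(dataset$region)), " regions, ",
           length(unique(dataset$measure)), " measures")

  if (length(config$rescale_measures)) {
    dataset <- rescale_measures(dataset, config$rescale_measures,
                                config$rescale_constant)
  }

  holdout_ids <- character()
  if (config$holdout > 0) {
    set.seed(config$seed + 1L)
    ids <- unique(dataset$participant_id)
    if (config$holdout >= length(ids)) {
      stop("config error: holdout exceeds the number of participants",
           call. = FALSE)
    }
    holdout_ids <- sort(sample(ids, config$holdout))
    dataset <- dataset[!dataset$participant_id %in% holdout_ids, ,
                       drop = FALSE]
    log_info("withheld ", length(holdout_ids),
             " participants as exploratory subset")
  }

  log_info("fitting pooled stability map")
  map_pooled <- fit_region_map(dataset, grouping = "pooled",
                               ci_level = config$ci_level)
  log_info("fitting ", config$grouping, "-grouped stability map")
  map_grouped <- fit_region_map(dataset, grouping = config$grouping,
                                ci_level = NA)
  summary_pooled <- summarize_map(map_pooled)
  dispersion <- tryCatch(dispersion_decomposition(map_grouped),
                         error = function(e) {
                           log_info("dispersion skipped: ",
                                    conditionMessage(e))
                           NULL
                         })
  log_info("running model-comparison grid")
  grid <- comparison_grid(dataset, grouping = config$grouping,
                          threshold = config$delta_cfi_threshold)

  rank_rows <- list()
  for (me in unique(map_grouped$measure)) {
    for (est in c("icc", "sigma_b2", "sigma_e2")) {
      for (tg in c("region", "site")) {
        m <- tryCatch(suppressMessages(
          estimate_matrix(map_grouped, estimate = est, targets = tg,
                          measure = me)), error = function(e) NULL)
        ro <- if (!is.null(m) && nrow(m) >= 2 && ncol(m) >= 2) {
          rank_order_stability(m)
        } else {
          list(icc_2_1 = NA_real_, icc_3_1 = NA_real_)
        }
        rank_rows[[length(rank_rows) + 1]] <-
          data.frame(measure = me, estimate = est, targets = tg,
                     icc_2_1 = ro$icc_2_1, icc_3_1 = ro$icc_3_1,
                     stringsAsFactors = FALSE)
      }
    }
  }
  rank_order <- do.call(rbind, rank_rows)

  ok <- map_pooled[map_pooled$status == "ok" & !is.na(map_pooled$icc), ,
                   drop = FALSE]
  design <- if (nrow(ok)) {
    data.frame(measure = ok$measure, region = ok$region, icc = ok$icc,
               timepoints_for_icc2_90 = mapply(
                 function(b, e) required_timepoints(sigma_b2 = b, sigma_e2 = e),
                 pmax(ok$sigma_b2, 0), pmax(ok$sigma_e2, 0)),
               stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(design)) {
    rownames(design) <- NULL
    att <- attenuation_power_report(
      data.frame(label = paste(design$measure, design$region, sep = ":"),
                 rel_region = pmax(design$icc, 1e-3)))
    design$r_observed <- att$r_observed
    design$n_required <- att$n_required
    design$pct_extra_participants <- att$pct_extra_participants
  }

  results <- list(stability_pooled = map_pooled,
                  stability_grouped = map_grouped,
                  map_summary = summary_pooled,
                  dispersion = dispersion,
                  comparison_grid = grid$grid,
                  comparison_flag_fractions = grid$summary,
                  rank_order = rank_order,
                  design_report = design)

  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      p <- file.path(config$out_dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      files[[name]] <<- p
    }
    wr(as.data.frame(map_pooled), "stability_pooled")
    wr(as.data.frame(map_grouped), "stability_grouped")
    wr(summary_pooled, "map_summary")
    wr(dispersion, "dispersion")
    wr(grid$grid, "comparison_grid")
    wr(rank_order, "rank_order")
    wr(design, "design_report")
    p <- file.path(config$out_dir, "comparison_flag_fractions.json")
    jsonlite::write_json(grid$summary, p, pretty = TRUE, digits = NA)
    files[["comparison_flag_fractions"]] <- p
  }

  manifest <- list(
    package = "icedstab",
    version = as.character(utils::packageVersion("icedstab")),
    seed = config$seed,
    grouping = config$grouping,
    rescale = list(measures = config$rescale_measures,
                   constant = config$rescale_constant),
    delta_cfi_threshold = config$delta_cfi_threshold,
    holdout_participants = holdout_ids,
    n_participants = length(unique(dataset$participant_id)),
    n_regions = length(unique(dataset$region)),
    measures = unique(dataset$measure),
    stage_rows = lapply(results, function(r) if (is.null(r)) 0L else nrow(r)),
    files = as.list(files))
  if (!is.null(config$out_dir)) {
    mp <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, pretty = TRUE, auto_unbox = TRUE,
                         digits = NA)
    manifest$files$manifest <- mp
  }
  manifest$results <- results
  invisible(manifest)
}
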