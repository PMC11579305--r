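#' Validate the pipeline's input tables
#'
#' Schema-checks the location, HAQI, estimate, and (optionally) prevalence
#' tables, applying the estimate repair rules of [validate_estimates()].
#' Both-sex estimate rows lacking `prop_female_cases` are rejected here
#' unless a prevalence surface is available to impute from.
#'
#' @param estimates Estimate data frame (or path to CSV).
#' @param locations Hierarchy data frame (or path).
#' @param haqi HAQI data frame (or path).
#' @param prevalence Optional [prevalence_surface()] (or path to the draws
#'   CSV) used as the `prop_female_cases` fallback.
#' @return A list of class `"validation_report"`: `estimates` (accepted
#'   rows), `hierarchy`, `haqi`, `prevalence`, `rejected`, and the row
#'   accounting `n_in`, `n_out`, `n_rejected`.
#' @export
validate_inputs <- function(estimates, locations, haqi, prevalence = NULL) {
  if (is.character(locations)) locations <- read_locations(locations)
  hierarchy <- if (inherits(locations, "location_hierarchy")) locations else
    location_hierarchy(locations)
  if (is.character(haqi)) haqi <- read_haqi(haqi)
  if (is.character(prevalence)) {
    prevalence <- df_to_prevalence(utils::read.csv(prevalence,
                                                   stringsAsFactors = FALSE))
  }
  if (is.character(estimates)) {
    estimates <- utils::read.csv(estimates, stringsAsFactors = FALSE)
  }
  v <- validate_estimates(estimates)
  est <- v$estimates
  rejected <- v$rejected

  unknown <- !est$location_id %in% hierarchy$location_id
  if (any(unknown)) {
    r <- est[unknown, , drop = FALSE]
    r$reason <- "location not in hierarchy"
    rejected <- rbind(rejected, r)
    est <- est[!unknown, , drop = FALSE]
  }
  nophi <- est$sex == "both" & !is.finite(est$prop_female_cases) &
    is.null(prevalence)
  if (any(nophi)) {
    r <- est[nophi, , drop = FALSE]
    r$reason <- "both-sex row lacks prop_female_cases and no prevalence fallback"
    rejected <- rbind(rejected, r)
    est <- est[!nophi, , drop = FALSE]
  }
  rownames(est) <- NULL
  structure(list(estimates = est, hierarchy = hierarchy, haqi = haqi,
                 prevalence = prevalence, rejected = rejected,
                 n_in = v$n_in, n_out = nrow(est),
                 n_rejected = nrow(rejected)),
            class = "validation_report")
}

#' Run the full estimation pipeline
#'
#' Executes, in order: input validation, indicator crosswalk
#' ([fit_crosswalk()] / [apply_crosswalk()]), sex splitting
#' ([fit_sex_model()] / [split_both_sex()]), the location cascade
#' ([run_cascade()]), coverage draws, and prevalence-weighted aggregation
#' ([build_results()]). Any stage can be toggled off; a skipped crosswalk
#' passes estimates through unchanged (only sensible for MAT-only data).
#'
#' @param estimates,locations,haqi,prevalence Inputs as in
#'   [validate_inputs()]; `prevalence` is required for aggregation.
#' @param config A list of sub-configurations: `crosswalk` (list with
#'   `trim_pct`), `sex_split` (list with `trim_pct`), `cascade` (a
#'   [cascade_config()]), `years_report` (years in the results table),
#'   `stages` (named logical toggles `crosswalk`, `sex_split`),
#'   and `seed` (propagated to every stochastic stage).
#' @return A list of class `"matcov_run"`: `results` (the aggregated
#'   table), `crosswalk_model`, `sex_model`, `cascade`, `coverage`,
#'   `validation`, and `manifest` (seed, config hash, per-stage row
#'   counts).
#' @export
run_pipeline <- function(estimates, locations, haqi, prevalence,
                         config = pipeline_config()) {
  v <- validate_inputs(estimates, locations, haqi, prevalence)
  est <- v$estimates
  counts <- list(input = c(rows_in = v$n_in, rows_out = nrow(est),
                           rows_rejected = v$n_rejected))

  cw_model <- NULL
  if (isTRUE(config$stages[["crosswalk"]])) {
    pairs <- build_matched_pairs(est, v$haqi)
    cw_model <- fit_crosswalk(pairs, trim_pct = config$crosswalk$trim_pct)
    est <- apply_crosswalk(est, cw_model, v$haqi)
    counts$crosswalk <- c(rows_in = nrow(est), rows_out = nrow(est),
                          n_pairs = nrow(pairs),
                          n_unmatched = attr(pairs, "n_unmatched"),
                          n_trimmed = cw_model$n_trimmed)
  }

  sex_model <- NULL
  if (isTRUE(config$stages[["sex_split"]])) {
    n_in <- nrow(est)
    sex_model <- fit_sex_model(est, v$prevalence,
                               trim_pct = config$sex_split$trim_pct)
    est <- split_both_sex(est, sex_model, v$prevalence)
    counts$sex_split <- c(rows_in = n_in, rows_out = nrow(est))
  } else if (any(est$sex == "both")) {
    stop("sex_split stage disabled but both-sex rows present", call. = FALSE)
  }

  cascade <- run_cascade(est, v$hierarchy, v$haqi, config$cascade)
  cov <- coverage_draws(cascade, n_draws = n_draws(v$prevalence))
  results <- build_results(cov, v$prevalence, v$hierarchy,
                           years = config$years_report)
  counts$cascade <- c(rows_in = nrow(est),
                      nodes_fitted = length(cascade$nodes))
  counts$aggregation <- c(rows_out = nrow(results))

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "cascade")],
                               auto_unbox = TRUE)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(tf)),
                   stage_counts = counts)
  unlink(tf)
  structure(list(results = results, crosswalk_model = cw_model,
                 sex_model = sex_model, cascade = cascade, coverage = cov,
                 validation = v, manifest = manifest),
            class = "matcov_run")
}

#' @rdname run_pipeline
#' @param seed Integer seed propagated to the cascade's draw generation.
#' @param years_report Years summarized in the results table.
#' @param crosswalk_trim,sex_split_trim Trimming fractions per stage.
#' @param cascade A [cascade_config()].
#' @param stages Named logical toggles.
#' @export
pipeline_config <- function(seed = 1L, years_report = c(2000, 2021),
                            crosswalk_trim = 0.05, sex_split_trim = 0,
                            cascade = cascade_config(seed = seed),
                            stages = c(crosswalk = TRUE, sex_split = TRUE)) {
  list(seed = as.integer(seed), years_report = years_report,
       crosswalk = list(trim_pct = crosswalk_trim),
       sex_split = list(trim_pct = sex_split_trim),
       cascade = cascade, stages = stages)
}
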