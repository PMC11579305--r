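#' Survey coverage estimates
#'
#' A coverage-estimate table holds one row per survey-derived proportion of
#' people with major depressive disorder receiving a treatment indicator.
#' Required columns:
#'
#' * `estimate_id`, `study_id`, `location_id` — identifiers (character).
#' * `sex` — `"male"`, `"female"` or `"both"`.
#' * `age_start`, `age_end` — half-open age interval \[start, end) in years,
#'   `0 <= age_start < age_end <= 100`.
#' * `year` — calendar year of data collection.
#' * `indicator` — `"MAT"` (minimally adequate treatment, the reference),
#'   `"antidepressant"`, or `"any_service"`.
#' * `mean` — observed proportion; exact 0/1 are clamped (see
#'   [clamp_proportion()]).
#' * `se` — standard error on the proportion scale; if missing, the
#'   binomial fallback `sqrt(p(1-p)/n)` is imputed from `sample_size`.
#' * `sample_size` — number of cases the proportion is based on.
#' * `prop_female_cases` — proportion of the study's cases that are female;
#'   required (or imputable from a prevalence surface) when `sex == "both"`.
#'
#' `validate_estimates()` normalises types, applies the clamping and
#' standard-error fallback rules, rejects rows that cannot be repaired, and
#' returns the accepted rows together with a rejection report.
#'
#' @param x Data frame of estimates.
#' @return A list with elements `estimates` (accepted, normalised rows),
#'   `rejected` (offending rows with a `reason` column), and `n_in`.
#' @export
validate_estimates <- function(x) {
  need <- c("estimate_id", "study_id", "location_id", "sex", "age_start",
            "age_end", "year", "indicator", "mean", "se", "sample_size",
            "prop_female_cases")
  miss <- setdiff(need, names(x))
  if ("prop_female_cases" %in% miss) {
    x$prop_female_cases <- NA_real_
    miss <- setdiff(miss, "prop_female_cases")
  }
  if ("se" %in% miss) {
    x$se <- NA_real_
    miss <- setdiff(miss, "se")
  }
  if (length(miss)) {
    stop("estimate table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)[, need]
  for (col in c("estimate_id", "study_id", "location_id", "sex", "indicator")) {
    x[[col]] <- as.character(x[[col]])
  }
  for (col in c("age_start", "age_end", "year", "mean", "se", "sample_size",
                "prop_female_cases")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!x$sex %in% c("male", "female", "both"), "invalid sex")
  flag(!x$indicator %in% c("MAT", "antidepressant", "any_service"),
       "invalid indicator")
  flag(!is.finite(x$age_start) | x$age_start < 0, "invalid age_start")
  flag(!is.finite(x$age_end) | x$age_end <= x$age_start | x$age_end > 100,
       "invalid age interval")
  flag(!is.finite(x$year), "invalid year")
  flag(!is.finite(x$mean) | x$mean < 0 | x$mean > 1, "mean outside [0, 1]")
  flag(is.finite(x$sample_size) & x$sample_size <= 0, "non-positive sample size")
  flag(!is.finite(x$se) & !is.finite(x$sample_size),
       "no uncertainty: se and sample_size both missing")
  flag((x$mean <= 0 | x$mean >= 1) & !is.finite(x$sample_size),
       "boundary mean without sample_size to clamp")
  flag(is.finite(x$se) & x$se <= 0, "non-positive se")
  flag(x$sex == "both" & is.finite(x$prop_female_cases) &
         (x$prop_female_cases < 0 | x$prop_female_cases > 1),
       "prop_female_cases outside [0, 1]")

  ok <- is.na(reason)
  rejected <- x[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!ok]
  out <- x[ok, , drop = FALSE]

  if (nrow(out)) {
    out$mean <- clamp_proportion(out$mean, out$sample_size)
    imp <- !is.finite(out$se)
    out$se[imp] <- sqrt(out$mean[imp] * (1 - out$mean[imp]) /
                          out$sample_size[imp])
  }
  rownames(out) <- NULL
  list(estimates = out, rejected = rejected, n_in = nrow(x))
}

#' Read and write the package's CSV interchange tables
#'
#' Plain UTF-8 CSV with a header row. `read_estimates()` validates on read
#' and stops if any row is rejected, printing the reasons; use
#' [validate_estimates()] directly for a tolerant load.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_estimates()`: validated estimate data frame.
#' @export
read_estimates <- function(path) {
  v <- validate_estimates(utils::read.csv(path, stringsAsFactors = FALSE))
  if (nrow(v$rejected)) {
    stop("rejected ", nrow(v$rejected), " row(s) from ", path, ": ",
         paste(unique(v$rejected$reason), collapse = "; "), call. = FALSE)
  }
  v$estimates
}

#' @rdname read_estimates
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_estimates
#' @export
read_locations <- function(path) {
  location_hierarchy(utils::read.csv(path, stringsAsFactors = FALSE,
                                     na.strings = c("NA", "")))
}

#' @rdname read_estimates
#' @export
read_haqi <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location_id", "year", "haqi")
  if (!all(need %in% names(h))) {
    stop("HAQI table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  h$location_id <- as.character(h$location_id)
  h
}
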