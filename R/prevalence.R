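#' Prevalence surfaces
#'
#' A prevalence surface stores major-depressive-disorder case counts with
#' sampling draws, keyed by country, year, sex, and age group. It is the
#' exogenous denominator of every coverage proportion: the package never
#' estimates prevalence, it consumes it.
#'
#' @param keys Data frame with columns `location_id`, `year`, `sex`
#'   (male/female), `age_start`, `age_end`.
#' @param draws Numeric matrix, one row per key row, one column per draw;
#'   all entries finite and non-negative.
#' @return A list of class `"prevalence_surface"` with elements `keys` and
#'   `draws`.
#' @export
prevalence_surface <- function(keys, draws) {
  need <- c("location_id", "year", "sex", "age_start", "age_end")
  if (!all(need %in% names(keys))) {
    stop("prevalence keys must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  draws <- as.matrix(draws)
  if (nrow(draws) != nrow(keys)) {
    stop("draws must have one row per key row", call. = FALSE)
  }
  if (any(!is.finite(draws)) || any(draws < 0)) {
    stop("prevalence draws must be finite and non-negative", call. = FALSE)
  }
  if (any(!keys$sex %in% c("male", "female"))) {
    stop("prevalence sex must be male or female", call. = FALSE)
  }
  keys <- as.data.frame(keys, stringsAsFactors = FALSE)[, need]
  keys$location_id <- as.character(keys$location_id)
  rownames(keys) <- NULL
  dimnames(draws) <- NULL
  structure(list(keys = keys, draws = draws), class = "prevalence_surface")
}

#' @rdname prevalence_surface
#' @param x A `prevalence_surface` (or, for `df_to_prevalence`, a data
#'   frame with `draw_*` columns as written by [prevalence_to_df()]).
#' @export
prevalence_to_df <- function(x) {
  d <- as.data.frame(x$draws)
  names(d) <- sprintf("draw_%d", seq_len(ncol(d)) - 1L)
  cbind(x$keys, d)
}

#' @rdname prevalence_surface
#' @export
df_to_prevalence <- function(x) {
  dc <- grep("^draw_", names(x))
  if (!length(dc)) stop("no draw_* columns found", call. = FALSE)
  prevalence_surface(x[, setdiff(names(x), names(x)[dc]), drop = FALSE],
                     as.matrix(x[, dc, drop = FALSE]))
}

#' @rdname prevalence_surface
#' @export
n_draws <- function(x) ncol(x$draws)

#' Proportion of cases that are female, from a prevalence surface
#'
#' Used to impute `prop_female_cases` for both-sex survey rows that do not
#' report it: the female share of mean case counts for the row's country,
#' year, and overlapping age groups.
#'
#' @param prevalence A [prevalence_surface()].
#' @param location_id,year,age_start,age_end The cell to impute for.
#' @return Proportion in (0, 1).
#' @export
prop_female_from_prevalence <- function(prevalence, location_id, year,
                                        age_start = 0, age_end = 100) {
  k <- prevalence$keys
  sel <- k$location_id == location_id & k$year == year &
    k$age_end > age_start & k$age_start < age_end
  if (!any(sel)) {
    stop("no prevalence for location ", location_id, ", year ", year,
         call. = FALSE)
  }
  m <- rowMeans(prevalence$draws[sel, , drop = FALSE])
  fem <- sum(m[k$sex[sel] == "female"])
  tot <- sum(m)
  if (tot <= 0) stop("zero cases in prevalence cell", call. = FALSE)
  fem / tot
}
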