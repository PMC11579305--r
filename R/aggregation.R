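#' Per-draw treated-case counts
#'
#' Multiplies coverage draws by prevalence (case-count) draws cell by cell,
#' pairing draw `d` of coverage with draw `d` of prevalence so that
#' uncertainty propagates jointly.
#'
#' @param coverage A draws table (`keys` + `draws`) as returned by
#'   [coverage_draws()].
#' @param prevalence A [prevalence_surface()] on the same cells.
#' @return A draws table of treated counts on the intersection of cells
#'   (an error if draw counts differ or a coverage cell has no prevalence).
#' @export
treated_counts <- function(coverage, prevalence) {
  if (ncol(coverage$draws) != ncol(prevalence$draws)) {
    stop("draw-count mismatch: coverage has ", ncol(coverage$draws),
         ", prevalence has ", ncol(prevalence$draws), call. = FALSE)
  }
  ck <- do.call(paste, c(coverage$keys[c("location_id", "year", "sex",
                                         "age_start", "age_end")],
                         sep = "|"))
  pk <- do.call(paste, c(prevalence$keys[c("location_id", "year", "sex",
                                           "age_start", "age_end")],
                         sep = "|"))
  idx <- match(ck, pk)
  if (anyNA(idx)) {
    stop("no prevalence for cell(s): ",
         paste(utils::head(ck[is.na(idx)], 3), collapse = "; "),
         call. = FALSE)
  }
  list(keys = coverage$keys,
       draws = coverage$draws * prevalence$draws[idx, , drop = FALSE])
}

#' Aggregate per-draw counts up the location hierarchy
#'
#' Sums country-level per-draw counts over descendants to produce counts
#' at region, super-region, and global level (countries pass through).
#' Proportions must be formed per draw *after* aggregation — see
#' [build_results()].
#'
#' @param counts A draws table with country-level `keys`/`draws`.
#' @param hierarchy A [location_hierarchy()].
#' @return A draws table covering every hierarchy node, keyed by
#'   (location_id, year, sex, age_start, age_end).
#' @export
aggregate_hierarchy <- function(counts, hierarchy) {
  countries <- hierarchy$location_id[hierarchy$level == "country"]
  have <- unique(counts$keys$location_id)
  if (!all(counts$keys$location_id %in% countries)) {
    stop("counts must be country-level", call. = FALSE)
  }
  keys_out <- list()
  draws_out <- list()
  cell <- do.call(paste, c(counts$keys[c("year", "sex", "age_start",
                                         "age_end")], sep = "|"))
  for (id in hierarchy$location_id) {
    if (id %in% countries) {
      sel <- counts$keys$location_id == id
      if (!any(sel)) stop("missing counts for country '", id, "'",
                          call. = FALSE)
      keys_out[[id]] <- counts$keys[sel, , drop = FALSE]
      draws_out[[id]] <- counts$draws[sel, , drop = FALSE]
    } else {
      members <- intersect(descendants(hierarchy, id), countries)
      miss <- setdiff(members, have)
      if (length(miss)) {
        stop("missing counts for country '", miss[1L], "' under '", id, "'",
             call. = FALSE)
      }
      sel <- which(counts$keys$location_id %in% members)
      g <- cell[sel]
      agg <- rowsum(counts$draws[sel, , drop = FALSE], g, reorder = TRUE)
      parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
      keys_out[[id]] <- data.frame(location_id = id,
                                   year = as.numeric(parts[, 1L]),
                                   sex = parts[, 2L],
                                   age_start = as.numeric(parts[, 3L]),
                                   age_end = as.numeric(parts[, 4L]),
                                   stringsAsFactors = FALSE)
      dimnames(agg) <- NULL
      draws_out[[id]] <- agg
    }
  }
  keys <- do.call(rbind, keys_out)
  rownames(keys) <- NULL
  list(keys = keys, draws = do.call(rbind, draws_out))
}

#' Summarize draws into a point estimate and 95% uncertainty interval
#'
#' The point estimate is the mean of the draws; the interval spans the
#' 2.5th to 97.5th percentiles computed by linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param x Numeric vector of draws (>= 2), or a matrix (rows summarized).
#' @return Named vector `c(mean, lower, upper)`, or a 3-column matrix.
#' @export
summarize_draws <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, summarize_draws))
    colnames(out) <- c("mean", "lower", "upper")
    return(out)
  }
  if (length(x) < 2L) stop("need at least 2 draws", call. = FALSE)
  q <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  c(mean = mean(x), lower = q[1L], upper = q[2L])
}

#' Age-sex standardised coverage
#'
#' Weights stratum-specific coverage draws by a fixed reference
#' distribution (here, the global age-sex distribution of cases), per
#' draw, then summarizes.
#'
#' @param coverage A draws table for a single location-year, keyed by
#'   `sex`, `age_start`, `age_end`.
#' @param weights Data frame with `sex`, `age_start`, `age_end`, `weight`;
#'   weights must sum to 1 within 1e-8.
#' @return A vector of per-draw standardised proportions.
#' @export
standardise_coverage <- function(coverage, weights) {
  if (abs(sum(weights$weight) - 1) > 1e-8) {
    stop("standardisation weights must sum to 1", call. = FALSE)
  }
  ck <- paste(coverage$keys$sex, coverage$keys$age_start,
              coverage$keys$age_end, sep = "|")
  wk <- paste(weights$sex, weights$age_start, weights$age_end, sep = "|")
  idx <- match(wk, ck)
  if (anyNA(idx)) stop("coverage missing stratum ", wk[is.na(idx)][1L],
                       call. = FALSE)
  as.vector(crossprod(coverage$draws[idx, , drop = FALSE], weights$weight))
}

#' Global age-sex case-distribution weights from a prevalence surface
#'
#' @param prevalence A [prevalence_surface()].
#' @param year Reference year of the distribution (default: latest).
#' @return Data frame `sex`, `age_start`, `age_end`, `weight` (sums to 1).
#' @export
standard_weights <- function(prevalence, year = max(prevalence$keys$year)) {
  k <- prevalence$keys
  sel <- k$year == year
  m <- rowMeans(prevalence$draws[sel, , drop = FALSE])
  g <- paste(k$sex[sel], k$age_start[sel], k$age_end[sel], sep = "|")
  tot <- tapply(m, g, sum)
  parts <- do.call(rbind, strsplit(names(tot), "|", fixed = TRUE))
  data.frame(sex = parts[, 1L], age_start = as.numeric(parts[, 2L]),
             age_end = as.numeric(parts[, 3L]),
             weight = as.vector(tot) / sum(tot), stringsAsFactors = FALSE)
}

#' Per-draw percent change between two years
#'
#' @param draws_a,draws_b Paired draw vectors for the earlier and later
#'   period; all `draws_a` must be non-zero.
#' @return Per-draw values of `100 * (b - a) / a`.
#' @export
percent_change <- function(draws_a, draws_b) {
  stopifnot(length(draws_a) == length(draws_b))
  if (any(draws_a == 0)) stop("baseline draws contain zeros", call. = FALSE)
  100 * (draws_b - draws_a) / draws_a
}

#' Build the results table: counts, proportions, intervals, change
#'
#' Combines coverage and prevalence draws into treated-case counts,
#' aggregates both up the hierarchy, and reports, for every location, year
#' and sex (male, female, and both — both-sex values are per-draw sums of
#' counts, never averages of proportions): mean and 95% UI of cases,
#' treated cases, and the proportion treated (in percent, formed per draw
#' as treated/cases then summarized), the age-sex standardised proportion,
#' and the percent change in the proportion between the first and last
#' requested year.
#'
#' @param coverage A draws table from [coverage_draws()].
#' @param prevalence A [prevalence_surface()] on the same cells.
#' @param hierarchy A [location_hierarchy()].
#' @param years Years to report (default: those present in `coverage`).
#' @param weights Standardisation weights (default: global case
#'   distribution at the latest requested year).
#' @return Data frame, one row per location-year-sex.
#' @export
build_results <- function(coverage, prevalence, hierarchy, years = NULL,
                          weights = NULL) {
  if (is.null(years)) years <- sort(unique(coverage$keys$year))
  sel_c <- coverage$keys$year %in% years
  coverage <- list(keys = coverage$keys[sel_c, , drop = FALSE],
                   draws = coverage$draws[sel_c, , drop = FALSE])
  treated <- treated_counts(coverage, prevalence)
  sel_p <- match(do.call(paste, c(coverage$keys, sep = "|")),
                 do.call(paste, c(prevalence$keys, sep = "|")))
  cases <- list(keys = coverage$keys,
                draws = prevalence$draws[sel_p, , drop = FALSE])
  treated_all <- aggregate_hierarchy(treated, hierarchy)
  cases_all <- aggregate_hierarchy(cases, hierarchy)
  if (is.null(weights)) {
    glob <- hierarchy$location_id[hierarchy$level == "global"]
    gsel <- cases_all$keys$location_id == glob &
      cases_all$keys$year == max(years)
    m <- rowMeans(cases_all$draws[gsel, , drop = FALSE])
    kk <- cases_all$keys[gsel, , drop = FALSE]
    weights <- data.frame(sex = kk$sex, age_start = kk$age_start,
                          age_end = kk$age_end, weight = m / sum(m))
  }

  key3 <- function(k) paste(k$location_id, k$year, k$sex, sep = "|")
  rows <- list()
  for (loc in hierarchy$location_id) {
    for (yr in years) {
      sel <- treated_all$keys$location_id == loc & treated_all$keys$year == yr
      for (sx in c("male", "female", "both")) {
        ss <- if (sx == "both") sel else sel & treated_all$keys$sex == sx
        tr <- colSums(treated_all$draws[ss, , drop = FALSE])
        ca <- colSums(cases_all$draws[ss, , drop = FALSE])
        pr <- 100 * tr / ca
        std <- if (sx == "both") {
          # stratum coverage at this node: per-draw treated / cases
          kk <- treated_all$keys[sel, , drop = FALSE]
          cdr <- treated_all$draws[sel, , drop = FALSE] /
            pmax(cases_all$draws[sel, , drop = FALSE], .Machine$double.xmin)
          s <- standardise_coverage(list(keys = kk, draws = cdr), weights)
          100 * summarize_draws(s)
        } else rep(NA_real_, 3)
        st <- summarize_draws(tr); sc <- summarize_draws(ca)
        sp <- summarize_draws(pr)
        rows[[length(rows) + 1L]] <- data.frame(
          location_id = loc, year = yr, sex = sx,
          cases_mean = sc[1L], cases_lower = sc[2L], cases_upper = sc[3L],
          treated_mean = st[1L], treated_lower = st[2L],
          treated_upper = st[3L],
          proportion_mean = sp[1L], proportion_lower = sp[2L],
          proportion_upper = sp[3L],
          standardised_mean = std[1L], standardised_lower = std[2L],
          standardised_upper = std[3L], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (length(years) >= 2L) {
    y0 <- min(years); y1 <- max(years)
    out$change_mean <- NA_real_
    out$change_lower <- NA_real_
    out$change_upper <- NA_real_
    for (loc in unique(out$location_id)) {
      for (sx in c("male", "female", "both")) {
        pd <- function(yr) {
          sel <- treated_all$keys$location_id == loc &
            treated_all$keys$year == yr &
            (if (sx == "both") TRUE else treated_all$keys$sex == sx)
          100 * colSums(treated_all$draws[sel, , drop = FALSE]) /
            colSums(cases_all$draws[sel, , drop = FALSE])
        }
        ch <- summarize_draws(percent_change(pd(y0), pd(y1)))
        tgt <- out$location_id == loc & out$sex == sx & out$year == y1
        out$change_mean[tgt] <- ch[1L]
        out$change_lower[tgt] <- ch[2L]
        out$change_upper[tgt] <- ch[3L]
      }
    }
  }
  out
}
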