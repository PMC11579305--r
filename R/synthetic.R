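#' Generative parameters for the synthetic world
#'
#' Defaults mirror the magnitudes reported for the real analysis: an
#' antidepressant-use indicator bias of 0.18 logits, an any-service bias of
#' 0.06 logits at HAQI 100 with a -0.012 per-unit HAQI interaction, a
#' female advantage of 0.35 logits, study-level random effects with SD 0.3,
#' 5% outlier contamination shifted by 1.5 logits, and 85% of rows
#' reported collapsed across sexes.
#'
#' The age pattern is piecewise linear on the logit scale: a structural
#' zero below age 1, a flat low level (`age_low_logit`) from 1 to 15, a
#' linear rise from 15 to a plateau at 40, the plateau (contributing 0) to
#' 80, then a mild decline (`age_decline_slope` per year) to 100.
#'
#' @param intercept_logit Logit coverage for a male at HAQI 100, plateau age.
#' @param beta_haqi Logit change per HAQI unit.
#' @param beta_female Female minus male logit difference.
#' @param bias_ad Antidepressant-use indicator bias (logit).
#' @param bias_any_at_haqi100 Any-service bias at HAQI 100 (logit).
#' @param bias_any_haqi_slope Any-service bias change per HAQI unit.
#' @param study_re_sd SD of study-level Gaussian random effects.
#' @param outlier_fraction Fraction of survey rows contaminated.
#' @param outlier_shift Absolute logit shift applied to outlier rows.
#' @param frac_both_sex Probability a study reports both sexes collapsed.
#' @param age_low_logit Age-curve level (relative to plateau) on \[1, 15).
#' @param age_decline_slope Age-curve slope per year above age 80 (< 0).
#' @return A list of class `"true_params"`.
#' @export
true_params <- function(intercept_logit = -1.0,
                        beta_haqi = 0.04,
                        beta_female = 0.35,
                        bias_ad = 0.18,
                        bias_any_at_haqi100 = 0.06,
                        bias_any_haqi_slope = -0.012,
                        study_re_sd = 0.3,
                        outlier_fraction = 0.05,
                        outlier_shift = 1.5,
                        frac_both_sex = 0.85,
                        age_low_logit = -1.2,
                        age_decline_slope = -0.01) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 0.5, study_re_sd >= 0,
            frac_both_sex >= 0, frac_both_sex <= 1)
  structure(list(
    intercept_logit = intercept_logit, beta_haqi = beta_haqi,
    beta_female = beta_female, bias_ad = bias_ad,
    bias_any_at_haqi100 = bias_any_at_haqi100,
    bias_any_haqi_slope = bias_any_haqi_slope, study_re_sd = study_re_sd,
    outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
    frac_both_sex = frac_both_sex, age_low_logit = age_low_logit,
    age_decline_slope = age_decline_slope), class = "true_params")
}

#' Configuration of the synthetic world
#'
#' The default world has 3 super-regions x 2 regions x 3 countries = 18
#' countries observed 2000-2021, surveyed by 32 studies — the same order of
#' size as the real evidence base (32 studies, 31 countries, ~145
#' estimates, ~63 matched indicator pairs).
#'
#' @param n_super_regions,regions_per_super,countries_per_region Tree shape.
#' @param years Calendar years covered.
#' @param seed Integer seed fixing all randomness of the generator.
#' @param n_draws Number of prevalence draws.
#' @param true_params A [true_params()] object.
#' @param n_studies Number of surveys emitted by [generate_surveys()].
#' @param bands_per_study Possible numbers of age bands per study.
#' @param indicator_prob Probability each indicator is reported by a study.
#' @param size_range Range of per-row case counts (uniform integer draw).
#' @return A list of class `"world_config"`.
#' @export
world_config <- function(n_super_regions = 3, regions_per_super = 2,
                         countries_per_region = 3, years = 2000:2021,
                         seed = 1L, n_draws = 500L,
                         true_params = matcov::true_params(),
                         n_studies = 32L, bands_per_study = 1:3,
                         indicator_prob = 0.7,
                         size_range = c(100L, 2000L)) {
  stopifnot(n_super_regions >= 1, regions_per_super >= 1,
            countries_per_region >= 1, length(years) >= 1, n_draws >= 2,
            n_studies >= 1)
  structure(list(
    n_super_regions = n_super_regions, regions_per_super = regions_per_super,
    countries_per_region = countries_per_region, years = as.integer(years),
    seed = as.integer(seed), n_draws = as.integer(n_draws),
    true_params = true_params, n_studies = as.integer(n_studies),
    bands_per_study = bands_per_study, indicator_prob = indicator_prob,
    size_range = size_range), class = "world_config")
}

# survey age bands (adults; children are not surveyed for MAT)
.survey_bands <- function() {
  data.frame(age_start = c(15, 25, 40, 60, 80),
             age_end = c(25, 40, 60, 80, 100))
}

# prevalence age groups, including the under-1 structural-zero group
.prev_groups <- function() {
  data.frame(age_start = c(0, 1, 5, 15, 25, 40, 60, 80),
             age_end = c(1, 5, 15, 25, 40, 60, 80, 100))
}

#' Age pattern of the true coverage surface (logit scale, relative to plateau)
#'
#' @param age Ages in years (>= 1; below 1 coverage is a structural zero and
#'   this curve is not defined).
#' @param params A [true_params()] object.
#' @return Logit-scale age contribution.
#' @export
age_curve_logit <- function(age, params = true_params()) {
  lo <- params$age_low_logit
  out <- numeric(length(age))
  out[age < 15] <- lo
  r <- age >= 15 & age < 40
  out[r] <- lo * (40 - age[r]) / 25
  out[age >= 40 & age <= 80] <- 0
  d <- age > 80
  out[d] <- params$age_decline_slope * (age[d] - 80)
  out
}

#' True coverage surface of the synthetic world
#'
#' @param haqi HAQI value(s) in \[0, 100\].
#' @param sex `"male"` or `"female"`.
#' @param age Age(s) in years.
#' @inheritParams age_curve_logit
#' @return Coverage proportion; exactly 0 for age < 1.
#' @export
true_coverage <- function(haqi, sex, age, params = true_params()) {
  n <- max(length(haqi), length(sex), length(age))
  haqi <- rep_len(haqi, n); sex <- rep_len(sex, n); age <- rep_len(age, n)
  lp <- params$intercept_logit + params$beta_haqi * (haqi - 100) +
    params$beta_female * (sex == "female") + age_curve_logit(age, params)
  out <- invlogit(lp)
  out[age < 1] <- 0
  out
}

# relative case weights by prevalence age group; the female share of cases
# is flat in age (as observed for MDD) and varies only across countries
.case_age_weights <- function() c(0.001, 0.004, 0.05, 0.18, 0.28, 0.27, 0.17, 0.045)
.female_share_base <- function() 0.60

#' Generate a synthetic world
#'
#' Builds the location hierarchy, a country-year HAQI table (country base
#' level drawn from Uniform(30, 95) with a small upward secular trend,
#' clamped to \[0, 100\]), and a prevalence surface of major-depressive-
#' disorder case counts with log-normal draw noise around a smooth age-sex
#' case distribution. The true coverage surface is available through
#' [true_coverage()] with the config's parameters.
#'
#' @param config A [world_config()].
#' @return A list of class `"world"`: `hierarchy`, `haqi`, `prevalence`
#'   (a [prevalence_surface()]), `config`, and `phi` (expected proportion
#'   female among cases by country and age group).
#' @export
generate_world <- function(config = world_config()) {
  set.seed(config$seed)
  h <- list(data.frame(location_id = "G", name = "Global", level = "global",
                       parent_id = NA_character_))
  for (s in seq_len(config$n_super_regions)) {
    sid <- sprintf("SR%d", s)
    h[[length(h) + 1L]] <- data.frame(location_id = sid,
                                      name = sprintf("Super-region %d", s),
                                      level = "super_region", parent_id = "G")
    for (r in seq_len(config$regions_per_super)) {
      rid <- sprintf("R%d_%d", s, r)
      h[[length(h) + 1L]] <- data.frame(location_id = rid,
                                        name = sprintf("Region %d.%d", s, r),
                                        level = "region", parent_id = sid)
      for (k in seq_len(config$countries_per_region)) {
        cid <- sprintf("C%d_%d_%d", s, r, k)
        h[[length(h) + 1L]] <- data.frame(
          location_id = cid, name = sprintf("Country %d.%d.%d", s, r, k),
          level = "country", parent_id = rid)
      }
    }
  }
  hierarchy <- location_hierarchy(do.call(rbind, h))
  countries <- hierarchy$location_id[hierarchy$level == "country"]
  years <- config$years

  base <- stats::runif(length(countries), 30, 95)
  mid <- mean(years)
  haqi <- data.frame(
    location_id = rep(countries, each = length(years)),
    year = rep(years, length(countries)),
    haqi = pmin(100, pmax(0, rep(base, each = length(years)) +
                            0.25 * (rep(years, length(countries)) - mid))))

  # country scale of case counts and country-level female share of cases
  scale_c <- stats::rlnorm(length(countries), log(2e5), 0.5)
  share_c <- pmin(0.95, pmax(0.05, .female_share_base() +
                               stats::runif(length(countries), -0.05, 0.05)))
  grp <- .prev_groups()
  w_age <- .case_age_weights()

  keys <- expand.grid(location_id = countries, year = years,
                      sex = c("male", "female"), g = seq_len(nrow(grp)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys$age_start <- grp$age_start[keys$g]
  keys$age_end <- grp$age_end[keys$g]
  ci <- match(keys$location_id, countries)
  sexw <- ifelse(keys$sex == "female", share_c[ci], 1 - share_c[ci])
  expected <- scale_c[ci] * (1 + 0.01 * (keys$year - min(years))) *
    w_age[keys$g] * sexw
  keys$g <- NULL
  noise <- matrix(stats::rnorm(nrow(keys) * config$n_draws, 0, 0.05),
                  nrow(keys), config$n_draws)
  draws <- expected * exp(noise - 0.05^2 / 2)
  prevalence <- prevalence_surface(keys, draws)

  phi <- data.frame(location_id = countries, prop_female = share_c)

  structure(list(hierarchy = hierarchy, haqi = haqi, prevalence = prevalence,
                 phi = phi, config = config), class = "world")
}

# expected proportion female among cases for a country (flat in age)
.world_phi <- function(world, location_id, age_start, age_end) {
  p <- world$phi
  i <- match(location_id, p$location_id)
  if (is.na(i)) stop("no phi for ", location_id)
  p$prop_female[i]
}

#' Generate synthetic survey estimates
#'
#' Emulates the survey evidence base: each study samples one country and
#' year, reports 1-3 adult age bands, and reports each indicator (MAT,
#' antidepressant use, any-service use) independently with probability
#' `indicator_prob` (at least one). Observed logit means equal the true
#' logit plus the indicator bias plus a study-level Gaussian random effect;
#' binomial sampling noise is applied on the proportion scale with case
#' counts drawn uniformly from `size_range`. With probability
#' `frac_both_sex` a study reports collapsed both-sex rows whose mean is
#' the case-weighted (by proportion female among cases) average of the two
#' sex strata. A fraction `outlier_fraction` of rows receives an additional
#' logit shift of `outlier_shift` with deterministically alternating sign.
#'
#' @param world A [generate_world()] result.
#' @param config The [world_config()] used to build the world (defaults to
#'   the one stored in `world`).
#' @return A validated estimate data frame (see [validate_estimates()]).
#' @export
generate_surveys <- function(world, config = world$config) {
  set.seed(config$seed + 1000L)
  tp <- config$true_params
  countries <- world$hierarchy$location_id[world$hierarchy$level == "country"]
  bands <- .survey_bands()
  rows <- vector("list", 0L)
  for (s in seq_len(config$n_studies)) {
    sid <- sprintf("S%02d", s)
    country <- sample(countries, 1L)
    year <- sample(config$years, 1L)
    u <- stats::rnorm(1L, 0, tp$study_re_sd)
    nb <- sample(config$bands_per_study, 1L)
    bi <- sort(sample(nrow(bands), nb))
    ind <- c("MAT", "antidepressant", "any_service")[
      stats::runif(3) < config$indicator_prob]
    if (!length(ind)) ind <- sample(c("MAT", "antidepressant", "any_service"), 1L)
    hq <- haqi_lookup(world$haqi, country, year)
    for (b in bi) {
      a0 <- bands$age_start[b]; a1 <- bands$age_end[b]
      # collapse decided per study-band cell, shared across indicators so
      # that matched crosswalk pairs keep a common sex stratum
      collapse <- stats::runif(1) < tp$frac_both_sex
      # band-average true logit, same integration rule the cascade uses
      grid <- seq(a0 + 0.5, a1 - 0.5, by = 1)
      phi <- .world_phi(world, country, a0, a1)
      for (indicator in ind) {
        bias <- switch(indicator, MAT = 0, antidepressant = tp$bias_ad,
                       any_service = tp$bias_any_at_haqi100 +
                         tp$bias_any_haqi_slope * (hq - 100))
        obs <- list()
        for (sx in c("male", "female")) {
          lt <- mean(logit(true_coverage(hq, sx, grid, tp)))
          p <- invlogit(lt + bias + u)
          n <- sample(config$size_range[1]:config$size_range[2], 1L)
          ph <- stats::rbinom(1L, n, p) / n
          obs[[sx]] <- list(p = ph, n = n)
        }
        if (collapse) {
          n <- obs$male$n + obs$female$n
          pb <- (1 - phi) * obs$male$p + phi * obs$female$p
          pm <- clamp_proportion(obs$male$p, obs$male$n)
          pf <- clamp_proportion(obs$female$p, obs$female$n)
          se <- sqrt((1 - phi)^2 * pm * (1 - pm) / obs$male$n +
                       phi^2 * pf * (1 - pf) / obs$female$n)
          rows[[length(rows) + 1L]] <- data.frame(
            estimate_id = NA_character_, study_id = sid,
            location_id = country, sex = "both", age_start = a0,
            age_end = a1, year = year, indicator = indicator,
            mean = clamp_proportion(pb, n), se = se, sample_size = n,
            prop_female_cases = phi)
        } else {
          for (sx in c("male", "female")) {
            p <- clamp_proportion(obs[[sx]]$p, obs[[sx]]$n)
            rows[[length(rows) + 1L]] <- data.frame(
              estimate_id = NA_character_, study_id = sid,
              location_id = country, sex = sx, age_start = a0, age_end = a1,
              year = year, indicator = indicator, mean = p,
              se = sqrt(p * (1 - p) / obs[[sx]]$n),
              sample_size = obs[[sx]]$n,
              prop_female_cases = if (sx == "female") 1 else 0)
          }
        }
      }
    }
  }
  est <- do.call(rbind, rows)
  est$estimate_id <- sprintf("E%04d", seq_len(nrow(est)))

  k <- round(tp$outlier_fraction * nrow(est))
  if (k > 0) {
    out_idx <- sort(sample(nrow(est), k))
    sgn <- rep_len(c(1, -1), k)  # alternate sign by row order: balanced
    lt <- logit(est$mean[out_idx]) + sgn * tp$outlier_shift
    est$mean[out_idx] <- invlogit(lt)
  }
  validate_estimates(est)$estimates
}

#' Write the synthetic world and surveys to CSV files
#'
#' Produces `locations.csv`, `haqi.csv`, `prevalence.csv`, `truth.csv`
#' (the generating coverage surface, for recovery testing) and
#' `estimates.csv` in `dir`.
#'
#' @inheritParams generate_surveys
#' @param dir Output directory (created if needed).
#' @param estimates Optional pre-generated estimate table.
#' @return Invisibly, the named vector of file paths.
#' @export
write_world <- function(world, dir, estimates = NULL,
                        config = world$config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(locations = file.path(dir, "locations.csv"),
             haqi = file.path(dir, "haqi.csv"),
             prevalence = file.path(dir, "prevalence.csv"),
             truth = file.path(dir, "truth.csv"),
             estimates = file.path(dir, "estimates.csv"))
  write_table_csv(as.data.frame(unclass(world$hierarchy)), paths["locations"])
  write_table_csv(world$haqi, paths["haqi"])
  write_table_csv(prevalence_to_df(world$prevalence), paths["prevalence"])

  grp <- .prev_groups()
  tr <- expand.grid(location_id = world$hierarchy$location_id[
    world$hierarchy$level == "country"], year = config$years,
    sex = c("male", "female"), g = seq_len(nrow(grp)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr$age_start <- grp$age_start[tr$g]; tr$age_end <- grp$age_end[tr$g]
  tr$g <- NULL
  mid <- (tr$age_start + tr$age_end) / 2
  tr$coverage <- true_coverage(haqi_lookup(world$haqi, tr$location_id, tr$year),
                               tr$sex, mid, config$true_params)
  write_table_csv(tr, paths["truth"])
  if (is.null(estimates)) estimates <- generate_surveys(world, config)
  write_table_csv(estimates, paths["estimates"])
  invisible(paths)
}
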