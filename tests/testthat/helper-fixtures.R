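# small hand-built hierarchy: 1 global, 2 super-regions, 3 regions, 5 countries
tiny_hierarchy <- function() {
  location_hierarchy(data.frame(
    location_id = c("G", "SR1", "SR2", "R1a", "R1b", "R2a",
                    "CA", "CB", "CC", "CD", "CE"),
    name = c("Global", "Super 1", "Super 2", "Region 1a", "Region 1b",
             "Region 2a", "A", "B", "C", "D", "E"),
    level = c("global", "super_region", "super_region", "region", "region",
              "region", "country", "country", "country", "country", "country"),
    parent_id = c(NA, "G", "G", "SR1", "SR1", "SR2",
                  "R1a", "R1a", "R1b", "R2a", "R2a"),
    stringsAsFactors = FALSE))
}

flat_haqi <- function(locations, years = 2000:2021, value = 70) {
  expand.grid(location_id = locations, year = years,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    transform(haqi = value)
}

# one estimate row with sensible defaults, overridable field by field
est_row <- function(estimate_id = "E1", study_id = "S1", location_id = "CA",
                    sex = "both", age_start = 15, age_end = 25, year = 2010,
                    indicator = "MAT", mean = 0.1, se = 0.02,
                    sample_size = 500, prop_female_cases = 0.6) {
  data.frame(estimate_id = estimate_id, study_id = study_id,
             location_id = location_id, sex = sex, age_start = age_start,
             age_end = age_end, year = year, indicator = indicator,
             mean = mean, se = se, sample_size = sample_size,
             prop_female_cases = prop_female_cases,
             stringsAsFactors = FALSE)
}

# matched pairs drawn from the crosswalk generative model itself:
# n_pairs logit differences with study random effects, the generative
# indicator biases, and an optional outlier fraction
simulate_pairs <- function(seed, n_pairs = 63, n_studies = 21,
                           bias_ad = 0.18, bias_any = 0.06,
                           bias_any_haqi = -0.012, study_sd = 0.3,
                           outlier_frac = 0.05, outlier_shift = 1.5) {
  set.seed(seed)
  study <- sample(sprintf("S%02d", seq_len(n_studies)), n_pairs,
                  replace = TRUE)
  haqi <- stats::runif(n_pairs, 30, 95)
  alt <- sample(c("antidepressant", "any_service"), n_pairs, replace = TRUE)
  se <- stats::runif(n_pairs, 0.1, 0.3)
  u <- stats::rnorm(n_studies, 0, study_sd)[match(study,
                                                  sprintf("S%02d",
                                                          seq_len(n_studies)))]
  truth <- ifelse(alt == "antidepressant", bias_ad,
                  bias_any + bias_any_haqi * (haqi - 100))
  y <- truth + u + stats::rnorm(n_pairs, 0, se)
  k <- round(outlier_frac * n_pairs)
  if (k > 0) {
    idx <- sample(n_pairs, k)
    y[idx] <- y[idx] + rep_len(c(1, -1), k) * outlier_shift
  }
  data.frame(pair_id = sprintf("P%03d", seq_len(n_pairs)), study_id = study,
             location_id = "CA", sex = "both", age_start = 15, age_end = 25,
             year = 2010, indicator_alt = alt, logit_diff = y, se_diff = se,
             haqi_centered = haqi - 100, stringsAsFactors = FALSE)
}

# draws table constructor for aggregation tests
draws_table <- function(location_id, year, sex, age_start, age_end, draws) {
  list(keys = data.frame(location_id = location_id, year = year, sex = sex,
                         age_start = age_start, age_end = age_end,
                         stringsAsFactors = FALSE),
       draws = as.matrix(draws))
}
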