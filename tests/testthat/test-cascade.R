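# noise-free sex-specific estimates on dense age bands for one country
dense_country_data <- function(haqi = 80, tp = true_params(),
                               width = 5, se = 0.004) {
  starts <- seq(15, 100 - width, by = width)
  rows <- list()
  for (a0 in starts) {
    for (sx in c("male", "female")) {
      grid <- seq(a0 + 0.25, a0 + width - 0.25, by = 0.5)
      p <- invlogit(mean(logit(true_coverage(haqi, sx, grid, tp))))
      rows[[length(rows) + 1L]] <- data.frame(
        estimate_id = sprintf("E_%s_%d", sx, a0), study_id = "S1",
        location_id = "CA", sex = sx, age_start = a0, age_end = a0 + width,
        year = 2015, indicator = "MAT", mean = p, se = se,
        sample_size = 1e5, prop_female_cases = as.numeric(sx == "female"),
        haqi_centered = haqi - 100, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("assign_data applies the inclusive year window over the subtree", {
  h <- tiny_hierarchy()
  e <- rbind(est_row("E1", location_id = "CA", year = 2010),
             est_row("E2", location_id = "CC", year = 2010),
             est_row("E3", location_id = "CD", year = 2010))
  expect_identical(assign_data(e, h, "SR1", 2017, 7)$estimate_id,
                   c("E1", "E2"))
  expect_identical(nrow(assign_data(e, h, "SR1", 2018, 7)), 0L)
  expect_identical(assign_data(e, h, "G", 2003, 7)$estimate_id,
                   c("E1", "E2", "E3"))
})

test_that("assign_data equals a brute-force filter on random fixtures", {
  set.seed(12)
  h <- tiny_hierarchy()
  locs <- h$location_id[h$level == "country"]
  e <- do.call(rbind, lapply(1:80, function(i)
    est_row(sprintf("E%d", i), location_id = sample(locs, 1),
            year = sample(1995:2025, 1))))
  for (node in c("G", "SR1", "R2a", "CB")) {
    for (yr in c(2000, 2012, 2021)) {
      got <- assign_data(e, h, node, yr, 7)$estimate_id
      want <- e$estimate_id[e$location_id %in% descendants(h, node) &
                              abs(e$year - yr) <= 7]
      expect_setequal(got, want)
    }
  }
})

test_that("a node with no data reproduces its parent's parameters exactly", {
  cfg <- world_config(seed = 13, n_studies = 6L)
  w <- generate_world(cfg)
  est <- generate_surveys(w, cfg)
  est <- est[est$sex != "both", ]
  fit <- run_cascade(est, w$hierarchy, w$haqi, cascade_config(seed = 13))
  ctr <- w$hierarchy$location_id[w$hierarchy$level == "country"]
  empty <- ctr[!ctr %in% est$location_id]
  expect_gt(length(empty), 0)
  for (loc in empty) {
    parent <- w$hierarchy$parent_id[w$hierarchy$location_id == loc]
    expect_identical(fit$nodes[[loc]]$theta, fit$nodes[[parent]]$theta)
    # prediction is therefore the parent surface at this country's HAQI
    hv <- haqi_lookup(w$haqi, loc, 2015)
    expect_equal(
      predict_coverage(fit, loc, c(20, 50, 85), "female", 2015),
      predict_coverage(fit, parent, c(20, 50, 85), "female", 2015,
                       haqi_value = hv))
  }
})

test_that("dense noise-free data reproduces the generating surface", {
  tp <- true_params()
  h <- location_hierarchy(data.frame(
    location_id = c("G", "SR1", "R1", "CA"), name = c("g", "s", "r", "c"),
    level = c("global", "super_region", "region", "country"),
    parent_id = c(NA, "G", "SR1", "R1")))
  d <- dense_country_data(haqi = 80, tp = tp)
  fit <- run_cascade(d, h, flat_haqi("CA", value = 80),
                     cascade_config(seed = 1))
  mids <- c(17.5, 25, 35, 45, 55, 65, 75, 90)
  for (sx in c("male", "female")) {
    pred <- predict_coverage(fit, "CA", mids, sx, 2015)
    expect_equal(pred, true_coverage(80, sx, mids, tp), tolerance = 0.005)
  }
})

test_that("the 80-100 profile is non-increasing even against rising data", {
  h <- location_hierarchy(data.frame(
    location_id = c("G", "SR1", "R1", "CA"), name = c("g", "s", "r", "c"),
    level = c("global", "super_region", "region", "country"),
    parent_id = c(NA, "G", "SR1", "R1")))
  d <- dense_country_data(haqi = 80)
  rising <- d$age_start >= 80
  d$mean[rising] <- invlogit(logit(d$mean[rising]) +
                               0.04 * (d$age_start[rising] - 80) + 0.5)
  fit <- run_cascade(d, h, flat_haqi("CA", value = 80),
                     cascade_config(seed = 1))
  for (id in names(fit$nodes)) {
    th <- fit$nodes[[id]]$theta
    expect_lte(th[["v100"]], th[["v80"]] + 1e-10)
    expect_true(fit$nodes[["CA"]]$constrained ||
                  th[["v100"]] < th[["v80"]] + 1e-10)
  }
  pr <- predict_coverage(fit, "CA", seq(80, 100, by = 2), "male", 2015)
  expect_true(all(diff(pr) <= 1e-12))
})

test_that("vanishing country prior collapses countries onto their region", {
  cfg <- world_config(seed = 14)
  w <- generate_world(cfg)
  est <- generate_surveys(w, cfg)
  est <- est[est$sex != "both", ]
  cc <- cascade_config(seed = 14,
                       prior_sd_by_level = c(super_region = 0.8,
                                             region = 0.5, country = 1e-6))
  fit <- run_cascade(est, w$hierarchy, w$haqi, cc)
  ctr <- w$hierarchy$location_id[w$hierarchy$level == "country"][1:6]
  for (loc in ctr) {
    parent <- w$hierarchy$parent_id[w$hierarchy$location_id == loc]
    expect_equal(fit$nodes[[loc]]$theta, fit$nodes[[parent]]$theta,
                 tolerance = 1e-4)
  }
})

test_that("coverage below age 1 is exactly zero everywhere", {
  cfg <- world_config(seed = 15, n_draws = 30)
  w <- generate_world(cfg)
  est <- generate_surveys(w, cfg)
  est <- est[est$sex != "both", ]
  fit <- run_cascade(est, w$hierarchy, w$haqi,
                     cascade_config(seed = 15, n_draws = 30))
  expect_identical(predict_coverage(fit, "G", c(0, 0.5, 0.99), "female", 2010),
                   c(0, 0, 0))
  cov <- coverage_draws(fit, years = c(2010), n_draws = 30)
  under1 <- cov$keys$age_end <= 1
  expect_true(any(under1))
  expect_true(all(cov$draws[under1, ] == 0))
  expect_true(all(cov$draws >= 0 & cov$draws < 1))
})

test_that("parameter draws are seeded, unbiased, and respect degeneracy", {
  node <- list(theta = c(a = 1, b = -2),
               vcov = matrix(c(0.04, 0.01, 0.01, 0.09), 2))
  d1 <- generate_draws(node, 400, seed = 99)
  d2 <- generate_draws(node, 400, seed = 99)
  expect_identical(d1, d2)
  mc_se <- sqrt(diag(node$vcov) / 400)
  expect_lt(max(abs(colMeans(d1) - node$theta) / mc_se), 3.5)
  # zero covariance: draws pinned at the point estimate (up to the floor)
  d0 <- generate_draws(list(theta = c(a = 1, b = -2),
                            vcov = matrix(0, 2, 2)), 50, seed = 1)
  expect_equal(sweep(d0, 2, c(1, -2)), matrix(0, 50, 2), tolerance = 1e-3,
               ignore_attr = TRUE)
  # genuinely broken covariance triggers the repair warning
  expect_warning(generate_draws(list(theta = c(a = 0, b = 0),
                                     vcov = matrix(c(1, 2, 2, 1), 2)),
                                10, seed = 1), "flooring")
})

test_that("draw-mean predictions agree with point predictions", {
  h <- location_hierarchy(data.frame(
    location_id = c("G", "SR1", "R1", "CA"), name = c("g", "s", "r", "c"),
    level = c("global", "super_region", "region", "country"),
    parent_id = c(NA, "G", "SR1", "R1")))
  d <- dense_country_data(haqi = 80, se = 0.01)
  fit <- run_cascade(d, h, flat_haqi("CA", value = 80),
                     cascade_config(seed = 2, n_draws = 500))
  cov <- coverage_draws(fit, locations = "CA", years = 2015, n_draws = 500)
  adult <- cov$keys$age_start >= 15 & cov$keys$sex == "male"
  for (i in which(adult)) {
    pt <- invlogit(mean(logit(predict_coverage(
      fit, "CA", seq(cov$keys$age_start[i] + 0.25,
                     cov$keys$age_end[i] - 0.25, by = 0.5), "male", 2015))))
    dm <- mean(cov$draws[i, ])
    expect_equal(dm, pt, tolerance = 0.02)
  }
})
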