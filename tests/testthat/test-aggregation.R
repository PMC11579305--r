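test_that("treated counts are the per-draw elementwise product", {
  keys <- expand.grid(location_id = c("CA", "CB"), year = 2020,
                      sex = c("male", "female"), age_start = c(15, 40),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys$age_end <- keys$age_start + 25
  set.seed(3)
  cov <- list(keys = keys, draws = matrix(runif(8 * 10), 8, 10))
  prev <- prevalence_surface(keys, matrix(rexp(8 * 10, 1 / 100), 8, 10))
  tr <- treated_counts(cov, prev)
  for (i in 1:8) for (d in 1:10) {
    expect_identical(tr$draws[i, d], cov$draws[i, d] * prev$draws[i, d])
  }
  expect_identical(treated_counts(list(keys = keys,
                                       draws = matrix(0, 8, 10)),
                                  prev)$draws, matrix(0, 8, 10))
  expect_error(treated_counts(list(keys = keys,
                                   draws = matrix(1, 8, 9)), prev),
               "draw-count mismatch")
})

test_that("hierarchy aggregation equals brute-force recursion, exactly", {
  h <- tiny_hierarchy()
  ctr <- h$location_id[h$level == "country"]
  keys <- expand.grid(location_id = ctr, year = c(2000, 2021),
                      sex = c("male", "female"), age_start = 15,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys$age_end <- 100
  set.seed(4)
  counts <- list(keys = keys,
                 draws = matrix(rexp(nrow(keys) * 20, 1 / 50),
                                nrow(keys), 20))
  agg <- aggregate_hierarchy(counts, h)
  for (node in c("G", "SR1", "R2a")) {
    members <- intersect(descendants(h, node), ctr)
    for (yr in c(2000, 2021)) for (sx in c("male", "female")) {
      want <- colSums(counts$draws[keys$location_id %in% members &
                                     keys$year == yr & keys$sex == sx, ,
                                   drop = FALSE])
      sel <- agg$keys$location_id == node & agg$keys$year == yr &
        agg$keys$sex == sx
      expect_equal(as.vector(agg$draws[sel, ]), want, tolerance = 1e-12)
    }
  }
  # single-child chains pass through unchanged
  sel_r1b <- agg$keys$location_id == "R1b"
  sel_cc <- counts$keys$location_id == "CC"
  o <- order(agg$keys$year[sel_r1b], agg$keys$sex[sel_r1b])
  o2 <- order(keys$year[sel_cc], keys$sex[sel_cc])
  expect_equal(agg$draws[which(sel_r1b)[o], ],
               counts$draws[which(sel_cc)[o2], ])
  # a missing country is an error naming it
  broken <- list(keys = keys[keys$location_id != "CD", ],
                 draws = counts$draws[keys$location_id != "CD", ])
  expect_error(aggregate_hierarchy(broken, h), "CD")
})

test_that("draw summaries use the mean and 2.5/97.5 type-7 percentiles", {
  s <- summarize_draws(as.numeric(1:500))
  expect_equal(unname(s), c(250.5, 13.475, 487.525))
  expect_equal(unname(summarize_draws(rep(3.2, 10))), rep(3.2, 3))
  expect_error(summarize_draws(1), "at least 2")
  # one wild value moves the mean but not the upper percentile's order
  x <- c(rep(1, 499), 1e6)
  s2 <- summarize_draws(x)
  expect_gt(s2[["mean"]], 1)
  expect_equal(s2[["upper"]], stats::quantile(x, 0.975, names = FALSE))
  m <- summarize_draws(rbind(as.numeric(1:500), rep(2, 500)))
  expect_equal(m[1, ], c(mean = 250.5, lower = 13.475, upper = 487.525))
})

test_that("standardisation is the per-draw weighted stratum sum", {
  cov <- draws_table("G", 2021, c("male", "female"), c(15, 15), c(100, 100),
                     rbind(rep(0.2, 5), rep(0.4, 5)))
  w <- data.frame(sex = c("male", "female"), age_start = 15, age_end = 100,
                  weight = c(0.5, 0.5))
  expect_equal(standardise_coverage(cov, w), rep(0.3, 5))
  w2 <- transform(w, weight = c(0, 1))
  expect_equal(standardise_coverage(cov, w2), rep(0.4, 5))
  expect_error(standardise_coverage(cov, transform(w, weight = c(0.5, 0.6))),
               "sum to 1")
  # random fixture equals the dot product oracle
  set.seed(9)
  cov3 <- draws_table("G", 2021, rep(c("male", "female"), 3),
                      rep(c(15, 40, 60), each = 2),
                      rep(c(40, 60, 100), each = 2),
                      matrix(runif(6 * 8), 6, 8))
  wts <- runif(6); wts <- wts / sum(wts)
  w3 <- data.frame(sex = cov3$keys$sex, age_start = cov3$keys$age_start,
                   age_end = cov3$keys$age_end, weight = wts)
  expect_equal(standardise_coverage(cov3, w3),
               as.vector(wts %*% cov3$draws))
})

test_that("percent change is computed per draw", {
  expect_equal(percent_change(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(percent_change(rep(0.10, 4), rep(0.11, 4)), rep(10, 4))
  expect_error(percent_change(c(0, 1), c(1, 1)), "zeros")
})

test_that("per-draw treated counts are conserved up the hierarchy", {
  cfg <- world_config(seed = 21, n_draws = 40)
  w <- generate_world(cfg)
  est <- generate_surveys(w, cfg)
  est <- est[est$sex != "both", ]
  fit <- run_cascade(est, w$hierarchy, w$haqi,
                     cascade_config(seed = 21, n_draws = 40))
  cov <- coverage_draws(fit, years = c(2000, 2021), n_draws = 40)
  sel <- w$prevalence$keys$year %in% c(2000, 2021)
  prev <- prevalence_surface(w$prevalence$keys[sel, ],
                             w$prevalence$draws[sel, ])
  tr <- aggregate_hierarchy(treated_counts(cov, prev), w$hierarchy)
  ctr <- w$hierarchy$location_id[w$hierarchy$level == "country"]
  glob <- colSums(tr$draws[tr$keys$location_id == "G", ])
  by_ctr <- colSums(tr$draws[tr$keys$location_id %in% ctr, ])
  expect_equal(glob, by_ctr, tolerance = 1e-12)
  srs <- w$hierarchy$location_id[w$hierarchy$level == "super_region"]
  expect_equal(glob, colSums(tr$draws[tr$keys$location_id %in% srs, ]),
               tolerance = 1e-12)
})

test_that("reported proportions are per-draw ratios, not ratios of means", {
  # two draws engineered so the two definitions disagree
  tr <- draws_table("CA", 2021, "female", 15, 100, rbind(c(10, 90)))
  ca <- draws_table("CA", 2021, "female", 15, 100, rbind(c(100, 100)))
  per_draw <- summarize_draws(100 * tr$draws[1, ] / ca$draws[1, ])
  ratio_of_means <- 100 * mean(tr$draws[1, ]) / mean(ca$draws[1, ])
  expect_equal(per_draw[["mean"]], 50)
  expect_equal(ratio_of_means, 50)  # same here, but spread differs:
  tr2 <- draws_table("CA", 2021, "female", 15, 100, rbind(c(10, 90)))
  ca2 <- draws_table("CA", 2021, "female", 15, 100, rbind(c(50, 200)))
  pd <- mean(100 * tr2$draws[1, ] / ca2$draws[1, ])   # (20 + 45) / 2
  rm <- 100 * mean(tr2$draws[1, ]) / mean(ca2$draws[1, ])  # 50/125
  expect_equal(pd, 32.5)
  expect_equal(rm, 40)
  h <- location_hierarchy(data.frame(
    location_id = c("G", "S", "R", "CA"), name = c("g", "s", "r", "c"),
    level = c("global", "super_region", "region", "country"),
    parent_id = c(NA, "G", "S", "R")))
  res <- build_results(draws_table("CA", 2021, c("male", "female"),
                                   15, 100, rbind(c(0.2, 0.45), c(0.2, 0.45))),
                       prevalence_surface(data.frame(
                         location_id = "CA", year = 2021,
                         sex = c("male", "female"), age_start = 15,
                         age_end = 100), rbind(c(50, 200), c(50, 200))),
                       h, years = 2021)
  got <- res$proportion_mean[res$location_id == "CA" & res$sex == "both"]
  expect_equal(got, mean(100 * c(0.2, 0.45)))  # per-draw definition
})

test_that("shifting case weights can reverse increasing stratum trends", {
  # two regions, each with *increasing* treated proportion 2000 -> 2021,
  # but the low-coverage region grows much faster in case counts
  h <- tiny_hierarchy()
  ctr <- c("CA", "CB", "CC", "CD", "CE")
  nd <- 4
  mk <- function(year, prop_hi, prop_lo, cases_hi, cases_lo) {
    cases <- c(cases_hi, rep(cases_lo / 4, 4))
    prop <- c(prop_hi, rep(prop_lo, 4))
    list(cov = draws_table(ctr, year, "female", 15, 100,
                           matrix(prop, 5, nd)),
         prev = prevalence_surface(
           data.frame(location_id = ctr, year = year, sex = "female",
                      age_start = 15, age_end = 100),
           matrix(cases, 5, nd)))
  }
  a <- mk(2000, prop_hi = 0.25, prop_lo = 0.02, cases_hi = 30, cases_lo = 120)
  b <- mk(2021, prop_hi = 0.27, prop_lo = 0.022, cases_hi = 41, cases_lo = 300)
  prop_at <- function(x, node) {
    tr <- aggregate_hierarchy(treated_counts(x$cov, x$prev), h)
    ca <- aggregate_hierarchy(list(keys = x$prev$keys, draws = x$prev$draws), h)
    mean(colSums(tr$draws[tr$keys$location_id == node, , drop = FALSE]) /
           colSums(ca$draws[ca$keys$location_id == node, , drop = FALSE]))
  }
  # every stratum increases ...
  expect_gt(0.27, 0.25); expect_gt(0.022, 0.02)
  # ... yet the aggregate falls
  expect_lt(prop_at(b, "G"), prop_at(a, "G"))
})
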