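test_that("pair building matches on study, location, sex, age band and year", {
  h <- tiny_hierarchy()
  hq <- flat_haqi("CA", value = 80)
  e <- rbind(est_row("E1", indicator = "MAT", mean = 0.10),
             est_row("E2", indicator = "antidepressant", mean = 0.15))
  p <- build_matched_pairs(e, hq)
  expect_identical(nrow(p), 1L)
  expect_equal(p$logit_diff, logit(0.15) - logit(0.10))
  expect_equal(p$se_diff,
               sqrt(logit_se(0.15, 0.02)^2 + logit_se(0.10, 0.02)^2))
  expect_equal(p$haqi_centered, -20)
  # differing sex -> no pair
  e2 <- rbind(est_row("E1", sex = "male", indicator = "MAT"),
              est_row("E2", sex = "female", indicator = "antidepressant"))
  p2 <- build_matched_pairs(e2, hq)
  expect_identical(nrow(p2), 0L)
  expect_identical(attr(p2, "n_unmatched"), 1L)
})

test_that("pair enumeration equals the brute-force O(n^2) oracle", {
  set.seed(5)
  n <- 60
  e <- do.call(rbind, lapply(seq_len(n), function(i) {
    est_row(sprintf("E%02d", i),
            study_id = sample(c("S1", "S2", "S3"), 1),
            sex = sample(c("both", "male"), 1),
            age_start = sample(c(15, 25), 1), age_end = 99,
            year = sample(2008:2010, 1),
            indicator = sample(c("MAT", "antidepressant", "any_service"), 1),
            mean = runif(1, 0.05, 0.4))
  }))
  e$age_end <- e$age_start + 10
  hq <- flat_haqi("CA")
  got <- build_matched_pairs(e, hq)
  want <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (e$indicator[i] != "MAT" && e$indicator[j] == "MAT" &&
          e$study_id[i] == e$study_id[j] &&
          e$location_id[i] == e$location_id[j] &&
          e$sex[i] == e$sex[j] && e$age_start[i] == e$age_start[j] &&
          e$age_end[i] == e$age_end[j] && e$year[i] == e$year[j]) {
        want <- want + 1L
      }
    }
  }
  expect_identical(nrow(got), want)
})

test_that("null data yields coefficients indistinguishable from zero", {
  p <- simulate_pairs(31, bias_ad = 0, bias_any = 0, bias_any_haqi = 0,
                      outlier_frac = 0)
  f <- fit_crosswalk(p, trim_pct = 0, eliminate = FALSE)
  for (tm in .cw_terms <- c("beta_ad", "beta_any", "beta_any_haqi")) {
    expect_lt(abs(f$beta[tm]), 3 * f$se_beta[tm] + 1e-8)
  }
  # backward elimination on null data tends to the empty model
  f2 <- fit_crosswalk(p, trim_pct = 0)
  expect_lte(length(f2$included_terms), 3L)
})

test_that("crosswalk recovery: moderate replicates centre on the truth", {
  betas <- vapply(1:25, function(s) {
    f <- fit_crosswalk(simulate_pairs(400 + s), eliminate = FALSE)
    f$beta[["beta_ad"]]
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.18), 0.05)
})

test_that("trimming excludes ceil(5%) of pairs and reduces outlier damage", {
  err_t <- err_u <- numeric(20)
  for (s in 1:20) {
    p <- simulate_pairs(600 + s, outlier_frac = 0)
    k <- ceiling(0.08 * nrow(p))      # contaminate 8% upward
    p$logit_diff[seq_len(k)] <- p$logit_diff[seq_len(k)] + 1.5
    ft <- fit_crosswalk(p, trim_pct = 0.05, eliminate = FALSE)
    fu <- fit_crosswalk(p, trim_pct = 0, eliminate = FALSE)
    expect_identical(ft$n_trimmed, as.integer(ceiling(0.05 * nrow(p))))
    err_t[s] <- abs(ft$beta[["beta_ad"]] - 0.18)
    err_u[s] <- abs(fu$beta[["beta_ad"]] - 0.18)
  }
  expect_lt(mean(err_t), mean(err_u))
})

test_that("preconditions on the pair set are enforced", {
  p <- simulate_pairs(3)
  expect_error(fit_crosswalk(p[1:5, ]), "at least 10")
  expect_error(fit_crosswalk(p[p$indicator_alt == "antidepressant", ]),
               "both alternative indicators")
})

# crosswalk model with the reported bias-correction coefficients, used to
# check the adjustment arithmetic against closed forms
table_model <- function() {
  nm <- c("beta_ad", "beta_any", "beta_any_haqi")
  cv <- diag(1e-4, 3)
  dimnames(cv) <- list(nm, nm)
  structure(list(
    beta = c(beta_ad = 0.18, beta_any = 0.06, beta_any_haqi = -0.012),
    included_terms = nm, coef_cov = cv,
    tau2 = 0, trim_mask = logical(0), n_pairs = 63L, n_trimmed = 4L,
    trim_pct = 0.05), class = "crosswalk_model")
}

test_that("applying the crosswalk shifts logits by the indicator correction", {
  m <- table_model()
  hq <- flat_haqi("CA", value = 100)
  mat <- est_row("E1", indicator = "MAT")
  out <- apply_crosswalk(mat, m, hq)
  expect_equal(out$mean, mat$mean)
  expect_equal(out$se, mat$se)

  any100 <- est_row("E2", indicator = "any_service", mean = 0.2)
  o100 <- apply_crosswalk(any100, m, hq)
  expect_equal(logit(o100$mean), logit(0.2) - 0.06, tolerance = 1e-10)

  # at HAQI 80 the correction grows to 0.06 + (-0.012) * (-20) = 0.30
  o80 <- apply_crosswalk(any100, m, flat_haqi("CA", value = 80))
  expect_equal(logit(o80$mean), logit(0.2) - 0.30, tolerance = 1e-10)
})

test_that("the any-service correction increases monotonically as HAQI falls", {
  m <- table_model()
  shift <- vapply(c(95, 80, 60, 40), function(h) {
    o <- apply_crosswalk(est_row("E", indicator = "any_service", mean = 0.2),
                         m, flat_haqi("CA", value = h))
    logit(0.2) - logit(o$mean)
  }, numeric(1))
  expect_true(all(diff(shift) > 0))
})

test_that("crosswalked uncertainty never shrinks", {
  p <- simulate_pairs(77)
  f <- fit_crosswalk(p)
  e <- rbind(est_row("E1", indicator = "antidepressant", mean = 0.2),
             est_row("E2", indicator = "any_service", mean = 0.15),
             est_row("E3", indicator = "MAT", mean = 0.1))
  out <- apply_crosswalk(e, f, flat_haqi("CA", value = 55))
  expect_true(all(logit_se(out$mean, out$se) >=
                    logit_se(out$mean_unadjusted, out$se_unadjusted) - 1e-12))
})
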