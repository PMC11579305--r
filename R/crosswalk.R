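#' Build matched indicator pairs for the crosswalk
#'
#' Pairs each antidepressant-use or any-service estimate with a minimally-
#' adequate-treatment (MAT) estimate from the same study reported for the
#' same location, sex, exact age band, and year. The logit difference
#' between the two members is the unit of crosswalk inference; its variance
#' is the sum of the two delta-method logit variances. The country-year
#' HAQI (centred at 100) is attached as the effect modifier.
#'
#' @param estimates Validated estimate data frame.
#' @param haqi HAQI table (`location_id`, `year`, `haqi`).
#' @return Data frame of matched pairs: `pair_id`, `study_id`,
#'   `location_id`, `sex`, `age_start`, `age_end`, `year`, `indicator_alt`,
#'   `logit_diff`, `se_diff`, `haqi_centered`, plus the member estimate
#'   ids. Alt estimates without a MAT partner are silently unmatched; the
#'   attribute `n_unmatched` reports how many.
#' @export
build_matched_pairs <- function(estimates, haqi) {
  key <- function(d) paste(d$study_id, d$location_id, d$sex, d$age_start,
                           d$age_end, d$year, sep = "|")
  mat <- estimates[estimates$indicator == "MAT", , drop = FALSE]
  alt <- estimates[estimates$indicator != "MAT", , drop = FALSE]
  mk <- key(mat)
  ak <- key(alt)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(alt))) {
    partners <- which(mk == ak[i])
    for (j in partners) {
      la <- logit(alt$mean[i]); lm <- logit(mat$mean[j])
      sa <- logit_se(alt$mean[i], alt$se[i])
      sm <- logit_se(mat$mean[j], mat$se[j])
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = alt$study_id[i], location_id = alt$location_id[i],
        sex = alt$sex[i], age_start = alt$age_start[i],
        age_end = alt$age_end[i], year = alt$year[i],
        indicator_alt = alt$indicator[i],
        alt_estimate_id = alt$estimate_id[i],
        mat_estimate_id = mat$estimate_id[j],
        logit_diff = la - lm, se_diff = sqrt(sa^2 + sm^2),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(pair_id = character(0))
    attr(out, "n_unmatched") <- nrow(alt)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$haqi_centered <- haqi_lookup(haqi, out$location_id, out$year) - 100
  out$pair_id <- sprintf("P%04d", seq_len(nrow(out)))
  out <- out[, c("pair_id", "study_id", "location_id", "sex", "age_start",
                 "age_end", "year", "indicator_alt", "alt_estimate_id",
                 "mat_estimate_id", "logit_diff", "se_diff", "haqi_centered")]
  attr(out, "n_unmatched") <- sum(!ak %in% mk)
  out
}

.cw_terms <- c("beta_ad", "beta_any", "beta_any_haqi")

.cw_design <- function(pairs, terms = .cw_terms) {
  is_ad <- as.numeric(pairs$indicator_alt == "antidepressant")
  is_any <- as.numeric(pairs$indicator_alt == "any_service")
  X <- cbind(beta_ad = is_ad, beta_any = is_any,
             beta_any_haqi = is_any * pairs$haqi_centered)
  X[, terms, drop = FALSE]
}

#' Fit the trimmed network-meta-analysis crosswalk model
#'
#' Models the logit difference of each matched pair as an indicator bias:
#' `beta_ad` for antidepressant use, `beta_any + beta_any_haqi * (HAQI -
#' 100)` for any-service use, with study-level Gaussian random effects and
#' known pair variances. Estimation trims the `trim_pct` worst-fitting
#' pairs by likelihood contribution (see [fit_remr()]), then performs
#' backward elimination: terms are removed one at a time whenever removal
#' lowers the Bayesian information criterion, except that a main effect is
#' never removed while its HAQI interaction is retained; ties are broken by
#' dropping the term with the larger Wald p value. The final model is
#' refitted by REML on the retained pairs and terms.
#'
#' @param pairs Output of [build_matched_pairs()] (>= 10 rows, both
#'   alternative indicators represented).
#' @param trim_pct Trimming fraction, default 0.05.
#' @param eliminate Run BIC backward elimination (default `TRUE`). Set to
#'   `FALSE` to keep the full three-term model, e.g. in parameter-recovery
#'   experiments where selection-to-zero would be conflated with
#'   estimation error.
#' @return A list of class `"crosswalk_model"`: `beta` (named length-3
#'   vector, eliminated terms 0), `included_terms`, `coef_cov` (retained
#'   terms), `tau2`, `trim_mask` (by `pair_id`), `fit_stats`, `n_pairs`.
#' @export
fit_crosswalk <- function(pairs, trim_pct = 0.05, eliminate = TRUE) {
  if (nrow(pairs) < 10L) {
    stop("crosswalk needs at least 10 matched pairs, got ", nrow(pairs),
         call. = FALSE)
  }
  if (!all(c("antidepressant", "any_service") %in% pairs$indicator_alt)) {
    stop("both alternative indicators must be represented in the pairs",
         call. = FALSE)
  }
  y <- pairs$logit_diff
  se <- pairs$se_diff
  study <- pairs$study_id

  # trim under the full model, then hold the inclusion mask fixed
  full <- fit_remr(y, .cw_design(pairs), se, study, trim_pct = trim_pct)
  inc <- full$included

  fit_terms <- function(terms, method) {
    fit_remr(y[inc], .cw_design(pairs[inc, , drop = FALSE], terms), se[inc],
             study[inc], trim_pct = 0, method = method)
  }

  terms <- .cw_terms
  current <- fit_terms(terms, "ml")
  while (eliminate) {
    droppable <- terms
    if ("beta_any_haqi" %in% terms) {
      droppable <- setdiff(droppable, "beta_any")
    }
    if (!length(droppable) || length(terms) == 0L) break
    cand <- lapply(droppable, function(tm) fit_terms(setdiff(terms, tm), "ml"))
    bics <- vapply(cand, `[[`, numeric(1), "bic")
    best <- which(bics == min(bics))
    if (length(best) > 1L) {  # tie: drop the least significant term
      pv <- vapply(droppable[best], function(tm) current$p_value[tm], numeric(1))
      best <- best[which.max(pv)]
    }
    if (min(bics) < current$bic) {
      terms <- setdiff(terms, droppable[best[1L]])
      current <- cand[[best[1L]]]
    } else break
  }

  final <- fit_terms(terms, "reml")
  beta <- stats::setNames(numeric(3), .cw_terms)
  beta[terms] <- final$beta
  trim_mask <- stats::setNames(inc, pairs$pair_id)
  structure(list(
    beta = beta, included_terms = terms, coef_cov = final$vcov,
    tau2 = final$tau2, trim_mask = trim_mask,
    se_beta = final$se_beta, p_value = final$p_value,
    fit_stats = list(loglik = final$loglik, loglik_ml = final$loglik_ml,
                     bic = final$bic),
    n_pairs = nrow(pairs), n_trimmed = sum(!inc), trim_pct = trim_pct),
    class = "crosswalk_model")
}

#' Adjust estimates to the MAT reference level
#'
#' MAT rows pass through unchanged. Antidepressant-use rows are shifted on
#' the logit scale by `-beta_ad`; any-service rows by `-(beta_any +
#' beta_any_haqi * (HAQI - 100))` using the row's country-year HAQI
#' (eliminated terms contribute nothing). The sampling variance of the
#' correction, from the coefficient covariance, is added to the row's logit
#' variance, so adjusted standard errors never shrink. Results are returned
#' on the proportion scale with delta-method standard errors.
#'
#' @param estimates Validated estimate data frame.
#' @param model A fitted [fit_crosswalk()] model.
#' @param haqi HAQI table (needed when the HAQI interaction is retained).
#' @return The estimate data frame with adjusted `mean` and `se`, plus
#'   columns `crosswalked` (logical) and the original values in
#'   `mean_unadjusted`, `se_unadjusted`.
#' @export
apply_crosswalk <- function(estimates, model, haqi = NULL) {
  out <- estimates
  out$mean_unadjusted <- out$mean
  out$se_unadjusted <- out$se
  out$crosswalked <- out$indicator != "MAT"
  idx <- which(out$crosswalked)
  if (!length(idx)) return(out)

  need_haqi <- "beta_any_haqi" %in% model$included_terms &&
    any(out$indicator[idx] == "any_service")
  hc <- numeric(nrow(out))
  if (need_haqi) {
    if (is.null(haqi)) stop("HAQI table required for any-service adjustment",
                            call. = FALSE)
    ai <- idx[out$indicator[idx] == "any_service"]
    hc[ai] <- haqi_lookup(haqi, out$location_id[ai], out$year[ai]) - 100
  }
  for (i in idx) {
    a <- c(beta_ad = as.numeric(out$indicator[i] == "antidepressant"),
           beta_any = as.numeric(out$indicator[i] == "any_service"),
           beta_any_haqi = as.numeric(out$indicator[i] == "any_service") * hc[i])
    a_ret <- a[model$included_terms]
    corr <- sum(a_ret * model$beta[model$included_terms])
    var_corr <- if (length(a_ret)) {
      as.numeric(a_ret %*% model$coef_cov %*% a_ret)
    } else 0
    lt <- logit(out$mean[i], what = out$estimate_id[i]) - corr
    lv <- logit_se(out$mean[i], out$se[i])^2 + var_corr
    p <- invlogit(lt)
    out$mean[i] <- p
    out$se[i] <- sqrt(lv) * p * (1 - p)
  }
  out
}
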