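#' Fit the proportion-female sex model
#'
#' Regresses logit coverage of bias-corrected estimates on the proportion
#' of cases that are female (`phi`), with study random effects and known
#' logit-scale sampling variances. The intercept is the all-male level
#' (`phi = 0`); the slope is the female-versus-male logit difference.
#' Sex-specific rows enter with `phi = 0` (male) or `1` (female); both-sex
#' rows with their reported `prop_female_cases`, imputed from the
#' prevalence surface when missing.
#'
#' @param estimates Crosswalk-adjusted estimate data frame.
#' @param prevalence Optional [prevalence_surface()] used to impute
#'   `prop_female_cases` for both-sex rows that lack it.
#' @param trim_pct Trimming fraction (default 0: no trimming).
#' @return A list of class `"sex_split_model"`: `beta0`, `beta1`,
#'   `coef_cov` (2x2), `tau2`, `n_used`.
#' @export
fit_sex_model <- function(estimates, prevalence = NULL, trim_pct = 0) {
  phi <- sex_model_phi(estimates, prevalence)
  if (length(unique(phi)) < 2L) {
    stop("proportion-female values are all identical; sex model is ",
         "rank-deficient", call. = FALSE)
  }
  y <- logit(estimates$mean, what = estimates$estimate_id)
  se <- logit_se(estimates$mean, estimates$se)
  X <- cbind(beta0 = 1, beta1 = phi)
  fit <- fit_remr(y, X, se, estimates$study_id, trim_pct = trim_pct)
  structure(list(beta0 = fit$beta[["beta0"]], beta1 = fit$beta[["beta1"]],
                 coef_cov = fit$vcov, tau2 = fit$tau2,
                 se_beta = fit$se_beta, p_value = fit$p_value,
                 trim_mask = fit$included, n_used = fit$n_used),
            class = "sex_split_model")
}

#' @rdname fit_sex_model
#' @return `sex_model_phi()`: the proportion-female predictor for each row.
#' @export
sex_model_phi <- function(estimates, prevalence = NULL) {
  phi <- ifelse(estimates$sex == "male", 0,
                ifelse(estimates$sex == "female", 1,
                       estimates$prop_female_cases))
  miss <- which(!is.finite(phi))
  for (i in miss) {
    if (is.null(prevalence)) {
      stop("both-sex row ", estimates$estimate_id[i], " has no ",
           "prop_female_cases and no prevalence surface to impute from",
           call. = FALSE)
    }
    phi[i] <- prop_female_from_prevalence(
      prevalence, estimates$location_id[i], estimates$year[i],
      estimates$age_start[i], estimates$age_end[i])
  }
  phi
}

#' Solve the sex split for one both-sex proportion
#'
#' Finds the male proportion `p_m` such that the case-weighted mixture
#' `(1 - phi) * p_m + phi * p_f` reproduces the observed both-sex
#' proportion `p_b`, where the female proportion is linked by the model's
#' logit offset, `p_f = invlogit(logit(p_m) + beta1)`. Solved by bisection
#' on `logit(p_m)` to a residual below `1e-10`.
#'
#' @param p_b Observed both-sex proportion in (0, 1).
#' @param phi Proportion of cases that are female, in \[0, 1\].
#' @param beta1 Female-male logit difference.
#' @return Named vector `c(p_m, p_f)`.
#' @export
solve_sex_split <- function(p_b, phi, beta1) {
  stopifnot(p_b > 0, p_b < 1, phi >= 0, phi <= 1)
  if (phi == 0) return(c(p_m = p_b, p_f = invlogit(logit(p_b) + beta1)))
  if (phi == 1) return(c(p_m = invlogit(logit(p_b) - beta1), p_f = p_b))
  f <- function(lm) (1 - phi) * invlogit(lm) +
    phi * invlogit(lm + beta1) - p_b
  lo <- logit(p_b) - abs(beta1) - 1
  hi <- logit(p_b) + abs(beta1) + 1
  while (f(lo) > 0) lo <- lo - 1
  while (f(hi) < 0) hi <- hi + 1
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < 1e-10) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  p_m <- invlogit(mid)
  c(p_m = p_m, p_f = invlogit(mid + beta1))
}

#' Split both-sex estimates into sex-specific estimates
#'
#' Each both-sex row is replaced by a male and a female row whose
#' case-weighted average reproduces the observed both-sex mean exactly
#' (see [solve_sex_split()]). Sex-specific input rows pass through
#' unchanged. Split uncertainty: each output's logit variance is the
#' parent logit variance plus the slope's sampling variance scaled by
#' `|phi - 1[sex = female]|`, so uncertainty never shrinks and is shared
#' symmetrically around the aggregate. Rows with `phi` exactly 0 or 1 are
#' reassigned wholly to the present sex and no counterpart row is emitted.
#'
#' @param estimates Crosswalk-adjusted estimate data frame.
#' @param model A fitted [fit_sex_model()].
#' @param prevalence Optional [prevalence_surface()] for `phi` imputation.
#' @return Estimate data frame with `sex` only `"male"`/`"female"`; split
#'   rows carry `split_from` (the parent `estimate_id`).
#' @export
split_both_sex <- function(estimates, model, prevalence = NULL) {
  est <- estimates
  est$split_from <- NA_character_
  keep <- est[est$sex != "both", , drop = FALSE]
  both <- est[est$sex == "both", , drop = FALSE]
  if (!nrow(both)) {
    rownames(keep) <- NULL
    return(keep)
  }
  phi <- sex_model_phi(both, prevalence)
  v_b1 <- model$coef_cov["beta1", "beta1"]
  pieces <- vector("list", nrow(both))
  for (i in seq_len(nrow(both))) {
    row <- both[i, , drop = FALSE]
    if (phi[i] <= 0 || phi[i] >= 1) {
      row$sex <- if (phi[i] >= 1) "female" else "male"
      row$prop_female_cases <- phi[i]
      row$split_from <- row$estimate_id
      pieces[[i]] <- row
      next
    }
    sol <- solve_sex_split(row$mean, phi[i], model$beta1)
    lv <- logit_se(row$mean, row$se)^2
    mk <- function(sex, p) {
      r <- row
      r$sex <- sex
      r$mean <- p
      v <- lv + v_b1 * abs(phi[i] - (sex == "female"))
      r$se <- sqrt(v) * p * (1 - p)
      r$sample_size <- row$sample_size *
        if (sex == "female") phi[i] else 1 - phi[i]
      r$prop_female_cases <- phi[i]
      r$estimate_id <- paste0(row$estimate_id, "_", substr(sex, 1, 1))
      r$split_from <- row$estimate_id
      r
    }
    pieces[[i]] <- rbind(mk("male", sol[["p_m"]]), mk("female", sol[["p_f"]]))
  }
  out <- rbind(keep, do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}
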