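#' Trimmed mixed-effects meta-regression on the logit scale
#'
#' The workhorse shared by the crosswalk and sex-split stages: a Gaussian
#' mixed-effects model for observations `y_i` with known sampling variances
#' `se_i^2`, a study-level random intercept with variance `tau2`, and an
#' optional trimmed maximum-likelihood estimator that excludes the fixed
#' fraction of observations contributing worst to the likelihood.
#'
#' The marginal model is `y ~ N(X beta, V)` with
#' `V = diag(se^2) + tau2 * Z Z'` where `Z` indicates study membership.
#' `tau2` is estimated by restricted maximum likelihood (or ML, used for
#' BIC-based model comparison) via a one-dimensional profile; `beta` is the
#' generalized-least-squares solution at the profiled `tau2`.
#'
#' Trimming iterates: fit on the currently included set; score *every*
#' observation by its marginal negative log-likelihood contribution
#' `0.5 log(2 pi (se_i^2 + tau2)) + 0.5 r_i^2 / (se_i^2 + tau2)`; exclude
#' the `ceil(trim_pct * n)` worst; refit; stop when the excluded set is
#' stable (or after `max_iter` passes).
#'
#' @param y Numeric response (logit differences or logit proportions).
#' @param X Design matrix (no implicit intercept).
#' @param se Known sampling standard errors, > 0.
#' @param study Study identifiers (random-intercept grouping).
#' @param trim_pct Fraction of observations to trim (0 disables trimming).
#' @param method `"reml"` (default) or `"ml"`.
#' @param tau2_fixed Optional fixed value for `tau2` (skips profiling).
#' @param max_iter Maximum trimming passes.
#' @return A list of class `"remr_fit"`: `beta`, `vcov`, `tau2`,
#'   `included` (logical inclusion mask), `loglik` (at `method`),
#'   `loglik_ml`, `bic`, `se_beta`, `p_value`, `n_used`, `converged`.
#' @export
fit_remr <- function(y, X, se, study, trim_pct = 0, method = c("reml", "ml"),
                     tau2_fixed = NULL, max_iter = 100L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(se) == n, length(study) == n, all(se > 0))
  if (n <= ncol(X)) stop("more coefficients than observations", call. = FALSE)
  study <- as.character(study)

  k_trim <- if (trim_pct > 0) ceiling(trim_pct * n) else 0L
  included <- rep(TRUE, n)
  converged <- TRUE
  for (iter in seq_len(if (k_trim > 0) max_iter else 1L)) {
    fit <- .remr_core(y[included], X[included, , drop = FALSE], se[included],
                      study[included], method, tau2_fixed)
    if (k_trim == 0L) break
    r <- y - as.vector(X %*% fit$beta)
    v <- se^2 + fit$tau2
    nll <- 0.5 * log(2 * pi * v) + 0.5 * r^2 / v
    worst <- order(nll, decreasing = TRUE)[seq_len(k_trim)]
    new_included <- rep(TRUE, n)
    new_included[worst] <- FALSE
    if (identical(new_included, included)) break
    included <- new_included
    if (iter == max_iter) {
      converged <- FALSE
      warning("trimming did not stabilise after ", max_iter, " iterations")
    }
  }
  fit <- .remr_core(y[included], X[included, , drop = FALSE], se[included],
                    study[included], method, tau2_fixed)
  ml <- .remr_core(y[included], X[included, , drop = FALSE], se[included],
                   study[included], "ml", tau2_fixed)
  n_used <- sum(included)
  p <- ncol(X)
  se_beta <- sqrt(diag(fit$vcov))
  z <- fit$beta / se_beta
  structure(list(
    beta = fit$beta, vcov = fit$vcov, tau2 = fit$tau2, included = included,
    loglik = fit$loglik, loglik_ml = ml$loglik,
    bic = -2 * ml$loglik + (p + 1) * log(n_used),
    se_beta = se_beta, p_value = 2 * stats::pnorm(-abs(z)),
    n_used = n_used, converged = converged, method = method),
    class = "remr_fit")
}

# GLS at profiled tau2; dense V is fine at meta-analytic sample sizes
.remr_core <- function(y, X, se, study, method, tau2_fixed) {
  n <- length(y)
  Z <- outer(study, unique(study), `==`) * 1
  S <- tcrossprod(Z)  # 1 where same study

  p <- ncol(X)
  crit <- function(tau2) {
    V <- diag(se^2, n) + tau2 * S
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    if (p > 0) {
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
      XtViX <- crossprod(X, Vi_X)
      beta <- solve(XtViX, crossprod(X, Vi_y))
      r <- y - as.vector(X %*% beta)
      logdetXtViX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    } else {
      r <- y
      logdetXtViX <- 0
    }
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    quad <- sum(r * Vi_r)
    if (method == "reml") {
      0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXtViX + quad)
    } else {
      0.5 * (n * log(2 * pi) + logdetV + quad)
    }
  }

  if (!is.null(tau2_fixed)) {
    tau2 <- tau2_fixed
  } else {
    ub <- max(stats::var(y), max(se^2)) * 10 + 1e-8
    opt <- stats::optimize(crit, c(0, ub), tol = 1e-8)
    # compare against the tau2 = 0 boundary explicitly
    tau2 <- if (crit(0) <= opt$objective) 0 else opt$minimum
  }
  if (p > 0) {
    V <- diag(se^2, n) + tau2 * S
    ch <- chol(V)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, Vi_X)
    beta <- as.vector(solve(XtViX, crossprod(X, Vi_y)))
    names(beta) <- colnames(X)
    vcov <- solve(XtViX)
    dimnames(vcov) <- list(colnames(X), colnames(X))
  } else {
    beta <- stats::setNames(numeric(0), character(0))
    vcov <- matrix(0, 0, 0)
  }
  list(beta = beta, vcov = vcov, tau2 = tau2, loglik = -crit(tau2))
}
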