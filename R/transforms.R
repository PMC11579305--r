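#' Logit and inverse-logit transforms
#'
#' All pooling in the package happens on the logit (log-odds) scale, where
#' treatment-coverage proportions are unbounded and indicator biases act
#' additively. `logit()` refuses boundary values; see [clamp_proportion()]
#' for the rule applied to raw survey proportions of exactly 0 or 1.
#'
#' @param p Proportion(s) strictly inside (0, 1).
#' @param x Real value(s).
#' @param what Optional label (e.g. an estimate id) used in error messages.
#' @return `logit()` returns `log(p / (1 - p))`; `invlogit()` its inverse.
#' @examples
#' logit(0.5)           # 0
#' invlogit(logit(0.18))
#' @export
logit <- function(p, what = NULL) {
  bad <- !is.finite(p) | p <= 0 | p >= 1
  if (any(bad)) {
    lab <- if (is.null(what)) which(bad)[1L] else what[bad][1L]
    stop("logit() requires proportions strictly in (0, 1); offending value ",
         format(p[bad][1L]), " at ", lab, call. = FALSE)
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
invlogit <- function(x) {
  # guarded form, stable for large |x|
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Delta-method standard error of a logit-transformed proportion
#'
#' @inheritParams logit
#' @param se_p Standard error(s) on the proportion scale, > 0.
#' @return `se_p / (p * (1 - p))`.
#' @examples
#' logit_se(0.5, 0.05)  # 0.2
#' @export
logit_se <- function(p, se_p, what = NULL) {
  bad <- !is.finite(p) | p <= 0 | p >= 1 | !is.finite(se_p) | se_p <= 0
  if (any(bad)) {
    lab <- if (is.null(what)) which(bad)[1L] else what[bad][1L]
    stop("logit_se() requires p in (0, 1) and se_p > 0; offending input at ",
         lab, call. = FALSE)
  }
  se_p / (p * (1 - p))
}

#' Convert a logit-scale coefficient to an odds ratio
#'
#' Coefficients in the crosswalk and sex models act additively on log-odds;
#' their exponentials are odds ratios, the scale on which results tables
#' usually report them.
#'
#' @param beta Finite logit-scale coefficient(s).
#' @return `exp(beta)`, unrounded.
#' @examples
#' coefficient_to_or(0.18)  # 1.20 to 2 d.p.
#' @export
coefficient_to_or <- function(beta) {
  if (any(!is.finite(beta))) stop("coefficient must be finite", call. = FALSE)
  exp(beta)
}

#' Clamp boundary proportions before logit transform
#'
#' Survey proportions of exactly 0 or 1 are replaced by `1/(4n)` and
#' `1 - 1/(4n)` (n = sample size), the smallest perturbation that keeps the
#' implied count error below a quarter of an observation. Interior values
#' pass through unchanged.
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param sample_size Positive sample size(s), required when any p is 0 or 1.
#' @return Proportions strictly inside (0, 1).
#' @export
clamp_proportion <- function(p, sample_size) {
  at0 <- p <= 0
  at1 <- p >= 1
  if (any(at0 | at1)) {
    n <- rep_len(sample_size, length(p))
    if (any(!is.finite(n[at0 | at1]) | n[at0 | at1] <= 0)) {
      stop("sample_size required to clamp boundary proportions", call. = FALSE)
    }
    p[at0] <- 1 / (4 * n[at0])
    p[at1] <- 1 - 1 / (4 * n[at1])
  }
  p
}
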