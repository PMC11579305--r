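#' Configuration of the location-cascade meta-regression
#'
#' The cascade fits a logit-coverage surface at every node of the location
#' hierarchy, from the global node down, with each parent's fitted
#' parameters acting as the Gaussian prior mean for its children. The
#' surface is piecewise linear on the logit scale over `age_knots`, plus a
#' fixed female-male offset and a per-unit HAQI coefficient (HAQI centred
#' at 100). Below age 1 coverage is a structural zero; on \[80, 100\] the
#' age profile is constrained non-increasing.
#'
#' @param age_knots Strictly increasing knots; first must be 1, last 100.
#' @param time_window_years Half-width of the data window: estimates inform
#'   the fit up to this many years before and after the prediction years.
#' @param years Prediction years.
#' @param n_draws Number of parameter draws per node.
#' @param prior_sd_by_level Named vector of prior SDs (logit scale) on a
#'   child's knot values and sex offset around the parent fit, by child
#'   level.
#' @param haqi_prior_scale Multiplier applied to the level prior SD for the
#'   HAQI coefficient (a per-unit-HAQI scale is ~25 times smaller than a
#'   logit-level scale).
#' @param shape_sd_frac,sex_sd_frac Fractions of the level prior SD allowed
#'   for, respectively, independent per-knot deviations from the parent age
#'   pattern and the deviation of the sex offset.
#' @param base_sd Vague prior SDs at the global node: `knots`, `sex`,
#'   `haqi`.
#' @param smooth_sd SD of the random-walk smoothing prior on differences of
#'   adjacent knot values at the global node.
#' @param seed Integer seed for draw generation.
#' @return A list of class `"cascade_config"`.
#' @export
cascade_config <- function(age_knots = c(1, 5, 10, 15, 20, 30, 40, 50, 60,
                                         70, 80, 100),
                           time_window_years = 7, years = 2000:2021,
                           n_draws = 500L,
                           prior_sd_by_level = c(super_region = 0.8,
                                                 region = 0.5,
                                                 country = 0.3),
                           haqi_prior_scale = 0.05,
                           shape_sd_frac = 0.25, sex_sd_frac = 0.5,
                           base_sd = c(knots = 10, sex = 2, haqi = 0.5),
                           smooth_sd = 1, seed = 1L) {
  stopifnot(all(diff(age_knots) > 0), age_knots[1] == 1,
            age_knots[length(age_knots)] == 100,
            all(prior_sd_by_level > 0), smooth_sd > 0, n_draws >= 2)
  structure(list(age_knots = age_knots,
                 time_window_years = time_window_years,
                 years = as.integer(years), n_draws = as.integer(n_draws),
                 prior_sd_by_level = prior_sd_by_level,
                 haqi_prior_scale = haqi_prior_scale,
                 shape_sd_frac = shape_sd_frac, sex_sd_frac = sex_sd_frac,
                 base_sd = base_sd,
                 smooth_sd = smooth_sd, seed = as.integer(seed)),
            class = "cascade_config")
}

# hat-function basis of the piecewise-linear age curve at point ages
.age_basis <- function(ages, knots) {
  ages <- pmin(pmax(ages, knots[1]), knots[length(knots)])
  K <- length(knots)
  B <- matrix(0, length(ages), K)
  seg <- findInterval(ages, knots, rightmost.closed = TRUE)
  seg[seg >= K] <- K - 1L
  w <- (ages - knots[seg]) / (knots[seg + 1L] - knots[seg])
  B[cbind(seq_along(ages), seg)] <- 1 - w
  B[cbind(seq_along(ages), seg + 1L)] <- w
  colnames(B) <- sprintf("v%g", knots)
  B
}

# exact average of the basis over an age band [a0, a1), clipped to [1, 100]
.band_basis <- function(a0, a1, knots) {
  a0 <- max(a0, knots[1]); a1 <- min(a1, knots[length(knots)])
  if (a1 <= a0) return(.age_basis(a0, knots))
  pts <- sort(unique(c(a0, a1, knots[knots > a0 & knots < a1])))
  B <- .age_basis(pts, knots)
  dx <- diff(pts)
  # trapezoid rule is exact for a piecewise-linear integrand
  avg <- colSums((B[-nrow(B), , drop = FALSE] +
                    B[-1, , drop = FALSE]) / 2 * dx) / (a1 - a0)
  matrix(avg, 1, dimnames = list(NULL, colnames(B)))
}

.cascade_par_names <- function(knots) c(sprintf("v%g", knots), "b_sex", "b_haqi")

# design matrix for estimate rows: band-averaged age basis, sex, HAQI
.cascade_design <- function(data, knots) {
  n <- nrow(data)
  B <- matrix(0, n, length(knots))
  for (i in seq_len(n)) {
    B[i, ] <- .band_basis(data$age_start[i], data$age_end[i], knots)
  }
  X <- cbind(B, b_sex = as.numeric(data$sex == "female"),
             b_haqi = data$haqi_centered)
  colnames(X) <- .cascade_par_names(knots)
  X
}

# prior (mean m, precision P) for a node given its parent fit
.cascade_prior <- function(parent, level, config) {
  knots <- config$age_knots
  K <- length(knots)
  p <- K + 2L
  if (is.null(parent)) {
    m <- rep(0, p)
    sd <- c(rep(config$base_sd[["knots"]], K), config$base_sd[["sex"]],
            config$base_sd[["haqi"]])
    P <- diag(1 / sd^2, p)
    # random-walk smoothing of adjacent knot values (global level only)
    D <- matrix(0, K - 1L, p)
    for (j in seq_len(K - 1L)) {
      D[j, j] <- -1 / config$smooth_sd
      D[j, j + 1L] <- 1 / config$smooth_sd
    }
    P <- P + crossprod(D)
  } else {
    m <- parent$theta
    sd_l <- config$prior_sd_by_level[[level]]
    # children inherit the parent age pattern: knot values deviate through
    # a common level shift (SD sd_l) plus small independent shape wiggles,
    # so the likelihood (which pins only band averages) cannot see-saw the
    # curve between knots
    sd_shape <- config$shape_sd_frac * sd_l
    Sigma_v <- sd_l^2 * matrix(1, K, K) + sd_shape^2 * diag(K)
    P <- matrix(0, p, p)
    P[1:K, 1:K] <- chol2inv(chol(Sigma_v))
    P[K + 1L, K + 1L] <- 1 / (config$sex_sd_frac * sd_l)^2
    P[K + 2L, K + 2L] <- 1 / (config$haqi_prior_scale * sd_l)^2
  }
  list(m = m, P = P)
}

#' Fit one node of the cascade
#'
#' Maximizes the penalized Gaussian log-likelihood of the node's logit
#' observations (age bands integrated by averaging the piecewise-linear
#' basis over the band) under a Gaussian prior centred at the parent's
#' fitted parameters. Because the model is linear in its parameters this
#' posterior mode is the closed-form ridge solution; with no data it
#' equals the prior mean exactly. If the fitted knot value at 100 exceeds
#' the value at 80, the fit is repeated with the two tied (the exact
#' active-set solution of the non-increasing constraint on \[80, 100\]).
#'
#' @param data Estimate rows for this node (may be empty); must carry a
#'   `haqi_centered` column.
#' @param parent Parent node fit, or `NULL` for the global node.
#' @param config A [cascade_config()].
#' @param level Hierarchy level of the node being fitted.
#' @param tau2 Between-study heterogeneity variance added to the Gaussian
#'   likelihood as a study-block covariance (rows from one study share one
#'   random level); estimated once at the global node by [run_cascade()].
#' @return A list: `theta` (named), `vcov`, `constrained`, `n_obs`.
#' @export
fit_node <- function(data, parent, config, level = "global", tau2 = 0) {
  knots <- config$age_knots
  pn <- .cascade_par_names(knots)
  pr <- .cascade_prior(parent, level, config)
  i80 <- match(sprintf("v%g", 80), pn)
  i100 <- match(sprintf("v%g", knots[length(knots)]), pn)
  if (is.na(i80)) i80 <- i100 - 1L  # last interior knot guards the tail

  if (is.null(data) || nrow(data) == 0L) {
    vc <- solve(pr$P)
    dimnames(vc) <- list(pn, pn)
    return(list(theta = stats::setNames(pr$m, pn), vcov = vc,
                constrained = FALSE, n_obs = 0L))
  }
  X <- .cascade_design(data, knots)
  y <- logit(data$mean, what = data$estimate_id)
  se2 <- logit_se(data$mean, data$se)^2
  if (tau2 > 0) {
    # study-block marginal covariance: correlated rows within one study
    # carry less independent information than their count suggests
    V <- diag(se2, nrow(data)) +
      tau2 * outer(data$study_id, data$study_id, `==`)
    ch <- chol(V)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    A <- crossprod(X, Vi_X) + pr$P
    b <- crossprod(X, Vi_y) + pr$P %*% pr$m
  } else {
    w <- 1 / se2
    A <- crossprod(X, X * w) + pr$P
    b <- crossprod(X, y * w) + pr$P %*% pr$m
  }
  theta <- solve(A, b)[, 1L]
  constrained <- FALSE
  if (theta[i100] > theta[i80]) {
    constrained <- TRUE
    p <- length(pn)
    Amap <- diag(p)[, -i100, drop = FALSE]   # reduced space: drop v(100)
    Amap[i100, i80 - (i80 > i100)] <- 1      # tie v(100) to v(80)
    Ar <- crossprod(Amap, A %*% Amap)
    br <- crossprod(Amap, b)
    phi <- solve(Ar, br)[, 1L]
    theta <- as.vector(Amap %*% phi)
    vcov <- Amap %*% solve(Ar) %*% t(Amap)
  } else {
    vcov <- solve(A)
  }
  names(theta) <- pn
  dimnames(vcov) <- list(pn, pn)
  list(theta = theta, vcov = vcov, constrained = constrained,
       n_obs = nrow(data))
}

#' Select the estimates informing a node at a prediction year
#'
#' @param estimates Estimate data frame.
#' @param hierarchy A [location_hierarchy()].
#' @param node Location id of the node.
#' @param year Prediction year.
#' @param window Half-width in years (inclusive at the boundary).
#' @return The subset of rows located at or below `node` whose collection
#'   year lies within `year +/- window`.
#' @export
assign_data <- function(estimates, hierarchy, node, year,
                        window = 7) {
  locs <- descendants(hierarchy, node)
  estimates[estimates$location_id %in% locs &
              abs(estimates$year - year) <= window, , drop = FALSE]
}

#' Run the full location cascade
#'
#' Fits the global node on all windowed data, then walks the hierarchy
#' depth-first, fitting each node once on the data at or below it with its
#' parent's fit as the prior. Estimates outside the data window around the
#' prediction-year range (`config$years` widened by
#' `config$time_window_years` on each side) are excluded; see
#' [assign_data()] for the per-year window rule.
#'
#' @param estimates Sex-specific, crosswalk-adjusted estimate data frame
#'   (country-level locations).
#' @param hierarchy A [location_hierarchy()].
#' @param haqi HAQI table.
#' @param config A [cascade_config()].
#' @return A list of class `"cascade_fit"`: `nodes` (per-location fits),
#'   `hierarchy`, `haqi`, `config`.
#' @export
run_cascade <- function(estimates, hierarchy, haqi,
                        config = cascade_config()) {
  if (any(estimates$sex == "both")) {
    stop("cascade input must be sex-specific; run split_both_sex() first",
         call. = FALSE)
  }
  bad <- setdiff(unique(estimates$location_id), hierarchy$location_id)
  if (length(bad)) {
    stop("estimate location(s) not in hierarchy: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  est <- estimates[estimates$year >= min(config$years) - config$time_window_years &
                     estimates$year <= max(config$years) + config$time_window_years,
                   , drop = FALSE]
  if (nrow(est)) {
    est$haqi_centered <- haqi_lookup(haqi, est$location_id, est$year) - 100
  }
  # between-study heterogeneity, estimated once at the global level by
  # REML with the same design, then held fixed down the cascade
  tau2 <- 0
  if (length(unique(est$study_id)) > 1L) {
    # full-rank saturated design: one level per observed age band, plus
    # sex and HAQI; richer than the spline so tau2 is not inflated by
    # curve misfit
    band <- factor(paste(est$age_start, est$age_end))
    Xg <- stats::model.matrix(~ 0 + band)
    Xg <- cbind(Xg, b_sex = as.numeric(est$sex == "female"),
                b_haqi = est$haqi_centered)
    if (nrow(est) > ncol(Xg) + 1L) {
      tau2 <- fit_remr(logit(est$mean), Xg, logit_se(est$mean, est$se),
                       est$study_id)$tau2
    }
  }
  nodes <- list()
  fit_rec <- function(id, parent_fit) {
    lvl <- hierarchy$level[hierarchy$location_id == id]
    sub <- est[est$location_id %in% descendants(hierarchy, id), , drop = FALSE]
    f <- tryCatch(fit_node(sub, parent_fit, config, lvl, tau2 = tau2),
                  error = function(e) {
                    stop("cascade fit failed at node '", id, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
    f$location_id <- id
    f$level <- lvl
    nodes[[id]] <<- f
    for (ch in children(hierarchy, id)) fit_rec(ch, f)
  }
  root <- hierarchy$location_id[hierarchy$level == "global"]
  fit_rec(root, NULL)
  structure(list(nodes = nodes, hierarchy = hierarchy, haqi = haqi,
                 config = config, tau2 = tau2), class = "cascade_fit")
}

# mean HAQI over the member countries of any node
.node_haqi <- function(fit, location_id, year) {
  h <- fit$hierarchy
  if (h$level[h$location_id == location_id] == "country") {
    return(haqi_lookup(fit$haqi, location_id, year))
  }
  ctr <- intersect(descendants(h, location_id),
                   h$location_id[h$level == "country"])
  vapply(year, function(yr) mean(haqi_lookup(fit$haqi, ctr, yr)), numeric(1))
}

#' Predict coverage from a cascade fit
#'
#' @param fit A [run_cascade()] result.
#' @param location_id Location id (any level; non-country nodes use the
#'   mean HAQI of their member countries).
#' @param age Ages in years; ages below 1 return exactly 0.
#' @param sex `"male"` or `"female"`.
#' @param year Calendar year (determines the HAQI).
#' @param haqi_value Optional explicit HAQI, overriding the lookup.
#' @return Coverage proportions.
#' @export
predict_coverage <- function(fit, location_id, age, sex, year,
                             haqi_value = NULL) {
  node <- fit$nodes[[location_id]]
  if (is.null(node)) stop("no fit for location '", location_id, "'",
                          call. = FALSE)
  n <- max(length(age), length(sex), length(year))
  age <- rep_len(age, n); sex <- rep_len(sex, n); year <- rep_len(year, n)
  hv <- if (is.null(haqi_value)) .node_haqi(fit, location_id, year) else
    rep_len(haqi_value, n)
  X <- cbind(.age_basis(age, fit$config$age_knots),
             b_sex = as.numeric(sex == "female"), b_haqi = hv - 100)
  out <- invlogit(as.vector(X %*% node$theta))
  out[age < 1] <- 0
  out
}

#' Draw parameter samples for a fitted node
#'
#' Multivariate-normal samples around the posterior mode with the node's
#' parameter covariance. A covariance that is not positive definite is
#' repaired by flooring its eigenvalues at 1e-10 (with a warning).
#'
#' @param node A node fit from [run_cascade()] (or [fit_node()]).
#' @param n_draws Number of samples.
#' @param seed Integer seed.
#' @return `n_draws` x `n_parameters` matrix.
#' @export
generate_draws <- function(node, n_draws, seed) {
  set.seed(seed)
  V <- node$vcov
  p <- ncol(V)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values)))) {
    warning("covariance not positive definite; flooring eigenvalues at 1e-10")
  }
  # a zero eigenvalue is expected when the tail constraint is active
  # (the covariance is then singular by construction, not broken)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 1e-10)), p)
  z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  sweep(tcrossprod(z, L), 2, node$theta, `+`)
}

#' Coverage draws on a prediction grid
#'
#' Generates parameter draws for each requested location and evaluates
#' coverage per draw over years, sexes, and age groups. Age groups are
#' evaluated as the band-average of the linear predictor (logit scale)
#' over the part of the group at or above age 1, back-transformed; groups
#' entirely below age 1 are exactly 0 in every draw.
#'
#' @param fit A [run_cascade()] result.
#' @param locations Location ids (default: all countries).
#' @param years Years (default: the config's prediction years).
#' @param age_groups Data frame with `age_start`, `age_end`.
#' @param n_draws,seed Draw count and seed (defaults from the config).
#' @return A list with `keys` (location_id, year, sex, age_start, age_end)
#'   and `draws` (matrix, one column per draw) — the same layout as a
#'   [prevalence_surface()].
#' @export
coverage_draws <- function(fit, locations = NULL, years = NULL,
                           age_groups = NULL, n_draws = NULL, seed = NULL) {
  h <- fit$hierarchy
  cfg <- fit$config
  if (is.null(locations)) locations <- h$location_id[h$level == "country"]
  if (is.null(years)) years <- cfg$years
  if (is.null(age_groups)) age_groups <- .prev_groups()
  if (is.null(n_draws)) n_draws <- cfg$n_draws
  if (is.null(seed)) seed <- cfg$seed
  knots <- cfg$age_knots
  grid <- expand.grid(year = years, sex = c("male", "female"),
                      g = seq_len(nrow(age_groups)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ab <- matrix(0, nrow(age_groups), length(knots))
  zero_grp <- age_groups$age_end <= 1
  frac_above1 <- pmin(1, pmax(0, (age_groups$age_end - pmax(age_groups$age_start, 1)) /
                                (age_groups$age_end - age_groups$age_start)))
  for (g in seq_len(nrow(age_groups))) {
    if (!zero_grp[g]) {
      ab[g, ] <- .band_basis(age_groups$age_start[g], age_groups$age_end[g],
                             knots)
    }
  }
  keys_list <- vector("list", length(locations))
  draws_list <- vector("list", length(locations))
  for (li in seq_along(locations)) {
    loc <- locations[li]
    node <- fit$nodes[[loc]]
    if (is.null(node)) stop("no fit for location '", loc, "'", call. = FALSE)
    th_draws <- generate_draws(node, n_draws,
                               seed + 7919L * (match(loc, h$location_id)))
    hv <- .node_haqi(fit, loc, grid$year)
    X <- cbind(ab[grid$g, , drop = FALSE],
               b_sex = as.numeric(grid$sex == "female"), b_haqi = hv - 100)
    lp <- X %*% t(th_draws)                     # cells x draws
    cov <- invlogit(lp) * frac_above1[grid$g]   # sub-1 part contributes 0
    cov[zero_grp[grid$g], ] <- 0
    keys_list[[li]] <- data.frame(location_id = loc, year = grid$year,
                                  sex = grid$sex,
                                  age_start = age_groups$age_start[grid$g],
                                  age_end = age_groups$age_end[grid$g],
                                  stringsAsFactors = FALSE)
    draws_list[[li]] <- cov
  }
  keys <- do.call(rbind, keys_list)
  rownames(keys) <- NULL
  draws <- do.call(rbind, draws_list)
  dimnames(draws) <- NULL
  list(keys = keys, draws = draws)
}
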