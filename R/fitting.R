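# Training machinery: normalized curve distance, endpoint-trend fitting with
# BIC family selection, AICc endpoint-combination selection, and the global
# multi-start fit of the four model constants.

# Composite Simpson weights on [a, b] with n points (n odd).
simpson_weights <- function(n, a, b) {
  if (n %% 2L == 0L) n <- n + 1L
  h <- (b - a) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}

# Evaluate set.seed(seed) around `code` without clobbering the caller's RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Normalized L2 distance between two survival curves
#'
#' The training distance metric: the root-integrated squared difference
#' between measured and predicted surviving fractions over the clinically
#' relevant dose window, normalized by the integral of the predicted
#' curve over the same window,
#' \deqn{L2 = \sqrt{\int_{0.5}^{4} (SF_m - SF_p)^2 dD} \Big/
#'            \int_{0.5}^{4} SF_p \, dD.}
#' Restricting the window to 0.5-4 Gy avoids weighting the fit towards
#' the low-dose shoulder, where biological uncertainty is largest. Note
#' the metric is not symmetric in its arguments: only the predicted curve
#' normalizes.
#'
#' @param measured,predicted Survival curves (anything with `alpha` and
#'   `beta` fields; typically [lqm] objects).
#' @param window Dose window \[Gy\], default `c(0.5, 4)`.
#' @param n_grid Number of Simpson quadrature points (odd; default 513,
#'   at which the quadrature error is far below 1e-6 for LQM curves).
#' @return Dimensionless distance >= 0.
#' @export
l2_curve_distance <- function(measured, predicted, window = c(0.5, 4),
                              n_grid = 513L) {
  D <- seq(window[1], window[2], length.out = n_grid)
  w <- simpson_weights(n_grid, window[1], window[2])
  sf_m <- exp(-(measured$alpha * D + measured$beta * D^2))
  sf_p <- exp(-(predicted$alpha * D + predicted$beta * D^2))
  den <- sum(w * sf_p)
  if (den <= 0) domain_error("degenerate predicted curve: zero integral")
  sqrt(sum(w * (sf_m - sf_p)^2)) / den
}

# Information criteria under the Gaussian-residual convention with additive
# constants dropped; only differences are meaningful.
ic_bic <- function(rss, n, k) n * log(max(rss, 1e-300) / n) + k * log(n)
ic_aicc <- function(rss, n, k) {
  n * log(max(rss, 1e-300) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit configuration
#'
#' Collects every knob of the training pipeline in one place so that runs
#' are reproducible from the stored configuration.
#'
#' @param seed RNG seed used for the multi-start jitter (and derived
#'   streams).
#' @param n_starts Number of random multi-start initial guesses; the
#'   published procedure used 10000, which remains the default.
#' @param jitter Half-width of the uniform relative jitter applied to the
#'   per-endpoint starting values (default 0.10, i.e. +/-10%).
#' @param grid_n Simpson points for the L2 distance (odd).
#' @param dose_window Dose window \[Gy\] of the L2 distance.
#' @param lower,upper Box bounds on (f1, m1, q1, f2).
#' @param maxit Iteration cap per local optimization.
#' @param rel_tol Relative objective tolerance of each local
#'   optimization (bounded PORT quasi-Newton via [stats::nlminb()]).
#' @param loocv_starts Multi-start budget for each leave-one-out refit.
#' @param selection_starts Multi-start budget per endpoint combination in
#'   [select_endpoint_combination()].
#' @param compute_covariance Estimate the Gauss-Newton parameter
#'   covariance after fitting.
#' @return A list of class `cirbe_fit_config`.
#' @export
fit_config <- function(seed = 1L,
                       n_starts = 10000L,
                       jitter = 0.10,
                       grid_n = 513L,
                       dose_window = c(0.5, 4),
                       lower = c(1e-6, 0, 0, 1e-6),
                       upper = c(1, 10, 1e-2, 1),
                       maxit = 500L,
                       rel_tol = 1e-12,
                       loocv_starts = 50L,
                       selection_starts = 5L,
                       compute_covariance = TRUE) {
  if (n_starts < 1L) usage_error("'n_starts' must be at least 1")
  if (grid_n %% 2L == 0L) grid_n <- grid_n + 1L
  structure(list(seed = as.integer(seed), n_starts = as.integer(n_starts),
                 jitter = jitter, grid_n = as.integer(grid_n),
                 dose_window = dose_window, lower = lower, upper = upper,
                 maxit = as.integer(maxit), rel_tol = rel_tol,
                 loocv_starts = as.integer(loocv_starts),
                 selection_starts = as.integer(selection_starts),
                 compute_covariance = compute_covariance),
            class = "cirbe_fit_config")
}

# Precompute everything the objective needs from a training dataset:
# photon endpoints, measured SF matrix on the quadrature grid, weights.
prep_fit_data <- function(dataset, config) {
  df <- as.data.frame(dataset)
  n <- nrow(df)
  a_x <- df$alpha_x
  b_x <- df$beta_x
  d3x <- (-a_x + sqrt(a_x^2 + 12 * b_x)) / (2 * b_x)
  d1x <- (-a_x + sqrt(a_x^2 + 4 * b_x)) / (2 * b_x)
  lin <- b_x == 0
  d3x[lin] <- 3 / a_x[lin]
  d1x[lin] <- 1 / a_x[lin]
  D <- seq(config$dose_window[1], config$dose_window[2],
           length.out = config$grid_n)
  w <- simpson_weights(config$grid_n, config$dose_window[1],
                       config$dose_window[2])
  M <- exp(-(outer(D, df$alpha_c) + outer(D^2, df$beta_c)))
  list(n = n, let = df$let_d, d3x = d3x, d1x = d1x,
       D = D, D2 = D^2, w = w, M = M)
}

# Per-record L2 distances for theta = (f1, m1, q1, f2); NA on infeasible
# geometry (non-positive or mis-ordered predicted endpoints).
per_record_l2 <- function(theta, prep) {
  f1 <- theta[1]; m1 <- theta[2]; q1 <- theta[3]; f2 <- theta[4]
  d3c <- prep$d3x / (1 + f1 * prep$let) + q1 * prep$let^2 + m1
  d1c <- prep$d1x / (1 + f2 * prep$let)
  if (any(d1c <= 0) || any(d3c <= d1c)) return(NULL)
  ab <- endpoint_ab_vec(d3c, d1c)
  sf_p <- exp(-(outer(prep$D, ab$alpha) + outer(prep$D2, ab$beta)))
  num <- sqrt(colSums(prep$w * (prep$M - sf_p)^2))
  den <- colSums(prep$w * sf_p)
  num / den
}

# Infeasible endpoint geometry (d_e3 <= d_e1) gets a large finite penalty so
# bounded quasi-Newton line searches can back out of it; a *start* that is
# infeasible is discarded before optimization (see fit_model).
objective_theta <- function(theta, prep, penalty = 1e10) {
  r <- per_record_l2(theta, prep)
  if (is.null(r)) return(penalty)
  sum(r^2)
}

# Branch-aware partial derivatives of (alpha, beta) with respect to the two
# endpoints. Piecewise-smooth: each record uses its active branch.
endpoint_ab_grad_vec <- function(d3, d1) {
  ab <- endpoint_ab_vec(d3, d1)
  a <- ab$alpha; b <- ab$beta; br <- ab$branch
  da3 <- da1 <- db3 <- db1 <- numeric(length(d3))

  u <- br == 1L
  if (any(u)) {
    K <- d1[u] * d3[u]^2 - d3[u] * d1[u]^2
    dK3 <- 2 * d1[u] * d3[u] - d1[u]^2
    dK1 <- d3[u]^2 - 2 * d3[u] * d1[u]
    na <- d3[u]^2 - 3 * d1[u]^2
    nb <- 3 * d1[u] - d3[u]
    da3[u] <- (2 * d3[u] * K - na * dK3) / K^2
    da1[u] <- (-6 * d1[u] * K - na * dK1) / K^2
    db3[u] <- (-K - nb * dK3) / K^2
    db1[u] <- (3 * K - nb * dK1) / K^2
  }
  z <- br == 2L
  if (any(z)) {
    Q <- d3[z]^2 + d1[z]^2
    na <- 3 * d3[z] + d1[z]
    da3[z] <- (3 * Q - na * 2 * d3[z]) / Q^2
    da1[z] <- (Q - na * 2 * d1[z]) / Q^2
  }
  w <- br == 3L
  if (any(w)) {
    Q <- d3[w]^4 + d1[w]^4
    nb <- 3 * d3[w]^2 + d1[w]^2
    db3[w] <- (6 * d3[w] * Q - nb * 4 * d3[w]^3) / Q^2
    db1[w] <- (2 * d1[w] * Q - nb * 4 * d1[w]^3) / Q^2
  }
  list(alpha = a, beta = b, branch = br,
       da3 = da3, da1 = da1, db3 = db3, db1 = db1)
}

# Objective and its analytic gradient in theta = (f1, m1, q1, f2).
# Returns list(value, grad); infeasible geometry gives the penalty with a
# zero gradient (starts are screened for feasibility before optimization).
obj_and_grad <- function(theta, prep, penalty = 1e10) {
  f1 <- theta[1]; m1 <- theta[2]; q1 <- theta[3]; f2 <- theta[4]
  let <- prep$let
  s1 <- 1 / (1 + f1 * let)
  s2 <- 1 / (1 + f2 * let)
  d3 <- prep$d3x * s1 + q1 * let^2 + m1
  d1 <- prep$d1x * s2
  if (any(d1 <= 0) || any(d3 <= d1)) {
    return(list(value = penalty, grad = rep(0, 4)))
  }
  g <- endpoint_ab_grad_vec(d3, d1)
  S <- exp(-(outer(prep$D, g$alpha) + outer(prep$D2, g$beta)))
  R <- prep$M - S
  wR_S <- prep$w * R * S
  T1 <- colSums(wR_S * prep$D)
  T2 <- colSums(wR_S * prep$D2)
  wS <- prep$w * S
  U1 <- colSums(wS * prep$D)
  U2 <- colSums(wS * prep$D2)
  den <- colSums(wS)
  num2 <- colSums(prep$w * R^2)
  num <- sqrt(num2)
  r <- num / den
  # d(r^2)/dalpha = 2 r dr/da with dnum/da = T1/num, dden/da = -U1
  pa <- 2 * (T1 / den^2 + num2 * U1 / den^3)
  pb <- 2 * (T2 / den^2 + num2 * U2 / den^3)
  # chain to theta: endpoint sensitivities per record
  dd3_f1 <- -prep$d3x * let * s1^2
  dd1_f2 <- -prep$d1x * let * s2^2
  grad <- c(
    sum((pa * g$da3 + pb * g$db3) * dd3_f1),
    sum(pa * g$da3 + pb * g$db3),
    sum((pa * g$da3 + pb * g$db3) * let^2),
    sum((pa * g$da1 + pb * g$db1) * dd1_f2))
  list(value = sum(r^2), grad = grad)
}

# nlminb calls objective and gradient separately; cache the last evaluation.
make_objective <- function(prep) {
  last_theta <- NULL
  last <- NULL
  ensure <- function(theta) {
    if (is.null(last_theta) || !identical(theta, last_theta)) {
      last <<- obj_and_grad(theta, prep)
      last_theta <<- theta
    }
    last
  }
  list(value = function(theta) ensure(theta)$value,
       grad = function(theta) ensure(theta)$grad)
}

#' Trend specification for one endpoint
#'
#' Pairs a slope family with an intercept family from the registry.
#'
#' @param slope,intercept Registered family ids (see
#'   [list_trend_families()]).
#' @param slope_par,intercept_par Numeric parameter vectors (may be
#'   omitted when the spec is only used as a fitting template).
#' @return A list of class `cirbe_trend_spec`.
#' @export
trend_spec <- function(slope, slope_par = NULL,
                       intercept = "zero", intercept_par = NULL) {
  sfam <- get_trend_family(slope, "slope")
  ifam <- get_trend_family(intercept, "intercept")
  if (!is.null(slope_par) && length(slope_par) != sfam$n_par) {
    usage_error("wrong number of slope parameters")
  }
  if (!is.null(intercept_par) && length(intercept_par) != ifam$n_par) {
    usage_error("wrong number of intercept parameters")
  }
  structure(list(slope = slope, slope_par = slope_par,
                 intercept = intercept, intercept_par = intercept_par,
                 k = sfam$n_par + ifam$n_par),
            class = "cirbe_trend_spec")
}

# Predicted endpoint doses under a trend spec: D_X * slope(LET) + intercept(LET).
trend_predict <- function(spec, d_x, let_d) {
  sfam <- get_trend_family(spec$slope, "slope")
  ifam <- get_trend_family(spec$intercept, "intercept")
  d_x * sfam$fun(let_d, spec$slope_par) + ifam$fun(let_d, spec$intercept_par)
}

# Measured endpoint doses at a survival level, from the stored carbon-ion
# LQM parameters. Records whose measured curve is degenerate are NA.
measured_endpoints <- function(dataset, endpoint_sf) {
  df <- as.data.frame(dataset)
  a <- df$alpha_c
  b <- df$beta_c
  L <- -log(endpoint_sf)
  out <- rep(NA_real_, nrow(df))
  ok <- a > 0 | b > 0
  quad <- ok & b > 0
  out[quad] <- (-a[quad] + sqrt(a[quad]^2 + 4 * b[quad] * L)) / (2 * b[quad])
  linear <- ok & b == 0
  out[linear] <- L / a[linear]
  out
}

photon_endpoints <- function(dataset, endpoint_sf) {
  df <- as.data.frame(dataset)
  a <- df$alpha_x
  b <- df$beta_x
  L <- -log(endpoint_sf)
  out <- numeric(nrow(df))
  quad <- b > 0
  out[quad] <- (-a[quad] + sqrt(a[quad]^2 + 4 * b[quad] * L)) / (2 * b[quad])
  out[!quad] <- L / a[!quad]
  out
}

#' Relative endpoint residuals under a trend specification
#'
#' Per record, the relative distance between the trend-predicted and the
#' measured carbon-ion endpoint dose at one survival level:
#' (D_pred - D_meas) / D_meas. Records with a non-positive or undefined
#' measured endpoint are skipped with a message.
#'
#' @param dataset A training dataset (see [read_training_csv()]).
#' @param endpoint_sf The survival level of the endpoint (e.g. `exp(-3)`).
#' @param spec A [trend_spec()] with parameter values filled in.
#' @return Numeric residual vector; attribute `skipped` lists skipped row
#'   indices.
#' @export
relative_endpoint_residuals <- function(dataset, endpoint_sf, spec) {
  d_meas <- measured_endpoints(dataset, endpoint_sf)
  d_x <- photon_endpoints(dataset, endpoint_sf)
  let <- as.data.frame(dataset)$let_d
  bad <- !is.finite(d_meas) | d_meas <= 0
  if (any(bad)) {
    message(sprintf("skipping %d record(s) with undefined measured endpoint", sum(bad)))
  }
  keep <- !bad
  d_pred <- trend_predict(spec, d_x[keep], let[keep])
  res <- (d_pred - d_meas[keep]) / d_meas[keep]
  attr(res, "skipped") <- which(bad)
  res
}

# Least-squares fit of one (slope, intercept) family pair for one endpoint.
fit_trend_pair <- function(d_x, d_meas, let, slope_id, intercept_id) {
  sfam <- get_trend_family(slope_id, "slope")
  ifam <- get_trend_family(intercept_id, "intercept")
  k <- sfam$n_par + ifam$n_par
  obj <- function(par) {
    sp <- par[seq_len(sfam$n_par)]
    ip <- par[sfam$n_par + seq_len(ifam$n_par)]
    denom_ok <- all(1 + sp[1] * let > 0)
    if (sfam$n_par > 0 && !denom_ok) return(1e10)
    d_pred <- d_x * sfam$fun(let, sp) + ifam$fun(let, ip)
    sum(((d_pred - d_meas) / d_meas)^2)
  }
  if (k == 0L) {
    return(list(par = numeric(0), rss = obj(numeric(0)), k = 0L))
  }
  start <- c(sfam$start, ifam$start)
  fit <- nlminb(start, obj,
                lower = c(sfam$lower, ifam$lower),
                upper = c(sfam$upper, ifam$upper),
                control = list(iter.max = 500, eval.max = 1000))
  list(par = fit$par, rss = fit$objective, k = k)
}

#' Fit the LET trend of one radiosensitivity endpoint
#'
#' For each (slope, intercept) family pair in the registry, fits the
#' trend D_SF,C = D_SF,X * Slope(LET) + Intercept(LET) by least squares
#' on the relative endpoint residuals, scores each pair by BIC (Gaussian
#' residual convention, BIC = n ln(RSS/n) + k ln(n)), and returns the
#' minimizing pair. BIC (rather than AICc) is used at this stage because
#' its stronger parameter penalty keeps each endpoint's description
#' minimal before several endpoints are composed into one model.
#'
#' @inheritParams relative_endpoint_residuals
#' @param slope_families,intercept_families Family ids to sweep (defaults:
#'   all registered).
#' @return List with `best` (a [trend_spec()] with fitted parameters),
#'   `bic`, `rss`, and `table` (one row per family pair, sorted by BIC).
#' @export
fit_endpoint_trend <- function(dataset, endpoint_sf,
                               slope_families = list_trend_families("slope"),
                               intercept_families = list_trend_families("intercept")) {
  d_meas <- measured_endpoints(dataset, endpoint_sf)
  d_x <- photon_endpoints(dataset, endpoint_sf)
  let <- as.data.frame(dataset)$let_d
  keep <- is.finite(d_meas) & d_meas > 0
  d_meas <- d_meas[keep]; d_x <- d_x[keep]; let <- let[keep]
  n <- length(d_meas)
  if (length(unique(let)) == 1L) {
    warning("all records share one LET value: slope and intercept are ",
            "confounded (design degeneracy)", call. = FALSE)
  }
  rows <- list()
  for (s in slope_families) {
    for (i in intercept_families) {
      fit <- fit_trend_pair(d_x, d_meas, let, s, i)
      if (n <= fit$k + 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        slope = s, intercept = i, k = fit$k, n = n, rss = fit$rss,
        bic = ic_bic(fit$rss, n, fit$k),
        par = I(list(fit$par)), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) convergence_error("no feasible trend family pair (n too small)")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$bic), ]
  bestrow <- tab[1, ]
  sfam <- get_trend_family(bestrow$slope, "slope")
  par <- bestrow$par[[1]]
  best <- trend_spec(bestrow$slope,
                     slope_par = par[seq_len(sfam$n_par)],
                     intercept = bestrow$intercept,
                     intercept_par = par[sfam$n_par + seq_len(bestrow$k - sfam$n_par)])
  list(best = best, bic = bestrow$bic, rss = bestrow$rss,
       table = tab[, c("slope", "intercept", "k", "n", "rss", "bic")])
}

# ---- endpoint-combination selection ----------------------------------------

# RSS (sum of squared L2 distances) of the composed model for an arbitrary
# endpoint set. par packs, per endpoint in order, slope then intercept
# parameters. dxm is n x J photon endpoints, L the lethality per endpoint.
combo_rss <- function(par, specs, dxm, L, let, prep) {
  J <- length(specs)
  Dc <- matrix(0, nrow = nrow(dxm), ncol = J)
  pos <- 0L
  for (j in seq_len(J)) {
    sfam <- get_trend_family(specs[[j]]$slope, "slope")
    ifam <- get_trend_family(specs[[j]]$intercept, "intercept")
    sp <- par[pos + seq_len(sfam$n_par)]; pos <- pos + sfam$n_par
    ip <- par[pos + seq_len(ifam$n_par)]; pos <- pos + ifam$n_par
    if (sfam$n_par > 0 && any(1 + sp[1] * let <= 0)) return(Inf)
    Dc[, j] <- dxm[, j] * sfam$fun(let, sp) + ifam$fun(let, ip)
  }
  if (any(Dc <= 0)) return(Inf)
  # per-record least squares of L ~ alpha D + beta D^2 over the J endpoints
  s2 <- rowSums(Dc^2); s3 <- rowSums(Dc^3); s4 <- rowSums(Dc^4)
  sDL <- as.numeric(Dc %*% L); sD2L <- as.numeric(Dc^2 %*% L)
  det <- s2 * s4 - s3^2
  alpha <- (s4 * sDL - s3 * sD2L) / det
  beta <- (s2 * sD2L - s3 * sDL) / det
  bz <- beta < 0
  az <- alpha < 0 & !bz
  alpha[bz] <- (sDL / s2)[bz]; beta[bz] <- 0
  beta[az] <- (sD2L / s4)[az]; alpha[az] <- 0
  sf_p <- exp(-(outer(prep$D, alpha) + outer(prep$D2, beta)))
  num <- sqrt(colSums(prep$w * (prep$M - sf_p)^2))
  den <- colSums(prep$w * sf_p)
  sum((num / den)^2)
}

#' Select which endpoints the model should be built from
#'
#' For every 2-, 3-, and 4-endpoint combination of the candidate survival
#' levels, composes a model (best LET trend per endpoint, endpoints
#' converted to an LQM curve per record by least squares with
#' non-negativity constraints), refits all trend parameters jointly by
#' minimizing the sum of squared L2 curve distances, and scores the
#' combination by AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1). Fewer, less
#' correlated endpoints win when extra trend parameters are unwarranted.
#'
#' @param dataset A training dataset.
#' @param candidate_sfs Candidate endpoint survival levels; default
#'   e^-3, e^-2, e^-1, e^-1/2.
#' @param config A [fit_config()]; `selection_starts` controls the small
#'   multi-start budget of each joint refit.
#' @return A data.frame of class `cirbe_selection` with one row per
#'   combination (columns: endpoints, k, n, rss, aicc, feasible), sorted
#'   by AICc ascending; attribute `specs` holds the per-endpoint fitted
#'   trend specs.
#' @export
select_endpoint_combination <- function(dataset,
                                        candidate_sfs = exp(-c(3, 2, 1, 0.5)),
                                        config = fit_config()) {
  df <- as.data.frame(dataset)
  n <- nrow(df)
  prep <- prep_fit_data(dataset, config)
  # per-endpoint best trends and their fitted parameters
  per_ep <- lapply(candidate_sfs, function(sf) fit_endpoint_trend(dataset, sf))
  labels <- sprintf("e^%.3g", log(candidate_sfs))
  combos <- unlist(lapply(2:min(4, length(candidate_sfs)), function(m) {
    asplit(combn(seq_along(candidate_sfs), m), 2)
  }), recursive = FALSE)
  rows <- list()
  specs_out <- list()
  for (ci in seq_along(combos)) {
    idx <- combos[[ci]]
    specs <- lapply(per_ep[idx], `[[`, "best")
    k <- sum(vapply(specs, `[[`, numeric(1), "k"))
    label <- paste(labels[idx], collapse = " + ")
    if (n <= k + 1L) {
      rows[[ci]] <- data.frame(endpoints = label, k = k, n = n,
                               rss = NA_real_, aicc = NA_real_,
                               feasible = FALSE)
      next
    }
    dxm <- vapply(candidate_sfs[idx], function(sf) photon_endpoints(dataset, sf),
                  numeric(n))
    L <- -log(candidate_sfs[idx])
    start <- unlist(lapply(specs, function(s) c(s$slope_par, s$intercept_par)))
    lower <- unlist(lapply(specs, function(s) {
      c(get_trend_family(s$slope, "slope")$lower,
        get_trend_family(s$intercept, "intercept")$lower)
    }))
    upper <- unlist(lapply(specs, function(s) {
      c(get_trend_family(s$slope, "slope")$upper,
        get_trend_family(s$intercept, "intercept")$upper)
    }))
    obj <- function(par) combo_rss(par, specs, dxm, L, df$let_d, prep)
    starts <- with_seed(config$seed + ci, {
      c(list(start), lapply(seq_len(max(0L, config$selection_starts - 1L)),
                            function(i) start * (1 + runif(length(start), -config$jitter, config$jitter))))
    })
    best <- NULL
    for (st in starts) {
      st <- pmin(pmax(st, lower), upper)
      if (!is.finite(obj(st))) next
      fit <- nlminb(st, obj, lower = lower, upper = upper,
                    control = list(iter.max = config$maxit))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    if (is.null(best)) {
      rows[[ci]] <- data.frame(endpoints = label, k = k, n = n,
                               rss = NA_real_, aicc = NA_real_,
                               feasible = FALSE)
      next
    }
    rows[[ci]] <- data.frame(endpoints = label, k = k, n = n,
                             rss = best$objective,
                             aicc = ic_aicc(best$objective, n, k),
                             feasible = TRUE)
    specs_out[[label]] <- specs
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  structure(tab, specs = specs_out,
            class = c("cirbe_selection", "data.frame"))
}

# ---- global fit of (f1, m1, q1, f2) ----------------------------------------

# Starting point from fitting each retained endpoint's trend alone:
# D_e-3 with inverse-linear slope + quadratic-offset intercept (f1, q1, m1),
# D_e-1 with inverse-linear slope and no intercept (f2).
per_endpoint_start <- function(dataset) {
  f3 <- fit_trend_pair(photon_endpoints(dataset, exp(-3)),
                       measured_endpoints(dataset, exp(-3)),
                       as.data.frame(dataset)$let_d,
                       "inverse_linear", "quadratic_offset")
  f1fit <- fit_trend_pair(photon_endpoints(dataset, exp(-1)),
                          measured_endpoints(dataset, exp(-1)),
                          as.data.frame(dataset)$let_d,
                          "inverse_linear", "zero")
  # pair params are (f, q, m) and (f)
  c(f1 = f3$par[1], m1 = f3$par[3], q1 = f3$par[2], f2 = f1fit$par[1])
}

#' Fit the four model constants to a training dataset
#'
#' Minimizes the sum over records of squared L2 curve distances between
#' each measured carbon-ion survival curve and the curve the model
#' predicts from the record's photon parameters and LET, over
#' theta = (f1, m1, q1, f2) with non-negativity bounds. Because this
#' objective is sensitive to the starting point, the fit is multi-start:
#' the per-endpoint trend fits provide a base value, and `n_starts`
#' initial guesses are drawn uniformly within +/- `jitter` of it (the
#' first start is the unjittered base). Negative raw (alpha, beta) flow
#' through the same non-negativity constraint branches as at inference
#' time. Deterministic given `config$seed`; invariant to record order.
#'
#' @param dataset A filtered training dataset (see
#'   [apply_curation_filters()]).
#' @param config A [fit_config()].
#' @return An object of class `cirbe_fit`: `params`
#'   (a [model_parameters()] carrying the Gauss-Newton covariance when
#'   `config$compute_covariance`), `objective`, `n_starts`,
#'   `converged_fraction`, `seed`, `start_base`, and `config`.
#' @export
fit_model <- function(dataset, config = fit_config()) {
  df <- as.data.frame(dataset)
  if (nrow(df) < 6L) usage_error("need at least 6 records to fit 4 parameters")
  prep <- prep_fit_data(dataset, config)
  base <- per_endpoint_start(dataset)
  base <- pmin(pmax(base, config$lower), config$upper)
  starts <- with_seed(config$seed, {
    c(list(unname(base)),
      lapply(seq_len(config$n_starts - 1L), function(i) {
        unname(base) * (1 + runif(4, -config$jitter, config$jitter))
      }))
  })
  best <- NULL
  n_ok <- 0L
  n_bad_start <- 0L
  objfun <- make_objective(prep)
  for (st in starts) {
    st <- pmin(pmax(st, config$lower), config$upper)
    if (is.null(per_record_l2(st, prep))) {
      n_bad_start <- n_bad_start + 1L
      next
    }
    fit <- tryCatch(
      nlminb(st, objfun$value, gradient = objfun$grad,
             lower = config$lower, upper = config$upper,
             control = list(iter.max = config$maxit,
                            eval.max = 4L * config$maxit,
                            abs.tol = 1e-20, rel.tol = config$rel_tol,
                            x.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective) || fit$objective >= 1e9) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$objective < best$value) {
      best <- list(par = fit$par, value = fit$objective)
    }
  }
  if (is.null(best)) {
    convergence_error(sprintf(
      "all %d starts failed (%d infeasible at start)",
      length(starts), n_bad_start))
  }
  theta <- best$par
  sigma <- matrix(0, 4, 4)
  if (isTRUE(config$compute_covariance)) {
    sigma <- tryCatch(gauss_newton_covariance(theta, prep),
                      error = function(e) matrix(0, 4, 4))
  }
  params <- model_parameters(theta[1], theta[2], theta[3], theta[4],
                             covariance = sigma, version = "fitted")
  structure(list(params = params, objective = best$value,
                 n_starts = length(starts),
                 converged_fraction = n_ok / length(starts),
                 seed = config$seed, start_base = base, config = config),
            class = "cirbe_fit")
}

#' @export
print.cirbe_fit <- function(x, ...) {
  cat(sprintf("carbon-ion model fit: objective = %.6g over %d starts (%.0f%% converged)\n",
              x$objective, x$n_starts, 100 * x$converged_fraction))
  print(x$params)
  invisible(x)
}

# Gauss-Newton covariance on the per-record L2 residuals:
# sigma2_hat * (J'J)^-1 with J the finite-difference Jacobian.
gauss_newton_covariance <- function(theta, prep) {
  r0 <- per_record_l2(theta, prep)
  if (is.null(r0)) convergence_error("infeasible parameters for covariance")
  n <- length(r0)
  J <- matrix(0, nrow = n, ncol = 4L)
  for (j in 1:4) {
    h <- 1e-5 * (abs(theta[j]) + 1e-8)
    up <- theta; up[j] <- theta[j] + h
    dn <- theta; dn[j] <- max(theta[j] - h, 0)
    ru <- per_record_l2(up, prep)
    rd <- per_record_l2(dn, prep)
    if (is.null(ru) || is.null(rd)) convergence_error("Jacobian evaluation infeasible")
    J[, j] <- (ru - rd) / (up[j] - dn[j])
  }
  jtj <- crossprod(J)
  qrj <- qr(jtj)
  if (qrj$rank < 4L) convergence_error("rank-deficient residual Jacobian")
  sigma2 <- sum(r0^2) / max(n - 4L, 1L)
  sigma <- sigma2 * solve(qrj, diag(4))
  (sigma + t(sigma)) / 2
}

#' Gauss-Newton covariance of a fitted model
#'
#' Estimates the 4x4 covariance of (f1, m1, q1, f2) from the fit's
#' per-record L2 residuals as sigma2_hat (J'J)^-1, where J is the
#' finite-difference residual Jacobian and sigma2_hat = RSS/(n-4).
#'
#' @param fit A `cirbe_fit` object from [fit_model()].
#' @param dataset The training dataset the fit used.
#' @return Symmetric positive-semidefinite 4x4 matrix ordered
#'   (f1, m1, q1, f2).
#' @export
estimate_parameter_covariance <- function(fit, dataset) {
  prep <- prep_fit_data(dataset, fit$config)
  theta <- c(fit$params$f1, fit$params$m1, fit$params$q1, fit$params$f2)
  gauss_newton_covariance(theta, prep)
}
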