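#' Model parameter set (f1, m1, q1, f2) with covariance
#'
#' The empirical carbon-ion model has four free constants: f1
#' \[(keV/um)^-1\] and the intercept constants q1 \[(keV/um)^-2, Gy-scaled\]
#' and m1 \[Gy\] governing the D_(e^-3) endpoint, and f2 \[(keV/um)^-1\]
#' governing the D_(e^-1) endpoint. Their 4x4 covariance (ordered
#' f1, m1, q1, f2) feeds the delta-method confidence bands.
#'
#' @param f1,m1,q1,f2 Model constants; f1, f2 > 0 and m1, q1 >= 0.
#' @param covariance Symmetric positive-semidefinite 4x4 matrix over
#'   (f1, m1, q1, f2); defaults to the zero matrix (no uncertainty).
#' @param version Optional provenance string for the parameter set.
#' @return An object of class `cirbe_params`.
#' @seealso [published_parameters()] for the published reference values.
#' @export
model_parameters <- function(f1, m1, q1, f2,
                             covariance = matrix(0, 4, 4),
                             version = NULL) {
  vals <- c(f1 = f1, m1 = m1, q1 = q1, f2 = f2)
  if (any(!is.finite(vals))) domain_error("model parameters must be finite")
  if (f1 <= 0 || f2 <= 0) domain_error("f1 and f2 must be positive")
  if (q1 < 0 || m1 < 0) domain_error("q1 and m1 must be non-negative")
  covariance <- as.matrix(covariance)
  check_covariance(covariance, n = 4L)
  dimnames(covariance) <- list(names(vals), names(vals))
  structure(list(f1 = f1, m1 = m1, q1 = q1, f2 = f2,
                 covariance = covariance, version = version),
            class = "cirbe_params")
}

check_covariance <- function(sigma, n) {
  if (!is.matrix(sigma) || any(dim(sigma) != n)) {
    domain_error(sprintf("covariance must be a %dx%d matrix", n, n))
  }
  if (any(!is.finite(sigma))) domain_error("covariance must be finite")
  if (max(abs(sigma - t(sigma))) > 1e-12 * max(1, max(abs(sigma)))) {
    domain_error("covariance must be symmetric")
  }
  if (any(diag(sigma) < 0)) domain_error("covariance diagonal must be non-negative")
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1e-300)) {
    domain_error("covariance must be positive semi-definite")
  }
  invisible(sigma)
}

#' @export
print.cirbe_params <- function(x, ...) {
  cat("carbon-ion RBE model parameters",
      if (!is.null(x$version)) sprintf("(%s)", x$version), "\n")
  cat(sprintf("  f1 = %.6e (keV/um)^-1\n", x$f1))
  cat(sprintf("  m1 = %.6e Gy\n", x$m1))
  cat(sprintf("  q1 = %.6e (keV/um)^-2\n", x$q1))
  cat(sprintf("  f2 = %.6e (keV/um)^-1\n", x$f2))
  invisible(x)
}

#' Published model constants
#'
#' Loads the packaged parameter resource: the published values of
#' (f1, m1, q1, f2) and their full covariance, as obtained by fitting the
#' model to the curated 360-record training set of photon/carbon-ion
#' survival measurements. These are the default parameters for all
#' predictions.
#'
#' @param path Optional path to an alternative parameter JSON file.
#' @return A [model_parameters()] object.
#' @export
published_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_parameters_v1.json",
                        package = "cirbe", mustWork = TRUE)
  }
  read_parameters_json(path)
}

#' Read a model-parameter JSON file
#'
#' @param path Path to a JSON file with keys `f1`, `m1`, `q1`, `f2`,
#'   per-parameter uncertainties `se`, and pairwise `cov` entries (or a
#'   full `covariance` matrix, as written by [write_parameters_json()]).
#' @return A [model_parameters()] object.
#' @export
read_parameters_json <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("parameter file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("f1", "m1", "q1", "f2")
  if (!all(need %in% names(j))) {
    schema_error("parameter JSON must contain f1, m1, q1, f2")
  }
  if (!is.null(j$covariance)) {
    sigma <- matrix(unlist(j$covariance), 4, 4)
  } else {
    se <- unlist(j$se)[need]
    sigma <- diag(se^2)
    cv <- j$cov
    pairs <- list(c("f1", "m1"), c("f1", "q1"), c("f1", "f2"),
                  c("q1", "m1"), c("m1", "f2"), c("q1", "f2"))
    idx <- stats::setNames(seq_along(need), need)
    for (p in pairs) {
      key <- paste(p, collapse = "_")
      if (!is.null(cv[[key]])) {
        sigma[idx[p[1]], idx[p[2]]] <- cv[[key]]
        sigma[idx[p[2]], idx[p[1]]] <- cv[[key]]
      }
    }
  }
  model_parameters(j$f1, j$m1, j$q1, j$f2, covariance = sigma,
                   version = j$version)
}

#' Write a model-parameter JSON file
#'
#' @param params A [model_parameters()] object.
#' @param path Output path.
#' @param extra Optional named list appended to the JSON (e.g. fit
#'   provenance).
#' @return Invisibly, `path`.
#' @export
write_parameters_json <- function(params, path, extra = NULL) {
  obj <- c(list(f1 = params$f1, m1 = params$m1, q1 = params$q1,
                f2 = params$f2,
                covariance = unname(params$covariance),
                version = params$version %||% "fitted"),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict carbon-ion radiosensitivity endpoints from photon endpoints
#'
#' The core closed forms of the model. The photon D_(e^-3) endpoint is
#' scaled by an inverse-linear LET slope and shifted by a quadratic
#' intercept; the photon D_(e^-1) endpoint is scaled by its own
#' inverse-linear slope with no intercept:
#' \deqn{D_{e^{-3}},C = D_{e^{-3}},X (1 + f_1 LET_d)^{-1} + q_1 LET_d^2 + m_1}
#' \deqn{D_{e^{-1}},C = D_{e^{-1}},X (1 + f_2 LET_d)^{-1}}
#'
#' @param d_e3_x,d_e1_x Photon doses \[Gy\] achieving survival e^-3 and
#'   e^-1; must be positive. Vectorized (recycled against `let_d`).
#' @param let_d Dose-weighted LET \[keV um^-1\], >= 0.
#' @param params A [model_parameters()] object.
#' @return List with elements `d_e3` and `d_e1` \[Gy\].
#' @export
predict_endpoints <- function(d_e3_x, d_e1_x, let_d, params) {
  if (any(d_e3_x <= 0) || any(d_e1_x <= 0)) {
    domain_error("photon endpoints must be positive")
  }
  check_let(let_d)
  list(
    d_e3 = d_e3_x * slope_inverse_linear(let_d, params$f1) +
      intercept_quadratic(let_d, params$q1, params$m1),
    d_e1 = d_e1_x * slope_inverse_linear(let_d, params$f2)
  )
}

#' Convert the two endpoints (D_(e^-3), D_(e^-1)) to LQM parameters
#'
#' With endpoints at survival levels e^-3 and e^-1, the LQM coefficients
#' interpolating both exactly are
#' \deqn{\alpha = (D_3^2 - 3 D_1^2) / (D_1 D_3^2 - D_3 D_1^2)}
#' \deqn{\beta  = (3 D_1 - D_3)   / (D_1 D_3^2 - D_3 D_1^2)}
#' When one of these is negative the corresponding least-squares
#' single-parameter solution through the endpoint lethalities (3, 1) is
#' used instead: beta is negative iff D_3 > 3 D_1, in which case
#' alpha = (3 D_3 + D_1) / (D_3^2 + D_1^2) with beta = 0; alpha is
#' negative iff D_3 < sqrt(3) D_1, in which case
#' beta = (3 D_3^2 + D_1^2) / (D_3^4 + D_1^4) with alpha = 0. The two
#' conditions are mutually exclusive.
#'
#' @param d_e3 Dose \[Gy\] at survival e^-3; must exceed `d_e1`.
#' @param d_e1 Dose \[Gy\] at survival e^-1; must be positive.
#' @return List with `lqm` (an [lqm] object) and `branch`, one of
#'   `"unconstrained"`, `"beta_zeroed"`, `"alpha_zeroed"`.
#' @export
alpha_beta_from_endpoints <- function(d_e3, d_e1) {
  if (!is.finite(d_e3) || !is.finite(d_e1) || d_e1 <= 0 || d_e3 <= d_e1) {
    domain_error(paste0(
      "endpoint ordering violated: need d_e3 > d_e1 > 0 ",
      "(log-survival must fall faster at the lower-SF endpoint); got d_e3 = ",
      format(d_e3), ", d_e1 = ", format(d_e1)))
  }
  ab <- endpoint_ab_vec(d_e3, d_e1)
  list(lqm = lqm(ab$alpha, ab$beta),
       branch = c("unconstrained", "beta_zeroed", "alpha_zeroed")[ab$branch])
}

# Vectorized endpoint -> (alpha, beta) with non-negativity branches.
# branch codes: 1 unconstrained, 2 beta_zeroed, 3 alpha_zeroed.
# Assumes d_e3 > d_e1 > 0 elementwise (caller checks).
endpoint_ab_vec <- function(d_e3, d_e1) {
  denom <- d_e1 * d_e3^2 - d_e3 * d_e1^2
  alpha <- (d_e3^2 - 3 * d_e1^2) / denom
  beta <- (3 * d_e1 - d_e3) / denom
  branch <- rep.int(1L, length(alpha))
  bz <- beta < 0
  az <- alpha < 0
  if (any(bz)) {
    alpha[bz] <- (3 * d_e3[bz] + d_e1[bz]) / (d_e3[bz]^2 + d_e1[bz]^2)
    beta[bz] <- 0
    branch[bz] <- 2L
  }
  if (any(az)) {
    beta[az] <- (3 * d_e3[az]^2 + d_e1[az]^2) / (d_e3[az]^4 + d_e1[az]^4)
    alpha[az] <- 0
    branch[az] <- 3L
  }
  list(alpha = alpha, beta = beta, branch = branch)
}

#' Least-squares LQM coefficients from a set of radiosensitivity endpoints
#'
#' Solves -ln(SF_i) ~ alpha * D_i + beta * D_i^2 by ordinary least squares
#' over an arbitrary endpoint set, using the closed-form sum expressions
#' \deqn{\alpha = \frac{\sum D^4 \sum D \log SF - \sum D^3 \sum D^2 \log SF}
#'                     {\sum D^3 \sum D^3 - \sum D^2 \sum D^4}}
#' \deqn{\beta = \frac{\sum D^2 \sum D^2 \log SF - \sum D^3 \sum D \log SF}
#'                    {\sum D^3 \sum D^3 - \sum D^2 \sum D^4}}
#' The raw solution is returned unconstrained and may be negative; with
#' exactly two endpoints it reproduces the exact interpolant.
#'
#' @param endpoints A data.frame (or list of lists) with columns/fields
#'   `survival_fraction` in (0,1) and `dose` > 0; at least two distinct
#'   doses required.
#' @return List with raw `alpha` and `beta` (unconstrained).
#' @export
lqm_from_endpoint_set <- function(endpoints) {
  if (is.data.frame(endpoints)) {
    sf <- endpoints$survival_fraction
    D <- endpoints$dose
  } else {
    sf <- vapply(endpoints, `[[`, numeric(1), "survival_fraction")
    D <- vapply(endpoints, `[[`, numeric(1), "dose")
  }
  if (any(sf <= 0) || any(sf >= 1)) domain_error("survival fractions must be in (0,1)")
  if (any(D <= 0)) domain_error("endpoint doses must be positive")
  if (length(unique(D)) < 2L) {
    domain_error("need at least 2 endpoints with distinct doses")
  }
  lsf <- log(sf)
  s2 <- sum(D^2); s3 <- sum(D^3); s4 <- sum(D^4)
  s1l <- sum(D * lsf); s2l <- sum(D^2 * lsf)
  denom <- s3 * s3 - s2 * s4
  list(alpha = (s4 * s1l - s3 * s2l) / denom,
       beta = (s2 * s2l - s3 * s1l) / denom)
}

#' Predict the carbon-ion survival curve from the photon curve and LET
#'
#' The full prediction chain: extract the photon endpoints D_(e^-3),X and
#' D_(e^-1),X from the photon LQM curve, map them to carbon-ion endpoints
#' via [predict_endpoints()], and convert back to LQM coefficients via
#' [alpha_beta_from_endpoints()] with the non-negativity branches.
#'
#' @param photon Photon reference [lqm] curve (alpha_X, beta_X).
#' @param let_d Dose-weighted LET \[keV um^-1\] of the carbon-ion beam
#'   (scalar, >= 0).
#' @param params A [model_parameters()] object; defaults to the packaged
#'   published values.
#' @return An object of class `cirbe_prediction`: list with `lqm`
#'   (predicted carbon-ion curve), `d_e3`, `d_e1` (predicted endpoints,
#'   Gy), `branch`, and `let_d`.
#' @examples
#' pred <- predict_cion_lqm(lqm(0.3, 0.03), let_d = 60.5)
#' pred$lqm
#' rbe_at_survival(lqm(0.3, 0.03), pred$lqm, 0.10)
#' @export
predict_cion_lqm <- function(photon, let_d, params = published_parameters()) {
  if (length(let_d) != 1L) domain_error("'let_d' must be a scalar")
  d3x <- dose_at_survival(photon, exp(-3))
  d1x <- dose_at_survival(photon, exp(-1))
  ep <- predict_endpoints(d3x, d1x, let_d, params)
  ab <- alpha_beta_from_endpoints(ep$d_e3, ep$d_e1)
  structure(list(lqm = ab$lqm, d_e3 = ep$d_e3, d_e1 = ep$d_e1,
                 branch = ab$branch, let_d = let_d),
            class = "cirbe_prediction")
}

#' @export
print.cirbe_prediction <- function(x, ...) {
  cat(sprintf(
    "carbon-ion prediction at LET_d = %.4g keV/um [%s]\n", x$let_d, x$branch))
  cat(sprintf("  alpha_C = %.6g Gy^-1, beta_C = %.6g Gy^-2\n",
              x$lqm$alpha, x$lqm$beta))
  cat(sprintf("  D_e-3 = %.6g Gy, D_e-1 = %.6g Gy\n", x$d_e3, x$d_e1))
  invisible(x)
}
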