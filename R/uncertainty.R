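#' LQM curve with fit uncertainty
#'
#' Bundles an [lqm] curve with the standard errors of its coefficients and
#' their covariance, as reported by whatever least-squares fit produced the
#' curve. Feeds [measured_curve_band()].
#'
#' @param curve An [lqm] object.
#' @param se_alpha,se_beta Standard errors of alpha and beta (>= 0).
#' @param cov_alpha_beta Covariance of (alpha, beta); must satisfy
#'   |cov| <= se_alpha * se_beta.
#' @return An object of class `covariant_lqm`.
#' @export
covariant_lqm <- function(curve, se_alpha, se_beta, cov_alpha_beta = 0) {
  if (se_alpha < 0 || se_beta < 0) domain_error("standard errors must be >= 0")
  if (abs(cov_alpha_beta) > se_alpha * se_beta + 1e-15) {
    domain_error("invalid covariance: |cov(alpha,beta)| exceeds se_alpha*se_beta")
  }
  structure(list(lqm = curve, se_alpha = se_alpha, se_beta = se_beta,
                 cov_alpha_beta = cov_alpha_beta),
            class = "covariant_lqm")
}

# Coverage -> multiplier on SE. The published convention is exactly 1.96
# for ~95% bands and 1.0 for 68.3% bands; other levels fall back to the
# normal quantile.
coverage_factor <- function(coverage) {
  if (abs(coverage - 0.95) < 1e-9) return(1.96)
  if (abs(coverage - 0.683) < 1e-9) return(1.0)
  qnorm((1 + coverage) / 2)
}

new_band <- function(doses, central, se_ln, coverage) {
  z <- coverage_factor(coverage)
  lnc <- log(central)
  band <- data.frame(
    dose = doses,
    central = central,
    lower = pmin(1, pmax(0, exp(lnc - z * se_ln))),
    upper = pmin(1, pmax(0, exp(lnc + z * se_ln)))
  )
  structure(band, coverage = coverage, class = c("cirbe_band", "data.frame"))
}

#' Confidence band around a measured survival curve
#'
#' First-order (delta-method) propagation of the LQM fit covariance to the
#' survival curve. On the log-survival scale the variance is exact for the
#' LQM because ln SF = -(alpha D + beta D^2) is linear in (alpha, beta):
#' var(ln SF) = D^2 var(alpha) + D^4 var(beta) + 2 D^3 cov(alpha, beta).
#' The band is formed as exp(ln SF +/- z * SE), which keeps it positive.
#'
#' @param clqm A [covariant_lqm()] object.
#' @param doses Dose grid \[Gy\], >= 0.
#' @param coverage Nominal coverage; 0.95 uses the factor 1.96 exactly,
#'   0.683 uses 1.0.
#' @return A `cirbe_band` data.frame with columns dose, central, lower,
#'   upper (surviving fractions, clipped to \[0, 1\]).
#' @export
measured_curve_band <- function(clqm, doses, coverage = 0.95) {
  if (any(doses < 0)) domain_error("'doses' must be non-negative")
  va <- clqm$se_alpha^2
  vb <- clqm$se_beta^2
  cab <- clqm$cov_alpha_beta
  if (va * vb - cab^2 < -1e-12 * max(va * vb, 1)) {
    domain_error("(alpha, beta) covariance matrix is not positive semi-definite")
  }
  central <- survival_fraction(clqm$lqm, doses)
  se_ln <- sqrt(doses^2 * va + doses^4 * vb + 2 * doses^3 * cab)
  new_band(doses, central, se_ln, coverage)
}

# ln SF of the model prediction at fixed doses, as a function of the
# 4-vector theta = (f1, m1, q1, f2), with the constraint branch forced so
# the map stays differentiable at the central value.
predicted_lnsf_fixed_branch <- function(theta, d3x, d1x, let_d, doses, branch) {
  d3c <- d3x / (1 + theta[1] * let_d) + theta[3] * let_d^2 + theta[2]
  d1c <- d1x / (1 + theta[4] * let_d)
  denom <- d1c * d3c^2 - d3c * d1c^2
  if (branch == "unconstrained") {
    a <- (d3c^2 - 3 * d1c^2) / denom
    b <- (3 * d1c - d3c) / denom
  } else if (branch == "beta_zeroed") {
    a <- (3 * d3c + d1c) / (d3c^2 + d1c^2)
    b <- 0
  } else {
    a <- 0
    b <- (3 * d3c^2 + d1c^2) / (d3c^4 + d1c^4)
  }
  -(a * doses + b * doses^2)
}

natural_branch <- function(theta, d3x, d1x, let_d) {
  d3c <- d3x / (1 + theta[1] * let_d) + theta[3] * let_d^2 + theta[2]
  d1c <- d1x / (1 + theta[4] * let_d)
  if (d3c > 3 * d1c) "beta_zeroed"
  else if (d3c < sqrt(3) * d1c) "alpha_zeroed"
  else "unconstrained"
}

#' Confidence band around a predicted carbon-ion survival curve
#'
#' Propagates the 4x4 covariance of the model constants (f1, m1, q1, f2)
#' through the full prediction chain by the delta method. The gradient of
#' ln SF(D) with respect to the constants is computed by central finite
#' differences with the constraint branch held fixed at the central
#' prediction's branch (the branch switch is a measure-zero
#' non-smoothness; a warning is issued if the perturbed parameters would
#' naturally cross it). Variance = g' Sigma g per dose; the band is
#' exp(ln SF +/- z SE).
#'
#' @param photon Photon reference [lqm] curve.
#' @param let_d Dose-weighted LET \[keV um^-1\] (scalar).
#' @param params A [model_parameters()] object carrying the covariance.
#' @param doses Dose grid \[Gy\], >= 0.
#' @param coverage Nominal coverage (default 0.95 -> factor 1.96).
#' @param rel_step Relative finite-difference step per parameter.
#' @return A `cirbe_band` data.frame; attribute `branch` records the
#'   central constraint branch.
#' @export
predicted_curve_band <- function(photon, let_d, params, doses,
                                 coverage = 0.95, rel_step = 1e-5) {
  if (any(doses < 0)) domain_error("'doses' must be non-negative")
  sigma <- params$covariance
  check_covariance(sigma, 4L)
  pred <- predict_cion_lqm(photon, let_d, params)
  central <- survival_fraction(pred$lqm, doses)
  theta <- c(params$f1, params$m1, params$q1, params$f2)
  d3x <- dose_at_survival(photon, exp(-3))
  d1x <- dose_at_survival(photon, exp(-1))

  g <- matrix(0, nrow = length(doses), ncol = 4L)
  crossed <- FALSE
  for (j in 1:4) {
    h <- rel_step * (abs(theta[j]) + 1e-8)
    up <- theta; up[j] <- theta[j] + h
    dn <- theta; dn[j] <- theta[j] - h
    g[, j] <- (predicted_lnsf_fixed_branch(up, d3x, d1x, let_d, doses, pred$branch) -
                 predicted_lnsf_fixed_branch(dn, d3x, d1x, let_d, doses, pred$branch)) /
      (2 * h)
    if (natural_branch(up, d3x, d1x, let_d) != pred$branch ||
        natural_branch(dn, d3x, d1x, let_d) != pred$branch) {
      crossed <- TRUE
    }
  }
  if (crossed) {
    warning("parameter perturbation crosses a constraint branch; ",
            "band computed holding the central branch fixed",
            call. = FALSE)
  }
  var_ln <- rowSums((g %*% sigma) * g)
  var_ln[var_ln < 0] <- 0
  band <- new_band(doses, central, sqrt(var_ln), coverage)
  attr(band, "branch") <- pred$branch
  band
}

#' Write a confidence band to CSV
#'
#' @param band A `cirbe_band` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_band_csv <- function(band, path) {
  write.csv(as.data.frame(band), path, row.names = FALSE)
  invisible(path)
}
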