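#' LET trend functions for the endpoint correlation slope and intercept
#'
#' The photon/carbon-ion correlation for a radiosensitivity endpoint D_SF is
#' modelled as D_SF,C = D_SF,X * Slope(LET_d) + Intercept(LET_d). These
#' functions are the named slope and intercept families; both slope families
#' equal 1 at zero LET and decrease monotonically for f > 0.
#'
#' @param let_d Dose-weighted LET \[keV um^-1\]; vectorized, must be >= 0.
#' @param f Slope rate constant \[(keV/um)^-1\].
#' @return Dimensionless slope value(s).
#' @export
slope_inverse_linear <- function(let_d, f) {
  check_let(let_d)
  denom <- 1 + f * let_d
  if (any(denom <= 0)) {
    domain_error("slope undefined: 1 + f * let_d must be positive")
  }
  1 / denom
}

#' @rdname slope_inverse_linear
#' @export
slope_inverse_linear_squared <- function(let_d, f) {
  slope_inverse_linear(let_d, f)^2
}

#' @rdname slope_inverse_linear
#' @param q Quadratic coefficient \[Gy (keV/um)^-2\].
#' @param m Vertical offset \[Gy\].
#' @export
intercept_quadratic <- function(let_d, q, m) {
  check_let(let_d)
  q * let_d^2 + m
}

check_let <- function(let_d) {
  if (any(!is.finite(let_d)) || any(let_d < 0)) {
    domain_error("'let_d' must be non-negative and finite")
  }
  invisible(let_d)
}

# ---- extensible family registry -------------------------------------------
# The named families are the ones retained after the candidate-function
# sweep; the registry accepts additional user families so the search space
# can be widened without touching the fitting code.

.trend_registry <- new.env(parent = emptyenv())

trend_family <- function(fun, n_par, par_names, lower, upper, start) {
  list(fun = fun, n_par = n_par, par_names = par_names,
       lower = lower, upper = upper, start = start)
}

#' Register a trend-function family
#'
#' Adds a slope or intercept family to the registry used by
#' [fit_endpoint_trend()]. A family is a function of
#' `(let_d, par)` where `par` is a numeric vector of length `n_par`.
#'
#' @param id Family identifier (string), unique within its role.
#' @param role `"slope"` or `"intercept"`.
#' @param fun Function `(let_d, par)` returning the trend value.
#' @param n_par Number of free parameters.
#' @param par_names Character names of the parameters.
#' @param lower,upper Box bounds used during fitting.
#' @param start Default starting values.
#' @return Invisibly, the family id.
#' @export
register_trend_family <- function(id, role = c("slope", "intercept"),
                                  fun, n_par, par_names,
                                  lower = rep(0, n_par),
                                  upper = rep(Inf, n_par),
                                  start = rep(0.01, n_par)) {
  role <- match.arg(role)
  stopifnot(is.function(fun), n_par == length(par_names))
  assign(paste(role, id, sep = ":"),
         trend_family(fun, n_par, par_names, lower, upper, start),
         envir = .trend_registry)
  invisible(id)
}

get_trend_family <- function(id, role) {
  key <- paste(role, id, sep = ":")
  if (!exists(key, envir = .trend_registry, inherits = FALSE)) {
    usage_error(sprintf("unknown %s family '%s'", role, id))
  }
  get(key, envir = .trend_registry, inherits = FALSE)
}

#' List registered trend families
#' @param role `"slope"` or `"intercept"`.
#' @return Character vector of family ids.
#' @export
list_trend_families <- function(role = c("slope", "intercept")) {
  role <- match.arg(role)
  keys <- ls(envir = .trend_registry)
  sub("^[a-z]+:", "", keys[startsWith(keys, paste0(role, ":"))])
}

register_builtin_families <- function() {
  register_trend_family(
    "inverse_linear", "slope",
    function(let_d, par) slope_inverse_linear(let_d, par[1]),
    1L, "f", lower = 0, upper = 1, start = 0.02
  )
  register_trend_family(
    "inverse_linear_squared", "slope",
    function(let_d, par) slope_inverse_linear_squared(let_d, par[1]),
    1L, "f", lower = 0, upper = 1, start = 0.01
  )
  register_trend_family(
    "quadratic_offset", "intercept",
    function(let_d, par) intercept_quadratic(let_d, par[1], par[2]),
    2L, c("q", "m"), lower = c(0, 0), upper = c(1e-2, 10),
    start = c(1e-5, 0.5)
  )
  register_trend_family(
    "zero", "intercept",
    function(let_d, par) rep(0, length(let_d)),
    0L, character(0), lower = numeric(0), upper = numeric(0),
    start = numeric(0)
  )
}
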