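test_that("slope and intercept trend functions match their closed forms", {
  expect_equal(slope_inverse_linear(0, 0.5), 1)
  expect_equal(slope_inverse_linear(100, 0.01), 0.5)
  expect_equal(slope_inverse_linear(60.5, 0.02095070), 0.441011,
               tolerance = 1e-6)
  expect_equal(slope_inverse_linear_squared(0, 0.9), 1)
  expect_equal(slope_inverse_linear_squared(100, 0.01), 0.25)
  expect_equal(slope_inverse_linear_squared(60.5, 0.02095070), 0.194491,
               tolerance = 1e-5)
  expect_equal(intercept_quadratic(0, 1, 0.5955453), 0.5955453)
  expect_equal(intercept_quadratic(60.5, 2.133918e-5, 0.5955453), 0.673652,
               tolerance = 1e-6)
  expect_equal(intercept_quadratic(10, 0, 0), 0)
  expect_error(slope_inverse_linear(-1, 0.01), class = "cirbe_domain_error")
  expect_error(slope_inverse_linear(200, -0.01), class = "cirbe_domain_error")
})

test_that("slope families are strictly decreasing in LET and equal 1 at zero", {
  lets <- seq(0, 350, by = 0.5)
  for (f in c(0.005, 0.02095070, 0.1)) {
    s1 <- slope_inverse_linear(lets, f)
    s2 <- slope_inverse_linear_squared(lets, f)
    expect_equal(s1[1], 1)
    expect_equal(s2[1], 1)
    expect_true(all(diff(s1) < 0))
    expect_true(all(diff(s2) < 0))
  }
})

test_that("predict_endpoints reproduces the published parameterization", {
  p <- table3()
  ep0 <- predict_endpoints(5, 2, 0, p)
  expect_equal(ep0$d_e3, 5 + p$m1)
  expect_equal(ep0$d_e1, 2)
  ep <- predict_endpoints(5, 2, 60.5, p)
  expect_equal(ep$d_e3, 2.87871, tolerance = 1e-5)
  expect_equal(ep$d_e1, 0.85120, tolerance = 1e-5)
  p0 <- model_parameters(p$f1, 0, 0, p$f2)
  ep_id <- predict_endpoints(3, 1, 0, p0)
  expect_equal(ep_id$d_e3, 3)
  expect_equal(ep_id$d_e1, 1)
  expect_error(predict_endpoints(-1, 2, 10, p), class = "cirbe_domain_error")
})

test_that("endpoint-to-LQM conversion hits the exact geometries and branches", {
  r <- alpha_beta_from_endpoints(3, 1)
  expect_equal(r$lqm$alpha, 1, tolerance = 1e-12)
  expect_equal(r$lqm$beta, 0, tolerance = 1e-12)
  expect_equal(r$branch, "unconstrained")
  # d_e3 = sqrt(3) d_e1 sits exactly on the branch boundary; both the
  # unconstrained solve and the alpha-zeroed closed form give (0, 1)
  r <- alpha_beta_from_endpoints(sqrt(3), 1)
  expect_equal(r$lqm$alpha, 0, tolerance = 1e-12)
  expect_equal(r$lqm$beta, 1, tolerance = 1e-12)
  r <- alpha_beta_from_endpoints(5, 2)
  expect_equal(r$lqm$alpha, 13 / 30, tolerance = 1e-12)
  expect_equal(r$lqm$beta, 1 / 30, tolerance = 1e-12)
  r <- alpha_beta_from_endpoints(4, 1)
  expect_equal(r$branch, "beta_zeroed")
  expect_equal(r$lqm$alpha, 13 / 17, tolerance = 1e-12)
  expect_equal(r$lqm$beta, 0)
  expect_error(alpha_beta_from_endpoints(1, 2), class = "cirbe_domain_error")
})

test_that("unconstrained conversion equals the 2x2 linear solve and interpolates exactly", {
  set.seed(7)
  n <- 1e4
  d1 <- runif(n, 0.2, 6)
  d3 <- d1 * runif(n, sqrt(3), 3)
  ab <- cirbe:::endpoint_ab_vec(d3, d1)
  expect_true(all(ab$branch == 1L))
  # independent oracle: solve the 2x2 system per endpoint pair
  a_ref <- numeric(n)
  b_ref <- numeric(n)
  for (i in seq_len(n)) {
    sol <- solve(matrix(c(d3[i], d3[i]^2, d1[i], d1[i]^2), 2, byrow = TRUE),
                 c(3, 1))
    a_ref[i] <- sol[1]
    b_ref[i] <- sol[2]
  }
  expect_equal(ab$alpha, a_ref, tolerance = 1e-10)
  expect_equal(ab$beta, b_ref, tolerance = 1e-10)
  # both endpoints reproduced through the survival curve
  sf3 <- exp(-(ab$alpha * d3 + ab$beta * d3^2))
  sf1 <- exp(-(ab$alpha * d1 + ab$beta * d1^2))
  expect_equal(sf3, rep(exp(-3), n), tolerance = 1e-9)
  expect_equal(sf1, rep(exp(-1), n), tolerance = 1e-9)
})

test_that("constrained branches match a dense grid least-squares oracle", {
  grid_minimize <- function(fun, lo, hi, n = 200001L) {
    x <- seq(lo, hi, length.out = n)
    x[which.min(fun(x))]
  }
  cases <- list(c(4, 1), c(6.5, 2), c(10, 3))  # d3 > 3 d1
  for (cs in cases) {
    d3 <- cs[1]; d1 <- cs[2]
    r <- alpha_beta_from_endpoints(d3, d1)
    expect_equal(r$branch, "beta_zeroed")
    a_star <- grid_minimize(function(a) (a * d3 - 3)^2 + (a * d1 - 1)^2, 0, 3)
    expect_equal(r$lqm$alpha, a_star, tolerance = 1e-4)
  }
  cases <- list(c(1.5, 1), c(2.2, 1.6), c(4, 3))  # d3 < sqrt(3) d1
  for (cs in cases) {
    d3 <- cs[1]; d1 <- cs[2]
    r <- alpha_beta_from_endpoints(d3, d1)
    expect_equal(r$branch, "alpha_zeroed")
    b_star <- grid_minimize(function(b) (b * d3^2 - 3)^2 + (b * d1^2 - 1)^2, 0, 3)
    expect_equal(r$lqm$beta, b_star, tolerance = 1e-4)
  }
})

test_that("no endpoint pair triggers both constraint branches", {
  set.seed(11)
  d1 <- runif(2e4, 0.05, 8)
  d3 <- d1 * (1 + rexp(2e4, 0.5))
  ab <- cirbe:::endpoint_ab_vec(d3, d1)
  bz <- d3 > 3 * d1
  az <- d3 < sqrt(3) * d1
  expect_false(any(bz & az))
  expect_equal(ab$branch == 2L, bz)
  expect_equal(ab$branch == 3L, az)
})

test_that("least-squares endpoint sets reduce to the exact two-endpoint solve", {
  two <- data.frame(survival_fraction = exp(-c(3, 1)), dose = c(5, 2))
  r <- lqm_from_endpoint_set(two)
  expect_equal(r$alpha, 13 / 30, tolerance = 1e-10)
  expect_equal(r$beta, 1 / 30, tolerance = 1e-10)
  # random two-endpoint sets agree with the closed form to 1e-10
  set.seed(13)
  for (i in 1:50) {
    d1 <- runif(1, 0.3, 5)
    d3 <- d1 * runif(1, 1.05, 5)
    r <- lqm_from_endpoint_set(
      data.frame(survival_fraction = exp(-c(3, 1)), dose = c(d3, d1)))
    ref <- cirbe:::endpoint_ab_vec(d3, d1)
    if (ref$branch == 1L) {
      expect_equal(r$alpha, ref$alpha, tolerance = 1e-10)
      expect_equal(r$beta, ref$beta, tolerance = 1e-10)
    }
  }
  collinear <- data.frame(survival_fraction = exp(-(1:3)), dose = 1:3)
  r <- lqm_from_endpoint_set(collinear)
  expect_equal(r$alpha, 1, tolerance = 1e-10)
  expect_equal(r$beta, 0, tolerance = 1e-10)
  quad <- data.frame(survival_fraction = exp(-(1:3)), dose = sqrt(1:3))
  r <- lqm_from_endpoint_set(quad)
  expect_equal(r$alpha, 0, tolerance = 1e-10)
  expect_equal(r$beta, 1, tolerance = 1e-10)
  expect_error(lqm_from_endpoint_set(
    data.frame(survival_fraction = c(0.5, 0.1), dose = c(2, 2))),
    class = "cirbe_domain_error")
})

test_that("the full prediction chain is self-consistent and identity at LET 0", {
  p <- table3()
  p_id <- model_parameters(p$f1, 0, 0, p$f2)
  pred <- predict_cion_lqm(lqm(0.3, 0.03), 0, p_id)
  expect_equal(pred$lqm$alpha, 0.3, tolerance = 1e-8)
  expect_equal(pred$lqm$beta, 0.03, tolerance = 1e-8)
  # unconstrained predictions pass through their own endpoints
  pred <- predict_cion_lqm(lqm(0.5, 0.05), 60.5, p)
  if (pred$branch == "unconstrained") {
    expect_equal(survival_fraction(pred$lqm, pred$d_e3), exp(-3),
                 tolerance = 1e-10)
    expect_equal(survival_fraction(pred$lqm, pred$d_e1), exp(-1),
                 tolerance = 1e-10)
  }
  # high LET forces the linearized (beta = 0) branch
  pred <- predict_cion_lqm(lqm(0.3, 0.03), 200, p)
  expect_equal(pred$branch, "beta_zeroed")
  expect_equal(pred$lqm$beta, 0)
})

test_that("beta_C reaches zero above a finite LET for any positive-beta photon input", {
  p <- table3()
  set.seed(17)
  for (i in 1:20) {
    photon <- lqm(runif(1, 0.05, 0.8), runif(1, 0.005, 0.1))
    branches <- vapply(seq(5, 350, by = 5), function(let) {
      predict_cion_lqm(photon, let, p)$branch
    }, character(1))
    expect_true(any(branches == "beta_zeroed"))
    # once linearized, stays linearized as LET grows
    first <- which(branches == "beta_zeroed")[1]
    expect_true(all(branches[first:length(branches)] == "beta_zeroed"))
  }
})

test_that("RBE10 versus LET shows the overkill maximum for radioresistant cells", {
  p <- table3()
  photon <- lqm(0.1, 0.02)
  lets <- seq(1, 350, by = 1)
  rbe10 <- vapply(lets, function(let) {
    rbe_at_survival(photon, predict_cion_lqm(photon, let, p)$lqm, 0.10)
  }, numeric(1))
  imax <- which.max(rbe10)
  expect_gt(imax, 1)
  expect_lt(imax, length(lets))
  expect_gt(rbe10[imax], rbe10[1])
  expect_gt(rbe10[imax], rbe10[length(lets)])
})

test_that("published parameter resource matches the printed constants", {
  p <- table3()
  expect_equal(p$f1, 2.095070e-2)
  expect_equal(p$m1, 5.955453e-1)
  expect_equal(p$q1, 2.133918e-5)
  expect_equal(p$f2, 2.230798e-2)
  expect_equal(sqrt(diag(p$covariance)),
               c(f1 = 8.575542e-3, m1 = 4.089380e-1, q1 = 8.756112e-6,
                 f2 = 3.479508e-3), tolerance = 1e-12)
  expect_equal(p$covariance["f1", "m1"], 2.945233e-3)
  expect_equal(p$covariance["q1", "m1"], -8.767703e-7)
  # printed covariance block is a valid (PSD) matrix
  ev <- eigen(p$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12 * max(ev)))
})

test_that("parameter JSON round-trips including covariance", {
  p <- table3()
  path <- tempfile(fileext = ".json")
  write_parameters_json(p, path)
  p2 <- read_parameters_json(path)
  expect_equal(theta_of(p2), theta_of(p), tolerance = 1e-12)
  expect_equal(unname(p2$covariance), unname(p$covariance), tolerance = 1e-12)
})
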