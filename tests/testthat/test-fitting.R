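test_that("L2 curve distance: identity, closed form, asymmetry, quadrature", {
  a <- lqm(0.5, 0.05)
  b <- lqm(0.9, 0)
  expect_equal(l2_curve_distance(a, a), 0)
  # closed form: measured exp(-D) vs predicted SF == 1 on [0.5, 4]
  # integral of (exp(-D)-1)^2 = [D - 2exp(-D)... ] evaluated analytically
  f <- function(D) D + 2 * exp(-D) - exp(-2 * D) / 2
  num <- sqrt((f(4) - f(0.5)))
  expect_equal(l2_curve_distance(lqm(1, 0), list(alpha = 0, beta = 0)),
               num / 3.5, tolerance = 1e-9)
  # not symmetric in its arguments (normalization uses the predicted curve)
  expect_false(isTRUE(all.equal(l2_curve_distance(a, b),
                                l2_curve_distance(b, a))))
  # default grid agrees with a 10x finer grid
  set.seed(23)
  for (i in 1:20) {
    m <- lqm(runif(1, 0.05, 1.5), runif(1, 0, 0.12))
    p <- lqm(runif(1, 0.05, 1.5), runif(1, 0, 0.12))
    expect_equal(l2_curve_distance(m, p, n_grid = 513L),
                 l2_curve_distance(m, p, n_grid = 5131L),
                 tolerance = 1e-6)
  }
})

test_that("relative endpoint residuals vanish on self-generated data", {
  # unconstrained-branch records interpolate their endpoints exactly, so
  # the generating trend leaves zero residual
  d0 <- unconstrained_dataset(seed = 21, n_cell_lines = 10)
  p <- table3()
  spec3 <- trend_spec("inverse_linear", p$f1, "quadratic_offset",
                      c(p$q1, p$m1))
  res <- relative_endpoint_residuals(d0, exp(-3), spec3)
  expect_lt(max(abs(res)), 1e-10)
  # single constructed record: slope 1/(1+0.02*50) = 0.5 maps 4 -> 2 exactly
  df <- data.frame(cell_line = "A", let_d = 50, alpha_x = 3 / 4, beta_x = 0,
                   alpha_c = 3 / 2, beta_c = 0, photon_source_kvp = 6000)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  ds <- read_training_csv(path)
  spec <- trend_spec("inverse_linear", 0.02)
  expect_equal(as.numeric(relative_endpoint_residuals(ds, exp(-3), spec)), 0,
               tolerance = 1e-12)
})

test_that("fit_endpoint_trend recovers a noiseless trend exactly", {
  # stay on the unconstrained branch so stored endpoints follow the
  # generating trend without constraint distortion
  d0 <- unconstrained_dataset(seed = 25)
  p <- table3()
  fit1 <- fit_endpoint_trend(d0, exp(-1),
                             slope_families = "inverse_linear",
                             intercept_families = "zero")
  expect_equal(fit1$best$slope_par, p$f2, tolerance = 1e-4)
  expect_lt(fit1$rss, 1e-10)
  fit3 <- fit_endpoint_trend(d0, exp(-3),
                             slope_families = "inverse_linear",
                             intercept_families = "quadratic_offset")
  expect_equal(fit3$best$slope_par, p$f1, tolerance = 1e-3)
  expect_equal(fit3$best$intercept_par[2], p$m1, tolerance = 1e-3)
  expect_lt(fit3$rss, 1e-10)
})

test_that("BIC penalizes spurious parameters when RSS is tied", {
  # with small noise the spurious intercept buys only a marginal RSS
  # improvement, so the k*ln(n) penalty decides
  dn <- unconstrained_dataset(seed = 26, n_cell_lines = 25,
                              noise_cv = 0.01)
  fit1 <- fit_endpoint_trend(dn, exp(-1))
  expect_equal(fit1$best$slope, "inverse_linear")
  expect_equal(fit1$best$intercept, "zero")
  tab <- fit1$table
  expect_true(all(diff(tab$bic) >= 0))
  rss_zero <- tab$rss[tab$slope == "inverse_linear" & tab$intercept == "zero"]
  rss_quad <- tab$rss[tab$slope == "inverse_linear" &
                        tab$intercept == "quadratic_offset"]
  expect_lte(rss_quad, rss_zero + 1e-12)  # nested model never fits worse
  bic_zero <- tab$bic[tab$slope == "inverse_linear" & tab$intercept == "zero"]
  bic_quad <- tab$bic[tab$slope == "inverse_linear" &
                        tab$intercept == "quadratic_offset"]
  expect_lt(bic_zero, bic_quad)
})

test_that("single-LET designs trigger the degeneracy warning", {
  d1 <- noiseless_dataset(seed = 27, n_cell_lines = 10, lets = 60.5)
  expect_warning(fit_endpoint_trend(d1, exp(-1)), "confounded")
})

test_that("endpoint-combination selection table has 11 rows and prefers the generating pair", {
  d0 <- generate_synthetic_dataset(synthetic_config(
    seed = 29, n_cell_lines = 12, lets = NULL, let_range = c(5, 150),
    endpoint_noise_cv = 0.02))
  sel <- select_endpoint_combination(d0, config = quick_config())
  expect_equal(nrow(sel), 11L)  # C(4,2) + C(4,3) + C(4,4)
  expect_true(all(sel$feasible))
  expect_true(all(is.finite(sel$aicc)))
  expect_true(all(diff(sel$aicc) >= 0))
  # the generating endpoints (e^-3, e^-1) win among 2-endpoint pairs
  pairs <- sel[vapply(strsplit(sel$endpoints, " \\+ "), length, integer(1)) == 2L, ]
  expect_equal(pairs$endpoints[which.min(pairs$aicc)], "e^-3 + e^-1")
})

test_that("fit_model recovers the generating constants from noiseless data", {
  d0 <- noiseless_dataset(seed = 3, n_cell_lines = 12, lets = NULL)
  fit <- fit_model(d0, quick_config())
  expect_equal(theta_of(fit$params), theta_of(table3()), tolerance = 1e-3)
  expect_lt(fit$objective, 1e-10)
  expect_equal(fit$converged_fraction, 1)
})

test_that("fit objective is monotone in the number of starts and order-invariant", {
  dn <- generate_synthetic_dataset(synthetic_config(
    seed = 31, n_cell_lines = 10, endpoint_noise_cv = 0.10))
  f1 <- fit_model(dn, quick_config(seed = 5, n_starts = 1))
  f20 <- fit_model(dn, quick_config(seed = 5, n_starts = 20))
  expect_lte(f20$objective, f1$objective + 1e-12)
  # shuffling records does not change the fit (same seed)
  df <- as.data.frame(dn)
  set.seed(99)
  shuffled <- cirbe:::new_training_dataset(
    df[sample(nrow(df)), setdiff(names(df), "record_id")])
  f_shuf <- fit_model(shuffled, quick_config(seed = 5, n_starts = 20))
  expect_equal(theta_of(f_shuf$params), theta_of(f20$params),
               tolerance = 1e-10)
})

test_that("analytic objective gradient matches central finite differences", {
  dn <- generate_synthetic_dataset(synthetic_config(
    seed = 33, n_cell_lines = 15, lets = NULL, endpoint_noise_cv = 0.05))
  cfg <- quick_config()
  prep <- cirbe:::prep_fit_data(dn, cfg)
  th_ref <- theta_of(table3())
  set.seed(35)
  for (i in 1:5) {
    th <- th_ref * (1 + runif(4, -0.3, 0.3))
    g <- cirbe:::obj_and_grad(th, prep)
    for (j in 1:4) {
      h <- 1e-6 * abs(th[j])
      up <- th; up[j] <- th[j] + h
      dn_ <- th; dn_[j] <- th[j] - h
      gn <- (cirbe:::objective_theta(up, prep) -
               cirbe:::objective_theta(dn_, prep)) / (2 * h)
      expect_equal(g$grad[j], gn, tolerance = 1e-5)
    }
  }
})

test_that("Gauss-Newton covariance shrinks with noise and is symmetric PSD", {
  d0 <- noiseless_dataset(seed = 37, n_cell_lines = 12, lets = NULL)
  f0 <- fit_model(d0, quick_config())
  expect_true(all(abs(f0$params$covariance) < 1e-12))
  dn <- generate_synthetic_dataset(synthetic_config(
    seed = 37, n_cell_lines = 30, lets = NULL, endpoint_noise_cv = 0.05))
  fn <- fit_model(dn, quick_config(n_starts = 10))
  sigma <- estimate_parameter_covariance(fn, dn)
  expect_equal(sigma, t(sigma))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-15 * max(ev)))
  expect_true(all(diag(sigma) > 0))
  expect_equal(unname(fn$params$covariance), sigma, tolerance = 1e-8)
})

test_that("fit configuration validates and records its knobs", {
  expect_error(fit_config(n_starts = 0), class = "cirbe_usage_error")
  cfg <- fit_config(grid_n = 128L)
  expect_equal(cfg$grid_n %% 2L, 1L)  # forced odd for Simpson
})
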