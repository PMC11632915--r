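# Shared fixtures, built in code at test time.

# Fast fitting configuration for tests (coarse grid, few starts).
quick_config <- function(seed = 1L, n_starts = 5L, loocv_starts = 5L,
                         selection_starts = 2L, ...) {
  fit_config(seed = seed, n_starts = n_starts, grid_n = 129L,
             loocv_starts = loocv_starts,
             selection_starts = selection_starts, ...)
}

# Dataset confined to the unconstrained branch: low LET and radioresistant
# photon inputs keep every record clear of the beta_zeroed region, so
# stored endpoints follow the generating trends exactly.
unconstrained_dataset <- function(seed, n_cell_lines = 15L,
                                  noise_cv = 0, let_range = c(5, 40)) {
  d <- generate_synthetic_dataset(synthetic_config(
    seed = seed, n_cell_lines = n_cell_lines, lets = NULL,
    let_range = let_range, alpha_x_range = c(0.05, 0.3),
    beta_x_range = c(0.01, 0.05), endpoint_noise_cv = noise_cv))
  stopifnot(all(as.data.frame(d)$beta_c > 0))
  d
}

# Noiseless synthetic dataset generated from the published constants.
noiseless_dataset <- function(seed = 3L, n_cell_lines = 12L,
                              lets = NULL, let_range = c(5, 200)) {
  generate_synthetic_dataset(synthetic_config(
    seed = seed, n_cell_lines = n_cell_lines, lets = lets,
    let_range = let_range, endpoint_noise_cv = 0))
}

# Constructed 10-record table with known curation violations:
# rows 1-2 low-energy photon source, row 3 LET > 350, rows 4-6 negative
# beta_c, rows 7-10 clean (including every boundary case: exactly 200 kVp,
# exactly LET 350, exactly beta_c = 0).
curation_fixture <- function() {
  df <- data.frame(
    cell_line = sprintf("CL%02d", 1:10),
    let_d = c(30, 50, 351, 60, 70, 80, 30, 350, 90, 100),
    alpha_x = rep(0.3, 10),
    beta_x = rep(0.03, 10),
    alpha_c = rep(0.6, 10),
    beta_c = c(0.05, 0.05, 0.05, -0.01, -0.2, -1e-6, 0.05, 0.05, 0, 0.02),
    photon_source_kvp = c(100, 199.99, 6000, 6000, 250, 1000,
                          200, 6000, 6000, 6000),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  read_training_csv(path)
}

table3 <- function() published_parameters()

theta_of <- function(params) c(params$f1, params$m1, params$q1, params$f2)
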