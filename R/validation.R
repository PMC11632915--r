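# Model validation: leave-one-out cross-validation, RBE deviation tables,
# bootstrap prediction intervals, LET-binned accuracy, comparison metrics.

let_bin_edges <- c(0, 20, 40, 70, 100, 200, Inf)
let_bin_labels <- c("entrance [0,20)", "proximal SOBP [20,40)",
                    "mid SOBP [40,70)", "distal SOBP [70,100)",
                    "distal edge [100,200)", "very high LET [200,Inf)")

#' Leave-one-out cross-validation of the model fit
#'
#' For every record, refits the four model constants on the remaining
#' n-1 records (with a reduced multi-start budget, `config$loocv_starts`)
#' and predicts the held-out record's carbon-ion curve from its photon
#' parameters and LET. The training subset of each refit provably
#' excludes its target (checked via a content hash). Deterministic given
#' `config$seed` and invariant to record order: every refit uses the same
#' seed, and both the objective and the starting point are sums over
#' records.
#'
#' @param dataset A filtered training dataset with at least 10 records.
#' @param config A [fit_config()].
#' @return An object of class `cirbe_loocv`: list with `predictions`
#'   (per-record `cirbe_prediction`s, keyed by record), `params` (list of
#'   per-refit [model_parameters()]), `failed` (indices of failed
#'   refits), and `dataset_hashes`.
#' @export
loocv <- function(dataset, config = fit_config()) {
  df <- as.data.frame(dataset)
  n <- nrow(df)
  if (n < 10L) usage_error("leave-one-out cross-validation needs >= 10 records")
  sub_cfg <- config
  sub_cfg$n_starts <- config$loocv_starts
  sub_cfg$compute_covariance <- FALSE
  key <- record_key(df)
  preds <- vector("list", n)
  pars <- vector("list", n)
  failed <- integer(0)
  hashes <- character(n)
  for (i in seq_len(n)) {
    train <- new_training_dataset(df[-i, setdiff(names(df), "record_id"),
                                     drop = FALSE])
    train_keys <- record_key(as.data.frame(train))
    if (key[i] %in% train_keys) {
      cirbe_error("held-out record leaked into its own training set",
                  "cirbe_leak_error")
    }
    hashes[i] <- content_hash(paste(sort(train_keys), collapse = "|"))
    fit <- tryCatch(fit_model(train, sub_cfg), error = function(e) NULL)
    if (is.null(fit)) {
      failed <- c(failed, i)
      next
    }
    pars[[i]] <- fit$params
    preds[[i]] <- predict_cion_lqm(lqm(df$alpha_x[i], df$beta_x[i]),
                                   df$let_d[i], fit$params)
  }
  names(preds) <- key
  structure(list(predictions = preds, params = pars, failed = failed,
                 dataset_hashes = hashes, seed = config$seed),
            class = "cirbe_loocv")
}

record_key <- function(df) {
  sprintf("%s@%.10g|%.10g|%.10g", df$cell_line, df$let_d,
          df$alpha_x, df$alpha_c)
}

# Small polynomial content hash (mod 2^31-1, exact in double arithmetic);
# enough to assert two record sets differ.
content_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Relative RBE deviations at fixed dose levels
#'
#' Per record and dose level, computes the predicted and measured RBE via
#' [rbe_at_dose()] against the record's photon curve (the measured RBE
#' uses the record's stored carbon-ion LQM parameters) and their relative
#' deviation (predicted - measured) / measured. Records with a degenerate
#' measured curve are skipped with a message.
#'
#' @param predictions A `cirbe_loocv` object, or a list of
#'   `cirbe_prediction`s parallel to the dataset rows.
#' @param dataset The matching training dataset.
#' @param dose_levels Carbon-ion dose levels \[Gy\].
#' @return Data.frame with columns record_id, cell_line, let_d,
#'   dose_level, rbe_predicted, rbe_measured, relative_deviation.
#' @export
rbe_deviations <- function(predictions, dataset,
                           dose_levels = c(0.5, 1, 2, 4)) {
  if (inherits(predictions, "cirbe_loocv")) predictions <- predictions$predictions
  df <- as.data.frame(dataset)
  if (length(predictions) != nrow(df)) {
    usage_error("predictions and dataset sizes do not match")
  }
  rows <- list()
  for (i in seq_len(nrow(df))) {
    pred <- predictions[[i]]
    if (is.null(pred)) next
    if (df$alpha_c[i] <= 0 && df$beta_c[i] <= 0) {
      message(sprintf("skipping record %d: degenerate measured curve", i))
      next
    }
    photon <- lqm(df$alpha_x[i], df$beta_x[i])
    measured <- lqm(df$alpha_c[i], df$beta_c[i])
    rbe_p <- rbe_at_dose(photon, pred$lqm, dose_levels)
    rbe_m <- rbe_at_dose(photon, measured, dose_levels)
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = df$record_id[i], cell_line = df$cell_line[i],
      let_d = df$let_d[i], dose_level = dose_levels,
      rbe_predicted = rbe_p, rbe_measured = rbe_m,
      relative_deviation = (rbe_p - rbe_m) / rbe_m,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap prediction intervals for RBE deviations
#'
#' Resamples the relative deviations with replacement within each dose
#' level and reports the mean (over resamples) of the percentile
#' endpoints of the deviation distribution at each confidence level.
#' Strata with fewer than 5 deviations are omitted with a warning.
#'
#' @param deviations Output of [rbe_deviations()].
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param levels Confidence levels as percentages (default 68.3 and 95).
#' @param seed RNG seed; deterministic given it.
#' @return Data.frame with columns dose_level, level, lower, upper, n.
#' @export
bootstrap_intervals <- function(deviations, n_boot = 2000L,
                                levels = c(68.3, 95), seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (d in sort(unique(deviations$dose_level))) {
      x <- deviations$relative_deviation[deviations$dose_level == d]
      x <- x[is.finite(x)]
      if (length(x) < 5L) {
        warning(sprintf("dose level %g Gy: fewer than 5 deviations; omitted", d),
                call. = FALSE)
        next
      }
      qs <- c((100 - levels) / 200, 1 - (100 - levels) / 200)
      acc <- matrix(0, nrow = n_boot, ncol = length(qs))
      for (b in seq_len(n_boot)) {
        acc[b, ] <- quantile(sample(x, replace = TRUE), probs = qs,
                             names = FALSE, type = 7)
      }
      est <- colMeans(acc)
      nl <- length(levels)
      rows[[length(rows) + 1L]] <- data.frame(
        dose_level = d, level = levels,
        lower = est[seq_len(nl)], upper = est[nl + seq_len(nl)],
        n = length(x))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' LET-binned accuracy summary
#'
#' Groups deviations into the fixed LET_d regions of a clinical
#' spread-out Bragg peak — entrance \[0,20), proximal SOBP \[20,40), mid
#' SOBP \[40,70), distal SOBP \[70,100), distal edge \[100,200), and very
#' high LET \[200,Inf) keV um^-1 (left-closed, right-open) — and reports
#' per bin the count, mean deviation (bias) and standard deviation
#' (accuracy).
#'
#' @param deviations Output of [rbe_deviations()] (carries `let_d`).
#' @return Data.frame with columns bin, let_lo, let_hi, n, mean_deviation,
#'   sd_deviation; all bins present, empty ones with n = 0.
#' @export
let_bin_summary <- function(deviations) {
  idx <- findInterval(deviations$let_d, let_bin_edges,
                      rightmost.closed = FALSE, left.open = FALSE)
  out <- data.frame(bin = let_bin_labels,
                    let_lo = let_bin_edges[-length(let_bin_edges)],
                    let_hi = let_bin_edges[-1],
                    n = 0L, mean_deviation = NA_real_,
                    sd_deviation = NA_real_, stringsAsFactors = FALSE)
  for (b in seq_along(let_bin_labels)) {
    x <- deviations$relative_deviation[idx == b]
    x <- x[is.finite(x)]
    out$n[b] <- length(x)
    if (length(x)) {
      out$mean_deviation[b] <- mean(x)
      out$sd_deviation[b] <- if (length(x) > 1L) sd(x) else 0
    }
  }
  out
}

#' Survival-curve comparison metrics
#'
#' The model-comparison summary: mean absolute relative deviation (with
#' standard error of the mean) between predicted and measured carbon-ion
#' response for the endpoints D_10% and D_50% and for the RBE at the 1, 2
#' and 4 Gy dose levels. To measure predictive (not descriptive)
#' accuracy, feed it held-out predictions from [loocv()].
#'
#' @param predictions A `cirbe_loocv` or list of `cirbe_prediction`s.
#' @param dataset The matching training dataset.
#' @return Data.frame with columns metric, mean_abs_dev, se, n (deviations
#'   as fractions; multiply by 100 for percent).
#' @export
comparison_metrics <- function(predictions, dataset) {
  if (inherits(predictions, "cirbe_loocv")) predictions <- predictions$predictions
  df <- as.data.frame(dataset)
  if (length(predictions) != nrow(df)) {
    usage_error("predictions and dataset sizes do not match")
  }
  dev_d10 <- dev_d50 <- numeric(0)
  dev_rbe <- list(`1` = numeric(0), `2` = numeric(0), `4` = numeric(0))
  for (i in seq_len(nrow(df))) {
    pred <- predictions[[i]]
    if (is.null(pred)) next
    if (df$alpha_c[i] <= 0 && df$beta_c[i] <= 0) next
    photon <- lqm(df$alpha_x[i], df$beta_x[i])
    measured <- lqm(df$alpha_c[i], df$beta_c[i])
    d10 <- dose_at_survival(measured, 0.10)
    d50 <- dose_at_survival(measured, 0.50)
    dev_d10 <- c(dev_d10, abs(dose_at_survival(pred$lqm, 0.10) - d10) / d10)
    dev_d50 <- c(dev_d50, abs(dose_at_survival(pred$lqm, 0.50) - d50) / d50)
    for (d in c(1, 2, 4)) {
      rp <- rbe_at_dose(photon, pred$lqm, d)
      rm_ <- rbe_at_dose(photon, measured, d)
      dev_rbe[[as.character(d)]] <- c(dev_rbe[[as.character(d)]],
                                      abs(rp - rm_) / rm_)
    }
  }
  summarize <- function(x) {
    c(mean = mean(x), se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0,
      n = length(x))
  }
  vals <- rbind(summarize(dev_d10), summarize(dev_d50),
                summarize(dev_rbe[["1"]]), summarize(dev_rbe[["2"]]),
                summarize(dev_rbe[["4"]]))
  data.frame(metric = c("D10%", "D50%", "RBE_1Gy", "RBE_2Gy", "RBE_4Gy"),
             mean_abs_dev = vals[, "mean"], se = vals[, "se"],
             n = as.integer(vals[, "n"]), stringsAsFactors = FALSE)
}

#' Run the full validation pipeline and write its artifacts
#'
#' Chains [loocv()], [rbe_deviations()], [bootstrap_intervals()],
#' [let_bin_summary()] and [comparison_metrics()], optionally writing
#' per-record deviations and bin summaries as CSV plus a JSON report.
#'
#' @param dataset A filtered training dataset.
#' @param config A [fit_config()].
#' @param n_boot,levels Passed to [bootstrap_intervals()].
#' @param dose_levels Passed to [rbe_deviations()].
#' @param out_dir Optional output directory for report files.
#' @return List of class `cirbe_validation`: `deviations`, `intervals`,
#'   `bins`, `metrics`, `loocv`.
#' @export
validate_model <- function(dataset, config = fit_config(),
                           n_boot = 2000L, levels = c(68.3, 95),
                           dose_levels = c(0.5, 1, 2, 4), out_dir = NULL) {
  cv <- loocv(dataset, config)
  dev <- rbe_deviations(cv, dataset, dose_levels)
  intervals <- bootstrap_intervals(dev, n_boot = n_boot, levels = levels,
                                   seed = config$seed)
  bins <- let_bin_summary(dev)
  metrics <- comparison_metrics(cv, dataset)
  report <- structure(list(deviations = dev, intervals = intervals,
                           bins = bins, metrics = metrics, loocv = cv),
                      class = "cirbe_validation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(dev, file.path(out_dir, "deviations.csv"), row.names = FALSE)
    write.csv(bins, file.path(out_dir, "let_bins.csv"), row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(intervals = intervals, n_records = nrow(as.data.frame(dataset)),
           failed_refits = cv$failed, seed = config$seed),
      file.path(out_dir, "validation.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  report
}
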