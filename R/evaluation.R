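# Metrics and the reproducible experiment drivers: the wavelength sweep,
# the train/test cross-validation matrix, and the divergence-versus-error
# study. Every driver is a pure function of (configuration, seeds) and can
# write its tables plus a JSON manifest next to them.

#' Median absolute sO2 estimation error
#'
#' The headline accuracy metric: `100 * median(|sO2_est - sO2_true|)` in
#' percentage points. The median of an even count is the mean of the two
#' central order statistics.
#'
#' @param estimates,truths Equal-length vectors of sO2 fractions.
#' @return Error in percentage points, in \[0, 100\].
#' @export
median_abs_error <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (length(estimates) == 0) stop("empty input")
  100 * stats::median(abs(estimates - truths))
}

#' Accuracy report for a set of estimates
#'
#' @param estimates,truths sO2 fractions.
#' @param stratum Optional label (variant name, sO2 decile, ...).
#' @return A `metrics_report` with `median_abs_error` (percentage points),
#'   `mean_squared_error` (fraction scale) and `n`.
#' @export
metrics_report <- function(estimates, truths, stratum = NULL) {
  structure(list(median_abs_error = median_abs_error(estimates, truths),
                 mean_squared_error = mean((estimates - truths)^2),
                 n = length(estimates), stratum = stratum),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("n = ", x$n, if (!is.null(x$stratum)) paste0(" (", x$stratum, ")"),
      ": median |error| = ", signif(x$median_abs_error, 3),
      " pp, MSE = ", signif(x$mean_squared_error, 3), "\n", sep = "")
  invisible(x)
}

# small deterministic seed derivation (exact in double arithmetic, < 2^31)
derive_seed <- function(seed, k) (seed * 69069 + k) %% 2147483647

# standard preparation pipeline: generate -> select -> (subset) -> z-score
# -> (resample to an exact count, with replacement)
prepare_training_data <- function(config, n, seed, keep = NULL) {
  ds <- generate_dataset(config, n_spectra = n, seed = seed)
  ds <- select_spectra(ds)$dataset
  if (!is.null(keep)) ds <- subset_wavelengths(ds, keep)
  ds <- zscore_dataset(ds)
  stratified_resample(ds, n, derive_seed(seed, 77))
}

#' Same-distribution held-out error of the masked LSTM
#'
#' The package's reference experiment: generate baseline-variant surrogate
#' spectra, run the standard selection / z-scoring / resampling pipeline,
#' train the masked LSTM on `n_train` spectra and evaluate the median
#' absolute error on `n_test` held-out spectra drawn independently from
#' the same distribution.
#'
#' @param seed Master seed; train set, test set and weight initialization
#'   use seeds derived from it.
#' @param n_train,n_test Training and held-out set sizes.
#' @param epochs Training epochs.
#' @param config Tissue variant (default the baseline).
#' @param verbose Print training progress.
#' @return A list with `epsilon_pp` (median absolute error, percentage
#'   points), the trained `model`, and `n_test`.
#' @export
baseline_holdout_error <- function(seed = 1, n_train = 50000, n_test = 10000,
                                   epochs = 30, config = NULL,
                                   verbose = FALSE) {
  if (is.null(config)) config <- builtin_variants()$BASE
  train_ds <- prepare_training_data(config, n_train, derive_seed(seed, 1))
  test_ds <- prepare_training_data(config, n_test, derive_seed(seed, 2))
  hyper <- lstm_hyperparams(epochs = epochs, seed = derive_seed(seed, 3))
  model <- train(build_lstm(hyper), train_ds, verbose = verbose)
  est <- predict(model, test_ds)
  list(epsilon_pp = median_abs_error(est, test_ds$so2), model = model,
       n_test = n_test)
}

#' Wavelength-count sweep
#'
#' Trains one masked-LSTM per (training wavelength count, seed) on
#' baseline-variant spectra restricted to evenly spaced wavelength
#' subsets, then evaluates every model at every test wavelength count.
#' Reproduces the two accuracy-versus-wavelength-count curves: accuracy
#' improves with more wavelengths, and is best when the inference
#' wavelength count matches the training one.
#'
#' @param nlambda_list Wavelength counts to sweep (both axes).
#' @param n_train,n_test Spectra per training / test set.
#' @param epochs Training epochs per model.
#' @param seeds Integer vector of replicate seeds.
#' @param config Tissue variant (default baseline).
#' @param batch_size Minibatch size (desk-scale default 256, so that small
#'   training sets still provide enough optimizer updates per epoch).
#' @param out_dir Optional output directory for the CSV and manifest.
#' @return A data.frame with columns `seed`, `nlambda_train`,
#'   `nlambda_test`, `epsilon_pp` (one row per combination per seed).
#' @export
run_wavelength_sweep <- function(nlambda_list = c(3, 10, 41),
                                 n_train = 10000, n_test = 4000,
                                 epochs = 15, seeds = 1:3, config = NULL,
                                 batch_size = 256, out_dir = NULL) {
  if (is.null(config)) config <- builtin_variants()$BASE
  rows <- list()
  for (s in seeds) {
    test_pools <- lapply(nlambda_list, function(nl) {
      prepare_training_data(config, n_test, derive_seed(s, 2),
                            keep = evenly_spaced_wavelengths(nl))
    })
    names(test_pools) <- nlambda_list
    for (nl_tr in nlambda_list) {
      tr <- prepare_training_data(config, n_train, derive_seed(s, 1),
                                  keep = evenly_spaced_wavelengths(nl_tr))
      hyper <- lstm_hyperparams(epochs = epochs, batch_size = batch_size,
                                seed = derive_seed(s, 3))
      model <- train(build_lstm(hyper), tr)
      for (nl_te in nlambda_list) {
        te <- test_pools[[as.character(nl_te)]]
        eps <- median_abs_error(predict(model, te), te$so2)
        rows[[length(rows) + 1L]] <-
          data.frame(seed = s, nlambda_train = nl_tr, nlambda_test = nl_te,
                     epsilon_pp = eps)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "wavelength_sweep.csv")
    data.table::fwrite(out, p)
    write_manifest(file.path(out_dir, "wavelength_sweep_manifest.json"),
                   config = list(nlambda_list = nlambda_list,
                                 n_train = n_train, n_test = n_test,
                                 epochs = epochs, variant = config$name),
                   seed = seeds, outputs = p)
  }
  out
}

#' Cross-validation matrix over tissue variants
#'
#' Trains one masked-LSTM per tissue variant (plus optionally a mixed
#' `ALL` model drawing equal spectra counts from every variant) and
#' evaluates every model on every variant's held-out set, yielding the
#' train-by-test error matrix whose diagonal is the in-distribution
#' error.
#'
#' @param variants Named list of `tissue_variant` configs.
#' @param n_train,n_test Spectra per training / test set.
#' @param epochs Training epochs per model.
#' @param seeds Replicate seeds; cells are averaged over them.
#' @param include_all Add the mixed `ALL` training row.
#' @param batch_size Minibatch size (desk-scale default 256).
#' @param out_dir Optional output directory.
#' @return A `crossval_matrix`: `epsilon` (train x test matrix of median
#'   absolute errors in percentage points, seed-averaged), `long` (per-seed
#'   data.frame), `seeds`.
#' @export
run_crossval <- function(variants, n_train = 8000, n_test = 3000,
                         epochs = 10, seeds = 1, include_all = TRUE,
                         batch_size = 256, out_dir = NULL) {
  stopifnot(length(variants) >= 2, !is.null(names(variants)))
  vnames <- names(variants)
  rows <- list()
  for (s in seeds) {
    trains <- lapply(vnames, function(v) {
      prepare_training_data(variants[[v]], n_train, derive_seed(s, 1))
    })
    names(trains) <- vnames
    tests <- lapply(vnames, function(v) {
      prepare_training_data(variants[[v]], n_test, derive_seed(s, 2))
    })
    names(tests) <- vnames
    train_rows <- vnames
    if (include_all) {
      k <- ceiling(n_train / length(vnames))
      mix <- ds_bind(lapply(seq_along(vnames), function(i) {
        stratified_resample(trains[[i]], k, derive_seed(s, 100 + i))
      }), variant = "ALL")
      trains$ALL <- mix
      train_rows <- c(vnames, "ALL")
    }
    for (tr in train_rows) {
      hyper <- lstm_hyperparams(epochs = epochs, batch_size = batch_size,
                                seed = derive_seed(s, 3))
      model <- train(build_lstm(hyper), trains[[tr]])
      for (te in vnames) {
        eps <- median_abs_error(predict(model, tests[[te]]), tests[[te]]$so2)
        rows[[length(rows) + 1L]] <-
          data.frame(seed = s, train = tr, test = te, epsilon_pp = eps)
      }
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(epsilon_pp ~ train + test, long, mean)
  train_rows <- unique(long$train)
  mat <- matrix(NA_real_, length(train_rows), length(vnames),
                dimnames = list(train_rows, vnames))
  for (i in seq_len(nrow(agg))) mat[agg$train[i], agg$test[i]] <- agg$epsilon_pp[i]
  out <- structure(list(epsilon = mat, long = long, seeds = seeds),
                   class = "crossval_matrix")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "crossval_matrix.csv")
    data.table::fwrite(data.frame(train = rownames(mat), mat,
                                  check.names = FALSE), p)
    write_manifest(file.path(out_dir, "crossval_manifest.json"),
                   config = list(variants = vnames, n_train = n_train,
                                 n_test = n_test, epochs = epochs,
                                 include_all = include_all),
                   seed = seeds, outputs = p)
  }
  out
}

#' @export
print.crossval_matrix <- function(x, ...) {
  cat("cross-validation matrix (median |error|, percentage points), ",
      length(x$seeds), " seed(s):\n", sep = "")
  print(round(x$epsilon, 2))
  invisible(x)
}

#' Divergence-versus-error study
#'
#' For each candidate tissue variant, computes (a) the aggregate
#' Jensen-Shannon distance between the candidate's training spectra and a
#' target dataset and (b) the median absolute error of a model trained on
#' that candidate when applied to the target. Reports the Pearson
#' correlation between the two across candidates (per seed and averaged)
#' and flags candidates whose error departs from the divergence-error
#' trend by more than 2 interquartile ranges of the residuals.
#'
#' @param variants Named list of candidate `tissue_variant` configs.
#' @param target_variant Name of the target variant (may be one of
#'   `variants` or not).
#' @param n_train,n_test Training / target set sizes.
#' @param epochs Training epochs per candidate model.
#' @param seeds Replicate seeds.
#' @param djs_n,djs_repeats Subsample size and repeats for [djs_bar()].
#' @param batch_size Minibatch size (desk-scale default 256).
#' @param out_dir Optional output directory.
#' @return A list: `table` (per-candidate seed-averaged `djs`, `epsilon_pp`,
#'   `outlier` flag, `rank`), `r_per_seed`, `r` (mean Pearson correlation).
#' @export
run_djs_study <- function(variants, target_variant, n_train = 6000,
                          n_test = 3000, epochs = 10, seeds = 1,
                          djs_n = 3000, djs_repeats = 3, batch_size = 256,
                          out_dir = NULL) {
  stopifnot(!is.null(names(variants)))
  vnames <- names(variants)
  tcfg <- if (target_variant %in% vnames) variants[[target_variant]] else
    stop("target_variant must name one of the candidate configs")
  per_seed <- list()
  for (s in seeds) {
    target <- prepare_training_data(tcfg, n_test, derive_seed(s, 5))
    djs <- numeric(length(vnames))
    eps <- numeric(length(vnames))
    for (i in seq_along(vnames)) {
      tr <- prepare_training_data(variants[[i]], n_train, derive_seed(s, 1))
      djs[i] <- djs_bar(tr, target, n_subsample = djs_n,
                        repeats = djs_repeats, seed = derive_seed(s, 9))$djs_bar
      hyper <- lstm_hyperparams(epochs = epochs, batch_size = batch_size,
                                seed = derive_seed(s, 3))
      model <- train(build_lstm(hyper), tr)
      eps[i] <- median_abs_error(predict(model, target), target$so2)
    }
    per_seed[[as.character(s)]] <-
      data.frame(seed = s, candidate = vnames, djs = djs, epsilon_pp = eps)
  }
  long <- do.call(rbind, per_seed)
  r_per_seed <- vapply(per_seed, function(d) {
    correlate_djs_error(d$djs, d$epsilon_pp)
  }, numeric(1))
  tab <- stats::aggregate(cbind(djs, epsilon_pp) ~ candidate, long, mean)
  tab <- tab[order(tab$djs), ]
  tab$rank <- seq_len(nrow(tab))
  tab$outlier <- flag_trend_outliers(tab$djs, tab$epsilon_pp)
  rownames(tab) <- NULL
  out <- list(table = tab, r_per_seed = as.numeric(r_per_seed),
              r = mean(r_per_seed), long = long)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, "djs_ranking.csv")
    data.table::fwrite(tab, p)
    write_manifest(file.path(out_dir, "djs_manifest.json"),
                   config = list(variants = vnames, target = target_variant,
                                 n_train = n_train, n_test = n_test,
                                 epochs = epochs, djs_n = djs_n,
                                 djs_repeats = djs_repeats),
                   seed = seeds, outputs = p)
  }
  out
}

#' Flag outliers from a linear trend
#'
#' Least-squares line of `y` on `x`; points whose absolute residual
#' exceeds 2 interquartile ranges of the residuals are flagged. Used to
#' surface candidates whose estimation error departs from the
#' divergence-error trend (which warrant expert inspection before
#' trusting the summary score).
#'
#' @param x,y Equal-length numeric vectors (n >= 4).
#' @return Logical vector of outlier flags.
#' @export
flag_trend_outliers <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) return(rep(FALSE, length(x)))
  res <- stats::resid(stats::lm(y ~ x))
  iqr <- stats::IQR(res)
  # a numerically perfect trend has no outliers
  tiny <- 1e-8 * max(diff(range(y)), 1e-12)
  if (iqr <= tiny) return(rep(FALSE, length(x)))
  abs(res) > 2 * iqr
}
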