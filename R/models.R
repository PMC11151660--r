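# Oximetry models: the wavelength-masked LSTM regressor (the method), a
# fixed-wavelength feedforward baseline (learned spectral decoloring), and
# non-negative linear unmixing.

#' Hyperparameters of the masked-LSTM regressor
#'
#' Defaults follow the reference training schedule: a 41-slot input
#' sequence feeding an LSTM with hidden size 100, whose per-step hidden
#' vectors are flattened into a 4100-long encoding consumed by a fully
#' connected head with one hidden layer of 1000 units (leaky-ReLU) and a
#' sigmoid output; mean-absolute-error loss, Adam with initial learning
#' rate 1e-3 halved after a 5-epoch validation-loss plateau (floor 1e-6),
#' 100 epochs. Batch size (1024) and the 20% validation split are package
#' defaults; they are not part of the published schedule.
#'
#' @param epochs Training epochs.
#' @param lstm_hidden LSTM hidden size.
#' @param fc_hidden Fully connected hidden layer width.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_factor Multiplier applied to the learning rate on plateau.
#' @param lr_patience Epochs without validation improvement before decay.
#' @param lr_min Learning-rate floor.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the training set held out for the
#'   plateau scheduler.
#' @param seed Seed for weight init, the validation split and shuffling.
#' @return An `lstm_hyperparams` list; `fc_input` is derived as
#'   `41 * lstm_hidden`.
#' @export
lstm_hyperparams <- function(epochs = 100, lstm_hidden = 100,
                             fc_hidden = 1000, initial_lr = 1e-3,
                             lr_factor = 0.5, lr_patience = 5,
                             lr_min = 1e-6, batch_size = 1024,
                             val_fraction = 0.2, seed = 1) {
  stopifnot(epochs >= 1, lstm_hidden >= 1, fc_hidden >= 1,
            initial_lr > 0, lr_factor > 0, lr_factor < 1, lr_patience >= 1,
            batch_size >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(input_slots = 41L, lstm_hidden = as.integer(lstm_hidden),
                 fc_hidden = as.integer(fc_hidden),
                 fc_input = 41L * as.integer(lstm_hidden),
                 epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 lr_min = lr_min, batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = seed),
            class = "lstm_hyperparams")
}

new_oximeter_model <- function(kind, hyper = NULL, extra = list()) {
  structure(c(list(kind = kind, weights = NULL, hyper = hyper,
                   trained_nlambda = NA_integer_,
                   trained_variant = NA_character_,
                   grid = wavelength_grid(), log = NULL), extra),
            class = "oximeter_model")
}

#' Build the wavelength-masked LSTM oximeter
#'
#' The model consumes the 41-step sequence of scalar amplitudes with a
#' boolean presence mask: at masked steps the recurrent state passes
#' through unchanged and the emitted hidden vector repeats the previous
#' one (zeros before the first present wavelength), so stored values at
#' masked slots can never influence predictions. All per-step hidden
#' vectors are flattened into the encoding feeding the fully connected
#' head; the sigmoid output constrains estimates to \[0, 1\].
#'
#' @param hyper An [lstm_hyperparams()] object.
#' @return An untrained `oximeter_model` of kind `"lstm"`.
#' @export
build_lstm <- function(hyper = lstm_hyperparams()) {
  stopifnot(inherits(hyper, "lstm_hyperparams"))
  new_oximeter_model("lstm", hyper)
}

#' Build the fixed-wavelength feedforward baseline
#'
#' A learned-spectral-decoloring style regressor: a fully connected network
#' (41 inputs, two leaky-ReLU hidden layers, sigmoid output) trained with
#' the same schedule as the LSTM. It requires the full wavelength set: any
#' masked wavelength at training or inference is an error. This
#' inflexibility is deliberate - it is what the recurrent architecture is
#' designed to remove.
#'
#' @param hidden Integer vector of the two hidden-layer widths.
#' @param hyper Training schedule, as [lstm_hyperparams()].
#' @return An untrained `oximeter_model` of kind `"lsd"`.
#' @export
build_lsd <- function(hidden = c(100, 100), hyper = lstm_hyperparams()) {
  stopifnot(length(hidden) == 2, all(hidden >= 1))
  new_oximeter_model("lsd", hyper, list(hidden = as.integer(hidden)))
}

#' Build a linear-unmixing "model"
#'
#' Wraps [linear_unmixing()] in the common model interface so it can be
#' used interchangeably with the learned estimators in experiments.
#'
#' @param table Chromophore table providing the unmixing basis.
#' @return An `oximeter_model` of kind `"lu"` (needs no training).
#' @export
build_lu <- function(table = chromophore_table()) {
  m <- new_oximeter_model("lu", NULL, list(table = table))
  m$weights <- list() # LU has no trainable parameters
  m
}

#' @export
print.oximeter_model <- function(x, ...) {
  cat("oximeter model, kind '", x$kind, "', ",
      if (is.null(x$weights)) "untrained" else "trained", sep = "")
  if (!is.na(x$trained_nlambda)) {
    cat(" (", x$trained_nlambda, " wavelengths, variant '",
        x$trained_variant, "')", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Train an oximeter model
#'
#' Minimizes mean absolute error with Adam; the learning rate is multiplied
#' by `lr_factor` whenever the validation loss fails to improve for
#' `lr_patience` consecutive epochs. Inputs must be per-spectrum z-scored
#' (see [zscore_dataset()]) and labels must be fractions. Training is
#' deterministic given the hyperparameter seed (single-threaded backend).
#'
#' @param model An untrained model from [build_lstm()] or [build_lsd()].
#' @param dataset A z-scored `spectra_dataset` with labels.
#' @param verbose Print per-epoch losses.
#' @param ... Unused.
#' @return The trained model, with a per-epoch `log` (train/validation
#'   loss and learning rate).
#' @export
train <- function(model, dataset, ...) UseMethod("train")

#' @rdname train
#' @export
train.oximeter_model <- function(model, dataset, verbose = FALSE, ...) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  h <- model$hyper
  check_normalized(dataset)
  if (any(dataset$so2 < 0 | dataset$so2 > 1)) {
    stop("labels must be sO2 fractions in [0, 1]")
  }
  if (model$kind == "lu") return(model) # nothing to fit
  if (model$kind == "lstm") {
    fit <- lstm_train_cpp(dataset$amplitudes, dataset$mask, dataset$so2,
                          h$lstm_hidden, h$fc_hidden, h$epochs, h$initial_lr,
                          h$lr_factor, h$lr_patience, h$lr_min, h$batch_size,
                          h$val_fraction, h$seed, verbose)
  } else if (model$kind == "lsd") {
    if (!all(dataset$mask)) {
      stop("the feedforward baseline requires the full wavelength set; ",
           "masked wavelengths are not supported by this architecture")
    }
    fit <- mlp_train_cpp(dataset$amplitudes, dataset$so2, model$hidden[1],
                         model$hidden[2], h$epochs, h$initial_lr,
                         h$lr_factor, h$lr_patience, h$lr_min, h$batch_size,
                         h$val_fraction, h$seed, verbose)
  } else stop("unknown model kind: ", model$kind)
  model$weights <- fit$weights
  model$log <- data.frame(epoch = seq_len(h$epochs),
                          train_loss = fit$train_loss,
                          val_loss = fit$val_loss, lr = fit$lr)
  model$trained_nlambda <- as.integer(stats::median(rowSums(dataset$mask)))
  model$trained_variant <- dataset$variant
  model
}

check_normalized <- function(dataset) {
  if (!isTRUE(dataset$normalized)) {
    stop("dataset is not z-scored; run zscore_dataset() first")
  }
  # spot-check the contract on a few spectra
  idx <- unique(c(1L, n_spectra(dataset)))
  for (i in idx) {
    v <- dataset$amplitudes[i, dataset$mask[i, ]]
    if (length(v) >= 2 && (abs(mean(v)) > 1e-6 || abs(mean(v^2) - 1) > 1e-4)) {
      stop("dataset flagged normalized but spectrum ", i,
           " is not z-scored (mean ", signif(mean(v), 3), ")")
    }
  }
  invisible(TRUE)
}

#' Predict sO2 for a dataset
#'
#' One estimate per spectrum, always in \[0, 1\]. The masked LSTM accepts
#' any wavelength mask regardless of the mask it was trained with; the
#' feedforward baseline rejects masked input; linear unmixing uses the
#' present wavelengths of each spectrum.
#'
#' @param object A trained `oximeter_model`.
#' @param dataset A `spectra_dataset` (z-scored for the learned kinds).
#' @param ... Unused.
#' @return Numeric vector of sO2 fractions.
#' @export
predict.oximeter_model <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (!identical(dataset$grid$wavelengths, object$grid$wavelengths)) {
    stop("dataset wavelength grid does not match the model grid")
  }
  if (is.null(object$weights)) stop("model is untrained")
  if (object$kind == "lu") {
    return(linear_unmixing_matrix(dataset$amplitudes, dataset$mask,
                                  object$table))
  }
  check_normalized(dataset)
  if (object$kind == "lstm") {
    if (any(rowSums(dataset$mask) == 0)) {
      stop("fully masked spectrum: no present wavelengths")
    }
    h <- object$hyper
    as.numeric(lstm_predict_cpp(object$weights, dataset$amplitudes,
                                dataset$mask, h$lstm_hidden, h$batch_size))
  } else {
    if (!all(dataset$mask)) {
      stop("the feedforward baseline requires the full wavelength set")
    }
    as.numeric(mlp_predict_cpp(object$weights, dataset$amplitudes,
                               object$hyper$batch_size))
  }
}

#' Non-negative linear spectral unmixing
#'
#' Fits `amplitudes ~ a * mu_a_HbO2 + b * mu_a_Hb` over the present
#' wavelengths with `a, b >= 0` (exact two-variable non-negative least
#' squares) and returns `a / (a + b)`. Scale-invariant in the input. The
#' degenerate all-zero fit returns 0.5 with attribute `flagged = TRUE`.
#'
#' @param spectrum Numeric length-41 amplitude vector (raw or z-scored).
#' @param mask Logical presence vector (default all present); at least 2
#'   present wavelengths.
#' @param table Chromophore table providing the basis spectra.
#' @return sO2 estimate in \[0, 1\].
#' @export
#' @examples
#' tab <- chromophore_table()
#' linear_unmixing(blood_absorption(0.3, 1, tab), table = tab) # 0.3
linear_unmixing <- function(spectrum, mask = rep(TRUE, 41L),
                            table = chromophore_table()) {
  stopifnot(length(spectrum) == 41L, length(mask) == 41L)
  if (sum(mask) < 2) stop("need at least 2 present wavelengths")
  v <- spectrum[mask]
  if (max(v) == min(v)) stop("constant spectrum cannot be unmixed")
  est <- linear_unmixing_matrix(matrix(spectrum, 1), matrix(mask, 1), table)
  est
}

# vectorized exact 2-variable NNLS over rows
linear_unmixing_matrix <- function(amps, mask, table = chromophore_table()) {
  a1 <- table$mu_a_hbo2
  a2 <- table$mu_a_hb
  m <- mask * 1
  x <- amps * m
  g11 <- as.numeric(m %*% (a1 * a1))
  g22 <- as.numeric(m %*% (a2 * a2))
  g12 <- as.numeric(m %*% (a1 * a2))
  b1 <- as.numeric(x %*% a1)
  b2 <- as.numeric(x %*% a2)
  det <- g11 * g22 - g12^2
  # unconstrained solution
  ca <- (g22 * b1 - g12 * b2) / det
  cb <- (g11 * b2 - g12 * b1) / det
  neg <- !(ca >= 0 & cb >= 0) | !is.finite(ca) | !is.finite(cb)
  if (any(neg)) {
    # boundary candidates: (b1/g11, 0) and (0, b2/g22), clipped at 0;
    # objective difference = -2 b'c + c'Gc, lower wins, ties toward lower s
    p1 <- pmax(0, b1 / g11)
    p2 <- pmax(0, b2 / g22)
    f1 <- -2 * b1 * p1 + g11 * p1^2
    f2 <- -2 * b2 * p2 + g22 * p2^2
    use1 <- f1 < f2
    ca[neg] <- ifelse(use1[neg], p1[neg], 0)
    cb[neg] <- ifelse(use1[neg], 0, p2[neg])
  }
  tot <- ca + cb
  est <- ifelse(tot > 0, ca / tot, 0.5)
  flagged <- tot <= 0
  if (any(flagged)) attr(est, "flagged") <- flagged
  pmin(1, pmax(0, est))
}

#' Save / load a trained model checkpoint
#'
#' Single-file checkpoint carrying weights, hyperparameters, grid,
#' training-wavelength signature and provenance.
#'
#' @param model A trained `oximeter_model`.
#' @param path Checkpoint file path.
#' @return `load_model` returns the `oximeter_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "oximeter_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "oximeter_model")) stop("not an oximeter model checkpoint")
  m
}
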