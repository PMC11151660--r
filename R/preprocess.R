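# Spectra selection, wavelength subsetting, per-spectrum z-scoring and
# stratified resampling. The pipeline order used throughout the package is
# selection -> subsetting -> z-scoring -> resampling.

#' Select high-signal spectra
#'
#' Discards spectra whose amplitude at 800 nm is below 10% of the dataset
#' maximum (a proxy for low signal-to-noise voxels dominated by optical
#' attenuation). If fewer than 10% of the input spectra survive that
#' threshold, the rule falls back to keeping the 10% of spectra with the
#' highest 800 nm amplitude (ties broken by stable input order). The
#' fallback is applied per dataset.
#'
#' @param dataset A `spectra_dataset` with non-negative amplitudes.
#' @return A list with elements `dataset` (the kept spectra) and `report`
#'   (a `selection_report` with counts `n_input`, `n_kept_threshold`,
#'   `fallback_used`, `n_final`).
#' @export
select_spectra <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  n <- n_spectra(dataset)
  if (n == 0) stop("empty dataset")
  i800 <- wavelength_index(800)
  if (!any(dataset$mask[, i800])) {
    stop("800 nm is masked in every spectrum; the selection rule needs it")
  }
  a800 <- ifelse(dataset$mask[, i800], dataset$amplitudes[, i800], -Inf)
  thr <- 0.10 * max(a800)
  keep <- which(a800 >= thr)
  n_thr <- length(keep)
  n_min <- ceiling(0.10 * n)
  fallback <- n_thr < n_min
  if (fallback) {
    keep <- order(-a800)[seq_len(n_min)] # stable for ties (radix)
    keep <- sort(keep)                   # preserve input order
  }
  report <- structure(
    list(n_input = n, n_kept_threshold = n_thr, fallback_used = fallback,
         n_final = length(keep)),
    class = "selection_report")
  list(dataset = ds_take(dataset, keep), report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection: ", x$n_input, " in, ", x$n_kept_threshold,
      " passed the 10%-of-max threshold at 800 nm, ",
      if (x$fallback_used) "top-10% fallback used, " else "",
      x$n_final, " kept\n", sep = "")
  invisible(x)
}

#' Per-spectrum z-score normalization
#'
#' Standardizes every spectrum over its present wavelengths to mean 0 and
#' population variance 1 (divide-by-N), discarding intensity information so
#' that models trained on simulations can be applied to uncalibrated
#' experimental data. Masked slots remain 0. Constant spectra cannot be
#' standardized and raise an error naming the offending rows.
#'
#' @param dataset A `spectra_dataset` (at least 2 present wavelengths per
#'   spectrum).
#' @return The z-scored `spectra_dataset` with `normalized = TRUE`.
#' @export
zscore_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  a <- dataset$amplitudes
  m <- dataset$mask
  k <- rowSums(m)
  if (any(k < 2)) {
    stop("z-scoring needs at least 2 present wavelengths; offending spectra: ",
         paste(utils::head(which(k < 2), 5), collapse = ", "))
  }
  a[!m] <- 0
  mu <- rowSums(a) / k
  ac <- (a - mu) * m
  sd_pop <- sqrt(rowSums(ac^2) / k)
  bad <- which(sd_pop == 0)
  if (length(bad) > 0) {
    stop("constant spectra cannot be z-scored (sigma = 0); offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- dataset
  out$amplitudes <- ac / sd_pop
  out$amplitudes[!m] <- 0
  out$normalized <- TRUE
  out
}

#' z-score a single spectrum over its present wavelengths
#'
#' @param x Numeric amplitude vector.
#' @param mask Logical presence vector (default: all present).
#' @return Numeric vector with masked entries 0 and the present entries
#'   standardized to mean 0, population variance 1.
#' @export
zscore_spectrum <- function(x, mask = rep(TRUE, length(x))) {
  stopifnot(length(x) == length(mask))
  v <- x[mask]
  if (length(v) < 2) stop("need at least 2 present wavelengths")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) stop("constant spectrum cannot be z-scored (sigma = 0)")
  out <- numeric(length(x))
  out[mask] <- (v - mean(v)) / s
  out
}

#' Stratified resampling with replacement
#'
#' Draws exactly `n` spectra uniformly with replacement, equalizing dataset
#' sizes before training so that no tissue variant dominates by its number
#' of extractable spectra. Uses an explicit counter-based generator, so the
#' result depends only on `seed`.
#'
#' @param dataset A non-empty `spectra_dataset`.
#' @param n Number of spectra to draw.
#' @param seed Seed for the counter-based stream.
#' @return A `spectra_dataset` with `n` spectra.
#' @export
stratified_resample <- function(dataset, n, seed) {
  stopifnot(inherits(dataset, "spectra_dataset"), n > 0)
  nn <- n_spectra(dataset)
  if (nn == 0) stop("empty dataset")
  u <- pa_runif_stream(seed, 0, as.integer(n))
  idx <- pmin(floor(u * nn) + 1L, nn)
  ds_take(dataset, idx)
}

# permutation of seq_len(n) from a named counter stream
counter_permutation <- function(seed, stream, n) {
  order(pa_runif_stream(seed, stream, n))
}

#' Restrict a dataset to a wavelength subset
#'
#' Masks out all wavelengths not in `keep` (amplitudes at removed slots are
#' set to 0). The 41-slot representation is retained, so models consuming
#' the full lattice keep working.
#'
#' @param dataset A `spectra_dataset`.
#' @param keep Wavelengths (nm) to keep; must lie on the grid, at least 2.
#' @return The masked `spectra_dataset`.
#' @export
subset_wavelengths <- function(dataset, keep) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (length(keep) < 2) stop("keep at least 2 wavelengths")
  slots <- wavelength_index(keep)
  out <- dataset
  drop <- setdiff(seq_len(41L), slots)
  out$mask[, drop] <- FALSE
  out$amplitudes[, drop] <- 0
  out
}
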