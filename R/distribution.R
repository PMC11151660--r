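# Dataset-distance machinery: per-wavelength histograms of z-scored
# spectra, Kullback-Leibler / Jensen-Shannon divergences, the aggregate
# per-wavelength Jensen-Shannon distance between datasets, candidate
# ranking and the divergence-error correlation.

JS_BINS <- 100L
JS_RANGE <- c(-3, 3)

#' Per-wavelength histograms of a dataset
#'
#' For every present wavelength, builds a 100-bin histogram of the
#' z-scored amplitudes at that wavelength across spectra, over the fixed
#' range -3 to +3 standard scores. Values outside the range are excluded
#' before normalization (the bins then renormalize to total mass 1); the
#' last bin is right-closed so a value exactly at +3 is counted. If the
#' dataset is not yet z-scored it is standardized first.
#'
#' @param dataset A `spectra_dataset`.
#' @return A `wavelength_histogram_set`: matrix `density` (100 x 41,
#'   columns summing to 1 or flagged empty), `n_samples` per wavelength,
#'   `present` wavelengths, and the bin `edges`.
#' @export
build_histograms <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (n_spectra(dataset) == 0) stop("empty dataset")
  if (!isTRUE(dataset$normalized)) dataset <- zscore_dataset(dataset)
  a <- dataset$amplitudes
  m <- dataset$mask
  width <- diff(JS_RANGE) / JS_BINS
  dens <- matrix(0, JS_BINS, 41L)
  nin <- integer(41L)
  for (j in seq_len(41L)) {
    v <- a[m[, j], j]
    v <- v[v >= JS_RANGE[1] & v <= JS_RANGE[2]]
    nin[j] <- length(v)
    if (length(v) == 0) next
    idx <- pmin(floor((v - JS_RANGE[1]) / width) + 1L, JS_BINS)
    dens[, j] <- tabulate(idx, JS_BINS) / length(v)
  }
  structure(list(density = dens, n_samples = nin,
                 present = colSums(m) > 0,
                 edges = seq(JS_RANGE[1], JS_RANGE[2], length.out = JS_BINS + 1)),
            class = "wavelength_histogram_set")
}

#' Kullback-Leibler divergence between binned densities
#'
#' `sum P(x) log(P(x)/Q(x))` in nats, with the conventions
#' `0 log(0/q) = 0` and `p log(p/0) = +Inf`.
#'
#' @param p,q Non-negative densities over the same bins (each summing
#'   to 1).
#' @return Divergence in nats; possibly `Inf`.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("densities have mismatched bin counts")
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence and distance
#'
#' The symmetrized, always-finite divergence
#' `0.5 KL(P || M) + 0.5 KL(Q || M)` with `M = (P + Q)/2`, bounded by
#' `ln 2` in nats. The reported score throughout the package is its
#' square root, the Jensen-Shannon *distance* (a metric), bounded by
#' `sqrt(ln 2) ~ 0.8326`.
#'
#' @param p,q Densities over the same bins.
#' @return `js_divergence`: divergence in nats; `js_distance`: its square
#'   root.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("densities have mismatched bin counts")
  m <- (p + q) / 2
  kp <- p > 0
  kq <- q > 0
  0.5 * sum(p[kp] * log(p[kp] / m[kp])) + 0.5 * sum(q[kq] * log(q[kq] / m[kq]))
}

#' @rdname js_divergence
#' @export
js_distance <- function(p, q) sqrt(max(0, js_divergence(p, q)))

#' Aggregate per-wavelength Jensen-Shannon distance between datasets
#'
#' The dataset-shift score used to pick training data: both datasets are
#' subsampled (without replacement, capped at the dataset size),
#' per-wavelength histograms of the z-scored spectra are built, the
#' Jensen-Shannon distance is computed per wavelength over the
#' intersection of the two wavelength sets, and the mean over wavelengths
#' is taken. The subsample/histogram/mean cycle is repeated `repeats`
#' times and averaged. Deterministic given `seed`.
#'
#' @param reference,target `spectra_dataset`s with a non-empty wavelength
#'   intersection.
#' @param n_subsample Spectra drawn per repeat from each dataset.
#' @param repeats Number of subsampling repeats.
#' @param seed Seed for the counter-based subsampling streams.
#' @return A `divergence_result`: `djs_bar` (mean over repeats of the
#'   per-repeat wavelength means), `per_wavelength` (named, averaged over
#'   repeats), `n_lambda_used`, and `repeats` (per-repeat scores).
#' @export
djs_bar <- function(reference, target, n_subsample = 10000, repeats = 10,
                    seed = 1) {
  stopifnot(inherits(reference, "spectra_dataset"),
            inherits(target, "spectra_dataset"), repeats >= 1)
  inter <- intersect(present_wavelengths(reference),
                     present_wavelengths(target))
  if (length(inter) == 0) {
    stop("empty wavelength intersection: the datasets share no wavelengths")
  }
  slots <- wavelength_index(inter)
  if (!isTRUE(reference$normalized)) reference <- zscore_dataset(reference)
  if (!isTRUE(target$normalized)) target <- zscore_dataset(target)
  per_rep <- numeric(repeats)
  per_wl <- matrix(NA_real_, repeats, length(slots))
  warned <- FALSE
  for (r in seq_len(repeats)) {
    ha <- build_histograms(subsample_ds(reference, n_subsample, seed, 2L * r))
    hb <- build_histograms(subsample_ds(target, n_subsample, seed, 2L * r + 1L))
    d <- vapply(seq_along(slots), function(k) {
      j <- slots[k]
      if (ha$n_samples[j] == 0 || hb$n_samples[j] == 0) return(NA_real_)
      js_distance(ha$density[, j], hb$density[, j])
    }, numeric(1))
    if (anyNA(d) && !warned) {
      warning("wavelength(s) without in-range samples dropped from the mean")
      warned <- TRUE
    }
    per_wl[r, ] <- d
    per_rep[r] <- mean(d, na.rm = TRUE)
  }
  pw <- colMeans(per_wl, na.rm = TRUE)
  names(pw) <- inter
  structure(list(djs_bar = mean(per_rep), per_wavelength = pw,
                 n_lambda_used = sum(!is.na(pw)), repeats = per_rep),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("aggregate Jensen-Shannon distance: ", signif(x$djs_bar, 4), " over ",
      x$n_lambda_used, " wavelengths (", length(x$repeats), " repeats, sd ",
      signif(stats::sd(x$repeats), 3), ")\n", sep = "")
  invisible(x)
}

subsample_ds <- function(ds, n, seed, stream) {
  nn <- n_spectra(ds)
  n <- min(n, nn)
  if (n == nn) return(ds)
  keys <- pa_runif_stream(seed, stream, nn)
  ds_take(ds, order(keys)[seq_len(n)])
}

#' Rank candidate training sets against a target dataset
#'
#' Computes the aggregate Jensen-Shannon distance between each candidate
#' and the target and returns the candidates in ascending order (best
#' match first; stable ties by input order). The top-ranked candidate is
#' the recommended training distribution for the target application.
#'
#' @param target The target `spectra_dataset`.
#' @param candidates Named list of candidate `spectra_dataset`s.
#' @param ... Passed to [djs_bar()] (`n_subsample`, `repeats`, `seed`).
#' @return A data.frame with columns `candidate`, `djs_bar`, `rank`,
#'   ordered by `djs_bar`.
#' @export
rank_training_sets <- function(target, candidates, ...) {
  stopifnot(length(candidates) >= 1)
  nm <- names(candidates)
  if (is.null(nm)) nm <- paste0("candidate_", seq_along(candidates))
  scores <- vapply(candidates, function(cd) djs_bar(cd, target, ...)$djs_bar,
                   numeric(1))
  ord <- order(scores) # stable: ties keep input order
  data.frame(candidate = nm[ord], djs_bar = as.numeric(scores[ord]),
             rank = seq_along(ord), row.names = NULL)
}

#' Correlation between divergence scores and estimation errors
#'
#' Pearson product-moment correlation between per-candidate divergence
#' scores and the corresponding sO2 estimation errors; the quantity that
#' justifies using the divergence as an unsupervised proxy for accuracy.
#'
#' @param scores,errors Equal-length numeric vectors (n >= 3), neither
#'   constant.
#' @return Pearson r in \[-1, 1\].
#' @export
correlate_djs_error <- function(scores, errors) {
  if (length(scores) != length(errors)) stop("length mismatch")
  if (length(scores) < 3) stop("need at least 3 pairs")
  if (stats::sd(scores) == 0 || stats::sd(errors) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(scores, errors)
}
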