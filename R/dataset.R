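#' Labeled spectra collections
#'
#' A `spectra_dataset` holds per-pixel photoacoustic amplitude spectra on the
#' fixed 41-channel lattice together with a wavelength presence mask, the
#' ground-truth oxygen saturation labels, the vessel depths where known, and
#' provenance (variant name, seed, generator version). Amplitudes at masked
#' slots are stored as zero.
#'
#' @param amplitudes Numeric n x 41 matrix, finite, non-negative unless the
#'   dataset has been z-scored.
#' @param mask Logical n x 41 matrix; `TRUE` where the wavelength is present.
#' @param so2 Numeric vector of ground-truth sO2 fractions in \[0, 1\].
#' @param depth Numeric vector of vessel depths in mm (or `NA`).
#' @param variant Variant name, non-empty string.
#' @param seed Generator seed used, for provenance.
#' @param normalized Logical: has per-spectrum z-scoring been applied?
#' @return A `spectra_dataset` object.
#' @export
spectra_dataset <- function(amplitudes, mask, so2, depth = NULL,
                            variant = "unknown", seed = NA_real_,
                            normalized = FALSE) {
  amplitudes <- as.matrix(amplitudes)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  n <- nrow(amplitudes)
  if (is.null(depth)) depth <- rep(NA_real_, n)
  stopifnot(ncol(amplitudes) == 41L, all(dim(mask) == dim(amplitudes)),
            length(so2) == n, length(depth) == n,
            all(is.finite(amplitudes)), !anyNA(mask),
            all(so2 >= 0 & so2 <= 1), nzchar(variant))
  amplitudes[!mask] <- 0
  dimnames(amplitudes) <- NULL
  dimnames(mask) <- NULL
  structure(
    list(amplitudes = amplitudes, mask = mask, so2 = as.numeric(so2),
         depth = as.numeric(depth), variant = as.character(variant)[1],
         seed = seed, generator_version = PAOX_GENERATOR_VERSION,
         grid = wavelength_grid(), normalized = isTRUE(normalized)),
    class = "spectra_dataset")
}

PAOX_GENERATOR_VERSION <- "1"

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("spectra_dataset: ", nrow(x$amplitudes), " spectra, ",
      sum(colSums(x$mask) > 0), "/41 wavelengths present, variant '",
      x$variant, "'", if (x$normalized) ", z-scored", "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname spectra_dataset
#' @param x A `spectra_dataset`.
n_spectra <- function(x) nrow(x$amplitudes)

#' Wavelengths present anywhere in a dataset
#' @noRd
present_wavelengths <- function(x) {
  wavelength_grid()$wavelengths[colSums(x$mask) > 0]
}

# take rows by index, preserving metadata
ds_take <- function(x, idx) {
  out <- x
  out$amplitudes <- x$amplitudes[idx, , drop = FALSE]
  out$mask <- x$mask[idx, , drop = FALSE]
  out$so2 <- x$so2[idx]
  out$depth <- x$depth[idx]
  out
}

# concatenate datasets (used by the mixed "ALL" training set)
ds_bind <- function(lst, variant = "ALL") {
  stopifnot(length(lst) >= 1)
  out <- lst[[1]]
  out$amplitudes <- do.call(rbind, lapply(lst, `[[`, "amplitudes"))
  out$mask <- do.call(rbind, lapply(lst, `[[`, "mask"))
  out$so2 <- unlist(lapply(lst, `[[`, "so2"), use.names = FALSE)
  out$depth <- unlist(lapply(lst, `[[`, "depth"), use.names = FALSE)
  out$variant <- variant
  out$normalized <- all(vapply(lst, `[[`, TRUE, "normalized"))
  out
}

.DS_CSV_COLS <- function() {
  w <- wavelength_grid()$wavelengths
  c("spectrum_id", paste0("a", w), paste0("m", w),
    "so2_true", "depth", "variant", "seed", "normalized")
}

#' Read and write spectra datasets as CSV
#'
#' Flat delimited-text serialization: one row per spectrum with the 41
#' amplitude columns (`a700` ... `a900`), the 41 presence-mask columns
#' (`m700` ... `m900`, 0/1), the label, depth and provenance. The round trip
#' is lossless including masks.
#'
#' @param dataset A `spectra_dataset`.
#' @param path CSV file path.
#' @return `read_dataset` returns a `spectra_dataset`; `write_dataset`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  w <- wavelength_grid()$wavelengths
  df <- data.frame(spectrum_id = seq_len(n_spectra(dataset)))
  amp <- dataset$amplitudes
  colnames(amp) <- paste0("a", w)
  msk <- dataset$mask * 1L
  colnames(msk) <- paste0("m", w)
  df <- cbind(df, amp, msk)
  df$so2_true <- dataset$so2
  df$depth <- dataset$depth
  df$variant <- dataset$variant
  df$seed <- dataset$seed
  df$normalized <- as.integer(dataset$normalized)
  # 17 significant digits guarantee an exact double round trip through text
  for (cl in names(df)) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  want <- .DS_CSV_COLS()
  missing <- setdiff(want, names(df))
  if (length(missing) > 0) {
    stop("dataset file schema violation in '", path, "': missing field(s) ",
         paste(missing, collapse = ", "))
  }
  w <- wavelength_grid()$wavelengths
  spectra_dataset(
    amplitudes = as.matrix(df[, paste0("a", w)]),
    mask = as.matrix(df[, paste0("m", w)]) > 0,
    so2 = df$so2_true, depth = df$depth,
    variant = df$variant[1], seed = df$seed[1],
    normalized = df$normalized[1] > 0)
}
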