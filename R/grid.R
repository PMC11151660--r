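#' The fixed 700-900 nm wavelength lattice
#'
#' All spectra handled by this package live on a fixed sampling lattice of 41
#' center wavelengths from 700 to 900 nm in 5 nm steps. Spectra with fewer
#' wavelengths are represented on the full lattice with a presence mask, which
#' is what makes the recurrent regressor wavelength-flexible.
#'
#' @return A `wavelength_grid` object with fields `wavelengths` (length 41)
#'   and `step` (5, nm).
#' @export
#' @examples
#' g <- wavelength_grid()
#' length(g$wavelengths)
wavelength_grid <- function() {
  g <- structure(list(wavelengths = seq(700, 900, by = 5), step = 5),
                 class = "wavelength_grid")
  validate_wavelength_grid(g)
  g
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat("wavelength grid: ", length(x$wavelengths), " channels, ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm, step ", x$step,
      " nm\n", sep = "")
  invisible(x)
}

validate_wavelength_grid <- function(g) {
  w <- g$wavelengths
  stopifnot(length(w) == 41L, w[1] == 700, w[41] == 900,
            all(diff(w) == g$step), g$step == 5)
  invisible(g)
}

#' Number of channels on the lattice
#' @noRd
n_wavelengths <- function() 41L

#' Map wavelengths to lattice slots
#'
#' @param nm Numeric vector of wavelengths in nm.
#' @return Integer slot indices (1-based) on the 41-channel lattice.
#' @export
wavelength_index <- function(nm) {
  idx <- match(nm, wavelength_grid()$wavelengths)
  if (anyNA(idx)) {
    stop("wavelength(s) not on the 700-900 nm / 5 nm grid: ",
         paste(nm[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Evenly spaced wavelength subsets
#'
#' Deterministic choice of `n` wavelengths used by the wavelength-count
#' experiments: slots are spread evenly over the 41-slot lattice with both
#' endpoints (700 and 900 nm) included. Fractional slot positions are rounded
#' to the nearest slot with ties broken toward the lower index, so the subset
#' is reproducible from `n` alone.
#'
#' @param n Number of wavelengths, between 2 and 41.
#' @return Numeric vector of `n` wavelengths in nm.
#' @export
#' @examples
#' evenly_spaced_wavelengths(3) # 700, 800, 900
evenly_spaced_wavelengths <- function(n) {
  stopifnot(length(n) == 1L, n >= 2L, n <= 41L)
  pos <- seq(1, 41, length.out = n)
  slots <- as.integer(ceiling(pos - 0.5)) # round half down
  wavelength_grid()$wavelengths[slots]
}
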