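# Embedded optical properties on the 700-900 nm lattice.
#
# The hemoglobin values are a 10 nm tabulation of molar extinction
# coefficients representative of the standard literature compilation
# (Prahl's hemoglobin tables), converted to whole-blood absorption at
# 150 g/L hemoglobin; water follows the Hale & Querry measurements; the
# melanosome interior follows the Jacques power law. All are linearly
# interpolated to the 5 nm grid. Units are mm^-1 throughout.

# molar extinction, cm^-1 / (mol/L), 10 nm spacing 700..900 nm
.EXT_NM   <- seq(700, 900, by = 10)
.EXT_HBO2 <- c(290, 320, 356, 390, 446, 518, 586, 650, 710, 756, 816,
               864, 916, 974, 1022, 1058, 1092, 1128, 1154, 1176, 1198)
.EXT_HB   <- c(1794.28, 1540.48, 1325.88, 1102.20, 1115.88, 1405.24,
               1548.52, 1311.88, 1075.44, 890.80, 761.72, 717.08, 693.76,
               693.04, 692.36, 691.32, 691.96, 693.20, 723.52, 741.32,
               761.84)
# pure water absorption, cm^-1
.WATER_CM <- c(0.0062, 0.0090, 0.0125, 0.0180, 0.0245, 0.0270, 0.0265,
               0.0245, 0.0230, 0.0225, 0.0215, 0.0205, 0.0225, 0.0270,
               0.0340, 0.0410, 0.0450, 0.0500, 0.0550, 0.0610, 0.0680)

# whole blood: 150 g/L hemoglobin, MW 64500 g/mol
.HB_MOLAR <- 150 / 64500
.EXT_TO_MM <- log(10) * .HB_MOLAR / 10  # cm^-1/(mol/L) -> mm^-1 at 150 g/L

#' Chromophore absorption tables on the wavelength grid
#'
#' Returns the embedded optical-property table used throughout the package:
#' absorption coefficients of fully oxygenated and fully deoxygenated whole
#' blood (150 g/L hemoglobin), pure water, the melanosome interior
#' (`1.7e12 * lambda^-3.48` cm^-1), and the background reduced scattering
#' coefficient (constant 1.0 mm^-1 by default, matching a fixed-anisotropy
#' tissue assumption). Values are interpolated to the 41-channel lattice.
#'
#' @param mu_s_prime_bg Background reduced scattering in mm^-1 (default 1.0).
#' @return A data.frame with columns `wavelength_nm`, `mu_a_hbo2`, `mu_a_hb`,
#'   `mu_a_water`, `mu_a_melanin_ref`, `mu_s_prime_bg` (all mm^-1), with a
#'   `source` attribute describing provenance.
#' @export
#' @examples
#' tab <- chromophore_table()
#' tab[tab$wavelength_nm == 800, ]
chromophore_table <- function(mu_s_prime_bg = 1.0) {
  stopifnot(is.numeric(mu_s_prime_bg), mu_s_prime_bg > 0)
  w <- wavelength_grid()$wavelengths
  tab <- data.frame(
    wavelength_nm    = w,
    mu_a_hbo2        = stats::approx(.EXT_NM, .EXT_HBO2, w)$y * .EXT_TO_MM,
    mu_a_hb          = stats::approx(.EXT_NM, .EXT_HB, w)$y * .EXT_TO_MM,
    mu_a_water       = stats::approx(.EXT_NM, .WATER_CM, w)$y / 10,
    mu_a_melanin_ref = 1.70e12 * w^(-3.48) / 10,
    mu_s_prime_bg    = rep(mu_s_prime_bg, length(w))
  )
  attr(tab, "source") <- paste(
    "Whole blood at 150 g/L hemoglobin from a 10 nm tabulation representative",
    "of the standard compilation (Prahl); water after Hale & Querry;",
    "melanosome interior after the Jacques power law. Linear interpolation",
    "to the 5 nm lattice; units mm^-1.")
  validate_chromophore_table(tab)
  tab
}

validate_chromophore_table <- function(tab) {
  num <- tab[, c("mu_a_hbo2", "mu_a_hb", "mu_a_water", "mu_a_melanin_ref",
                 "mu_s_prime_bg")]
  stopifnot(nrow(tab) == 41L, all(is.finite(as.matrix(num))),
            all(as.matrix(num) > 0))
  i760 <- match(760, tab$wavelength_nm)
  i900 <- match(900, tab$wavelength_nm)
  stopifnot(tab$mu_a_hb[i760] > tab$mu_a_hbo2[i760],
            tab$mu_a_hbo2[i900] > tab$mu_a_hb[i900])
  invisible(tab)
}

#' Absorption spectrum of partially oxygenated blood
#'
#' Linear mixing of the oxy- and deoxyhemoglobin endmembers scaled by the
#' blood volume fraction:
#' `mu_a(lambda) = bvf * (s * mu_a_HbO2(lambda) + (1 - s) * mu_a_Hb(lambda))`.
#'
#' @param s Oxygen saturation fraction in \[0, 1\].
#' @param bvf Blood volume fraction in \[0, 1\].
#' @param table Chromophore table from [chromophore_table()].
#' @return Numeric length-41 absorption spectrum in mm^-1.
#' @export
blood_absorption <- function(s, bvf, table = chromophore_table()) {
  stopifnot(length(s) == 1L, length(bvf) == 1L, is.finite(s), is.finite(bvf))
  if (s < 0 || s > 1) stop("oxygen saturation s must be in [0, 1]")
  if (bvf < 0 || bvf > 1) stop("blood volume fraction bvf must be in [0, 1]")
  bvf * (s * table$mu_a_hbo2 + (1 - s) * table$mu_a_hb)
}

#' Severinghaus oxygen dissociation reference
#'
#' Converts blood oxygen partial pressure to hemoglobin oxygen saturation
#' using the classic closed form
#' `S = 1 / (23400 / (pO2^3 + 150 * pO2) + 1)`,
#' the standard reference conversion for pO2 probe measurements.
#'
#' @param po2 Oxygen partial pressure in mmHg, non-negative (vectorized).
#' @return sO2 as a fraction in \[0, 1); `po2 = 0` returns the limit value 0.
#' @export
#' @examples
#' severinghaus_so2(26.9) # about 0.5 (P50 of adult hemoglobin)
severinghaus_so2 <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 < 0)) {
    stop("po2 must be finite and non-negative (mmHg)")
  }
  s <- ifelse(po2 == 0, 0, 1 / (23400 / (po2^3 + 150 * po2) + 1))
  as.numeric(s)
}

#' Export / import chromophore tables as delimited text
#'
#' Writes one two-column tab-separated file per chromophore
#' (`wavelength_nm`, `value_per_mm`) into `dir`, and reads such a directory
#' back into a table.
#'
#' @param table Chromophore table.
#' @param dir Directory for the per-chromophore text files.
#' @return `export_chromophores` returns the file paths invisibly;
#'   `import_chromophores` returns a chromophore table data.frame.
#' @export
export_chromophores <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- setdiff(names(table), "wavelength_nm")
  paths <- character(0)
  for (cl in cols) {
    p <- file.path(dir, paste0(cl, ".tsv"))
    utils::write.table(
      data.frame(wavelength_nm = table$wavelength_nm, value_per_mm = table[[cl]]),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname export_chromophores
#' @export
import_chromophores <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no chromophore .tsv files in ", dir)
  out <- NULL
  for (p in files) {
    d <- utils::read.table(p, header = TRUE, sep = "\t")
    if (!identical(names(d), c("wavelength_nm", "value_per_mm"))) {
      stop("bad chromophore file schema in ", p,
           ": expected columns wavelength_nm, value_per_mm")
    }
    if (is.null(out)) out <- data.frame(wavelength_nm = d$wavelength_nm)
    out[[sub("\\.tsv$", "", basename(p))]] <- d$value_per_mm
  }
  out
}
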