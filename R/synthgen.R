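# Fast analytic surrogate for Monte Carlo photoacoustic training data.
#
# A 1-D layered diffusion-approximation light model replaces volumetric
# photon transport: the fluence reaching a vessel at depth z is a product of
# a geometric divergence factor and Beer-Lambert attenuation through an
# optional water coupling layer, an optional melanin skin layer, and the
# blood-perfused background, using the effective attenuation coefficient
# mu_eff = sqrt(3 mu_a (mu_a + mu_s')). The measured amplitude is then
# fluence x vessel blood absorption x a radius-dependent self-shading
# factor, with multiplicative Gaussian noise.

#' Tissue variant configuration
#'
#' Describes one simulated tissue family: background oxygenation and blood
#' volume fraction, optional melanin skin layer, optional water coupling
#' layer, vessel radius/depth ranges, an illumination divergence proxy, the
#' voxel quantization, and the noise level. The built-in variants (see
#' [builtin_variants()]) differ from the baseline by exactly one of these
#' knobs each.
#'
#' @param name Variant identifier.
#' @param bg_medium `"blood"` (perfused muscle) or `"water"`.
#' @param bg_so2 Length-2 range of background oxygenation fractions; equal
#'   values give a fixed background.
#' @param bg_het Logical: draw the background oxygenation as a
#'   depth-correlated heterogeneous field instead of a single uniform value.
#' @param bg_bvf Background blood volume fraction.
#' @param skin_thickness Melanin layer thickness, mm (0 = none).
#' @param melanosome_fraction Length-2 range of melanosome volume fractions.
#' @param water_layer Water coupling layer thickness, mm (0 = none).
#' @param vessel_radius Length-2 range of vessel radii, mm.
#' @param vessel_depth Length-2 range of vessel depths below the tissue
#'   surface, mm.
#' @param illumination_spread Geometric-decay exponent of the beam
#'   divergence proxy `G(z) = (1 + z/z0)^-spread`; 0 = collimated wide beam.
#' @param illum_z0 Divergence length scale z0, mm.
#' @param grid_spacing Voxel size, mm; depths and radii are quantized to it.
#' @param noise_sigma Relative multiplicative noise standard deviation.
#' @param n_spectra Number of spectra to generate.
#' @param seed Master seed for the counter-based random streams.
#' @return A `tissue_variant` configuration object.
#' @export
variant_config <- function(name,
                           bg_medium = "blood",
                           bg_so2 = c(0.70, 0.70),
                           bg_het = FALSE,
                           bg_bvf = 0.01,
                           skin_thickness = 0,
                           melanosome_fraction = c(0, 0),
                           water_layer = 0,
                           vessel_radius = c(0.15, 1.0),
                           vessel_depth = c(0.5, 9.0),
                           illumination_spread = 0,
                           illum_z0 = 1,
                           grid_spacing = 0.3,
                           noise_sigma = 0.02,
                           n_spectra = 1000,
                           seed = 1) {
  cfg <- structure(
    list(name = name, bg_medium = bg_medium, bg_so2 = as.numeric(bg_so2),
         bg_het = isTRUE(bg_het), bg_bvf = bg_bvf,
         skin_thickness = skin_thickness,
         melanosome_fraction = as.numeric(melanosome_fraction),
         water_layer = water_layer, vessel_radius = as.numeric(vessel_radius),
         vessel_depth = as.numeric(vessel_depth),
         illumination_spread = illumination_spread, illum_z0 = illum_z0,
         grid_spacing = grid_spacing, noise_sigma = noise_sigma,
         n_spectra = as.integer(n_spectra), seed = seed),
    class = "tissue_variant")
  validate_variant(cfg)
}

#' @export
print.tissue_variant <- function(x, ...) {
  cat("tissue variant '", x$name, "': bg ", x$bg_medium, sep = "")
  if (x$bg_medium == "blood")
    cat(" (bvf ", x$bg_bvf, ", sO2 ", x$bg_so2[1], "-", x$bg_so2[2],
        if (x$bg_het) ", heterogeneous", ")", sep = "")
  cat("; skin ", x$skin_thickness, " mm; water ", x$water_layer,
      " mm; radii ", x$vessel_radius[1], "-", x$vessel_radius[2],
      " mm; voxel ", x$grid_spacing, " mm\n", sep = "")
  invisible(x)
}

validate_variant <- function(cfg) {
  with(cfg, {
    stopifnot(nzchar(name), bg_medium %in% c("blood", "water"),
              length(bg_so2) == 2, bg_so2[1] <= bg_so2[2],
              all(bg_so2 >= 0 & bg_so2 <= 1),
              bg_bvf >= 0, bg_bvf <= 1,
              length(melanosome_fraction) == 2,
              melanosome_fraction[1] <= melanosome_fraction[2],
              all(melanosome_fraction >= 0 & melanosome_fraction <= 1),
              length(vessel_radius) == 2, vessel_radius[1] <= vessel_radius[2],
              vessel_radius[1] >= 0,
              length(vessel_depth) == 2, vessel_depth[1] <= vessel_depth[2],
              grid_spacing > 0, noise_sigma >= 0,
              illumination_spread >= 0, illum_z0 > 0)
    if (skin_thickness < 0 || water_layer < 0) {
      stop("layer thicknesses must be non-negative")
    }
    if (vessel_depth[1] < skin_thickness) {
      stop("vessel_depth lower bound must be at least skin_thickness")
    }
  })
  invisible(cfg)
}

#' Save / load variant configurations as structured text
#'
#' @param cfg A `tissue_variant` configuration.
#' @param path YAML file path.
#' @export
write_variant_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tissue_variant"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_variant_config
#' @export
read_variant_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(variant_config, v)
}

#' Built-in tissue variants
#'
#' The baseline tissue family (`BASE`: muscle background with 1% blood
#' volume fraction at 70% oxygenation, vessel radii 0.15-1.0 mm carrying
#' pure blood with sO2 ~ U\[0,1\], 0.3 mm voxels, collimated wide-beam
#' illumination) and named variants that each change exactly one aspect:
#' background oxygenation ranges (uniform or heterogeneous), a water-only
#' background, a melanin skin layer, halved vessel radii, coarser/finer
#' voxel quantization, diverging illumination, and thick water coupling
#' layers. Device/acoustic variants of the full imaging chain are out of
#' scope of this analytic surrogate.
#'
#' @param n_spectra Spectra per dataset (stored in each config).
#' @param seed Master seed stored in each config.
#' @return Named list of `tissue_variant` configurations.
#' @export
builtin_variants <- function(n_spectra = 1000, seed = 1) {
  base <- variant_config("BASE", n_spectra = n_spectra, seed = seed)
  tweak <- function(name, ...) {
    args <- list(...)
    cfg <- unclass(base)
    cfg[names(args)] <- args
    cfg$name <- name
    do.call(variant_config, cfg)
  }
  list(
    BASE        = base,
    `BG_0-100`  = tweak("BG_0-100", bg_so2 = c(0, 1)),
    `BG_60-80`  = tweak("BG_60-80", bg_so2 = c(0.6, 0.8)),
    BG_H2O      = tweak("BG_H2O", bg_medium = "water"),
    `HET_0-100` = tweak("HET_0-100", bg_so2 = c(0, 1), bg_het = TRUE),
    `HET_60-80` = tweak("HET_60-80", bg_so2 = c(0.6, 0.8), bg_het = TRUE),
    SKIN        = tweak("SKIN", skin_thickness = 0.3,
                        melanosome_fraction = c(0.001, 0.05)),
    SMALL       = tweak("SMALL", vessel_radius = c(0.075, 0.5)),
    RES_0.15    = tweak("RES_0.15", grid_spacing = 0.15),
    RES_0.15_SMALL = tweak("RES_0.15_SMALL", grid_spacing = 0.15,
                           vessel_radius = c(0.075, 0.5)),
    RES_0.6     = tweak("RES_0.6", grid_spacing = 0.6),
    RES_1.2     = tweak("RES_1.2", grid_spacing = 1.2),
    ILLUM_5mm   = tweak("ILLUM_5mm", illumination_spread = 1, illum_z0 = 5),
    ILLUM_POINT = tweak("ILLUM_POINT", illumination_spread = 2, illum_z0 = 1),
    WATER_2cm   = tweak("WATER_2cm", water_layer = 20),
    WATER_4cm   = tweak("WATER_4cm", water_layer = 40)
  )
}

# effective attenuation coefficient of a layer, mm^-1
mu_eff <- function(mu_a, mu_s_prime) sqrt(3 * mu_a * (mu_a + mu_s_prime))

#' Relative fluence at depth under the layered surrogate
#'
#' `Phi(lambda, z) = G(z) * exp(-mu_a_water d_water - mu_eff_skin d_skin -
#' mu_eff_bg (z - d_skin))` with `G(z) = (1 + z/z0)^-spread`. Exposed mainly
#' for testing and plotting; [generate_dataset()] evaluates the same model
#' vectorized over spectra.
#'
#' @param depth Vessel depth below the tissue surface, mm.
#' @param config A `tissue_variant`.
#' @param table Chromophore table.
#' @param bg_so2 Background oxygenation sample (fraction).
#' @param melanosome Melanosome volume fraction sample.
#' @return Numeric length-41 relative fluence, in (0, 1\].
#' @export
fluence_at_depth <- function(depth, config, table = chromophore_table(),
                             bg_so2 = mean(config$bg_so2),
                             melanosome = mean(config$melanosome_fraction)) {
  stopifnot(length(depth) == 1L, depth >= 0)
  validate_variant(config)
  musp <- table$mu_s_prime_bg
  mu_bg <- if (config$bg_medium == "water") table$mu_a_water else
    blood_absorption(bg_so2, config$bg_bvf, table)
  mueff_bg <- mu_eff(mu_bg, musp)
  mueff_skin <- mu_eff(melanosome * table$mu_a_melanin_ref, musp)
  g <- (1 + depth / config$illum_z0)^(-config$illumination_spread)
  z_bg <- max(0, depth - config$skin_thickness)
  g * exp(-table$mu_a_water * config$water_layer -
            mueff_skin * min(depth, config$skin_thickness) -
            mueff_bg * z_bg)
}

# mean intra-vessel fluence of an absorbing cylinder proxy; V -> 1 as r -> 0
vessel_self_shading <- function(mu_a_vessel, radius) {
  x <- 2 * mu_a_vessel * radius
  v <- ifelse(x > 1e-12, (1 - exp(-x)) / x, 1)
  v
}

# fixed per-spectrum draw layout (counter-based streams; changing n_spectra
# never changes earlier spectra)
.DRAW_SO2 <- 1L; .DRAW_BG <- 2L; .DRAW_MEL <- 3L; .DRAW_RAD <- 4L
.DRAW_DEPTH <- 5L; .DRAW_NOISE <- 6:46; .DRAW_HET <- 47:86

#' Generate a labeled surrogate dataset
#'
#' Draws `n_spectra` vessels (sO2 ~ U\[0,1\], radius and depth from the
#' configured ranges, quantized to the voxel size), evaluates the layered
#' fluence model at each vessel, multiplies by the vessel blood absorption
#' spectrum and the radius-dependent self-shading factor, and applies
#' multiplicative Gaussian noise. Fully deterministic given the config
#' (including its seed); each spectrum consumes its own counter-based
#' random stream.
#'
#' @param config A `tissue_variant` configuration.
#' @param n_spectra,seed Optional overrides of the config fields.
#' @return A [spectra_dataset()] with all 41 wavelengths present.
#' @export
generate_dataset <- function(config, n_spectra = NULL, seed = NULL) {
  validate_variant(config)
  if (!is.null(n_spectra)) config$n_spectra <- as.integer(n_spectra)
  if (!is.null(seed)) config$seed <- seed
  n <- config$n_spectra
  if (is.na(n) || n <= 0) stop("n_spectra must be positive")
  tab <- chromophore_table()
  w <- wavelength_grid()$wavelengths
  gs <- config$grid_spacing

  U <- pa_runif_streams(config$seed, n, 86L)

  so2 <- U[.DRAW_SO2, ]
  radius <- config$vessel_radius[1] +
    U[.DRAW_RAD, ] * diff(config$vessel_radius)
  depth <- config$vessel_depth[1] +
    U[.DRAW_DEPTH, ] * diff(config$vessel_depth)
  # voxel quantization: a vessel occupies at least half a voxel
  radius <- ifelse(radius > 0, pmax(gs / 2, round(radius / gs) * gs), 0)
  depth <- pmax(gs, round(depth / gs) * gs)

  bg <- background_so2_samples(config, U, depth)
  mel <- config$melanosome_fraction[1] +
    U[.DRAW_MEL, ] * diff(config$melanosome_fraction)

  musp <- tab$mu_s_prime_bg
  # n x 41 attenuation exponent
  if (config$bg_medium == "water") {
    mueff_bg <- matrix(mu_eff(tab$mu_a_water, musp), n, 41, byrow = TRUE)
  } else {
    mu_bg <- config$bg_bvf *
      (outer(bg, tab$mu_a_hbo2) + outer(1 - bg, tab$mu_a_hb))
    mueff_bg <- sqrt(3 * mu_bg * sweep(mu_bg, 2, musp, `+`))
  }
  z_bg <- pmax(0, depth - config$skin_thickness)
  expo <- mueff_bg * z_bg
  if (config$skin_thickness > 0) {
    mu_skin <- outer(mel, tab$mu_a_melanin_ref)
    mueff_skin <- sqrt(3 * mu_skin * sweep(mu_skin, 2, musp, `+`))
    expo <- expo + mueff_skin * pmin(depth, config$skin_thickness)
  }
  if (config$water_layer > 0) {
    expo <- sweep(expo, 2, tab$mu_a_water * config$water_layer, `+`)
  }
  g <- (1 + depth / config$illum_z0)^(-config$illumination_spread)
  fluence <- g * exp(-expo)

  mu_vessel <- outer(so2, tab$mu_a_hbo2) + outer(1 - so2, tab$mu_a_hb)
  v <- vessel_self_shading(mu_vessel, radius)
  amps <- fluence * mu_vessel * v
  if (config$noise_sigma > 0) {
    eps <- stats::qnorm(t(U[.DRAW_NOISE, , drop = FALSE]))
    amps <- pmax(amps * (1 + config$noise_sigma * eps), 0)
  }
  colnames(amps) <- NULL
  spectra_dataset(amps, matrix(TRUE, n, 41), so2, depth = depth,
                  variant = config$name, seed = config$seed)
}

# Background oxygenation per spectrum. Homogeneous variants draw a single
# uniform value; heterogeneous variants emulate a smoothed random field by
# an AR(1) profile over voxel-quantized depth (correlation length 1.2 mm,
# uniform marginals via a Gaussian copula) averaged over the light path.
background_so2_samples <- function(config, U, depth) {
  lo <- config$bg_so2[1]; hi <- config$bg_so2[2]
  if (config$bg_medium == "water") return(rep(0, ncol(U)))
  if (!config$bg_het || hi - lo == 0) {
    return(lo + U[.DRAW_BG, ] * (hi - lo))
  }
  gs <- config$grid_spacing
  m <- length(.DRAW_HET)
  rho <- exp(-gs / 1.2)
  z <- stats::qnorm(U[.DRAW_HET, , drop = FALSE]) # m x n standard normals
  for (j in 2:m) z[j, ] <- rho * z[j - 1, ] + sqrt(1 - rho^2) * z[j, ]
  s_prof <- lo + (hi - lo) * stats::pnorm(z)
  cells <- pmin(m, pmax(1L, ceiling(depth / gs)))
  csum <- apply(s_prof, 2, cumsum)
  csum[cbind(cells, seq_along(cells))] / cells
}
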