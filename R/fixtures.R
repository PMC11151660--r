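#' Small bundled test datasets
#'
#' Deterministic desk-size datasets used by the unit tests and examples:
#' the baseline variant, the melanin-skin variant, the 4 cm water-layer
#' variant, and a noiseless `analytic` set with every attenuation
#' mechanism switched off (for which linear unmixing recovers the label
#' exactly). Regenerates bit-identically from the seed.
#'
#' @param seed Master seed.
#' @param n Spectra per dataset.
#' @return Named list of `spectra_dataset`s with a `manifest` attribute
#'   listing the provenance of each element.
#' @export
make_fixtures <- function(seed = 1, n = 500) {
  v <- builtin_variants(n_spectra = n)
  analytic <- variant_config("ANALYTIC", bg_bvf = 0, vessel_radius = c(0, 0),
                             illumination_spread = 0, noise_sigma = 0,
                             n_spectra = n, seed = derive_seed(seed, 4))
  out <- list(
    base = generate_dataset(v$BASE, seed = derive_seed(seed, 1)),
    skin = generate_dataset(v$SKIN, seed = derive_seed(seed, 2)),
    water4 = generate_dataset(v$WATER_4cm, seed = derive_seed(seed, 3)),
    analytic = generate_dataset(analytic)
  )
  attr(out, "manifest") <- data.frame(
    name = names(out),
    variant = vapply(out, `[[`, "", "variant"),
    seed = vapply(out, function(d) as.numeric(d$seed), 0),
    n = vapply(out, n_spectra, 0L),
    generator_version = vapply(out, `[[`, "", "generator_version"),
    row.names = NULL)
  out
}
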