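---
title: "Methods: wavelength-flexible photoacoustic oximetry and dataset-distance-guided training-set selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelength-flexible photoacoustic oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paox)
```

## The problem

Multispectral photoacoustic imaging measures, per pixel, an amplitude
proportional to the product of the local optical absorption coefficient and
the local light fluence. Because the fluence reaching depth is itself
wavelength dependent ("spectral coloring"), the measured spectrum of a blood
vessel is a distorted version of the blood absorption spectrum, and naive
linear unmixing of oxy-/deoxyhemoglobin systematically misestimates oxygen
saturation (sO~2~). Data-driven regressors trained on simulated tissue can
learn to undo the coloring, but two practical obstacles remain:

1. trained networks are usually locked to the wavelength set used in
   training, while real systems acquire different subsets; and
2. accuracy depends strongly on how well the training distribution matches
   the target data, which is hard to assess when no ground truth exists.

`paox` addresses both: a *wavelength-masked recurrent regressor* that accepts
any subset of a fixed 41-channel lattice (700--900 nm, 5 nm steps), and an
*aggregate Jensen--Shannon distance* between datasets that predicts which
training distribution fits a target dataset best.

## The masked recurrent regressor

Each spectrum is presented as a 41-step sequence of scalar amplitudes plus a
boolean presence mask. The LSTM (hidden size 100) advances its cell and
hidden state only at present steps; at masked steps the state passes through
unchanged and the emitted hidden vector repeats the previous one (zeros
before the first present wavelength). Stored values at masked slots therefore
cannot influence the output - an invariant the test suite asserts exactly.

All 41 emitted hidden vectors are flattened into a 4100-long encoding and fed
to a fully connected head - input layer 4100, one hidden layer of 1000 units
with leaky-ReLU activation (slope 0.3), and a single sigmoid output that
constrains estimates to [0, 1]. We read the published "three-layer fully
connected network (input size 4200, hidden size 1000, output size 1)" in the
classic input/hidden/output sense, i.e. two weight matrices; and we use
4100 = 41 x 100 for the encoding width since the extra 100 units in the
quoted input size are not derivable from the stated architecture (41 steps
x 100 hidden units). Internal consistency was preferred over copying what is
most plausibly a typo.

Training minimizes mean absolute error with Adam (beta1 = 0.9, beta2 = 0.999,
eps = 1e-8) at an initial learning rate of 1e-3, halved whenever the
validation loss fails to improve for 5 consecutive epochs (floor 1e-6).
Choices the published schedule leaves open, fixed here as package defaults:
batch size 1024 (large batches keep single-CPU epochs GEMM-bound), a 20%
random validation split (the plateau scheduler needs one), Glorot-uniform
initialization with a unit forget-gate bias, and an unidirectional LSTM. The
trainer is written in single-precision C++ (RcppArmadillo over BLAS); with a
fixed seed and a single-threaded BLAS it is bit-reproducible, and activation
functions use a monotone branchless exponential approximation (relative
error ~2e-6) so the elementwise loops vectorize.

Two baselines share the interface: **LU**, exact two-variable non-negative
least squares of the spectrum onto the HbO~2~/Hb absorption bases over the
present wavelengths (returning a/(a+b), scale invariant, 0.5 with a flag in
the degenerate all-zero case, ties resolved toward lower saturation); and
**LSD** (learned spectral decoloring), a fully connected 41 -> 100 -> 100 -> 1
regressor with the same training schedule that deliberately rejects masked
input - its inflexibility is the motivation for the recurrent design.

## The synthetic tissue generator

The Monte Carlo + acoustic simulation chain that produced the original
training data is deliberately replaced by a fast analytic surrogate, because
every method component (preprocessing, regressor, distance) is agnostic to
how spectra were produced, and the package must be buildable and testable on
one CPU. The surrogate is a 1-D layered diffusion approximation: a vessel at
depth z below the tissue surface receives fluence

Phi(lambda, z) = G(z) * exp(-mu_a,water d_water - mu_eff,skin d_skin -
mu_eff,bg (z - d_skin)),   mu_eff = sqrt(3 mu_a (mu_a + mu_s')),

with G(z) = (1 + z/z0)^-spread a geometric divergence proxy for the beam
(collimated wide beam: spread 0; 5 mm beam: spread 1, z0 = 5 mm; point
source: spread 2, z0 = 1 mm - geometric divergence is the dominant
first-order difference between these illuminations). The recorded amplitude
is Phi x mu_a,vessel x V(r, lambda) x (1 + noise), where
V = (1 - exp(-2 mu_a r)) / (2 mu_a r) is the mean fluence of an absorbing
slab of the vessel's diameter - the self-coloring that distinguishes small
from large vessels - and the noise is i.i.d. multiplicative Gaussian with
sigma = 0.02 by default (the reference pipeline states no noise model for
extracted spectra; 2% is a realistic shot/texture noise scale and is
configurable, including 0).

Baseline conditions: background muscle with 1% blood volume fraction at 70%
oxygenation; vessels carry pure blood with sO~2~ ~ U[0, 1]; radii U[0.15,
1.0] mm (halved in `SMALL`); depths U[0.5, 9.0] mm (within the plausible
high-signal region of the simulated volume); 0.3 mm voxels. Depths and radii
are quantized to the configured voxel size (vessels occupy at least half a
voxel), which is how the resolution variants coarsen the data. The named
variants each change exactly one knob: background oxygenation ranges
(uniform or heterogeneous), water-only background, a 0.3 mm melanin layer
with melanosome fraction U[0.1%, 5%], halved radii, voxel sizes 0.15/0.6/1.2
mm, diverging illumination, and 2/4 cm water coupling layers. Heterogeneous
backgrounds draw an AR(1) profile over depth cells (correlation length 1.2
mm, uniform marginals via a Gaussian copula) and attenuate with the
path-averaged oxygenation - a 1-D stand-in for volumetric Gaussian-filtered
noise; the mild nonlinearity of mu_eff in sO~2~ is ignored along the path.

Optical properties are embedded: whole-blood absorption at 150 g/L
hemoglobin from a 10 nm tabulation representative of the standard literature
compilation, water after Hale & Querry, the melanosome power law
1.7e12 lambda^-3.48 cm^-1, and a constant background reduced scattering of
1.0 mm^-1 (the reference simulations fix anisotropy and do not vary
scattering across variants). Device twins and acoustic forward modeling /
reconstruction are *not* emulated; variants that exist only through those
mechanisms are out of scope here, and absolute error levels obtained on the
surrogate are not comparable to ones obtained on Monte Carlo data.

What passing tests on the surrogate do show: the pipeline's contracts hold,
the regressor learns to invert layered spectral coloring, and the distance
measure discriminates and ranks these tissue families. What they cannot
show: performance on reconstruction artifacts, reflection artifacts, limited
bandwidth effects, or real tissue heterogeneity.

All randomness flows through counter-based splitmix64 streams keyed by
(seed, stream): results are independent of the platform RNG, and each
spectrum consumes its own stream, so enlarging a dataset never changes
earlier spectra.

## Preprocessing

The pipeline order is selection -> wavelength subsetting -> per-spectrum
z-scoring -> stratified resampling.

* **Selection**: spectra with amplitude at 800 nm below 10% of the dataset
  maximum are discarded (a proxy for low-SNR voxels); if fewer than 10% of
  spectra survive, the top 10% by 800 nm amplitude are kept instead (stable
  ties). The fallback operates per dataset - the source wording ("from the
  dataset") is ambiguous between per-volume and per-dataset, and the
  surrogate has no volumes.
* **z-scoring** uses the population (divide-by-N) standard deviation over the
  *present* wavelengths only, which makes "variance = 1" hold exactly for
  each spectrum; masked slots stay zero. Constant spectra are rejected with
  an error rather than zero-filled: a zero spectrum would be a silent
  out-of-distribution input to the network.
* **Resampling** draws uniformly with replacement to an exact count using the
  counter-based generator.
* **Wavelength subsets** for a count N are evenly spaced over the 41 slots
  with both endpoints included, fractional positions rounded to the nearest
  slot with ties toward the lower index - reproducible from N alone.

## The dataset distance

For two (z-scored) datasets the per-wavelength amplitude distributions are
histogrammed into 100 uniform bins on [-3, +3] standard scores; values
outside the range are excluded and the bins renormalized (the source is
silent on clipping versus exclusion; exclusion avoids artificial edge
spikes), with the last bin right-closed. Per wavelength in the intersection
of the two wavelength sets, the Jensen--Shannon *distance* - the square root
of 0.5 KL(P||M) + 0.5 KL(Q||M), M = (P+Q)/2, natural logarithm - is
computed, and the mean over wavelengths is the aggregate score. The square
root + natural log convention matches the routine the reference analysis
used and its reported score range (bounded by sqrt(ln 2) ~ 0.8326); the raw
divergence is also exposed. Zero-mass bins contribute via 0 log 0 = 0; no
pseudo-counts are needed since the mixture M is positive wherever P or Q is.
Wavelengths with no in-range samples on either side are dropped from the
mean with a warning (a 0/0 aggregate would otherwise be ambiguous). The
score is computed on subsamples (default 10,000 spectra, 10 repeats, both
configurable; the reference analysis used 100,000 x 10) and averaged;
subsampling is without replacement, capped at the dataset size, so comparing
a dataset with itself at full size gives exactly zero.

Candidates are ranked by ascending score (stable ties by input order); the
correlation between scores and realized estimation errors across candidates
is Pearson's r. Candidates departing from the least-squares score-error
trend by more than 2 interquartile ranges of the residuals are flagged as
outliers for expert inspection - a codification of the manual outlier
removal precedent in the reference analysis.

## Error metric and reference conversion

Accuracy is the median absolute error, 100 x median(|sO2_est - sO2_true|) in
percentage points (even counts: mean of the central order statistics). For
flow-phantom style reference measurements, pO~2~ readings convert to sO~2~
through the classic Severinghaus closed form
S = 1 / (23400 (pO2^3 + 150 pO2)^-1 + 1), which the reference cites but does
not print; the 1979 constants are used and documented here.

## Experiment drivers and problem sizes

Three seeded drivers reproduce the study designs: `run_wavelength_sweep`
(train at each wavelength count, test at every count),
`run_crossval` (every variant's model applied to every variant's held-out
set, plus an `ALL` model trained on an equal-proportion mixture - the
reference states no proportions), and `run_djs_study` (per-candidate
distance and error against a target, with Pearson r and outlier flags).
Every driver is a pure function of (configuration, seeds) and writes a JSON
manifest next to its tables.

The package's reference experiment (`baseline_holdout_error`) trains the
masked LSTM on 50,000 baseline-variant spectra for 30 epochs and evaluates
10,000 held-out spectra. The test suite exercises the qualitative claims at
smaller sizes chosen so the whole suite runs on one CPU in well under half
an hour: 5,000 training spectra and 8 epochs for the wavelength sweep and
the melanin transfer check (3 seeds and 1 seed respectively), and 3,000
training spectra, 8 epochs, 3 seeds, with 2,000-spectrum distance
subsamples, for the ten-variant distance-versus-error study. These sizes are
deliberate: large enough for the ordering properties to be stable under the
fixed seeds, small enough to keep the feedback loop fast.

## Known limitations

* The surrogate is 1-D and noise-simplified; it cannot stand in for
  acoustic/device effects, and error magnitudes are not transferable.
* The illumination proxy G(z) is wavelength independent, and per-spectrum
  z-scoring removes any scalar factor: a *mild* divergence change
  (`ILLUM_5mm`) therefore produces spectra identical to the baseline after
  normalization, differing only through the high-signal selection step. A
  strongly diverging source (`ILLUM_POINT`) does reshape the retained
  depth distribution and is distinguishable. In full photon transport,
  illumination geometry also colors the spectra; the surrogate cannot
  reproduce that pathway.
* The embedded optical tables are a close, but not verbatim, rendering of
  the standard compilations; all package results are self-consistent
  against the embedded values.
* The distance is computed per wavelength and averaged; joint-across-
  wavelength structure (and optimal-transport alternatives) is out of
  scope.
* Training determinism is guaranteed for a fixed seed on a single-threaded
  BLAS; multi-threaded BLAS may vary late decimals.
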