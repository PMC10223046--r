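#' Gaussian absorption band specification
#'
#' Absorption features appear in reflectance as Gaussian-shaped dips:
#' `depth * exp(-(lambda - center)^2 / (2 width^2))`.
#'
#' @param center_nm Band center wavelength (350-2500 nm).
#' @param width_nm Gaussian standard deviation (nm), > 0.
#' @param depth Dip depth in reflectance units (positive = absorption).
#' @return Object of class `band_spec`.
#' @export
band_spec <- function(center_nm, width_nm, depth) {
  if (center_nm < 350 || center_nm > 2500)
    stop("center_nm must lie within 350-2500 nm")
  if (width_nm <= 0) stop("width_nm must be > 0")
  structure(list(center_nm = center_nm, width_nm = width_nm, depth = depth),
            class = "band_spec")
}

#' Configuration of the synthetic Vis-SWIR reflectance generator
#'
#' The generator emulates the study design — two pasta products
#' (Pennette72 = class 1, Mezze Penne = class 0), six samples per product,
#' each measured frozen and thawed, fifty replicate spectra per sample per
#' state — and the qualitative spectral structure of the real data: water
#' absorption bands near 1450 and 1940 nm that deepen in the frozen state,
#' a frozen-state baseline raise over the window regions where frozen pasta
#' reflects more than thawed, and a class-1 reflectance offset over
#' 1300-2500 nm that is large in the thawed state and near zero in the
#' frozen state (the thawed state is the easier classification problem by
#' construction).
#'
#' The repeated-measure structure of the design is modeled through
#' per-sample spectral fingerprints: all replicate spectra of one physical
#' sample share a smooth random deviation from the product mean spectrum
#' (drawn once per sample as a sum of Gaussian-process-like components
#' with long and short correlation lengths), reflecting pan-to-pan
#' differences in composition, packing and surface structure. Replicate
#' variability mirrors contact-probe measurement: each replicate touches a
#' different spot of the heterogeneous sample, giving a smooth correlated
#' deviation (amplitude `noise_sd`, correlation length `noise_length_nm`),
#' on top of small white instrument noise (`instrument_noise_sd`). In the
#' frozen state replicate variability is inflated by
#' `state_noise_scale_frozen` (ice-crystal scattering), which together
#' with the near-zero frozen class offset makes the frozen problem the
#' harder one.
#'
#' @param n_samples_per_class Samples per product class (default 6).
#' @param n_spectra_per_sample_per_state Replicate spectra (default 50).
#' @param continuum_coeffs Polynomial coefficients `c(a, b, c)` of the
#'   baseline reflectance `a + b u + c u^2` in `u = (lambda - 350)/2150`;
#'   default runs gently from 0.45 at 350 nm to 0.65 at 2500 nm.
#' @param bands List of [band_spec()] absorption dips (defaults: water
#'   bands at 1450 nm depth 0.15 and 1940 nm depth 0.20, width 40 nm).
#' @param class_offset_thawed Reflectance offset added to class 1 over
#'   `class_offset_from_nm`..2500 nm in the thawed state (default 0.03).
#' @param class_offset_frozen Same for the frozen state (default 0.005,
#'   much smaller: frozen products are nearly indistinguishable).
#' @param class_offset_from_nm Lower edge of the class-offset window.
#' @param state_band_scale_frozen Multiplier deepening the absorption
#'   bands in the frozen state (default 1.3).
#' @param frozen_raise Baseline raise applied to frozen spectra over
#'   `frozen_raise_windows` (default 0.02).
#' @param frozen_raise_windows List of `c(from, to)` nm windows where the
#'   frozen state reflects more than the thawed state.
#' @param noise_sd Pointwise sd of the per-replicate deviation (default
#'   0.01 reflectance units).
#' @param noise_length_nm Correlation length (nm) of the replicate
#'   deviation (default 50); set to 0 for white replicate noise.
#' @param instrument_noise_sd Sd of additive white instrument noise
#'   (default 0.001).
#' @param state_noise_scale_frozen Replicate-variability multiplier in
#'   the frozen state (default 1.5).
#' @param sample_effect_sd Pointwise sd of the per-sample spectral
#'   fingerprint (default 0.01).
#' @param sample_effect_length_nm Correlation lengths (nm) of the
#'   fingerprint components, equal variance shares (default 150 and 15 nm).
#' @param grid Wavelength grid (default canonical 350-2500 nm at 1 nm).
#' @param seed RNG seed for [generate_dataset()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_samples_per_class = 6,
                             n_spectra_per_sample_per_state = 50,
                             continuum_coeffs = c(0.45, 0.12, 0.08),
                             bands = list(band_spec(1450, 40, 0.15),
                                          band_spec(1940, 40, 0.20)),
                             class_offset_thawed = 0.03,
                             class_offset_frozen = 0.005,
                             class_offset_from_nm = 1300,
                             state_band_scale_frozen = 1.3,
                             frozen_raise = 0.02,
                             frozen_raise_windows = list(c(350, 1450),
                                                         c(1600, 1850),
                                                         c(2100, 2400)),
                             noise_sd = 0.01,
                             noise_length_nm = 50,
                             instrument_noise_sd = 0.001,
                             state_noise_scale_frozen = 1.5,
                             sample_effect_sd = 0.01,
                             sample_effect_length_nm = c(150, 15),
                             grid = wavelength_grid(),
                             seed = 1) {
  stopifnot(n_samples_per_class >= 1, n_spectra_per_sample_per_state >= 1,
            noise_sd >= 0, sample_effect_sd >= 0)
  if (class_offset_thawed < class_offset_frozen || class_offset_frozen < 0)
    warning("study design expects class_offset_thawed >= class_offset_frozen >= 0")
  structure(list(
    n_samples_per_class = as.integer(n_samples_per_class),
    n_spectra_per_sample_per_state = as.integer(n_spectra_per_sample_per_state),
    continuum_coeffs = continuum_coeffs, bands = bands,
    class_offset_thawed = class_offset_thawed,
    class_offset_frozen = class_offset_frozen,
    class_offset_from_nm = class_offset_from_nm,
    state_band_scale_frozen = state_band_scale_frozen,
    frozen_raise = frozen_raise, frozen_raise_windows = frozen_raise_windows,
    noise_sd = noise_sd, noise_length_nm = noise_length_nm,
    instrument_noise_sd = instrument_noise_sd,
    state_noise_scale_frozen = state_noise_scale_frozen,
    sample_effect_sd = sample_effect_sd,
    sample_effect_length_nm = sample_effect_length_nm,
    grid = grid, seed = as.integer(seed)
  ), class = "generator_config")
}

generator_mean_spectrum <- function(cfg, product_class, physical_state) {
  lambda <- grid_wavelengths(cfg$grid)
  u <- (lambda - 350) / 2150
  cc <- cfg$continuum_coeffs
  refl <- cc[1] + cc[2] * u + cc[3] * u^2
  band_scale <- if (physical_state == "frozen") cfg$state_band_scale_frozen else 1
  for (b in cfg$bands)
    refl <- refl - band_scale * b$depth *
      exp(-(lambda - b$center_nm)^2 / (2 * b$width_nm^2))
  if (product_class == 1) {
    off <- if (physical_state == "frozen") cfg$class_offset_frozen
           else cfg$class_offset_thawed
    refl <- refl + off * (lambda >= cfg$class_offset_from_nm)
  }
  if (physical_state == "frozen")
    for (w in cfg$frozen_raise_windows)
      refl <- refl + cfg$frozen_raise * (lambda >= w[1] & lambda <= w[2])
  refl
}

#' Draw a per-sample spectral fingerprint
#'
#' A mean-zero random curve shared by all replicate spectra of one
#' physical sample: the sum of one smooth component per entry of
#' `sample_effect_length_nm`, each obtained by Gaussian-kernel smoothing
#' of white noise and scaled so the total pointwise standard deviation is
#' `sample_effect_sd`. Draws from the current RNG state.
#'
#' @param cfg A [generator_config()].
#' @return Numeric vector on the configured grid.
#' @export
sample_fingerprint <- function(cfg) {
  m <- cfg$grid$n_points
  ls <- cfg$sample_effect_length_nm
  if (cfg$sample_effect_sd == 0 || length(ls) == 0) return(numeric(m))
  amp <- cfg$sample_effect_sd / sqrt(length(ls))
  out <- numeric(m)
  for (l in ls) out <- out + amp * smooth_noise(m, l / cfg$grid$step_nm)
  out
}

# Unit-pointwise-variance correlated noise: white noise convolved with a
# Gaussian kernel of sd `ls_pts` grid points, kernel normalized in L2.
smooth_noise <- function(m, ls_pts) {
  half <- as.integer(ceiling(3 * ls_pts))
  k <- exp(-0.5 * ((-half:half) / ls_pts)^2)
  k <- k / sqrt(sum(k^2))
  e <- stats::rnorm(m + 2L * half)
  as.numeric(stats::filter(e, k, sides = 2))[half + seq_len(m)]
}

#' Generate one synthetic reflectance spectrum
#'
#' Reflectance is the class- and state-dependent mean spectrum (continuum
#' minus state-scaled Gaussian bands, plus class offset and frozen-state
#' raise) plus the sample's spectral fingerprint, a smooth per-replicate
#' deviation (probe repositioning; inflated by `state_noise_scale_frozen`
#' in the frozen state) and white instrument noise, clipped to \[0, 1\].
#' Draws from the current RNG state; seed it (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @param meta List or one-row data.frame with `sample_id`,
#'   `product_class`, `physical_state`.
#' @param sample_effect Fingerprint vector (or scalar shift) of this
#'   spectrum's sample; by default drawn fresh via [sample_fingerprint()].
#' @return Numeric reflectance vector on the configured grid.
#' @export
generate_spectrum <- function(cfg, meta, sample_effect = sample_fingerprint(cfg)) {
  m <- cfg$grid$n_points
  mu <- generator_mean_spectrum(cfg, meta$product_class, meta$physical_state)
  nsd <- cfg$noise_sd *
    if (meta$physical_state == "frozen") cfg$state_noise_scale_frozen else 1
  rep_dev <- if (nsd > 0 && cfg$noise_length_nm > 0)
    nsd * smooth_noise(m, cfg$noise_length_nm / cfg$grid$step_nm)
  else stats::rnorm(m, 0, nsd)
  refl <- mu + sample_effect + rep_dev +
    stats::rnorm(m, 0, cfg$instrument_noise_sd)
  pmin(pmax(refl, 0), 1)
}

#' Generate a full labeled synthetic dataset
#'
#' Iterates class (0, 1) x sample x state (frozen, thawed) x replicate in
#' a fixed order, drawing one spectral fingerprint per sample (shared by
#' both states and all replicates of that sample). With the defaults this
#' reproduces the study shape: 2 classes x 6 samples x 2 states x 50
#' replicates = 1200 spectra of 2151 variables, 600 per state.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A `spectra_dataset`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  n_rep <- cfg$n_spectra_per_sample_per_state
  total <- 2L * cfg$n_samples_per_class * 2L * n_rep
  refl <- matrix(0, total, cfg$grid$n_points)
  ids <- character(total); cls <- integer(total); states <- character(total)
  row <- 0L
  for (class in c(0L, 1L)) {
    for (s in seq_len(cfg$n_samples_per_class)) {
      sid <- sprintf("C%d_S%02d", class, s)
      eff <- sample_fingerprint(cfg)
      for (state in PHYSICAL_STATES) {
        meta <- list(sample_id = sid, product_class = class,
                     physical_state = state)
        for (r in seq_len(n_rep)) {
          row <- row + 1L
          refl[row, ] <- generate_spectrum(cfg, meta, sample_effect = eff)
          ids[row] <- sid; cls[row] <- class; states[row] <- state
        }
      }
    }
  }
  spectra_dataset(refl,
                  data.frame(sample_id = ids, product_class = cls,
                             physical_state = states),
                  cfg$grid)
}
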