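#' Gaussian band of a molar response spectrum
#'
#' @param center Band center (nm), inside the wavelength grid it will be
#'   evaluated on.
#' @param width Gaussian sigma (nm, > 0).
#' @param amplitude Peak molar response (AU M^-1 cm^-1 for absorbance,
#'   counts M^-1 for emission).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center, width, amplitude) {
  if (width <= 0) stop("band width must be positive")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

#' Noise description for the generators
#'
#' @param sigma_intensity Gaussian sd per intensity point (AU or counts,
#'   >= 0).
#' @param sigma_pH Gaussian sd per pH reading (>= 0).
#' @param seed Integer RNG seed; NULL leaves the RNG state alone.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_intensity = 0, sigma_pH = 0, seed = NULL) {
  if (sigma_intensity < 0 || sigma_pH < 0) stop("noise sigmas must be >= 0")
  structure(list(sigma_intensity = sigma_intensity, sigma_pH = sigma_pH,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_spec")
}

.with_noise_seed <- function(noise, expr) {
  if (!is.null(noise$seed)) withr::with_seed(noise$seed, expr) else expr
}

#' Evaluate a molar response spectrum from Gaussian bands
#'
#' Sum of Gaussian bands on a wavelength grid; every band center must lie
#' within the grid span.
#'
#' @param bands A `band_spec` or list of them (nonempty).
#' @param wavelengths Strictly increasing grid (nm).
#' @return Nonnegative numeric vector of per-wavelength molar response.
#' @export
gen_species_spectrum <- function(bands, wavelengths) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  if (!length(bands)) stop("empty band list")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  out <- numeric(length(wavelengths))
  for (b in bands) {
    if (b$center < min(wavelengths) || b$center > max(wavelengths))
      stop("band center ", b$center, " nm lies outside the wavelength grid")
    out <- out + b$amplitude * exp(-(wavelengths - b$center)^2 / (2 * b$width^2))
  }
  out
}

#' Default band sets of the Al(III)-CIP-NADP chromophores
#'
#' Fixture-quality molar absorptivity/emission profiles reproducing the
#' qualitative spectroscopy of the system: CIP absorbs strongly at 272 nm
#' (with the quinolone doublet near 323/335 nm) shifting to 275 nm on Al
#' complexation; NADP absorbs at 261 nm (adenine), and its Al complex is
#' hyperchromic at an unchanged maximum with a slightly narrowed band; CIP
#' emits at 426 nm, its Al complex at 433 nm with ~2.5x the intensity.
#' Amplitudes are typical molar absorptivities (1e4 scale) -- presentation
#' realism for the generators, not fitted quantities.
#'
#' @param channel `"absorbance"` or `"emission"`.
#' @return Named list of band lists: `CIP`, `NADP`, `AlCIP`, `AlNADP`.
#' @export
default_bands <- function(channel = c("absorbance", "emission")) {
  channel <- match.arg(channel)
  if (channel == "absorbance") {
    list(
      CIP = list(band_spec(272, 9, 3.5e4), band_spec(323, 7, 0.9e4),
                 band_spec(335, 7, 0.8e4)),
      NADP = list(band_spec(261, 11, 1.8e4)),
      AlCIP = list(band_spec(275, 9, 3.8e4), band_spec(330, 8, 1.1e4)),
      AlNADP = list(band_spec(261, 10, 2.3e4)))
  } else {
    list(
      CIP = list(band_spec(426, 18, 1.0e7)),
      NADP = list(),
      AlCIP = list(band_spec(433, 18, 2.5e7)),
      AlNADP = list())
  }
}

#' Default wavelength grids
#' @param channel `"absorbance"` (240-360 nm, 0.5 nm) or `"emission"`
#'   (380-520 nm, 1 nm).
#' @return Numeric grid in nm.
#' @export
default_wavelengths <- function(channel = c("absorbance", "emission")) {
  channel <- match.arg(channel)
  if (channel == "absorbance") seq(240, 360, by = 0.5) else seq(380, 520, by = 1)
}

#' Generate a 1:1 binding spectral titration
#'
#' Beer-Lambert bilinear matrix (1 cm path) of a two-species system: each
#' column is `ligand_spectrum * [L]_free + complex_spectrum * [ML]` with
#' concentrations from the exact 1:1 quadratic at the given conditional
#' constant, plus optional homoscedastic Gaussian noise. The noise-free
#' matrix has rank exactly 2.
#'
#' @param ligand_spectrum,complex_spectrum Molar responses on `wavelengths`.
#' @param ligand_total Fixed ligand total (mol/L); default 20e-6 (20 uM).
#' @param metal_totals Metal totals per sample (mol/L), including 0;
#'   default `c(0, 5, 10, 15, 20) * 1e-6`.
#' @param logK_cond Generating conditional constant (common log).
#' @param noise A [noise_spec()].
#' @param wavelengths Wavelength grid; default [default_wavelengths()].
#' @param channel Stored channel tag.
#' @param ligand_name Name for the ligand component.
#' @return A [spectra_matrix()].
#' @export
gen_uvvis_titration <- function(ligand_spectrum, complex_spectrum,
                                ligand_total = 20e-6,
                                metal_totals = c(0, 5, 10, 15, 20) * 1e-6,
                                logK_cond,
                                noise = noise_spec(),
                                wavelengths = default_wavelengths(),
                                channel = "absorbance",
                                ligand_name = "L") {
  if (length(ligand_spectrum) != length(wavelengths) ||
      length(complex_spectrum) != length(wavelengths))
    stop("spectra must be on the wavelength grid")
  bf <- bound_fraction_1to1(metal_totals, ligand_total, logK_cond)
  X <- outer(ligand_spectrum, bf$free_ligand) +
    outer(complex_spectrum, bf$complex)
  if (noise$sigma_intensity > 0)
    X <- X + .with_noise_seed(noise,
      matrix(stats::rnorm(length(X), 0, noise$sigma_intensity), nrow(X)))
  spectra_matrix(wavelengths, X, metal_totals,
                 stats::setNames(ligand_total, ligand_name), channel)
}

#' Generate a ternary competitive spectral titration
#'
#' Bilinear mixture of four species (two free ligands, two 1:1 binary
#' complexes) whose concentrations come from the competitive fixed-pH
#' speciation at the two conditional constants, plus an optional
#' ligand-ligand interaction term: a fixed band (scaled by the smaller
#' ligand total) added identically to every column, emulating a constant
#' association signature that the two-binary synthetic model cannot
#' reproduce.
#'
#' @param ligand_spectra,complex_spectra Named lists (by ligand) of molar
#'   responses on `wavelengths`.
#' @param ligand_totals Named totals of the two ligands (mol/L).
#' @param metal_totals Metal totals per sample, including 0.
#' @param logK_cond Named conditional constants of the binary complexes.
#' @param interaction_band Optional [band_spec()] for the interaction term.
#' @param noise A [noise_spec()].
#' @param wavelengths Wavelength grid.
#' @param channel Stored channel tag.
#' @return A [spectra_matrix()].
#' @export
gen_ternary_titration <- function(ligand_spectra, complex_spectra,
                                  ligand_totals = c(CIP = 20e-6, NADP = 20e-6),
                                  metal_totals = c(0, 5, 10, 15, 20, 25) * 1e-6,
                                  logK_cond = c(CIP = 10.2, NADP = 10.7),
                                  interaction_band = NULL,
                                  noise = noise_spec(),
                                  wavelengths = default_wavelengths(),
                                  channel = "absorbance") {
  ligs <- names(ligand_totals)
  conc <- competitive_1to1_speciation(metal_totals, ligand_totals, logK_cond)
  X <- 0
  for (nm in ligs) {
    X <- X + outer(ligand_spectra[[nm]], conc[[paste0("free_", nm)]]) +
      outer(complex_spectra[[nm]], conc[[paste0("complex_", nm)]])
  }
  if (!is.null(interaction_band)) {
    shape <- gen_species_spectrum(interaction_band, wavelengths)
    X <- X + outer(shape * min(ligand_totals), rep(1, length(metal_totals)))
  }
  if (noise$sigma_intensity > 0)
    X <- X + .with_noise_seed(noise,
      matrix(stats::rnorm(length(X), 0, noise$sigma_intensity), nrow(X)))
  spectra_matrix(wavelengths, X, metal_totals, ligand_totals, channel)
}

#' Generate a noisy pH-potentiometric titration
#'
#' [simulate_titration()] plus seeded Gaussian pH noise: the synthetic
#' stand-in for a measured titration curve.
#'
#' @param model An `eq_model`.
#' @param design A [titration_dataset()] design (pH ignored).
#' @param noise A [noise_spec()]; `sigma_pH` is the per-point reading sd.
#' @return A `titration_dataset` with observed (noisy) pH.
#' @export
gen_potentiometric_titration <- function(model, design, noise = noise_spec()) {
  d <- simulate_titration(model, design)
  if (noise$sigma_pH > 0) {
    ok <- !is.na(d$points$pH)
    d$points$pH[ok] <- d$points$pH[ok] + .with_noise_seed(noise,
      stats::rnorm(sum(ok), 0, noise$sigma_pH))
  }
  d
}

#' Standard titration designs of the Al-CIP-NADP study
#'
#' Builds the study's standard design frame: 50.0 mL initial volume, ligand totals
#' 0.001 M, KOH titrant 0.1026 M, 0.2 M KCl at 25 C. Ligands are dissolved
#' in their fully protonated forms (CIP as H2L+, NADP as H3L) and a strong
#' acid excess sets the starting pH near 2.4; the volume grid spans acid
#' excess, ligand protons, and (when metal is present) four hydrolysable
#' protons per Al plus a small overshoot, reaching pH ~ 11.
#'
#' @param c_al,c_cip,c_nadp Analytical totals of Al, CIP, NADP (mol/L).
#' @param acid_excess Strong-acid proton excess (mol/L), default 4e-3.
#' @param n_points Number of titrant additions (default 60).
#' @param initial_volume Initial volume (L), default 0.050.
#' @param titrant_conc KOH (mol/L), default 0.1026.
#' @return A [titration_dataset()] design (pH all NA).
#' @export
standard_titration_design <- function(c_al = 0, c_cip = 0, c_nadp = 0,
                                      acid_excess = 4e-3, n_points = 60,
                                      initial_volume = 0.050,
                                      titrant_conc = 0.1026) {
  totals <- c(H = acid_excess + 2 * c_cip + 3 * c_nadp)
  if (c_al > 0) totals["Al"] <- c_al
  if (c_cip > 0) totals["CIP"] <- c_cip
  if (c_nadp > 0) totals["NADP"] <- c_nadp
  v_eq <- initial_volume * (totals[["H"]] + 4 * c_al + 2e-3) / titrant_conc
  volumes <- seq(0, v_eq, length.out = n_points + 1L)[-1L]
  titration_dataset(initial_volume, totals, titrant_conc, volumes)
}
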