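#' Construct a spectral titration matrix
#'
#' Wavelength-by-sample intensity matrix from a titration in which the
#' ligand total(s) are fixed and the metal total varies across samples, the
#' layout rank annihilation factor analysis (RAFA) operates on. At least two
#' samples are required, one of them metal-free (it calibrates the ligand
#' molar response).
#'
#' @param wavelengths Strictly increasing wavelength grid (nm, positive).
#' @param intensity Numeric matrix, `length(wavelengths)` rows, one column
#'   per sample (absorbance units or fluorescence counts).
#' @param metal_totals Metal total (mol/L) per sample.
#' @param ligand_totals Named numeric vector of fixed ligand totals (mol/L);
#'   a single unnamed value is taken as a one-ligand system named `"L"`.
#' @param channel `"absorbance"` or `"emission"`.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(wavelengths, intensity, metal_totals, ligand_totals,
                           channel = c("absorbance", "emission")) {
  channel <- match.arg(channel)
  intensity <- as.matrix(intensity)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(wavelengths <= 0)) stop("wavelengths must be positive (nm)")
  if (nrow(intensity) != length(wavelengths))
    stop("intensity rows must match wavelength grid")
  if (ncol(intensity) != length(metal_totals))
    stop("intensity columns must match metal_totals")
  if (length(metal_totals) < 2L) stop("need at least 2 samples")
  if (!any(metal_totals == 0)) stop("need a metal-free sample")
  if (is.null(names(ligand_totals)))
    names(ligand_totals) <- if (length(ligand_totals) == 1L) "L" else
      stop("multiple ligand totals must be named")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensity = unname(intensity),
                 metal_totals = as.numeric(metal_totals),
                 ligand_totals = ligand_totals,
                 channel = channel),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat("Spectra matrix (", x$channel, "): ", length(x$wavelengths),
      " wavelengths x ", length(x$metal_totals), " samples\n", sep = "")
  cat("Wavelengths: ", min(x$wavelengths), "-", max(x$wavelengths), " nm\n", sep = "")
  cat("Metal totals (M):", paste(format(x$metal_totals), collapse = ", "), "\n")
  cat("Ligand totals (M):",
      paste(names(x$ligand_totals), format(unname(x$ligand_totals)), collapse = ", "), "\n")
  invisible(x)
}

#' 1:1 binding quadratic
#'
#' Exact speciation of M + L = ML at a conditional constant
#' \eqn{K = 10^{\log K}}: the positive root of
#' \eqn{K c^2 - (K(M_t+L_t)+1)c + K M_t L_t = 0} with
#' \eqn{c \le \min(M_t, L_t)}.
#'
#' @param metal_total,ligand_total Analytical totals (mol/L), vectorized
#'   over `metal_total`.
#' @param logK Conditional stability constant (common log, finite).
#' @return A data.frame with columns `complex`, `free_ligand`, `free_metal`.
#' @export
bound_fraction_1to1 <- function(metal_total, ligand_total, logK) {
  if (!is.finite(logK)) stop("logK must be finite")
  if (any(metal_total < 0) || any(ligand_total < 0)) stop("totals must be >= 0")
  K <- 10^logK
  M <- metal_total; L <- ligand_total
  if (K == 0) {
    cpx <- rep(0, length(M))
  } else {
    b <- M + L + 1 / K
    disc <- pmax(b^2 - 4 * M * L, 0)
    # smaller quadratic root, in the cancellation-safe form
    cpx <- 2 * M * L / (b + sqrt(disc))
  }
  cpx <- pmin(cpx, M, L)
  data.frame(complex = cpx, free_ligand = L - cpx, free_metal = M - cpx)
}

#' PCA relative standard deviation of a data matrix
#'
#' The residual-rank statistic used by RAFA: from the eigenvalues
#' \eqn{\lambda_1 \ge \dots \ge \lambda_s} of the (uncentered) covariance
#' matrix \eqn{X^\top X} of an r-by-s data matrix,
#' \deqn{RSD(n) = \sqrt{\frac{\sum_{j>n} \lambda_j}{r\,(s-n)}}.}
#' With `normalize = TRUE` the trailing eigenvalue sum is divided by the
#' total \eqn{\sum_j \lambda_j} instead, giving a scale-free fraction of
#' unexplained variance; either form is zero exactly when the matrix has
#' rank at most n, and both are minimized at the same point along a RAFA
#' scan.
#'
#' @param x Numeric matrix (wavelength x sample) or a `spectra_matrix`.
#' @param n_principal Number of retained principal components
#'   (0 <= n < number of samples).
#' @param normalize Divide by total variance instead of the per-element
#'   normalization (default FALSE).
#' @return Nonnegative scalar.
#' @export
rsd_statistic <- function(x, n_principal = 1L, normalize = FALSE) {
  if (inherits(x, "spectra_matrix")) x <- x$intensity
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("degenerate matrix: need at least 2 rows")
  s <- ncol(x)
  if (n_principal >= s) stop("n_principal must be smaller than the sample count")
  lam <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  trail <- sum(lam[seq.int(n_principal + 1L, s)])
  if (normalize) {
    tot <- sum(lam)
    if (tot == 0) return(0)
    sqrt(trail / tot)
  } else {
    sqrt(trail / (nrow(x) * (s - n_principal)))
  }
}

# ligand molar response: user-supplied, or calibrated from the metal-free
# sample divided by the ligand total
.ligand_response <- function(spectra, ligand_spectrum) {
  if (!is.null(ligand_spectrum)) {
    if (length(ligand_spectrum) != length(spectra$wavelengths))
      stop("ligand_spectrum must be on the spectra wavelength grid")
    return(as.numeric(ligand_spectrum))
  }
  i0 <- which(spectra$metal_totals == 0)[1]
  spectra$intensity[, i0] / sum(spectra$ligand_totals)
}

#' Rank annihilation of the free-ligand contribution
#'
#' Subtracts the bilinear free-ligand term (ligand molar response outer
#' free-ligand concentration vector) from the intensity matrix, with
#' free-ligand concentrations computed from the 1:1 binding quadratic at a
#' trial conditional constant. At the true constant the residual matrix
#' collapses to rank 1 (the complex alone) on noise-free data. Residuals
#' are signed; negative intensities are expected.
#'
#' @param spectra A `spectra_matrix` (single-ligand system).
#' @param trial_logK Trial conditional log K.
#' @param ligand_spectrum Optional per-wavelength molar response
#'   (AU M^-1 cm^-1) on the same grid; when NULL it is calibrated from the
#'   metal-free sample.
#' @return The residual intensity matrix (wavelength x sample).
#' @export
annihilate <- function(spectra, trial_logK, ligand_spectrum = NULL) {
  eps <- .ligand_response(spectra, ligand_spectrum)
  bf <- bound_fraction_1to1(spectra$metal_totals, sum(spectra$ligand_totals),
                            trial_logK)
  spectra$intensity - outer(eps, bf$free_ligand)
}

#' Scan trial constants for the RSD minimum (RAFA)
#'
#' Evaluates [rsd_statistic()] of the [annihilate()]d matrix over a grid of
#' trial conditional constants and reports the minimizer. Ties are broken
#' toward the smallest logK with a warning.
#'
#' @inheritParams annihilate
#' @param grid Strictly increasing trial logK values; default
#'   `seq(6, 14, by = 0.05)`.
#' @param n_principal Principal components retained after annihilation
#'   (default 1: the complex).
#' @param normalize Passed to [rsd_statistic()].
#' @return An object of class `rafa_scan`: list with `logK_grid`, `rsd`,
#'   `best_logK`, `n_principal`.
#' @export
scan_logK <- function(spectra, grid = seq(6, 14, by = 0.05),
                      ligand_spectrum = NULL, n_principal = 1L,
                      normalize = FALSE) {
  if (!length(grid)) stop("grid must be nonempty")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  eps <- .ligand_response(spectra, ligand_spectrum)
  rsd <- vapply(grid, function(k)
    rsd_statistic(annihilate(spectra, k, eps), n_principal, normalize),
    numeric(1))
  imin <- which(rsd == min(rsd))
  if (length(imin) > 1L)
    warning("flat RSD valley: ", length(imin),
            " grid points tie; taking the smallest logK")
  structure(list(logK_grid = grid, rsd = rsd, best_logK = grid[imin[1L]],
                 n_principal = as.integer(n_principal)),
            class = "rafa_scan")
}

#' @export
print.rafa_scan <- function(x, ...) {
  cat("RAFA scan over", length(x$logK_grid), "trial constants, n_principal =",
      x$n_principal, "\n")
  cat("best logK =", format(x$best_logK),
      "(min RSD =", format(min(x$rsd), digits = 4), ")\n")
  invisible(x)
}

#' Number of principal species in a spectral matrix
#'
#' Smallest number of principal components whose RSD falls below a
#' threshold: the PCA rank estimate used to count the species contributing
#' to a titration matrix.
#'
#' @param x Matrix or `spectra_matrix`.
#' @param rsd_threshold Positive cutoff on [rsd_statistic()].
#' @param normalize Passed to [rsd_statistic()].
#' @return Integer count of significant species (at most the sample count).
#' @export
estimate_rank <- function(x, rsd_threshold, normalize = FALSE) {
  if (rsd_threshold <= 0) stop("rsd_threshold must be positive")
  if (inherits(x, "spectra_matrix")) x <- x$intensity
  s <- ncol(x)
  for (n in seq_len(s - 1L)) {
    if (rsd_statistic(x, n, normalize) < rsd_threshold) return(n)
  }
  s
}

#' Residual spectra against the two-binary-complex synthetic model
#'
#' Builds synthetic ternary-system spectra under the assumptions that (1)
#' ligand-ligand interaction is negligible and (2) no mixed ternary complex
#' forms: the metal partitions between the two 1:1 complexes according to
#' the conditional constants, and each column is the bilinear sum of the
#' free ligands and the two binary complexes. The returned residual
#' (observed minus synthetic) isolates whatever the two-binary model cannot
#' explain, e.g. a ligand-ligand interaction band.
#'
#' @param spectra A two-ligand `spectra_matrix` (observed ternary
#'   titration).
#' @param ligand_spectra Named list (by ligand) of per-wavelength molar
#'   responses of the free ligands.
#' @param complex_spectra Named list (by ligand) of molar responses of the
#'   corresponding 1:1 complexes.
#' @param logK_cond Named numeric (by ligand) conditional constants of the
#'   two binary complexes.
#' @return Residual intensity matrix (wavelength x sample).
#' @export
residual_spectra <- function(spectra, ligand_spectra, complex_spectra,
                             logK_cond) {
  ligs <- names(spectra$ligand_totals)
  if (length(ligs) != 2L) stop("residual_spectra expects a two-ligand system")
  if (!all(ligs %in% names(logK_cond)))
    stop("conditional constants required for both ligands")
  for (nm in ligs) {
    for (sp in list(ligand_spectra[[nm]], complex_spectra[[nm]])) {
      if (is.null(sp) || length(sp) != length(spectra$wavelengths))
        stop("spectra for ligand '", nm, "' missing or not on the common grid")
    }
  }
  conc <- competitive_1to1_speciation(spectra$metal_totals,
                                      spectra$ligand_totals, logK_cond)
  synth <- 0
  for (nm in ligs) {
    synth <- synth + outer(ligand_spectra[[nm]], conc[[paste0("free_", nm)]]) +
      outer(complex_spectra[[nm]], conc[[paste0("complex_", nm)]])
  }
  spectra$intensity - synth
}

#' Competitive 1:1 speciation of two ligands for one metal
#'
#' Conditional-scale speciation with species ML_a and ML_b only (no proton
#' component), solved by the Newton mass-balance solver; the partition of
#' metal between two ligands at fixed pH.
#'
#' @param metal_totals Vector of metal totals (mol/L).
#' @param ligand_totals Named totals of the two ligands.
#' @param logK_cond Named conditional constants (same names).
#' @return data.frame with `metal_total`, `free_metal`, and per ligand
#'   `free_<name>` and `complex_<name>` columns.
#' @export
competitive_1to1_speciation <- function(metal_totals, ligand_totals, logK_cond) {
  ligs <- names(ligand_totals)
  comps <- c(list(eq_component("M", 0L, "metal")),
             lapply(ligs, function(nm) eq_component(nm, 0L, "ligand")))
  sp <- lapply(ligs, function(nm) {
    st <- c(1, 1); names(st) <- c("M", nm)
    eq_species(paste0("M", nm), st, logK_cond[[nm]])
  })
  model <- build_model(comps, sp)
  init <- NULL
  rows <- vector("list", length(metal_totals))
  for (i in seq_along(metal_totals)) {
    tot <- c(M = metal_totals[i], ligand_totals)
    r <- solve_speciation(model, tot, init = init)
    init <- r$free
    row <- list(metal_total = metal_totals[i], free_metal = r$free[["M"]])
    for (nm in ligs) {
      row[[paste0("free_", nm)]] <- r$free[[nm]]
      row[[paste0("complex_", nm)]] <- unname(r$species_conc[paste0("M", nm)])
    }
    rows[[i]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}
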