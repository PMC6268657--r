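# Independent brute-force oracles, deliberately naive: these never call the
# package's solvers.

# exact 1:1 binding by the quadratic formula, textbook form
oracle_quadratic_1to1 <- function(M, L, logK) {
  K <- 10^logK
  a <- K; b <- -(K * (M + L) + 1); cc <- K * M * L
  c1 <- (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
  min(c1, M, L)
}

# 2-component (metal + ligand, no proton) speciation by nested bisection on
# the free metal concentration; species must have nonnegative coefficients
oracle_bisect_2comp <- function(stoich, log_beta, totals, tol = 1e-14) {
  comp <- colnames(stoich)
  stopifnot(length(comp) == 2)
  conc_species <- function(free) 10^(log_beta + as.numeric(stoich %*% log10(free)))
  # given free metal, solve ligand balance by bisection, return metal residual
  metal_resid <- function(fm) {
    lig_resid <- function(fl) {
      cs <- conc_species(c(fm, fl))
      fl + sum(stoich[, 2] * cs) - totals[2]
    }
    lo <- totals[2] * 1e-16; hi <- totals[2]
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (lig_resid(mid) > 0) hi <- mid else lo <- mid
    }
    fl <- sqrt(lo * hi)
    cs <- conc_species(c(fm, fl))
    list(resid = fm + sum(stoich[, 1] * cs) - totals[1], free = c(fm, fl))
  }
  lo <- totals[1] * 1e-16; hi <- totals[1]
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (metal_resid(mid)$resid > 0) hi <- mid else lo <- mid
  }
  r <- metal_resid(sqrt(lo * hi))
  free <- r$free
  names(free) <- comp
  list(free = free, species = conc_species(free))
}

# trailing-eigenvalue sums via a plain SVD, independent of rsd_statistic
oracle_trailing_ssq <- function(X, n) {
  sv <- svd(X, nu = 0, nv = 0)$d
  sum(sv[seq.int(n + 1, length(sv))]^2)
}

default_cip_spectra <- function() {
  wl <- default_wavelengths()
  b <- default_bands()
  list(wl = wl,
       ligand = gen_species_spectrum(b$CIP, wl),
       complex = gen_species_spectrum(b$AlCIP, wl))
}
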