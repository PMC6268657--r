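#' Solve a multicomponent chemical equilibrium
#'
#' Solves the mass-balance system for the free component concentrations by a
#' damped Newton iteration on the natural-log free concentrations. For each
#' component j with analytical total \eqn{T_j},
#' \deqn{T_j = [j] + \sum_i S_{ij} c_i,\qquad
#'       c_i = 10^{\log\beta_i} \prod_k [k]^{S_{ik}},}
#' where \eqn{S} is the species stoichiometry matrix. Working in log space
#' keeps all concentrations strictly positive; the Newton step is halved
#' whenever the residual norm would increase. The proton total may be
#' negative (excess strong base); all other totals must be nonnegative.
#'
#' When `fixed_pH` is supplied the free proton concentration is clamped to
#' \eqn{10^{-pH}} and the proton mass balance is dropped, which is how
#' buffered (conditional-scale) systems are treated.
#'
#' If the Newton iteration fails to converge and the model has a proton
#' component, the solver falls back to an outer bisection on pH (the proton
#' excess function is monotone in pH) around an inner fixed-pH solve.
#'
#' @param model An `eq_model` from [build_model()].
#' @param totals Named numeric vector of analytical totals (mol/L), one per
#'   non-proton component; the proton total defaults to 0 if absent.
#' @param fixed_pH Optional pH at which to clamp the free proton
#'   concentration.
#' @param tol Convergence tolerance on the maximum relative mass-balance
#'   residual (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 200).
#' @param init Optional named vector of starting free concentrations
#'   (warm start).
#' @return A list of class `speciation_result` with `free` (named free
#'   concentrations), `species_conc` (named species concentrations), `pH`
#'   (if a proton component exists), `residuals` (relative mass-balance
#'   residuals), `converged`, `iterations`.
#' @export
solve_speciation <- function(model, totals, fixed_pH = NULL,
                             tol = 1e-10, max_iter = 200, init = NULL) {
  comp <- model$components$name
  h <- proton_name(model)
  tot <- stats::setNames(numeric(length(comp)), comp)
  unknown <- setdiff(names(totals), comp)
  if (length(unknown)) stop("totals name undeclared component(s): ",
                            paste(unknown, collapse = ", "))
  tot[names(totals)] <- totals
  missing_tot <- setdiff(setdiff(comp, h), names(totals))
  if (length(missing_tot))
    stop("missing totals for component(s): ", paste(missing_tot, collapse = ", "))
  if (any(tot[setdiff(comp, h)] < 0))
    stop("negative total for non-proton component")

  # components with an exactly-zero total are absent: eliminate them (free
  # concentration 0, every species containing them 0) and solve the reduced
  # system, so a metal-free sample yields exactly zero complexes
  zero <- setdiff(comp[tot == 0], h)
  if (length(zero) && length(zero) < length(comp)) {
    keep <- setdiff(comp, zero)
    keep_sp <- if (nrow(model$stoich)) {
      rowSums(abs(model$stoich[, zero, drop = FALSE])) == 0
    } else logical(0)
    red <- list(
      components = model$components[model$components$name %in% keep, , drop = FALSE],
      species = model$species[keep_sp],
      stoich = model$stoich[keep_sp, keep, drop = FALSE],
      log_beta = model$log_beta[keep_sp],
      temperature = model$temperature)
    class(red) <- "eq_model"
    r <- solve_speciation(red, totals = tot[keep],
                          fixed_pH = fixed_pH, tol = tol,
                          max_iter = max_iter, init = init)
    free <- stats::setNames(numeric(length(comp)), comp)
    free[names(r$free)] <- r$free
    spc <- stats::setNames(numeric(nrow(model$stoich)), rownames(model$stoich))
    spc[names(r$species_conc)] <- r$species_conc
    r$free <- free
    r$species_conc <- spc
    return(r)
  }

  res <- .solve_newton(model, tot, fixed_pH, tol, max_iter, init)
  if (!res$converged && is.null(fixed_pH) && !is.null(h)) {
    res2 <- .solve_ph_bisection(model, tot, tol, max_iter)
    if (res2$converged) res <- res2
  }
  if (!res$converged) {
    cond <- structure(
      class = c("eqspec_no_convergence", "error", "condition"),
      list(message = paste0("speciation solver did not converge (max relative residual ",
                            format(max(res$residuals), digits = 3), ")"),
           call = sys.call(-1), residuals = res$residuals))
    stop(cond)
  }
  res
}

# Newton core. `tot` is a full named vector over model components.
.solve_newton <- function(model, tot, fixed_pH, tol, max_iter, init = NULL) {
  comp <- model$components$name
  h <- proton_name(model)
  S <- model$stoich
  lb_ln <- model$log_beta * log(10)
  nsp <- nrow(S)

  lnf <- log(pmax(abs(tot), 1e-10))
  names(lnf) <- comp
  if (!is.null(h)) {
    lnf[h] <- if (!is.null(fixed_pH)) -fixed_pH * log(10) else
      log(if (tot[h] > 1e-9) tot[h] else 1e-7)
  }
  if (!is.null(init)) {
    ok <- intersect(names(init), comp)
    lnf[ok] <- log(pmax(init[ok], 1e-12))
    if (!is.null(fixed_pH) && !is.null(h)) lnf[h] <- -fixed_pH * log(10)
  }
  solve_for <- if (!is.null(fixed_pH) && !is.null(h)) setdiff(comp, h) else comp

  calc <- function(lnf) {
    cs <- if (nsp) exp(lb_ln + as.numeric(S %*% lnf)) else numeric(0)
    f <- exp(lnf) + (if (nsp) as.numeric(crossprod(S, cs)) else 0) - tot
    names(f) <- comp
    denom <- pmax(abs(tot), exp(lnf) + (if (nsp) as.numeric(crossprod(abs(S), cs)) else 0), 1e-300)
    list(cs = cs, f = f, rel = abs(f) / denom)
  }

  # log-scaling preconditioner: for components with positive totals, damped
  # fixed-point updates ln[j] += (ln T_j - ln calc_j)/m_j with calc_j the
  # positive-coefficient species sum and m_j the largest coefficient. This
  # walks the guess from arbitrarily far away into Newton's basin (high-order
  # polynuclear species make the raw residual astronomically steep).
  scale_for <- solve_for[tot[solve_for] > 0]
  if (!is.null(h)) scale_for <- setdiff(scale_for, h)
  if (length(scale_for) && nsp) {
    Spos <- pmax(S, 0)
    mj <- pmax(apply(Spos, 2, max), 1)
    logsumexp <- function(v) { m <- max(v); if (!is.finite(m)) m else m + log(sum(exp(v - m))) }
    for (k in 1:300) {
      ln_cs <- if (nsp) lb_ln + as.numeric(S %*% lnf) else numeric(0)
      ln_calc <- vapply(scale_for, function(j) {
        terms <- c(lnf[[j]],
                   if (nsp) ln_cs[Spos[, j] > 0] + log(Spos[Spos[, j] > 0, j]))
        logsumexp(terms)
      }, numeric(1))
      adj <- (log(tot[scale_for]) - ln_calc) / mj[scale_for]
      if (all(is.finite(adj)) && max(abs(adj)) < 1e-3) break
      adj[!is.finite(adj)] <- -3
      lnf[scale_for] <- lnf[scale_for] + pmax(pmin(adj, 3), -3)
    }
  }

  st <- calc(lnf)
  iter <- 0L
  while (iter < max_iter) {
    if (max(st$rel[solve_for]) < tol) break
    iter <- iter + 1L
    # J[j,k] = d f_j / d ln[k] = delta_jk [j] + sum_i S_ij S_ik c_i
    J <- diag(exp(lnf), length(comp))
    if (nsp) J <- J + crossprod(S, S * st$cs)
    dimnames(J) <- list(comp, comp)
    Jr <- J[solve_for, solve_for, drop = FALSE]
    step <- tryCatch(solve(Jr, -st$f[solve_for]), error = function(e) NULL)
    if (is.null(step))
      step <- tryCatch(
        as.numeric(qr.solve(Jr + diag(1e-12 * max(diag(Jr)), nrow(Jr)),
                            -st$f[solve_for])),
        error = function(e) rep(0, length(solve_for)))
    # limit the log-step, then damp by halving while the residual grows
    big <- max(abs(step))
    if (big > 5) step <- step * (5 / big)
    base_norm <- sqrt(sum(st$rel[solve_for]^2))
    lam <- 1
    repeat {
      lnf_try <- lnf
      lnf_try[solve_for] <- lnf[solve_for] + lam * step
      st_try <- calc(lnf_try)
      if (all(is.finite(st_try$f)) &&
          (sqrt(sum(st_try$rel[solve_for]^2)) < base_norm || lam < 1e-6)) break
      lam <- lam / 2
    }
    lnf <- lnf_try
    st <- st_try
  }
  free <- exp(lnf)
  out <- list(free = free,
              species_conc = stats::setNames(st$cs, rownames(S)),
              residuals = stats::setNames(st$rel, comp)[solve_for],
              converged = max(st$rel[solve_for]) < tol,
              iterations = iter)
  if (!is.null(h)) out$pH <- -log10(free[[h]])
  class(out) <- "speciation_result"
  out
}

# Fallback: bisection on pH around inner fixed-pH solves. The proton excess
# (calculated total H at clamped pH minus the analytical total) decreases
# monotonically with pH.
.solve_ph_bisection <- function(model, tot, tol, max_iter, lo = 0, hi = 14) {
  h <- proton_name(model)
  excess <- function(pH) {
    r <- .solve_newton(model, tot, fixed_pH = pH, tol, max_iter)
    if (!r$converged) return(NA_real_)
    hv <- r$free[[h]] + sum(model$stoich[, h] * r$species_conc)
    hv - tot[[h]]
  }
  flo <- excess(lo); fhi <- excess(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo < 0 || fhi > 0)
    return(list(converged = FALSE, residuals = stats::setNames(Inf, h)))
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    fm <- excess(mid)
    if (!is.finite(fm)) return(list(converged = FALSE, residuals = stats::setNames(Inf, h)))
    if (fm > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-13) break
  }
  r <- .solve_newton(model, tot, fixed_pH = (lo + hi) / 2, tol, max_iter)
  # rebuild as a full (unclamped) solution and polish with Newton
  .solve_newton(model, tot, fixed_pH = NULL, tol, max_iter, init = r$free)
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Speciation result (converged:", x$converged, "in", x$iterations, "iterations)\n")
  if (!is.null(x$pH)) cat("pH:", format(x$pH, digits = 6), "\n")
  cat("Free concentrations (M):\n"); print(signif(x$free, 6))
  if (length(x$species_conc)) {
    cat("Species concentrations (M):\n"); print(signif(x$species_conc, 6))
  }
  invisible(x)
}

#' Species distribution of a reference component versus pH
#'
#' Solves the speciation at each pH on a grid (proton clamped, buffered
#' convention) and returns the fraction of the reference component's total
#' held by each species, plus the free component. Fractions sum to 1 at
#' every grid point.
#'
#' @param model An `eq_model`.
#' @param totals Named analytical totals (mol/L) for the non-proton
#'   components.
#' @param pH_grid Strictly increasing pH values within [2, 11].
#' @param reference Component whose distribution is tabulated; defaults to
#'   the metal component if present.
#' @return A long-format data.frame with columns `pH`, `species`, `fraction`.
#' @export
distribution_vs_pH <- function(model, totals, pH_grid, reference = NULL) {
  if (any(diff(pH_grid) <= 0)) stop("pH_grid must be strictly increasing")
  if (min(pH_grid) < 2 || max(pH_grid) > 11)
    stop("pH_grid must lie within [2, 11]")
  if (is.null(reference)) {
    reference <- model$components$name[model$components$role == "metal"][1]
    if (is.na(reference)) stop("no metal component; supply `reference`")
  }
  if (!(reference %in% model$components$name))
    stop("reference '", reference, "' is not a component of the model")
  coef_ref <- model$stoich[, reference]
  Tref <- totals[[reference]]
  if (is.null(Tref) || Tref <= 0) stop("reference total must be positive")
  init <- NULL
  out <- vector("list", length(pH_grid))
  for (i in seq_along(pH_grid)) {
    r <- solve_speciation(model, totals, fixed_pH = pH_grid[i], init = init)
    init <- r$free
    frac <- c(stats::setNames(r$free[[reference]] / Tref, reference),
              (coef_ref * r$species_conc / Tref)[coef_ref != 0])
    out[[i]] <- data.frame(pH = pH_grid[i], species = names(frac),
                           fraction = unname(frac), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Free-ligand and complex fractions versus total metal
#'
#' Fixed-pH speciation over a grid of metal totals at constant ligand
#' totals: the distribution diagram of a competitive binding system.
#' For each ligand, the free fraction and the summed complexed fraction add
#' to 1.
#'
#' @param model An `eq_model` (fixed-pH/conditional scale: typically no
#'   proton component, or one clamped via `fixed_pH`).
#' @param ligand_totals Named totals (mol/L) of the ligand components.
#' @param metal_grid Nonnegative metal totals (mol/L).
#' @param fixed_pH Optional clamped pH (needed only if the model has a
#'   proton component).
#' @param metal Metal component name; defaults to the component with role
#'   `"metal"`.
#' @return Long-format data.frame: `metal_total`, `species` (free ligands
#'   and complexes), `concentration`, `fraction_of` (the ligand whose total
#'   normalizes the row), `fraction`.
#' @export
distribution_vs_metal <- function(model, ligand_totals, metal_grid,
                                  fixed_pH = NULL, metal = NULL) {
  if (any(metal_grid < 0)) stop("metal_grid must be nonnegative")
  if (is.null(metal)) {
    metal <- model$components$name[model$components$role == "metal"][1]
    if (is.na(metal)) stop("no metal component; supply `metal`")
  }
  ligs <- names(ligand_totals)
  init <- NULL
  out <- vector("list", length(metal_grid))
  for (i in seq_along(metal_grid)) {
    tot <- c(stats::setNames(metal_grid[i], metal), ligand_totals)
    r <- solve_speciation(model, tot, fixed_pH = fixed_pH, init = init)
    init <- r$free
    rows <- list()
    for (L in ligs) {
      coefL <- model$stoich[, L]
      free_row <- data.frame(metal_total = metal_grid[i], species = L,
                             concentration = r$free[[L]], fraction_of = L,
                             fraction = r$free[[L]] / ligand_totals[[L]],
                             stringsAsFactors = FALSE)
      idx <- which(coefL != 0)
      cpx <- data.frame(metal_total = metal_grid[i],
                        species = rownames(model$stoich)[idx],
                        concentration = unname(r$species_conc[idx]),
                        fraction_of = L,
                        fraction = unname(coefL[idx] * r$species_conc[idx]) /
                          ligand_totals[[L]],
                        stringsAsFactors = FALSE)
      rows[[L]] <- rbind(free_row, cpx)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Conditional stability constant at fixed pH
#'
#' Converts an absolute cumulative formation constant to its conditional
#' value at a given pH by subtracting the metal side-reaction coefficient
#' \deqn{\alpha_M = 1 + \sum_q 10^{\mathrm{lg}\beta_q}\,[H^+]^{-q},}
#' built from the metal hydrolysis constants (hydroxo species written as
#' deprotonation equilibria).
#'
#' @param log_beta_abs Absolute cumulative log beta.
#' @param hydrolysis Named or unnamed numeric vector of cumulative
#'   hydrolysis constants lg beta_q, in order q = 1, 2, ...; defaults to
#'   the Al(III) set [al_hydrolysis_log_beta()].
#' @param pH The fixed pH.
#' @return Conditional log K (dimensionless).
#' @seealso [side_reaction_coefficient()]
#' @export
conditional_constant <- function(log_beta_abs, hydrolysis = al_hydrolysis_log_beta(),
                                 pH) {
  log_beta_abs - side_reaction_coefficient(hydrolysis, pH)
}

#' Metal side-reaction coefficient from hydrolysis constants
#'
#' @inheritParams conditional_constant
#' @return log10 of alpha_M(pH); 0 when no hydrolysis term matters.
#' @export
side_reaction_coefficient <- function(hydrolysis = al_hydrolysis_log_beta(), pH) {
  if (!is.finite(pH)) stop("invalid pH")
  q <- seq_along(hydrolysis)
  log10(1 + sum(10^(unname(hydrolysis) + q * pH)))
}

#' Gibbs free energy of dissociation from a stability constant
#'
#' \eqn{\Delta G = \ln(10)\, R\, T\, \log K} in kcal/mol: the free energy
#' required to dissociate a complex whose formation constant is
#' \eqn{10^{\log K}}.
#'
#' @param logK Common-log stability constant.
#' @param temperature Kelvin (> 0); default 298.15.
#' @return Energy in kcal/mol.
#' @export
gibbs_from_logK <- function(logK, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  R_kcal <- 1.98720425864083e-3  # kcal mol^-1 K^-1
  log(10) * R_kcal * temperature * logK
}
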