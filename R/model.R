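#' Define a component of an equilibrium model
#'
#' A component is a basis constituent (metal ion, fully deprotonated ligand,
#' or the proton) from which every species is assembled. Charges are carried
#' for bookkeeping only; no electroneutrality constraint is imposed.
#'
#' @param name Unique component identifier, e.g. `"Al"`, `"CIP"`, `"H"`.
#' @param charge Signed integer charge (informational).
#' @param role One of `"metal"`, `"ligand"`, `"proton"`.
#' @return An object of class `eq_component`.
#' @export
eq_component <- function(name, charge = 0L, role = c("ligand", "metal", "proton")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, charge = as.integer(charge), role = role),
            class = "eq_component")
}

#' Define a species by its stoichiometry and cumulative formation constant
#'
#' A species \eqn{M_p L_q H_r} is described by signed stoichiometric
#' coefficients over the model components and its cumulative formation
#' constant \eqn{\log\beta} from the free components. Hydroxide-containing
#' species carry a proton coefficient of \eqn{-1} per OH (so hydrolysis is a
#' deprotonation equilibrium and OH⁻ itself is the species with
#' stoichiometry `c(H = -1)` and `log_beta = -pKw`).
#'
#' @param label Unique species label, e.g. `"Al(OH)"`, `"Al(CIP)(HNADP)"`.
#' @param stoichiometry Named integer vector mapping component names to
#'   signed coefficients; at least one coefficient must be nonzero.
#' @param log_beta Cumulative formation constant in common logarithm; must
#'   be finite.
#' @param adjustable Logical; marks the constant as refinable by
#'   [refine_constants()].
#' @return An object of class `eq_species`.
#' @export
eq_species <- function(label, stoichiometry, log_beta, adjustable = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named vector of component coefficients")
  if (all(stoichiometry == 0))
    stop("species '", label, "' has no nonzero stoichiometric coefficient")
  if (!is.finite(log_beta))
    stop("species '", label, "' has non-finite log_beta")
  structure(list(label = label,
                 stoichiometry = stoichiometry[stoichiometry != 0],
                 log_beta = as.numeric(log_beta),
                 adjustable = isTRUE(adjustable)),
            class = "eq_species")
}

#' Assemble and validate an equilibrium model
#'
#' Collects components and species into a validated model. Every
#' stoichiometry key must name a declared component, species labels must be
#' unique, and at most one component may carry the proton role. A bare free
#' component needs no species entry: the solver accounts for free
#' concentrations directly (equivalently, a species with a single unit
#' coefficient and `log_beta = 0`).
#'
#' @param components List of [eq_component()] objects.
#' @param species List of [eq_species()] objects (may be empty).
#' @param temperature Kelvin; default 298.15.
#' @return An object of class `eq_model` with elements `components`
#'   (data.frame), `species` (list), `stoich` (species-by-component matrix),
#'   `log_beta` (numeric vector), and `temperature`.
#' @export
build_model <- function(components, species = list(), temperature = 298.15) {
  if (inherits(components, "eq_component")) components <- list(components)
  if (inherits(species, "eq_species")) species <- list(species)
  stopifnot(length(components) >= 1L)
  comp_names <- vapply(components, function(c) c$name, character(1))
  if (anyDuplicated(comp_names))
    stop("duplicate component name: ",
         paste(unique(comp_names[duplicated(comp_names)]), collapse = ", "))
  roles <- vapply(components, function(c) c$role, character(1))
  if (sum(roles == "proton") > 1L)
    stop("at most one component may have role 'proton'")

  labels <- vapply(species, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate species label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  S <- matrix(0, nrow = length(species), ncol = length(comp_names),
              dimnames = list(labels, comp_names))
  for (i in seq_along(species)) {
    st <- species[[i]]$stoichiometry
    unknown <- setdiff(names(st), comp_names)
    if (length(unknown))
      stop("species '", labels[i], "' references undeclared component(s): ",
           paste(unknown, collapse = ", "))
    S[i, names(st)] <- st
  }
  structure(list(
    components = data.frame(
      name = comp_names,
      charge = vapply(components, function(c) c$charge, integer(1)),
      role = roles,
      stringsAsFactors = FALSE),
    species = species,
    stoich = S,
    log_beta = vapply(species, function(s) s$log_beta, numeric(1)),
    temperature = temperature), class = "eq_model")
}

#' @export
print.eq_model <- function(x, ...) {
  cat("Equilibrium model:", nrow(x$components), "components,",
      length(x$species), "species\n")
  cat("Components:", paste0(x$components$name, " (", x$components$role, ")",
                            collapse = ", "), "\n")
  if (length(x$species)) {
    tab <- data.frame(log_beta = x$log_beta,
                      adjustable = vapply(x$species, `[[`, logical(1), "adjustable"))
    rownames(tab) <- rownames(x$stoich)
    print(cbind(as.data.frame(x$stoich), tab))
  }
  invisible(x)
}

proton_name <- function(model) {
  p <- model$components$name[model$components$role == "proton"]
  if (length(p)) p else NULL
}

#' Replace formation constants in a model
#'
#' @param model An `eq_model`.
#' @param log_beta Named numeric vector mapping species labels to new
#'   cumulative log beta values.
#' @return The modified model.
#' @export
set_log_beta <- function(model, log_beta) {
  lab <- rownames(model$stoich)
  unknown <- setdiff(names(log_beta), lab)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  idx <- match(names(log_beta), lab)
  model$log_beta[idx] <- as.numeric(log_beta)
  for (k in seq_along(idx)) model$species[[idx[k]]]$log_beta <- as.numeric(log_beta[k])
  model
}

#' Add species to an existing model
#'
#' @param model An `eq_model`.
#' @param species A single [eq_species()] or list thereof.
#' @return A new validated model containing the extra species.
#' @export
add_species <- function(model, species) {
  if (inherits(species, "eq_species")) species <- list(species)
  comps <- lapply(seq_len(nrow(model$components)), function(i)
    eq_component(model$components$name[i], model$components$charge[i],
                 model$components$role[i]))
  build_model(comps, c(model$species, species), model$temperature)
}

# ---- built-in constants -----------------------------------------------------

#' Aluminium(III) hydrolysis species
#'
#' Cumulative hydrolysis constants for Al(OH)q, q = 1..4, expressed as
#' deprotonation equilibria (lg*beta*_q for Al³⁺ + q H₂O ⇌ Al(OH)q + q H⁺):
#' −5.5, −11.1, −16.6, −23.2 at 25 °C.
#'
#' @param metal Name of the metal component (default `"Al"`).
#' @param proton Name of the proton component (default `"H"`).
#' @return List of [eq_species()].
#' @export
al_hydrolysis_species <- function(metal = "Al", proton = "H") {
  lgb <- c(-5.5, -11.1, -16.6, -23.2)
  lapply(1:4, function(q) {
    st <- c(1, -q); names(st) <- c(metal, proton)
    eq_species(sprintf("%s(OH)%s", metal, if (q > 1) q else ""), st, lgb[q])
  })
}

#' Cumulative hydrolysis constants of Al(III)
#' @return Named numeric vector, names `"1"`..`"4"` (number of hydroxides).
#' @export
al_hydrolysis_log_beta <- function() c(`1` = -5.5, `2` = -11.1, `3` = -16.6, `4` = -23.2)

#' Hydroxide as a species (water autoprotolysis)
#'
#' @param pKw Ionic product of water in common logarithm; default 13.78
#'   (25 °C, 0.2 M KCl).
#' @param proton Proton component name.
#' @return An [eq_species()] for OH⁻ with proton coefficient −1.
#' @export
water_species <- function(pKw = 13.78, proton = "H") {
  st <- c(-1); names(st) <- proton
  eq_species("OH", st, -pKw)
}

#' Potentiometric formation constants of the Al(III)-CIP-NADP system
#'
#' Cumulative formation constants (log beta from free components, BEST
#' convention) for proton, binary Al(III), and mixed-ligand species of
#' ciprofloxacin (CIP) and NADP at 25 °C, I = 0.20 M KCl.
#'
#' @return A data.frame with columns `label`, `system`, `log_beta`, `sd` and
#'   the stoichiometric coefficients `Al`, `CIP`, `NADP`, `H`.
#' @export
cip_nadp_constants <- function() {
  tab <- rbind(
    # label                system  logb   sd    Al CIP NADP  H
    c("H(CIP)",            "CIP",   8.60, 0.03,  0, 1, 0, 1),
    c("H2(CIP)",           "CIP",  14.76, 0.03,  0, 1, 0, 2),
    c("H(NADP)",           "NADP",  9.93, 0.03,  0, 0, 1, 1),
    c("H2(NADP)",          "NADP", 16.09, 0.04,  0, 0, 1, 2),
    c("H3(NADP)",          "NADP", 19.90, 0.06,  0, 0, 1, 3),
    c("Al(CIP)",           "CIP",   9.36, 0.03,  1, 1, 0, 0),
    c("Al(HCIP)",          "CIP",  15.85, 0.08,  1, 1, 0, 1),
    c("Al(CIP)(HCIP)",     "CIP",  21.38, 0.03,  1, 2, 0, 1),
    c("Al(NADP)",          "NADP", 10.71, 0.02,  1, 0, 1, 0),
    c("Al(HNADP)",         "NADP", 16.01, 0.01,  1, 0, 1, 1),
    c("Al(H2NADP)",        "NADP", 19.16, 0.04,  1, 0, 1, 2),
    c("Al(H2NADP)2",       "NADP", 37.84, 0.06,  1, 0, 2, 4),
    c("Al(NADP)2(HNADP)",  "NADP", 29.82, 0.02,  1, 0, 3, 1),
    c("Al(H2NADP)3",       "NADP", 57.53, 0.04,  1, 0, 3, 6),
    c("Al(CIP)(HNADP)",    "ternary", 26.56, 0.02, 1, 1, 1, 1),
    c("Al(HCIP)(HNADP)",   "ternary", 32.49, 0.02, 1, 1, 1, 2))
  data.frame(label = tab[, 1], system = tab[, 2],
             log_beta = as.numeric(tab[, 3]), sd = as.numeric(tab[, 4]),
             Al = as.integer(tab[, 5]), CIP = as.integer(tab[, 6]),
             NADP = as.integer(tab[, 7]), H = as.integer(tab[, 8]),
             stringsAsFactors = FALSE)
}

#' Build a ready-made Al(III)-CIP-NADP model
#'
#' Assembles a validated [build_model()] for a chosen subsystem of the
#' Al(III)-ciprofloxacin-NADP equilibria, using the constants in
#' [cip_nadp_constants()], water autoprotolysis (pKw 13.78), and optionally
#' the Al(III) hydrolysis species.
#'
#' @param system Character subset of `c("CIP", "NADP", "ternary")`: which
#'   species families to include. Ligand components are included whenever any
#'   selected species needs them.
#' @param metal Include the Al component and Al-containing species
#'   (default TRUE; set FALSE for ligand-only protonation models).
#' @param hydrolysis Include Al(OH)q species (default `metal`).
#' @param pKw Water ionic product (common logarithm).
#' @return An `eq_model`.
#' @export
cip_nadp_model <- function(system = c("CIP", "NADP", "ternary"),
                           metal = TRUE, hydrolysis = metal, pKw = 13.78) {
  system <- match.arg(system, c("CIP", "NADP", "ternary"), several.ok = TRUE)
  tab <- cip_nadp_constants()
  tab <- tab[tab$system %in% system, ]
  if (!metal) tab <- tab[tab$Al == 0, ]
  use_cip <- any(tab$CIP > 0)
  use_nadp <- any(tab$NADP > 0)
  comps <- list()
  if (metal) comps <- c(comps, list(eq_component("Al", 3L, "metal")))
  if (use_cip) comps <- c(comps, list(eq_component("CIP", -1L, "ligand")))
  if (use_nadp) comps <- c(comps, list(eq_component("NADP", -3L, "ligand")))
  comps <- c(comps, list(eq_component("H", 1L, "proton")))
  sp <- lapply(seq_len(nrow(tab)), function(i) {
    st <- c(Al = tab$Al[i], CIP = tab$CIP[i], NADP = tab$NADP[i], H = tab$H[i])
    eq_species(tab$label[i], st[st != 0], tab$log_beta[i])
  })
  sp <- c(sp, list(water_species(pKw)))
  if (metal && hydrolysis) sp <- c(sp, al_hydrolysis_species())
  build_model(comps, sp)
}
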