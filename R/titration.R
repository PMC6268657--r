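#' Describe a pH-potentiometric titration design
#'
#' The experimental frame of a strong-base titration: a sample of known
#' analytical composition (including the excess strong-acid proton total)
#' titrated with KOH, recording pH at each addition. Dilution is accounted
#' for exactly: at added volume v the totals are rescaled by
#' \eqn{V_0/(V_0+v)} and the base subtracts \eqn{C_b v/(V_0+v)} from the
#' proton total.
#'
#' @param initial_volume Initial sample volume (L), e.g. 0.050.
#' @param totals Named analytical totals of the initial solution (mol/L);
#'   the proton entry counts dissociable protons on the dissolved ligand
#'   forms plus any strong-acid excess.
#' @param titrant_conc KOH concentration (mol/L, > 0), e.g. 0.1026.
#' @param volumes Strictly increasing added titrant volumes (L).
#' @param pH Optional measured/simulated pH per point (NA before
#'   simulation).
#' @param medium Free-text descriptor, default `"0.2 M KCl, 25 C"`.
#' @return An object of class `titration_dataset`.
#' @export
titration_dataset <- function(initial_volume, totals, titrant_conc, volumes,
                              pH = rep(NA_real_, length(volumes)),
                              medium = "0.2 M KCl, 25 C") {
  if (titrant_conc <= 0) stop("titrant_conc must be positive")
  if (length(volumes) && any(diff(volumes) <= 0))
    stop("added volumes must be strictly increasing")
  if (length(pH) != length(volumes)) stop("pH and volumes length mismatch")
  if (any(!is.na(pH) & (pH <= 0 | pH >= 14))) stop("pH must lie in (0, 14)")
  structure(list(initial_volume = initial_volume, totals = totals,
                 titrant_conc = titrant_conc,
                 points = data.frame(volume = as.numeric(volumes),
                                     pH = as.numeric(pH)),
                 medium = medium),
            class = "titration_dataset")
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat("Titration dataset:", nrow(x$points), "points, V0 =",
      x$initial_volume * 1e3, "mL, titrant", x$titrant_conc, "M KOH\n")
  cat("Totals (M):", paste(names(x$totals), format(unname(x$totals)),
                           collapse = ", "), "\n")
  cat("Medium:", x$medium, "\n")
  if (any(!is.na(x$points$pH)))
    cat("pH range:", format(range(x$points$pH, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

# analytical totals at one titration point (dilution + base addition)
.point_totals <- function(dataset, v, proton = "H") {
  V0 <- dataset$initial_volume
  f <- V0 / (V0 + v)
  tot <- dataset$totals * f
  if (!(proton %in% names(tot))) tot[proton] <- 0
  tot[proton] <- tot[proton] - dataset$titrant_conc * v / (V0 + v)
  tot
}

#' Simulate the pH curve of a titration design
#'
#' Computes the equilibrium pH at every titration point by
#' [solve_speciation()], warm-starting each point from the previous one.
#' Points at which the solver fails are flagged (pH NA), mirroring the
#' practice of omitting non-equilibrated points from the fit.
#'
#' @param model An `eq_model` with a proton component.
#' @param design A [titration_dataset()] (pH values ignored/overwritten).
#' @return The dataset with computed `pH` and a logical `converged` column
#'   in `points`.
#' @export
simulate_titration <- function(model, design) {
  h <- proton_name(model)
  if (is.null(h)) stop("model needs a proton component to titrate")
  pts <- design$points
  pH <- rep(NA_real_, nrow(pts))
  conv <- logical(nrow(pts))
  init <- NULL
  for (i in seq_len(nrow(pts))) {
    tot <- .point_totals(design, pts$volume[i], h)
    r <- tryCatch(solve_speciation(model, tot, init = init),
                  eqspec_no_convergence = function(e) NULL)
    if (!is.null(r)) {
      pH[i] <- r$pH
      conv[i] <- TRUE
      init <- r$free
    } else init <- NULL
  }
  design$points$pH <- pH
  design$points$converged <- conv
  design
}

#' Root-mean-square pH residual of a model against a titration
#'
#' \eqn{\sigma_{fit} = \sqrt{\mathrm{mean}_k (pH^{obs}_k - pH^{calc}_k)^2}}
#' over the usable points: the model-acceptance statistic of potentiometric
#' refinement (a good fit reaches values below 0.01).
#'
#' @param model An `eq_model`.
#' @param dataset A titration with observed pH values.
#' @param exclude Optional logical/integer mask of points to drop (e.g.
#'   non-equilibrated regions).
#' @return Nonnegative scalar.
#' @export
sigma_fit <- function(model, dataset, exclude = NULL) {
  res <- .ph_residuals(model, dataset, exclude)
  if (!length(res$residual)) stop("no usable titration points")
  sqrt(mean(res$residual^2))
}

# pH residuals (obs - calc) on the usable points; points where the solver
# fails under this model are excluded with a reason
.ph_residuals <- function(model, dataset, exclude = NULL) {
  pts <- dataset$points
  use <- !is.na(pts$pH)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) use <- use & !exclude else use[exclude] <- FALSE
  }
  h <- proton_name(model)
  idx <- which(use)
  calc <- rep(NA_real_, length(idx))
  init <- NULL
  for (k in seq_along(idx)) {
    tot <- .point_totals(dataset, pts$volume[idx[k]], h)
    r <- tryCatch(solve_speciation(model, tot, init = init),
                  eqspec_no_convergence = function(e) NULL)
    if (!is.null(r)) { calc[k] <- r$pH; init <- r$free } else init <- NULL
  }
  ok <- !is.na(calc)
  list(index = idx[ok], residual = pts$pH[idx[ok]] - calc[ok],
       excluded = idx[!ok])
}

#' Refine cumulative formation constants against titration data
#'
#' Least-squares refinement of selected log beta values so the simulated pH
#' curves reproduce the observed ones: a Gauss-Newton iteration with
#' Levenberg damping on the summed squared pH residuals over all datasets,
#' forward-difference Jacobian in log beta. Approximate standard deviations
#' come from the Jacobian at the solution,
#' \eqn{\mathrm{cov} = s^2 (J^\top J)^{-1}} with
#' \eqn{s^2 = SSR/(n-p)}.
#'
#' @param model An `eq_model` holding starting log beta values for the
#'   adjustable species.
#' @param datasets A `titration_dataset` or list of them, with observed pH.
#' @param adjustable Character vector of species labels to refine.
#' @param start Optional named numeric overriding the model's starting
#'   values.
#' @param max_iter Maximum Gauss-Newton iterations (default 50).
#' @param step_tol Convergence on the largest |delta log beta|
#'   (default 1e-5).
#' @param fd_step Forward-difference step in log beta (default 1e-4).
#' @return An object of class `fit_result`: `refined` (data.frame with
#'   `species`, `log_beta`, `sd`), `sigma_fit`, `n_points_used`,
#'   `excluded_points`, `model` (with refined constants), `converged`,
#'   `iterations`.
#' @export
refine_constants <- function(model, datasets, adjustable, start = NULL,
                             max_iter = 50, step_tol = 1e-5, fd_step = 1e-4,
                             verbose = FALSE) {
  if (inherits(datasets, "titration_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("need at least one dataset")
  lab <- rownames(model$stoich)
  if (!length(adjustable)) stop("no adjustable species given")
  unknown <- setdiff(adjustable, lab)
  if (length(unknown)) stop("adjustable species not in model: ",
                            paste(unknown, collapse = ", "))
  theta <- model$log_beta[match(adjustable, lab)]
  names(theta) <- adjustable
  if (!is.null(start)) theta[names(start)] <- start

  resid_all <- function(th) {
    m <- set_log_beta(model, th)
    out <- list()
    excl <- list()
    for (d in seq_along(datasets)) {
      r <- .ph_residuals(m, datasets[[d]])
      out[[d]] <- r$residual
      if (length(r$excluded))
        excl[[d]] <- data.frame(dataset = d, point = r$excluded,
                                reason = "solver non-convergence")
    }
    list(r = unlist(out), excluded = do.call(rbind, excl))
  }

  cur <- resid_all(theta)
  ssr <- sum(cur$r^2)
  lambda <- 1e-2
  converged <- FALSE
  iter <- 0L
  J <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    n <- length(cur$r)
    J <- matrix(0, n, length(theta), dimnames = list(NULL, adjustable))
    for (p in seq_along(theta)) {
      th <- theta; th[p] <- th[p] + fd_step
      rp <- resid_all(th)$r
      if (length(rp) != n) stop("point-exclusion pattern changed during ",
                                "differentiation; supply an exclusion mask")
      J[, p] <- (rp - cur$r) / fd_step
    }
    JtJ <- crossprod(J)
    colnorm <- sqrt(diag(JtJ))
    dead <- colnorm < 1e-12
    if (any(dead))
      stop("singular normal equations: species ",
           paste(adjustable[dead], collapse = ", "),
           " do(es) not affect the calculated pH (unidentifiable)")
    g <- crossprod(J, cur$r)
    dmax <- max(diag(JtJ))
    repeat {
      # Levenberg damping with a floored Marquardt scaling so the normal
      # equations stay well-posed even when a parameter loses leverage
      D <- diag(pmax(diag(JtJ), 1e-6 * dmax), length(theta))
      step <- tryCatch(solve(JtJ + lambda * D, -g), error = function(e) NULL)
      if (!is.null(step)) {
        # trust region: each constant moves at most 0.5 log unit per step
        step <- pmax(pmin(as.numeric(step), 0.5), -0.5)
        th_new <- theta + step
        names(th_new) <- adjustable
        new <- resid_all(th_new)
        # reject steps that lose titration points to solver failure
        if (length(new$r) == length(cur$r) && sum(new$r^2) < ssr) {
          theta <- th_new
          cur <- new
          ssr <- sum(new$r^2)
          lambda <- max(lambda / 10, 1e-12)
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
    if (verbose)
      message(sprintf("iter %d  ssr %.3e  sigma %.2e  lambda %.1e  max|step| %.2e",
                      iter, ssr, sqrt(ssr / length(cur$r)), lambda,
                      max(abs(step))))
    if (max(abs(step)) < step_tol || lambda > 1e10) {
      converged <- max(abs(step)) < step_tol
      break
    }
  }

  n <- length(cur$r); p <- length(theta)
  s2 <- if (n > p) ssr / (n - p) else 0
  covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  sds <- if (is.null(covm)) rep(NA_real_, p) else sqrt(pmax(diag(covm), 0))
  refined_model <- set_log_beta(model, theta)
  structure(list(
    refined = data.frame(species = adjustable, log_beta = unname(theta),
                         sd = sds, stringsAsFactors = FALSE),
    sigma_fit = sqrt(ssr / n),
    n_points_used = n,
    excluded_points = cur$excluded,
    model = refined_model,
    converged = converged,
    iterations = iter), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Formation-constant refinement (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(transform(x$refined, log_beta = round(log_beta, 3),
                  sd = signif(sd, 2)))
  cat("sigma_fit =", format(x$sigma_fit, digits = 4),
      "over", x$n_points_used, "points\n")
  if (!is.null(x$excluded_points) && nrow(x$excluded_points))
    cat(nrow(x$excluded_points), "points excluded (solver non-convergence)\n")
  invisible(x)
}

#' Stepwise model building by greedy sigma_fit reduction
#'
#' Adds candidate species to a base model one at a time, at each round
#' refining the constants of the species added so far and keeping the
#' candidate that lowers sigma_fit the most. The loop stops when sigma_fit
#' falls below `sigma_threshold` (default 0.01) or when no candidate
#' improves it by more than `min_improve` relative (default 5%).
#'
#' @param base_model An `eq_model` whose constants are held fixed.
#' @param candidates List of [eq_species()] with starting log beta values;
#'   labels must not collide with base species.
#' @param datasets Observed titration dataset(s).
#' @param sigma_threshold Stop when sigma_fit drops below this.
#' @param min_improve Minimum relative sigma_fit improvement to accept a
#'   candidate.
#' @param ... Passed to [refine_constants()].
#' @return List with `model` (final), `fit` (final `fit_result` or NULL if
#'   nothing was added), `trail` (data.frame logging each round), and
#'   `selected` (labels added).
#' @export
stepwise_model_build <- function(base_model, candidates, datasets,
                                 sigma_threshold = 0.01, min_improve = 0.05,
                                 ...) {
  if (inherits(datasets, "titration_dataset")) datasets <- list(datasets)
  if (inherits(candidates, "eq_species")) candidates <- list(candidates)
  base_lab <- rownames(base_model$stoich)
  cand_lab <- vapply(candidates, `[[`, character(1), "label")
  if (length(intersect(cand_lab, base_lab)))
    stop("candidates must be disjoint from the base model species")
  sigma0 <- sqrt(mean(unlist(lapply(datasets, function(d)
    .ph_residuals(base_model, d)$residual))^2))
  model <- base_model
  selected <- character(0)
  fit <- NULL
  trail <- data.frame(round = 0L, added = NA_character_, sigma_fit = sigma0,
                      stringsAsFactors = FALSE)
  round <- 0L
  while (sigma0 >= sigma_threshold && length(candidates)) {
    round <- round + 1L
    fits <- lapply(candidates, function(sp) {
      m <- add_species(model, sp)
      tryCatch(refine_constants(m, datasets,
                                adjustable = c(selected, sp$label), ...),
               error = function(e) NULL)
    })
    sig <- vapply(fits, function(f) if (is.null(f)) Inf else f$sigma_fit,
                  numeric(1))
    best <- which.min(sig)
    if (!is.finite(sig[best]) || sig[best] > sigma0 * (1 - min_improve)) break
    model <- fits[[best]]$model
    fit <- fits[[best]]
    selected <- c(selected, candidates[[best]]$label)
    trail <- rbind(trail, data.frame(round = round,
                                     added = candidates[[best]]$label,
                                     sigma_fit = sig[best]))
    candidates <- candidates[-best]
    sigma0 <- sig[best]
  }
  list(model = model, fit = fit, trail = trail, selected = selected)
}
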