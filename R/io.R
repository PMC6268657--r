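#' Read and write spectral titration matrices as CSV
#'
#' Layout: first column `wavelength_nm`, one column per sample whose header
#' carries the metal total in molar (`M_<total>`); a JSON sidecar (same
#' path with `.json` extension) stores the ligand totals and channel.
#' Numeric output is full precision; `read_spectra_csv(write_spectra_csv(x))`
#' round-trips exactly.
#'
#' @param x A [spectra_matrix()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_spectra_csv` returns `path` invisibly;
#'   `read_spectra_csv` returns a `spectra_matrix`.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_matrix"))
  df <- data.frame(wavelength_nm = x$wavelengths, x$intensity)
  names(df) <- c("wavelength_nm",
                 paste0("sample_", seq_along(x$metal_totals)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(schema_version = 1L,
               channel = x$channel,
               metal_totals = x$metal_totals,
               ligand_totals = as.list(x$ligand_totals))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar JSON: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("channel", "metal_totals", "ligand_totals"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "'")
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("empty spectra file")
  if (names(df)[1] != "wavelength_nm") stop("first column must be wavelength_nm")
  wl <- df[[1]]
  if (any(diff(wl) <= 0)) stop("non-monotone wavelength column")
  X <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(X) != length(meta$metal_totals))
    stop("sample count mismatch between CSV (", ncol(X),
         ") and sidecar (", length(meta$metal_totals), ")")
  spectra_matrix(wl, X, as.numeric(meta$metal_totals),
                 unlist(meta$ligand_totals), meta$channel)
}

#' Read and write potentiometric titrations as CSV
#'
#' Layout: columns `volume_L`, `pH` (and `converged` when present); the
#' JSON sidecar stores initial volume, analytical totals, titrant
#' concentration, and medium. Round-trips exactly.
#'
#' @param x A [titration_dataset()].
#' @param path CSV path.
#' @return `write_titration_csv` returns `path` invisibly;
#'   `read_titration_csv` a `titration_dataset`.
#' @export
write_titration_csv <- function(x, path) {
  stopifnot(inherits(x, "titration_dataset"))
  df <- data.frame(volume_L = x$points$volume, pH = x$points$pH)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(schema_version = 1L,
               initial_volume = x$initial_volume,
               totals = as.list(x$totals),
               titrant_conc = x$titrant_conc,
               medium = x$medium)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar JSON: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("initial_volume", "totals", "titrant_conc"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "'")
  df <- utils::read.csv(path)
  if (!nrow(df)) stop("empty titration file")
  if (!all(c("volume_L", "pH") %in% names(df)))
    stop("titration CSV needs columns volume_L and pH")
  titration_dataset(meta$initial_volume, unlist(meta$totals),
                    meta$titrant_conc, df$volume_L, df$pH,
                    medium = if (is.null(meta$medium)) "" else meta$medium)
}

#' Read and write equilibrium models as JSON
#'
#' Schema (versioned): a `components` array of `{name, charge, role}` and a
#' `species` array of `{label, stoichiometry, log_beta, adjustable}` with
#' stoichiometry as a name-to-coefficient map.
#'
#' @param model An `eq_model`.
#' @param path JSON path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   an `eq_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "eq_model"))
  obj <- list(
    schema_version = 1L,
    temperature = model$temperature,
    components = lapply(seq_len(nrow(model$components)), function(i)
      list(name = model$components$name[i],
           charge = model$components$charge[i],
           role = model$components$role[i])),
    species = lapply(model$species, function(s)
      list(label = s$label, stoichiometry = as.list(s$stoichiometry),
           log_beta = s$log_beta, adjustable = s$adjustable)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$components)) stop("model JSON missing components")
  comps <- lapply(obj$components, function(c)
    eq_component(c$name, c$charge, c$role))
  sp <- lapply(obj$species, function(s)
    eq_species(s$label, unlist(s$stoichiometry), s$log_beta,
               isTRUE(s$adjustable)))
  build_model(comps, sp,
              temperature = if (is.null(obj$temperature)) 298.15 else obj$temperature)
}
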