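#!/usr/bin/env Rscript
# Rank annihilation factor analysis of the binary spectral titrations from
# 01_simulate_data.R: estimates the number of principal species, scans the
# conditional stability constant over logK 6-14, and converts the best
# estimates to dissociation free energies. Writes the RSD-vs-logK tables
# and a summary JSON under results/rafa/.

suppressPackageStartupMessages(library(eqspec))
indir <- "results/data"; outdir <- "results/rafa"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

summary <- list()
for (sys in c("al_cip", "al_nadp")) {
  sm <- read_spectra_csv(file.path(indir, paste0("uvvis_", sys, ".csv")))
  n_species <- estimate_rank(sm, rsd_threshold = 5e-3)
  sc <- suppressWarnings(scan_logK(sm, grid = seq(6, 14, by = 0.05)))
  utils::write.csv(data.frame(logK = sc$logK_grid, rsd = sc$rsd),
                   file.path(outdir, paste0("rsd_scan_", sys, ".csv")),
                   row.names = FALSE)
  dg <- gibbs_from_logK(sc$best_logK)
  summary[[sys]] <- list(n_principal_species = n_species,
                         best_logK = sc$best_logK,
                         min_rsd = min(sc$rsd),
                         dissociation_dG_kcal_mol = dg)
  message(sprintf("%s: %d principal species; best logK = %.2f; dG = %.1f kcal/mol",
                  sys, n_species, sc$best_logK, dg))
}
message("note: at 20 uM ligand and logK ~ 10 binding is near-stoichiometric,")
message("so the RSD valley is shallow on the high-logK side; see the vignette.")

jsonlite::write_json(summary, file.path(outdir, "rafa_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", outdir)
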