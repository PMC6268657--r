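#!/usr/bin/env Rscript
# Generates the synthetic raw data for the whole analysis chain:
#  - binary absorbance titrations of CIP and NADP with Al(III)
#    (20 uM ligand, Al 0-20 uM, pH-7 buffer, 0.002 AU read noise),
#  - a ternary absorbance titration (20 uM each ligand, Al 0-25 uM) with a
#    small ligand-ligand interaction band near 290 nm,
#  - an emission titration of CIP (excitation 270 nm),
#  - pH-potentiometric titrations at ligand 0.001 M and metal:ligand ratios
#    0:1, 1:1, 1:2, 1:5 plus the 1:1:1 ternary run (KOH 0.1026 M, 50 mL),
# and writes everything as CSV + JSON sidecars under results/data/.

suppressPackageStartupMessages(library(eqspec))
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20120901L

wl <- default_wavelengths()
bands <- default_bands()
eps <- lapply(bands[c("CIP", "NADP", "AlCIP", "AlNADP")], function(b)
  gen_species_spectrum(b, wl))

message("-- binary UV-vis titrations (5-sample absorbance designs)")
sm_cip <- gen_uvvis_titration(eps$CIP, eps$AlCIP, ligand_total = 20e-6,
                              metal_totals = c(0, 5, 10, 15, 20) * 1e-6,
                              logK_cond = 10.2, ligand_name = "CIP",
                              noise = noise_spec(0.002, seed = seed))
write_spectra_csv(sm_cip, file.path(outdir, "uvvis_al_cip.csv"))
sm_nadp <- gen_uvvis_titration(eps$NADP, eps$AlNADP, ligand_total = 20e-6,
                               metal_totals = c(0, 5, 10, 15, 20) * 1e-6,
                               logK_cond = 10.7, ligand_name = "NADP",
                               noise = noise_spec(0.002, seed = seed + 1L))
write_spectra_csv(sm_nadp, file.path(outdir, "uvvis_al_nadp.csv"))

message("-- ternary UV-vis titration with a 290 nm interaction band")
sm_tern <- gen_ternary_titration(
  ligand_spectra = eps[c("CIP", "NADP")],
  complex_spectra = list(CIP = eps$AlCIP, NADP = eps$AlNADP),
  ligand_totals = c(CIP = 20e-6, NADP = 20e-6),
  metal_totals = c(0, 5, 10, 15, 20, 25) * 1e-6,
  logK_cond = c(CIP = 10.2, NADP = 10.7),
  interaction_band = band_spec(290, 6, 2e3),
  noise = noise_spec(0.002, seed = seed + 2L), wavelengths = wl)
write_spectra_csv(sm_tern, file.path(outdir, "uvvis_ternary.csv"))

message("-- emission titration of CIP (426 -> 433 nm, 2.5x gain)")
wl_em <- default_wavelengths("emission")
bands_em <- default_bands("emission")
sm_em <- gen_uvvis_titration(
  gen_species_spectrum(bands_em$CIP, wl_em),
  gen_species_spectrum(bands_em$AlCIP, wl_em),
  ligand_total = 20e-6, metal_totals = c(0, 5, 10, 15, 20) * 1e-6,
  logK_cond = 10.2, wavelengths = wl_em, channel = "emission",
  ligand_name = "CIP", noise = noise_spec(50, seed = seed + 3L))
write_spectra_csv(sm_em, file.path(outdir, "emission_al_cip.csv"))

message("-- potentiometric titrations (0.001 M ligand, KOH 0.1026 M)")
runs <- list(
  cip_0_1  = list(model = cip_nadp_model("CIP", metal = FALSE),
                  design = standard_titration_design(c_cip = 1e-3)),
  nadp_0_1 = list(model = cip_nadp_model("NADP", metal = FALSE),
                  design = standard_titration_design(c_nadp = 1e-3)),
  nadp_1_1 = list(model = cip_nadp_model("NADP"),
                  design = standard_titration_design(c_al = 1e-3, c_nadp = 1e-3)),
  nadp_1_2 = list(model = cip_nadp_model("NADP"),
                  design = standard_titration_design(c_al = 5e-4, c_nadp = 1e-3)),
  nadp_1_5 = list(model = cip_nadp_model("NADP"),
                  design = standard_titration_design(c_al = 2e-4, c_nadp = 1e-3)),
  ternary_1_1_1 = list(model = cip_nadp_model(),
                       design = standard_titration_design(c_al = 1e-3,
                                                          c_cip = 1e-3,
                                                          c_nadp = 1e-3)))
for (nm in names(runs)) {
  obs <- gen_potentiometric_titration(runs[[nm]]$model, runs[[nm]]$design,
                                      noise_spec(sigma_pH = 0.005,
                                                 seed = seed + match(nm, names(runs))))
  write_titration_csv(obs, file.path(outdir, paste0("titration_", nm, ".csv")))
  message(sprintf("   %s: %d points, pH %.2f-%.2f", nm, nrow(obs$points),
                  min(obs$points$pH, na.rm = TRUE),
                  max(obs$points$pH, na.rm = TRUE)))
}

message("-- equilibrium model JSON (all published constants)")
write_model_json(cip_nadp_model(), file.path(outdir, "model_al_cip_nadp.json"))
message("done; data under ", outdir)
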