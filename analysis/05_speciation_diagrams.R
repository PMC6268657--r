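#!/usr/bin/env Rscript
# Speciation diagrams of the competitive Al(III)-CIP-NADP system:
#  - conditional-scale distribution of the two ligands versus total Al at
#    pH 7.0, 20 uM each ligand (the linear-response regime used for
#    quantifying Al or the ligands by fluorescence),
#  - full-model species distribution of Al versus pH for the 1:1:1 system
#    at 10 mM,
#  - the Al side-reaction coefficient and conditional constants at pH 7.
# Tables go to results/speciation/; a PDF figure is drawn when ggplot2 is
# installed.

suppressPackageStartupMessages(library(eqspec))
outdir <- "results/speciation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("-- side-reaction coefficient and conditional constants at pH 7")
la <- side_reaction_coefficient(al_hydrolysis_log_beta(), 7.0)
message(sprintf("log alpha_Al(OH)(pH 7) = %.3f", la))
message(sprintf("dG(diss) at logK 10.2 / 10.7 = %.1f / %.1f kcal/mol",
                gibbs_from_logK(10.2), gibbs_from_logK(10.7)))

message("-- ligand distribution vs total Al (pH 7, conditional scale)")
m_cond <- build_model(
  list(eq_component("Al", 3L, "metal"),
       eq_component("CIP", -1L, "ligand"),
       eq_component("NADP", -3L, "ligand")),
  list(eq_species("Al(CIP)", c(Al = 1, CIP = 1), 10.2),
       eq_species("Al(NADP)", c(Al = 1, NADP = 1), 10.7)))
tab_m <- distribution_vs_metal(m_cond, c(CIP = 20e-6, NADP = 20e-6),
                               metal_grid = seq(0, 40e-6, by = 1e-6))
utils::write.csv(tab_m, file.path(outdir, "distribution_vs_al.csv"),
                 row.names = FALSE)

message("-- Al species distribution vs pH (1:1:1, 10 mM, full model)")
m_full <- cip_nadp_model()
tab_ph <- distribution_vs_pH(m_full, c(Al = 1e-2, CIP = 1e-2, NADP = 1e-2),
                             pH_grid = seq(3, 8, by = 0.05))
utils::write.csv(tab_ph, file.path(outdir, "distribution_vs_ph.csv"),
                 row.names = FALSE)
at7 <- tab_ph[abs(tab_ph$pH - 7) < 1e-9 & tab_ph$fraction > 0.01, ]
message("species above 1% of Al at pH 7.0:")
for (i in order(-at7$fraction))
  message(sprintf("   %-18s %5.1f%%", at7$species[i], 100 * at7$fraction[i]))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(tab_ph[tab_ph$fraction > 0.005, ],
              aes(pH, fraction, colour = species)) +
    geom_line() +
    labs(y = "fraction of total Al",
         title = "Al(III)-CIP-NADP 1:1:1 speciation (10 mM)") +
    theme_minimal()
  ggsave(file.path(outdir, "distribution_vs_ph.pdf"), p,
         width = 7, height = 4)
}
message("wrote ", outdir)
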