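#!/usr/bin/env Rscript
# Stage 5: phytoplankton community. Shannon diversity with
# treatment-by-day contrasts, Bray-Curtis NMDS ordinations, one-way
# PERMANOVA per sampling day preceded by dispersion-homogeneity tests,
# dominance of the diquat-tolerant taxa, and the chlorophyll-biomass
# correspondence check.

suppressMessages(library(mesotox))

ds <- suppressWarnings(read_dataset("results/dataset"))
res <- suppressWarnings(run_pipeline(ds, stages = "algae", seed = 1))
al <- res$algae

cat("PERMANOVA / dispersion / NMDS per day:\n")
print(al$permanova_table, digits = 3)
cat("\nDiversity contrasts (treatment vs control within day):\n")
print(al$diversity_contrasts$contrasts, digits = 3)
m7 <- community_matrix(ds, 7)
sh <- dominance_share(m7, c("Chlorella_spp", "Scenedesmus_quadricauda"),
                      factor(attr(m7, "treatment")))
cat("\nShare of the two tolerant taxa at day 7, by treatment (ug/L):\n")
print(round(100 * sh, 1))
cat(sprintf("\nChlorophyll-biomass linear model R^2 = %.2f\n",
            al$chlorophyll_biomass$r_squared))

write_results(
  list(permanova_table = al$permanova_table,
       diversity = al$diversity,
       diversity_contrasts = al$diversity_contrasts$contrasts,
       nmds_day7_coords = data.frame(
         tank_id = rownames(al$per_day[["7"]]$nmds$coordinates),
         al$per_day[["7"]]$nmds$coordinates)),
  "results/algae", seed = 1)
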