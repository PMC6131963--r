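#!/usr/bin/env Rscript
# Stage 6 — peeling mechanics.
#
# (a) Kendall thin-film peel force over the peel angle: larger angles need
#     less force, the rationale for detachment via dorsodistal septum
#     loading (> 90 deg peel angle).
# (b) Contact-stress comparison on a pad-scale block: pulling the septum
#     attachment line dorsodistally concentrates tensile normal traction
#     at the proximal edge of the ventral contact surface and raises the
#     mean pull-off traction relative to an equal-magnitude proximal pull.

library(padmech)
dir.create("results", showWarnings = FALSE)

cfg <- peel_config(width_b_mm = 1, thickness_d_mm = 0.1, E_MPa = 20,
                   R_Jm2 = 1)
th <- seq(10, 180, by = 5)
peel <- data.frame(theta_deg = th,
                   force_N = kendall_peel_force(cfg, theta_deg = th))
write.csv(peel, "results/kendall_peel.csv", row.names = FALSE)
message(sprintf("Kendall force falls from %.3g N (10 deg) to %.3g N (180 deg)",
                peel$force_N[1], peel$force_N[nrow(peel)]))
message(sprintf("ratio F(45 deg)/F(135 deg): %.2f",
                kendall_peel_force(cfg, 45) / kendall_peel_force(cfg, 135)))

rep <- septum_loadcase_comparison(peel_pad_domain(), material())
print(rep)
jsonlite::write_json(
  lapply(rep$cases, function(cs)
    cs[c("max_tensile", "max_location", "mean_tensile", "mean_signed")]),
  "results/septum_comparison.json", auto_unbox = TRUE, digits = NA)
message("wrote results/kendall_peel.csv and results/septum_comparison.json")
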