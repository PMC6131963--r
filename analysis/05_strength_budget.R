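#!/usr/bin/env Rscript
# Stage 5 — tensile load budgets.
#
# Plain area-times-strength failure bounds of the force-transmitting
# structures against two reference loads: the 1.27 N peak measured on a
# single digital pad and the 3.815 mN per-digit body-weight share.

library(padmech)
dir.create("results", showWarnings = FALSE)

message(sprintf("per-digit body-weight load: %.3f mN",
                per_digit_load(7, 18) * 1e3))
message(sprintf("collagen-layer capacity: %.1f-%.1f N",
                tensile_capacity(20000, 100), tensile_capacity(65000, 100)))
message(sprintf("septum capacity: %.2f-%.2f N",
                tensile_capacity(6500, 100), tensile_capacity(7500, 100)))
message(sprintf("muscle-bundle capacity (strength 0.2-0.4 MPa): up to %.1f mN",
                tensile_capacity(14000, 0.4) * 1e3))

bd <- budget_report()
print(bd)
write.csv(as.data.frame(bd), "results/load_budget.csv", row.names = FALSE)
message("wrote results/load_budget.csv")
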