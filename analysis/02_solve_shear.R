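#!/usr/bin/env Rscript
# Stage 2 — shear-loaded non-optimised model.
#
# Solves the pad model with the ventral face fixed and the 3.815 mN
# proximal pull (the body-weight share of one digit), recovers stresses,
# and quantifies the two published patterns: higher von Mises stress
# between the hole rows than between holes within a row, and a proximal ->
# distal stress decay.

library(padmech)
dir.create("results", showWarnings = FALSE)

dom <- build_design_domain(pad_params(), c(30, 20, 9))
mat <- material(E_MPa = 20, nu = 0.33)
sol <- solve_displacement(dom, mat, shear_load_case())
print(sol)

stress <- recover_stress(dom, mat, sol)
print(stress)

ct <- von_mises_contrasts(stress, dom)
print(ct)
message(sprintf("inter-row webs carry %.2fx the von Mises stress of intra-row webs",
                ct$ratio))

write_vtk_fields(dom, "results/solution.vtk",
                 cell_data = list(density = dom$density,
                                  von_mises = stress$von_mises,
                                  sigma1 = stress$principal[1, ]),
                 point_data = list(displacement = sol$U))
jsonlite::write_json(unclass(ct), "results/vm_contrasts.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote results/solution.vtk and results/vm_contrasts.json")
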