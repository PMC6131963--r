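test_that("schedule validates the stepped volume-reduction arithmetic", {
  sch <- optimisation_schedule()
  expect_equal(sch$n_stages, 24L)                 # 60% in 2.5% steps
  expect_equal(sch$targets[24], 0.40)
  expect_error(optimisation_schedule(total_reduction = 0.6, step = 0.07),
               "multiple")
  expect_error(optimisation_schedule(total_reduction = 1.2), "total_reduction")
})

test_that("compliance sensitivities are non-positive and match finite differences", {
  dom <- toy_domain(c(2L, 1L, 1L), c(0.2, 0.1, 0.1),
                    density = c(0.8, 0.6))
  mat <- material(E_MPa = 20)
  lc <- load_case(fixed = list(face_fixed("proximal")),
                  tractions = list(face_traction("distal",
                                                 force = c(1e-3, 0, 5e-4))))
  cs <- compliance_and_sensitivity(dom, mat, lc)
  expect_gt(cs$compliance, 0)
  expect_true(all(cs$sensitivity <= 0))
  h <- 1e-4
  for (e in 1:2) {
    fd <- vapply(c(h, -h), function(d) {
      dp <- dom; dp$density[e] <- dp$density[e] + d
      solve_displacement(dp, mat, lc)$compliance
    }, numeric(1))
    num <- (fd[1] - fd[2]) / (2 * h)
    expect_equal(as.numeric(cs$sensitivity)[e], num, tolerance = 1e-4)
  }
})

test_that("uniform solid under load has all non-positive sensitivities and quadratic compliance", {
  dom <- solid_box(c(4L, 3L, 3L), c(0.4, 0.3, 0.3))
  mat <- material()
  lc1 <- load_case(fixed = list(face_fixed("ventral")),
                   tractions = list(face_traction("distal",
                                                  force = c(2e-3, 0, 0))))
  lc2 <- load_case(fixed = list(face_fixed("ventral")),
                   tractions = list(face_traction("distal",
                                                  force = c(4e-3, 0, 0))))
  c1 <- compliance_and_sensitivity(dom, mat, lc1)
  c2 <- compliance_and_sensitivity(dom, mat, lc2)
  expect_true(all(c1$sensitivity <= 0))
  expect_equal(c2$compliance, 4 * c1$compliance, tolerance = 1e-10)
})

test_that("sensitivity filter preserves constants, spreads spikes, and can be identity", {
  dom <- solid_box(c(3L, 3L, 3L), c(0.3, 0.3, 0.3))
  const <- array(-2.5, c(3, 3, 3))
  expect_equal(filter_sensitivities(const, dom, 0.15), const)
  # radius below a voxel edge: identity
  spike <- array(0, c(3, 3, 3)); spike[2, 2, 2] <- -1
  expect_identical(filter_sensitivities(spike, dom, 0.05), spike)
  # explicit weight-sum oracle at radius 1.5 voxel edges
  r <- 0.15
  sm <- filter_sensitivities(spike, dom, r)
  h <- 0.1
  ctr <- padmech:::domain_centres(dom)
  for (v in seq_len(27)) {
    d_spike <- sqrt(sum((ctr[v, ] - ctr[14, ])^2))
    w_spike <- max(0, r - d_spike)
    wsum <- sum(pmax(0, r - sqrt(colSums((t(ctr) - ctr[v, ])^2))))
    expect_equal(sm[v], -w_spike / wsum, tolerance = 1e-12)
  }
  expect_true(all(sm <= 0))  # sign preserved
})

test_that("optimality-criteria update holds volume, bounds, and symmetry", {
  dom <- toy_domain(c(4L, 4L, 2L), c(0.4, 0.4, 0.2), density = 0.7,
                    symmetric = TRUE)
  # fixed point: uniform sensitivities at unchanged volume
  sens <- array(-1, dom$resolution)
  up <- update_densities(dom, sens, volume_fraction(dom))
  expect_equal(up$density, dom$density, tolerance = 1e-3)
  # strongly loaded block is retained preferentially
  dom2 <- toy_domain(c(4L, 2L, 1L), c(0.4, 0.2, 0.1), density = 0.8)
  sens2 <- array(-1e-6, dom2$resolution)
  sens2[1:2, , ] <- -1  # left block matters
  up2 <- update_densities(dom2, sens2, 0.65)
  expect_gt(mean(up2$density[1:2, , ]), mean(up2$density[3:4, , ]))
  expect_equal(volume_fraction(up2), 0.65, tolerance = 1e-4)
  expect_true(all(up2$density >= 0 & up2$density <= 1))
  # asymmetric sensitivities still yield an exactly mirror-symmetric field
  set.seed(7)
  sens3 <- array(-runif(32), dom$resolution)
  up3 <- update_densities(dom, sens3, 0.6)
  expect_identical(up3$density, padmech:::mirror_lateral(up3$density))
  # infeasible target under the move limit
  expect_error(update_densities(dom, sens, 0.2), "infeasible")
})

test_that("void and frozen voxels are respected by the update", {
  dom <- toy_domain(c(4L, 2L, 2L), c(0.4, 0.2, 0.2), density = 0.9)
  dom$void[1, 1, 1] <- TRUE; dom$density[1, 1, 1] <- 0
  dom$frozen[4, 2, 2] <- TRUE; dom$density[4, 2, 2] <- 1
  dom$n_solid <- sum(!dom$void)
  set.seed(3)
  sens <- array(-1, dom$resolution)
  sens[!dom$void] <- -runif(sum(!dom$void))
  up <- update_densities(dom, sens, 0.8)
  expect_equal(up$density[1, 1, 1], 0)
  expect_equal(up$density[4, 2, 2], 1)
  expect_equal(volume_fraction(up), 0.8, tolerance = 1e-4)
})

test_that("half-domain symmetry reduction reproduces the full solve", {
  dom <- build_design_domain(pad_params(), pad_small_res)
  frozen <- array(FALSE, dom$resolution)
  frozen[, , 1] <- !dom$void[, , 1]
  dom$frozen <- frozen
  mat <- material(); lc <- shear_load_case()
  expect_true(padmech:::symmetry_reducible(dom, lc))
  full <- solve_displacement(dom, mat, lc)
  half <- solve_displacement(padmech:::half_domain(dom), mat,
                             padmech:::half_load_case(lc))
  emap <- padmech:::half_expand_map(dom$resolution)
  u_exp <- half$u[emap$idx] * emap$sgn
  expect_lt(max(abs(u_exp - full$u)) / max(abs(full$u)), 1e-8)
  expect_equal(2 * half$compliance, full$compliance, tolerance = 1e-10)
})

test_that("optimisation follows the schedule and never loses stiffness order", {
  dom <- build_design_domain(pad_params(), pad_small_res)
  mat <- material(); lc <- shear_load_case()
  sch <- optimisation_schedule(total_reduction = 0.15, step = 0.025,
                               inner_iters_max = 4)
  opt <- suppressWarnings(optimise_topology(dom, mat, lc, schedule = sch))
  h <- opt$history
  expect_equal(nrow(h), 6L)
  expect_equal(h$volume_fraction, sch$targets, tolerance = 1e-4)
  expect_true(all(diff(h$volume_fraction) < 0))
  # optimal compliance cannot drop as the volume constraint tightens
  expect_true(all(diff(h$compliance_Nmm) >
                    -1e-6 * h$compliance_Nmm[-nrow(h)]))
  # mirror symmetry maintained exactly; voids stay empty
  expect_identical(opt$domain$density,
                   padmech:::mirror_lateral(opt$domain$density))
  expect_true(all(opt$domain$density[opt$domain$void] == 0))
  expect_true(all(opt$domain$density[, , 1][!opt$domain$void[, , 1]] == 1))
})

test_that("optimised cantilever keeps a connected load path", {
  dom <- solid_box(c(24L, 2L, 8L), c(2.4, 0.2, 0.8))
  mat <- material()
  lc <- load_case(fixed = list(face_fixed("proximal")),
                  tractions = list(face_traction("distal",
                                                 force = c(0, 0, -1e-4))))
  sch <- optimisation_schedule(total_reduction = 0.5, step = 0.025,
                               inner_iters_max = 10)
  opt <- suppressWarnings(
    optimise_topology(dom, mat, lc, schedule = sch, freeze_ventral = FALSE))
  mask <- opt$domain$density > 0.5
  lab <- padmech:::label_components(mask)
  support <- lab[1, , ][mask[1, , ]]
  loaded <- lab[24, , ][mask[24, , ]]
  expect_gt(length(support), 0)
  expect_gt(length(loaded), 0)
  expect_true(any(support %in% loaded))
  expect_equal(volume_fraction(opt$domain), 0.5, tolerance = 1e-4)
})
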