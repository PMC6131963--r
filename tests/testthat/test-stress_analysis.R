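test_that("trajectories are straight on a uniform uniaxial field", {
  dom <- solid_box(c(20L, 10L, 10L), c(2, 1, 1))
  st <- uniform_stress_field(dom, c(1, 0, 0, 0, 0, 0))
  seeds <- cbind(0.05, c(0.3, 0.5, 0.7), c(0.25, 0.5, 0.75))
  tr <- trace_trajectories(st, dom, seeds = seeds, step_mm = 0.05)
  expect_length(tr, 3L)
  for (i in seq_along(tr)) {
    p <- tr[[i]]$points
    expect_lt(max(abs(p[, 2] - seeds[i, 2])), 1e-10)
    expect_lt(max(abs(p[, 3] - seeds[i, 3])), 1e-10)
    expect_equal(tr[[i]]$termination, "left_domain")
    expect_gt(max(p[, 1]), 1.9)  # traverses the whole box
  }
})

test_that("sign continuity keeps trajectories smooth on a rotating field", {
  dom <- solid_box(c(30L, 6L, 30L), c(3, 0.6, 3))
  # principal direction rotates with x: eigenvector sign returned by eigen()
  # is arbitrary along the way and must be re-oriented by the integrator
  st <- synthetic_stress_field(dom, function(p) {
    th <- 0.9 * pi * p[1] / 3
    v <- c(cos(th), 0, sin(th))
    M <- 2 * tcrossprod(v) - 0.5 * diag(3)
    c(M[1, 1], M[2, 2], M[3, 3], M[2, 3], M[1, 3], M[1, 2])
  })
  step <- 0.05
  tr <- trace_trajectories(st, dom, seeds = cbind(0.1, 0.3, 0.2),
                           step_mm = step, max_steps = 500)
  p <- tr[[1]]$points
  expect_gt(nrow(p), 20)
  seg <- diff(p)
  lens <- sqrt(rowSums(seg^2))
  expect_true(all(lens <= 2 * step))             # no reversal jumps
  dots <- rowSums(seg[-1, , drop = FALSE] * seg[-nrow(seg), , drop = FALSE])
  expect_true(all(dots > 0))                     # consistently oriented
  # all points stay inside the bounding box
  expect_true(all(p >= -1e-12 & p <= matrix(c(3, 0.6, 3), nrow(p), 3,
                                            byrow = TRUE) + 1e-12))
})

test_that("seeds in void are skipped and void terminates integration", {
  dom <- solid_box(c(10L, 10L, 10L), c(1, 1, 1))
  dom$void[6:10, , ] <- TRUE
  dom$density[dom$void] <- 0
  st <- uniform_stress_field(dom, c(1, 0, 0, 0, 0, 0))
  expect_warning(
    tr <- trace_trajectories(st, dom,
                             seeds = rbind(c(0.05, 0.5, 0.5),
                                           c(0.75, 0.5, 0.5)),
                             step_mm = 0.05),
    "skipped")
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$termination, "entered_void")
  expect_lt(max(tr[[1]]$points[, 1]), 0.55)
})

test_that("uniform patch field gives unit contrast ratio and equal quartiles", {
  dom <- build_design_domain(pad_params(), pad_small_res)
  nel <- prod(dom$resolution)
  st <- uniform_stress_field(dom, c(1, 0, 0, 0, 0, 0))
  ct <- von_mises_contrasts(st, dom)
  expect_equal(ct$ratio, 1, tolerance = 1e-12)
  expect_equal(ct$quartile_means, rep(1, 4), tolerance = 1e-12)
  expect_gt(ct$n_inter, 0)
  expect_gt(ct$n_intra, 0)
})

test_that("a layout without holes flags the contrast ratio as undefined", {
  dom <- build_design_domain(
    pad_params(n_rows = 0, holes_per_row = 0,
               recess = recess_params("none")), pad_small_res)
  st <- uniform_stress_field(dom, c(1, 0, 0, 0, 0, 0))
  ct <- von_mises_contrasts(st, dom)
  expect_true(ct$no_holes)
  expect_true(is.na(ct$ratio))
})

test_that("contrast report is a pure function of its inputs", {
  dom <- build_design_domain(pad_params(), pad_small_res)
  mat <- material()
  sol <- solve_displacement(dom, mat, shear_load_case())
  st <- recover_stress(dom, mat, sol)
  expect_identical(von_mises_contrasts(st, dom), von_mises_contrasts(st, dom))
})

test_that("ridge profile recovers constructed extrema and ignores flat fields", {
  dom <- solid_box(c(20L, 40L, 5L), c(1, 2, 0.25))
  y <- (seq_len(40) - 0.5) * 0.05
  prof <- exp(-((y - 0.5) / 0.15)^2) + exp(-((y - 1.5) / 0.15)^2)
  dom$density <- array(rep(prof, each = 20), dom$resolution)
  rp <- ridge_profile(dom, duct_band = c(0, 1))
  expect_equal(sort(rp$maxima_y), c(0.525, 1.525), tolerance = 0.06)
  expect_length(rp$minima_y, 1L)
  expect_equal(rp$minima_y, 1.025, tolerance = 0.06)
  # full-density solid: no internal extrema
  flat <- solid_box(c(10L, 10L, 5L), c(1, 1, 0.5))
  rpf <- ridge_profile(flat, duct_band = c(0, 1))
  expect_length(rpf$minima_y, 0L)
  expect_length(rpf$maxima_y, 0L)
})
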