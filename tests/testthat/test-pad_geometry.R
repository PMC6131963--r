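test_that("default hole layout matches the published duct arrangement", {
  hc <- hole_centres(pad_params())
  expect_equal(nrow(hc), 15L)
  ys <- sort(unique(hc$y_mm))
  xs <- sort(unique(hc$x_mm))
  expect_equal(ys, c(0.25, 0.50, 0.75))           # rows 0.25 mm apart
  expect_equal(diff(xs), rep(0.14, 4))            # 0.14 mm pitch
  expect_equal(max(ys) - min(ys), 0.50)           # outermost-row span
  expect_equal(max(xs) - min(xs), 0.56)           # (n - 1) x pitch
  # brute-force pairwise check: within-row nearest neighbours at one pitch
  for (r in unique(hc$row)) {
    row <- hc[hc$row == r, ]
    d <- as.matrix(dist(row[, c("x_mm", "y_mm")]))
    diag(d) <- Inf
    expect_equal(unname(apply(d, 1, min)), rep(0.14, 5))
  }
})

test_that("hole field is laterally symmetric and centres on the mid-sagittal plane", {
  hc <- hole_centres(pad_params())
  expect_equal(sort(hc$y_mm), sort(1.0 - hc$y_mm))  # mirror-invariant set
  one <- hole_centres(pad_params(n_rows = 1, holes_per_row = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$y_mm, 0.5)
  expect_equal(one$x_mm, 0.75)
})

test_that("invalid geometries are rejected", {
  expect_error(pad_params(hole_pitch_mm = 0.09), "overlap")
  expect_error(pad_params(row_spacing_mm = 0.6), "footprint")
  expect_error(pad_params(length_mm = -1), "positive")
  expect_error(build_design_domain(pad_params(), c(8, 8, 4)), "resolution")
  expect_warning(build_design_domain(pad_params(), c(15, 10, 5)), "coarse")
  expect_error(build_design_domain(pad_params(), c(15, 10, 5), strict = TRUE),
               "coarse")
})

test_that("voxelisation reproduces the analytic void fraction and converges", {
  p <- pad_params(recess = recess_params("none"))
  analytic <- 15 * pi * 0.05^2 / (1.5 * 1.0)  # ~7.85% duct volume
  err <- vapply(list(c(60, 40, 18), c(120, 80, 36), c(240, 160, 72)),
                function(res) {
                  dom <- build_design_domain(p, res)
                  abs((1 - dom$n_solid / prod(res)) - analytic)
                }, numeric(1))
  expect_lt(err[3], 0.5 * err[2])  # halves or better at the finest doubling
  expect_lt(err[3], err[1])
  # no holes, no recess: solid box
  solid <- build_design_domain(
    pad_params(n_rows = 0, holes_per_row = 0,
               recess = recess_params("none")), c(30, 20, 9))
  expect_equal(sum(solid$void), 0L)
  expect_equal(volume_fraction(solid), 1)
})

test_that("voxel sizes follow the box dimensions and rebuilds are bit-identical", {
  dom <- build_design_domain(pad_params(), c(60, 40, 18))
  expect_equal(dom$voxel_mm, c(0.025, 0.025, 0.025))
  dom2 <- build_design_domain(pad_params(), c(60, 40, 18))
  expect_identical(dom, dom2)
  # mid-sagittal mirror symmetry of the void mask
  expect_identical(dom$void, padmech:::mirror_lateral(dom$void))
})

test_that("density starts at 1 on solid and 0 on void voxels", {
  dom <- build_design_domain(pad_params(), pad_small_res)
  expect_true(all(dom$density[dom$void] == 0))
  expect_true(all(dom$density[!dom$void] == 1))
  expect_true(all(dom$density >= 0 & dom$density <= 1))
})

test_that("morphometry fixture carries the published ranges", {
  fx <- morphometry_fixture()
  expect_equal(nrow(fx), 3L)
  col <- fx[fx$structure == "ventral_collagen_layer", ]
  expect_equal(c(col$area_um2_min, col$area_um2_max), c(20000, 65000))
  expect_equal(col$strength_MPa_min, 100)
  sep <- fx[fx$structure == "septum", ]
  expect_equal(c(sep$area_um2_min, sep$area_um2_max), c(6500, 7500))
  mus <- fx[fx$structure == "dorsoventral_muscle_bundles", ]
  expect_equal(c(mus$strength_MPa_min, mus$strength_MPa_max), c(0.2, 0.4))
  expect_true(all(fx$area_um2_min <= fx$area_um2_max))
  expect_true(all(fx$strength_MPa_min <= fx$strength_MPa_max))
  # CSV export round-trips with the documented header
  path <- withr::local_tempfile(fileext = ".csv")
  write_morphometry_csv(path)
  back <- read.csv(path)
  expect_equal(names(back), c("structure", "area_um2_min", "area_um2_max",
                              "strength_MPa_min", "strength_MPa_max"))
  expect_equal(back$area_um2_max, fx$area_um2_max)
  # the bundled synthetic CSV stays in sync with the in-code table
  bundled <- read.csv(system.file("extdata", "morphometry_synthetic.csv",
                                  package = "padmech"))
  expect_equal(bundled, back)
})
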