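# shared fixtures: all built in code at test time

solid_box <- function(res, box) padmech:::solid_domain(res, box)

# toy domain with explicit densities (no geometric validation)
toy_domain <- function(res, box, density = NULL, symmetric = FALSE) {
  d <- if (is.null(density)) array(1, res) else array(density, res)
  padmech:::new_design_domain(res, box / res, d,
                              void = array(FALSE, res),
                              frozen = array(FALSE, res),
                              symmetric = symmetric)
}

# uniform synthetic stress field on a domain (rows xx, yy, zz, yz, xz, xy)
uniform_stress_field <- function(domain, s6) {
  nel <- prod(domain$resolution)
  S <- matrix(s6, 6, nel)
  pr <- padmech:::principal_from_S(S)
  structure(list(S = S, von_mises = padmech:::von_mises_from_S(S),
                 principal = pr$values, directions = pr$directions,
                 solid = as.vector(!domain$void),
                 resolution = domain$resolution,
                 voxel_mm = domain$voxel_mm),
            class = "stress_field")
}

# stress field from an arbitrary tensor-valued function of voxel centres
synthetic_stress_field <- function(domain, tensor_fun) {
  ctr <- padmech:::domain_centres(domain)
  S <- apply(ctr, 1, tensor_fun)
  pr <- padmech:::principal_from_S(S)
  structure(list(S = S, von_mises = padmech:::von_mises_from_S(S),
                 principal = pr$values, directions = pr$directions,
                 solid = as.vector(!domain$void),
                 resolution = domain$resolution,
                 voxel_mm = domain$voxel_mm),
            class = "stress_field")
}

# 3-2-1 minimal rigid-body constraints for a box of dimensions `box`
minimal_constraints <- function(box) {
  list(point_fixed(c(0, 0, 0), dirs = 1:3),
       point_fixed(c(box[1], 0, 0), dirs = 2:3),
       point_fixed(c(0, box[2], 0), dirs = 3))
}

# uniaxial patch load: +/- sigma0 * A on the x end faces
patch_load <- function(box, sigma0) {
  A <- box[2] * box[3]
  load_case(fixed = minimal_constraints(box),
            tractions = list(
              face_traction("distal", force = c(sigma0 * A, 0, 0)),
              face_traction("proximal", force = c(-sigma0 * A, 0, 0))))
}

pad_small_res <- c(30L, 20L, 9L)  # desk resolution used throughout the tests
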