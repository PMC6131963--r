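#' Parametric description of the ventral collagen-layer design space
#'
#' The ventral collagen layer of a tree-frog digital pad is idealised as a
#' rectangular box pierced by vertical cylindrical holes (the mucus ducts)
#' arranged in longitudinal rows, with a scoop of material recessed at the
#' dorsoproximal edge where the proximal epiphysis of the distal phalanx sits.
#' Defaults are the published pad-model dimensions: a 1.5 x 1.0 x 0.45 mm box
#' with three rows of five holes (diameter 0.1 mm, within-row pitch 0.14 mm,
#' row spacing 0.25 mm).
#'
#' Coordinate convention: x runs proximal to distal (proximal face at x = 0),
#' y is lateral with the mid-sagittal plane at y = width/2, z runs ventral to
#' dorsal with the ventral (substrate-facing) face at z = 0. All lengths are
#' in mm; together with forces in N this gives stresses in MPa.
#'
#' @param length_mm longitudinal extent of the pad model (x), mm.
#' @param width_mm lateral extent (y), mm.
#' @param height_mm dorsoventral extent (z), mm.
#' @param hole_diameter_mm diameter of the vertical duct holes, mm.
#' @param hole_pitch_mm centre-to-centre spacing of holes within a row, mm.
#' @param row_spacing_mm centre-to-centre lateral spacing of the rows, mm.
#' @param n_rows number of longitudinal hole rows (0 for none). An odd count
#'   places the middle row on the mid-sagittal plane.
#' @param holes_per_row holes in each row (0 for none).
#' @param hole_field_offset_mm longitudinal shift of the hole-field centre
#'   from the pad mid-length, mm. The default 0 centres the duct field in the
#'   middle third of the pad.
#' @param recess recess descriptor from [recess_params()].
#' @return An object of class `pad_params`.
#' @seealso [hole_centres()], [build_design_domain()]
#' @examples
#' p <- pad_params()
#' nrow(hole_centres(p))  # 15 duct holes
#' @export
pad_params <- function(length_mm = 1.5, width_mm = 1.0, height_mm = 0.45,
                       hole_diameter_mm = 0.1, hole_pitch_mm = 0.14,
                       row_spacing_mm = 0.25, n_rows = 3, holes_per_row = 5,
                       hole_field_offset_mm = 0,
                       recess = recess_params()) {
  lens <- c(length_mm = length_mm, width_mm = width_mm, height_mm = height_mm,
            hole_diameter_mm = hole_diameter_mm, hole_pitch_mm = hole_pitch_mm,
            row_spacing_mm = row_spacing_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all pad dimensions and spacings must be strictly positive")
  if (n_rows < 0 || holes_per_row < 0)
    stop("n_rows and holes_per_row must be non-negative")
  has_holes <- n_rows >= 1 && holes_per_row >= 1
  if (has_holes && holes_per_row > 1 && hole_pitch_mm < hole_diameter_mm)
    stop("holes within a row overlap: hole_pitch_mm (", hole_pitch_mm,
         ") < hole_diameter_mm (", hole_diameter_mm, ")")
  p <- structure(list(
    length_mm = length_mm, width_mm = width_mm, height_mm = height_mm,
    hole_diameter_mm = hole_diameter_mm, hole_pitch_mm = hole_pitch_mm,
    row_spacing_mm = row_spacing_mm, n_rows = as.integer(n_rows),
    holes_per_row = as.integer(holes_per_row),
    hole_field_offset_mm = hole_field_offset_mm,
    recess = recess), class = "pad_params")
  if (has_holes) {
    hc <- hole_centres(p)  # validates that the footprint fits in the box
    r <- hole_diameter_mm / 2
    if (min(hc$x_mm) - r < 0 || max(hc$x_mm) + r > length_mm ||
        min(hc$y_mm) - r < 0 || max(hc$y_mm) + r > width_mm)
      stop("hole-field footprint exceeds the pad box footprint")
  }
  p
}

#' Proximal-epiphysis recess descriptor
#'
#' The recess approximates the space occupied by the neighbouring proximal
#' epiphysis of the distal phalanx: a quarter-cylinder scoop along the
#' dorsoproximal edge of the box (axis lateral, at x = 0, z = height).
#'
#' @param shape `"quarter_cylinder"` or `"none"`.
#' @param radius_mm scoop radius, mm; `NULL` means 0.3 x pad height,
#'   resolved when the domain is built.
#' @return An object of class `recess_params`.
#' @export
recess_params <- function(shape = c("quarter_cylinder", "none"),
                          radius_mm = NULL) {
  shape <- match.arg(shape)
  if (!is.null(radius_mm) && (!is.finite(radius_mm) || radius_mm <= 0))
    stop("recess radius must be strictly positive (or NULL for the default)")
  structure(list(shape = shape, radius_mm = radius_mm),
            class = "recess_params")
}

#' Duct-hole centres of the pad model
#'
#' Hole rows are laid out symmetrically about the mid-sagittal plane
#' (y = width/2); within a row, holes are spaced `hole_pitch_mm` apart and the
#' field is centred longitudinally at mid-length plus
#' `hole_field_offset_mm`.
#'
#' @param params a [pad_params()] object.
#' @return A data.frame with columns `row`, `hole`, `x_mm`, `y_mm`; one row
#'   per hole (`n_rows * holes_per_row` in total).
#' @export
hole_centres <- function(params) {
  stopifnot(inherits(params, "pad_params"))
  n_rows <- params$n_rows; n_holes <- params$holes_per_row
  if (n_rows < 1 || n_holes < 1)
    return(data.frame(row = integer(), hole = integer(),
                      x_mm = numeric(), y_mm = numeric()))
  ys <- params$width_mm / 2 +
    (seq_len(n_rows) - (n_rows + 1) / 2) * params$row_spacing_mm
  xs <- params$length_mm / 2 + params$hole_field_offset_mm +
    (seq_len(n_holes) - (n_holes + 1) / 2) * params$hole_pitch_mm
  out <- expand.grid(hole = seq_len(n_holes), row = seq_len(n_rows))
  data.frame(row = out$row, hole = out$hole,
             x_mm = xs[out$hole], y_mm = ys[out$row])
}

# Internal bare constructor: used by build_design_domain() and by toy
# domains in tests. No geometric validation beyond shape consistency.
new_design_domain <- function(resolution, voxel_mm, density, void, frozen,
                              params = NULL, symmetric = TRUE) {
  resolution <- as.integer(resolution)
  stopifnot(length(resolution) == 3L, length(voxel_mm) == 3L,
            identical(dim(density), resolution),
            identical(dim(void), resolution),
            identical(dim(frozen), resolution))
  structure(list(params = params, resolution = resolution,
                 voxel_mm = as.numeric(voxel_mm),
                 density = density, void = void, frozen = frozen,
                 n_solid = sum(!void), symmetric = isTRUE(symmetric)),
            class = "design_domain")
}

# Solid (non-void) rectangular toy domain; internal, mostly for tests.
solid_domain <- function(resolution, box_mm) {
  resolution <- as.integer(resolution)
  h <- box_mm / resolution
  dims <- resolution
  new_design_domain(resolution, h,
                    density = array(1, dims),
                    void = array(FALSE, dims),
                    frozen = array(FALSE, dims),
                    symmetric = FALSE)
}

#' Build the voxelised design domain of the pad model
#'
#' Voxelises the parametric pad geometry on a regular hexahedral grid. A voxel
#' is void if and only if its centre lies inside a duct-hole cylinder (holes
#' pierce the full height) or inside the proximal-epiphysis recess; all other
#' voxels start at density 1. Void voxels are permanently excluded from the
#' design space.
#'
#' @param params a [pad_params()] object.
#' @param resolution integer vector `(nx, ny, nz)` of voxel counts; at least
#'   `(10, 10, 5)`. Voxel edge lengths are `box dimensions / resolution` per
#'   axis (near-cubic grids such as 30x20x9 or 60x40x18 give uniform edges).
#' @param strict if `TRUE`, refuse resolutions that do not resolve a hole with
#'   at least 2 voxels across its diameter (otherwise a warning is issued).
#' @return An object of class `design_domain` with per-voxel `density`,
#'   `void` and `frozen` arrays.
#' @examples
#' dom <- build_design_domain(pad_params(), c(30, 20, 9))
#' volume_fraction(dom)
#' @export
build_design_domain <- function(params, resolution, strict = FALSE) {
  stopifnot(inherits(params, "pad_params"))
  resolution <- as.integer(resolution)
  if (length(resolution) != 3L || any(resolution < c(10L, 10L, 5L)))
    stop("resolution must be (nx, ny, nz) with nx, ny >= 10 and nz >= 5")
  box <- c(params$length_mm, params$width_mm, params$height_mm)
  h <- box / resolution
  hc <- hole_centres(params)
  if (nrow(hc) > 0) {
    across <- params$hole_diameter_mm / max(h[1], h[2])
    if (across < 2) {
      msg <- sprintf(
        "resolution too coarse: only %.2f voxels across a hole diameter", across)
      if (strict) stop(msg) else warning(msg)
    }
  }
  nx <- resolution[1]; ny <- resolution[2]; nz <- resolution[3]
  xc <- (seq_len(nx) - 0.5) * h[1]
  yc <- (seq_len(ny) - 0.5) * h[2]
  zc <- (seq_len(nz) - 0.5) * h[3]
  void <- array(FALSE, resolution)
  if (nrow(hc) > 0) {
    r2 <- (params$hole_diameter_mm / 2)^2
    in_hole <- matrix(FALSE, nx, ny)
    for (i in seq_len(nrow(hc)))
      in_hole <- in_hole |
        outer((xc - hc$x_mm[i])^2, (yc - hc$y_mm[i])^2, `+`) < r2
    void <- array(rep(in_hole, nz), resolution)
  }
  if (params$recess$shape == "quarter_cylinder") {
    rr <- params$recess$radius_mm
    if (is.null(rr)) rr <- 0.3 * params$height_mm
    # scoop along the lateral edge at (x = 0, z = height)
    in_rec <- outer(xc^2, (params$height_mm - zc)^2, `+`) < rr^2  # nx x nz
    rec3 <- aperm(array(rep(in_rec, ny), c(nx, nz, ny)), c(1, 3, 2))
    void <- void | rec3
  }
  density <- array(1, resolution)
  density[void] <- 0
  new_design_domain(resolution, h, density, void,
                    frozen = array(FALSE, resolution), params = params)
}

#' Volume fraction of a design domain
#'
#' Sum of voxel densities over the initially solid (non-void) voxels, divided
#' by the initial solid voxel count. Equals 1 for a freshly built domain.
#'
#' @param domain a `design_domain`.
#' @return A scalar in \[0, 1\].
#' @export
volume_fraction <- function(domain) {
  stopifnot(inherits(domain, "design_domain"))
  sum(domain$density[!domain$void]) / domain$n_solid
}

#' @export
print.design_domain <- function(x, ...) {
  cat(sprintf("design_domain %dx%dx%d voxels (%.4g x %.4g x %.4g mm each)\n",
              x$resolution[1], x$resolution[2], x$resolution[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  cat(sprintf("  solid voxels: %d (void fraction %.3f); volume fraction %.4f\n",
              x$n_solid, 1 - x$n_solid / prod(x$resolution),
              volume_fraction(x)))
  invisible(x)
}

# Mirror a per-voxel array about the mid-sagittal plane (y = width/2).
mirror_lateral <- function(arr) arr[, dim(arr)[2]:1, , drop = FALSE]

# Voxel centre coordinates (mm), element order = array order (x fastest).
domain_centres <- function(domain) {
  r <- domain$resolution; h <- domain$voxel_mm
  cbind(x = rep((seq_len(r[1]) - 0.5) * h[1], times = r[2] * r[3]),
        y = rep(rep((seq_len(r[2]) - 0.5) * h[2], each = r[1]), times = r[3]),
        z = rep((seq_len(r[3]) - 0.5) * h[3], each = r[1] * r[2]))
}

#' Morphometric cross-sections of the force-transmitting pad structures
#'
#' The bundled morphometry table emulates published cross-sectional-area
#' measurements of the three structures that transmit attachment forces in
#' the digital pad, with the tensile strengths assumed for each tissue:
#' the ventral collagen layer and the collagenous septum at 100 MPa (dense
#' collagen), the dorsoventral smooth-muscle bundles at 0.2-0.4 MPa
#' (skeletal-muscle range).
#'
#' @return A data.frame with one row per structure and columns `structure`,
#'   `area_um2_min`, `area_um2_max`, `strength_MPa_min`, `strength_MPa_max`,
#'   `source_digits`.
#' @seealso [tensile_capacity()], [budget_report()]
#' @export
morphometry_fixture <- function() {
  data.frame(
    structure = c("ventral_collagen_layer", "septum",
                  "dorsoventral_muscle_bundles"),
    area_um2_min = c(20000, 6500, 7000),
    area_um2_max = c(65000, 7500, 14000),
    strength_MPa_min = c(100, 100, 0.2),
    strength_MPa_max = c(100, 100, 0.4),
    source_digits = c("digits F_III, H_II, H_V of frog 3",
                      "digits F_III of frog 1; H_V of frog 3",
                      "digits F_I, H_V of frog 3; F_I of frog 1"),
    stringsAsFactors = FALSE)
}

#' Write the morphometry fixture as CSV
#'
#' @param path output file path.
#' @param fixture table from [morphometry_fixture()].
#' @return The path, invisibly.
#' @export
write_morphometry_csv <- function(path, fixture = morphometry_fixture()) {
  cols <- c("structure", "area_um2_min", "area_um2_max",
            "strength_MPa_min", "strength_MPa_max")
  utils::write.csv(fixture[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
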