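#' Tensile capacity of a structure from area and strength
#'
#' Plain area-times-strength failure bound with the unit conversion
#' 1 um^2 x 1 MPa = 1e-6 N. With the published morphometry this reproduces
#' the printed estimates: the ventral collagen layer withstands 2.0-6.5 N
#' (20,000-65,000 um^2 at 100 MPa), the septum 0.65-0.75 N, and the
#' dorsoventral muscle bundles 2.8-5.6 mN.
#'
#' @param area_um2 cross-sectional area, um^2 (vectorised).
#' @param strength_MPa tensile strength, MPa (vectorised).
#' @return Force at failure, N.
#' @export
tensile_capacity <- function(area_um2, strength_MPa) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stop("area_um2 must be positive")
  if (any(!is.finite(strength_MPa)) || any(strength_MPa <= 0))
    stop("strength_MPa must be positive")
  area_um2 * strength_MPa * 1e-6
}

#' Per-digit share of the body-weight load
#'
#' The reference shear load of the pad model: the body weight distributed
#' uniformly over all digits, `mass_kg * g / n_digits`. The defaults (7 g,
#' 18 digits, g = 9.81 m/s^2) give 3.815 mN.
#'
#' @param body_mass_g body mass, g.
#' @param n_digits number of digits sharing the load.
#' @param g_ms2 gravitational acceleration, m/s^2.
#' @return Force per digit, N.
#' @export
per_digit_load <- function(body_mass_g = 7, n_digits = 18, g_ms2 = 9.81) {
  if (!is.finite(body_mass_g) || body_mass_g < 0)
    stop("body_mass_g must be non-negative")
  if (!is.finite(n_digits) || n_digits < 1)
    stop("n_digits must be at least 1")
  body_mass_g * 1e-3 * g_ms2 / n_digits
}

#' Load budget of the force-transmitting pad structures
#'
#' Compares the tensile capacity of each structure in the morphometry table
#' against reference loads: by default the peak load measured on a single
#' digital pad (1.27 N) and the per-digit body-weight share (3.815 mN). The
#' septum and the dorsoventral muscle bundles jointly transmit normal loads,
#' so their summed capacity is reported as an additional row
#' (`septum_plus_muscle`).
#'
#' @param fixture table from [morphometry_fixture()].
#' @param demands_N named numeric vector of reference loads, N.
#' @return A data.frame (class `load_budget`) with one row per structure and
#'   demand: `structure`, `capacity_N_min`, `capacity_N_max`, `demand`,
#'   `demand_N`, `sufficient` (capacity_N_min >= demand_N).
#' @export
budget_report <- function(fixture = morphometry_fixture(),
                          demands_N = c(pad_peak_load = 1.27,
                                        per_digit_weight = per_digit_load())) {
  stopifnot(is.data.frame(fixture), all(c(
    "structure", "area_um2_min", "area_um2_max",
    "strength_MPa_min", "strength_MPa_max") %in% names(fixture)))
  if (is.null(names(demands_N)))
    names(demands_N) <- paste0("demand_", seq_along(demands_N))
  cap_min <- tensile_capacity(fixture$area_um2_min, fixture$strength_MPa_min)
  cap_max <- tensile_capacity(fixture$area_um2_max, fixture$strength_MPa_max)
  tab <- data.frame(structure = fixture$structure,
                    capacity_N_min = cap_min, capacity_N_max = cap_max,
                    stringsAsFactors = FALSE)
  joint <- c("septum", "dorsoventral_muscle_bundles")
  if (all(joint %in% tab$structure)) {
    jm <- tab$structure %in% joint
    tab <- rbind(tab, data.frame(structure = "septum_plus_muscle",
                                 capacity_N_min = sum(tab$capacity_N_min[jm]),
                                 capacity_N_max = sum(tab$capacity_N_max[jm])))
  }
  out <- merge(tab,
               data.frame(demand = names(demands_N),
                          demand_N = as.numeric(demands_N)),
               by = NULL)
  out$sufficient <- out$capacity_N_min >= out$demand_N
  out <- out[order(match(out$structure, tab$structure), out$demand_N), ]
  rownames(out) <- NULL
  class(out) <- c("load_budget", "data.frame")
  out
}

#' @export
print.load_budget <- function(x, ...) {
  y <- as.data.frame(x)
  y$capacity_N_min <- signif(y$capacity_N_min, 2)
  y$capacity_N_max <- signif(y$capacity_N_max, 2)
  print.data.frame(y, ...)
  invisible(x)
}
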