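#' Thin-film peel configuration
#'
#' Parameters of the Kendall peeling model of an elastic strip adhered to a
#' rigid substrate: peel-front width `b`, film thickness `d`, film modulus
#' `E`, adhesion energy per unit area `R`, and peel angle `theta` between
#' the pulled film and the substrate.
#'
#' @param width_b_mm peel-front width, mm.
#' @param thickness_d_mm film thickness, mm.
#' @param E_MPa film elastic modulus, MPa.
#' @param R_Jm2 adhesion energy per area, J/m^2 (1 J/m^2 = 1e-3 N/mm).
#' @param theta_deg peel angle in degrees, in (0, 180].
#' @return An object of class `peel_config`.
#' @export
peel_config <- function(width_b_mm = 1, thickness_d_mm = 0.1, E_MPa = 20,
                        R_Jm2 = 1, theta_deg = 90) {
  vals <- c(width_b_mm, thickness_d_mm, E_MPa, R_Jm2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("width, thickness, modulus and adhesion energy must be positive")
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0) ||
      any(theta_deg > 180))
    stop("theta_deg must lie in (0, 180]")
  structure(list(width_b_mm = width_b_mm, thickness_d_mm = thickness_d_mm,
                 E_MPa = E_MPa, R_Jm2 = R_Jm2, theta_deg = theta_deg),
            class = "peel_config")
}

#' Kendall peel force
#'
#' Steady-state peel force of a thin elastic film: the positive root of
#' `(F/b)^2 / (2 d E) + (F/b) (1 - cos theta) - R = 0`, balancing elastic
#' strip stretching, the work done against the peel angle, and the adhesion
#' energy. In the inextensible limit (`d E` large) this reduces to
#' `F = b R / (1 - cos theta)`: `b R` at 90 degrees and `b R / 2` at 180
#' degrees. The force decreases monotonically with the peel angle — the
#' mechanical rationale for detaching a pad by pulling at a large angle
#' (> 90 degrees), as dorsodistal septum loading does. At `theta -> 0` the
#' elastic term alone sets the force, which stays finite.
#'
#' @param config a [peel_config()].
#' @param theta_deg optional peel angle(s) overriding `config$theta_deg`
#'   (vectorised).
#' @return Peel force(s), N.
#' @export
kendall_peel_force <- function(config, theta_deg = NULL) {
  stopifnot(inherits(config, "peel_config"))
  th <- if (is.null(theta_deg)) config$theta_deg else theta_deg
  if (any(!is.finite(th)) || any(th <= 0) || any(th > 180))
    stop("theta_deg must lie in (0, 180]")
  b <- config$width_b_mm
  dE <- config$thickness_d_mm * config$E_MPa   # N/mm per unit width strain
  R <- config$R_Jm2 * 1e-3                     # J/m^2 -> N/mm
  tcos <- 1 - cos(th * pi / 180)
  # positive root of P^2/(2 d E) + P (1 - cos theta) - R = 0, P = F/b,
  # in the cancellation-free form (stable in the inextensible limit)
  P <- 2 * R / (tcos + sqrt(tcos^2 + 2 * R / dE))
  b * P
}

#' Solid pad-scale block for the peeling comparison
#'
#' The contact-stress comparison concerns the whole digital pad rather than
#' the thin ventral collagen layer alone: the septum attaches well above the
#' contact interface, and only at pad scale does its pull act through a
#' lever that concentrates tension at the proximal edge. This constructor
#' builds a solid block with the pad's footprint and roughly twice the
#' collagen-layer height (0.9 mm) as the default domain for
#' [septum_loadcase_comparison()].
#'
#' @param resolution voxel counts `(nx, ny, nz)`.
#' @param length_mm,width_mm,height_mm block dimensions, mm.
#' @return A solid `design_domain`.
#' @export
peel_pad_domain <- function(resolution = c(30, 20, 18), length_mm = 1.5,
                            width_mm = 1.0, height_mm = 0.9) {
  dom <- solid_domain(resolution, c(length_mm, width_mm, height_mm))
  dom$symmetric <- TRUE
  dom
}

#' Compare ventral contact stresses: septum loading vs proximal pull
#'
#' A minimal re-specification of the appendix-style comparison behind the
#' septum-peeling hypothesis. Case `septum` pulls dorsodistally on a
#' cross-lateral nodal line on the dorsal side of the pad block at the
#' septum's ventral attachment (default inclination 70 degrees from the
#' ventral plane, i.e. 90 degrees minus the ~20 degree rotation of the
#' septum plane about the transverse pad axis). Case `proximal_pull`
#' applies the same force magnitude as a tensile pull on the proximal end
#' surface. Both keep the ventral face fixed; the normal contact stress is
#' the z-component of the reaction traction on that face, tension positive
#' (pull-off).
#'
#' @param domain a `design_domain`; use [peel_pad_domain()] for the
#'   pad-scale comparison (on the thin collagen-layer slab the local field
#'   under the attachment line dominates the ventral tractions).
#' @param mat a [material()].
#' @param septum_x_mm longitudinal position of the septum's ventral
#'   attachment line, mm; `NULL` places it just distal of the duct field
#'   (or at 70% of the pad length without holes).
#' @param angle_deg inclination of the septum pull above the ventral plane,
#'   degrees (60-80 plausible; default 70).
#' @param force_N pull magnitude for both cases, N.
#' @param penalty_p SIMP exponent (the comparison is usually run on the
#'   non-optimised domain, where it is irrelevant).
#' @param solver linear solver selection, see [solve_displacement()].
#' @return An object of class `contact_stress_report`: per case the nodal
#'   ventral `traction_MPa` grid, `max_tensile` value and location,
#'   `mean_tensile` and `mean_signed` tractions, and the equilibrium check
#'   `normal_balance` (integral of normal traction minus applied normal
#'   force component).
#' @export
septum_loadcase_comparison <- function(domain, mat, septum_x_mm = NULL,
                                       angle_deg = 70, force_N = 3.815e-3,
                                       penalty_p = 3, solver = "auto") {
  stopifnot(inherits(domain, "design_domain"), inherits(mat, "material"))
  res <- domain$resolution; h <- domain$voxel_mm
  L <- res[1] * h[1]
  if (is.null(septum_x_mm)) {
    hc <- if (!is.null(domain$params)) hole_centres(domain$params) else
      data.frame(x_mm = numeric())
    septum_x_mm <- if (nrow(hc) > 0)
      min(L, max(hc$x_mm) + domain$params$hole_diameter_mm / 2 + 0.05 * L)
    else 0.7 * L
  }
  if (septum_x_mm < 0 || septum_x_mm > L)
    stop("septum attachment line lies outside the domain")
  ang <- angle_deg * pi / 180
  cases <- list(
    septum = load_case(
      fixed = list(face_fixed("ventral")),
      tractions = list(line_traction("dorsal", x_mm = septum_x_mm,
                                     force = force_N * c(cos(ang), 0,
                                                         sin(ang))))),
    proximal_pull = load_case(
      fixed = list(face_fixed("ventral")),
      tractions = list(face_traction("proximal",
                                     force = c(-force_N, 0, 0)))))
  reports <- lapply(names(cases), function(nm) {
    lc <- cases[[nm]]
    sol <- solve_displacement(domain, mat, lc, penalty_p = penalty_p,
                              solver = solver)
    ventral_traction_report(domain, sol, lc)
  })
  names(reports) <- names(cases)
  structure(list(cases = reports, force_N = force_N,
                 angle_deg = angle_deg, septum_x_mm = septum_x_mm),
            class = "contact_stress_report")
}

# Ventral normal traction from the fixed-face reactions. The substrate
# holds the pad down wherever it tends to lift, so a downward (-z) nodal
# reaction marks interface tension: t_n = -r_z / A_node, tension positive.
ventral_traction_report <- function(domain, sol, lc) {
  res <- domain$resolution; h <- domain$voxel_mm
  nodes <- matrix(face_nodes(res, "ventral"), res[1] + 1, res[2] + 1)
  rz <- matrix(sol$reactions[3 * as.vector(nodes)], res[1] + 1, res[2] + 1)
  # tributary areas: interior h^2, edges h^2/2, corners h^2/4
  wx <- c(0.5, rep(1, res[1] - 1), 0.5) * h[1]
  wy <- c(0.5, rep(1, res[2] - 1), 0.5) * h[2]
  A <- outer(wx, wy)
  tn <- -rz / A
  xg <- (0:res[1]) * h[1]
  yg <- (0:res[2]) * h[2]
  imax <- which(tn == max(tn), arr.ind = TRUE)[1, ]
  tens <- pmax(tn, 0)
  list(traction_MPa = tn, x_mm = xg, y_mm = yg,
       max_tensile = max(tn),
       max_location = c(x = xg[imax[1]], y = yg[imax[2]]),
       mean_tensile = sum(tens * A) / sum(A),
       mean_signed = sum(tn * A) / sum(A),
       normal_balance = sum(tn * A) - lc$total_force_N[3],
       applied_force_N = lc$total_force_N)
}

#' @export
print.contact_stress_report <- function(x, ...) {
  cat(sprintf(
    "contact_stress_report: |F| = %.4g N, septum line at x = %.3f mm, %g deg\n",
    x$force_N, x$septum_x_mm, x$angle_deg))
  for (nm in names(x$cases)) {
    cs <- x$cases[[nm]]
    cat(sprintf(
      "  %-14s max tensile %.4g MPa at x = %.3f mm; mean tensile %.4g MPa\n",
      nm, cs$max_tensile, cs$max_location["x"], cs$mean_tensile))
  }
  invisible(x)
}
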