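#' Stepped volume-reduction schedule for the topology optimisation
#'
#' The published optimisation removed 60% of the initial model volume in
#' 2.5% steps while maintaining maximum stiffness. Each stage lowers the
#' volume constraint by `step` and iterates the optimality-criteria update
#' until the density field settles.
#'
#' @param total_reduction fraction of the initial solid volume to remove
#'   (default 0.60). Must be an integer multiple of `step`.
#' @param step per-stage volume reduction (default 0.025; 24 stages for the
#'   defaults).
#' @param inner_iters_max optimality-criteria iterations allowed per stage.
#' @param convergence_tol stage convergence threshold on the maximum
#'   per-voxel density change.
#' @param filter_radius_factor sensitivity-filter radius in units of the
#'   mean voxel edge.
#' @param move optimality-criteria move limit per iteration.
#' @param damping optimality-criteria damping exponent.
#' @return An object of class `optimisation_schedule` with `n_stages` and
#'   per-stage `targets` (volume fractions).
#' @export
optimisation_schedule <- function(total_reduction = 0.60, step = 0.025,
                                  inner_iters_max = 30L,
                                  convergence_tol = 0.01,
                                  filter_radius_factor = 1.5,
                                  move = 0.2, damping = 0.5) {
  if (!(step > 0 && step <= total_reduction && total_reduction < 1))
    stop("need 0 < step <= total_reduction < 1")
  n <- total_reduction / step
  if (abs(n - round(n)) > 1e-9)
    stop("total_reduction must be an integer multiple of step")
  n <- as.integer(round(n))
  structure(list(total_reduction = total_reduction, step = step,
                 n_stages = n, targets = 1 - step * seq_len(n),
                 inner_iters_max = as.integer(inner_iters_max),
                 convergence_tol = convergence_tol,
                 filter_radius_factor = filter_radius_factor,
                 move = move, damping = damping),
            class = "optimisation_schedule")
}

#' Compliance and its density sensitivities
#'
#' Compliance `C = f' u` is the work of the applied loads; minimising it at
#' fixed volume maximises stiffness. Under SIMP the self-adjoint sensitivity
#' is `dC/drho_e = -p rho_e^(p-1) (E0 - Emin) u_e' k1 u_e`, non-positive for
#' every design voxel: removing material never lowers compliance.
#'
#' @inheritParams solve_displacement
#' @return A list with `compliance` (N mm), `sensitivity` (per-voxel array,
#'   zero on void voxels), and the `solution`.
#' @export
compliance_and_sensitivity <- function(domain, mat, lc, penalty_p = 3,
                                       solver = "auto", cache = NULL) {
  sol <- solve_displacement(domain, mat, lc, penalty_p = penalty_p,
                            solver = solver, cache = cache)
  cache <- sol$cache
  Ue <- matrix(sol$u[t(cache$edof)], 24)
  energy <- colSums(Ue * (cache$KE1 %*% Ue))  # u_e' k1 u_e per element
  rho <- as.numeric(domain$density)
  dC <- -penalty_p * rho^(penalty_p - 1) * (1 - E_MIN_REL) * mat$E_MPa * energy
  dC[as.vector(domain$void)] <- 0
  list(compliance = sol$compliance,
       sensitivity = array(dC, domain$resolution),
       solution = sol)
}

#' Mesh-independency filter for sensitivities
#'
#' Replaces each design voxel's sensitivity by a convex combination of its
#' neighbours within `radius_mm`, with linearly decaying weights
#' `w = radius - distance`. Void voxels are excluded; weights renormalise at
#' boundaries, so a spatially constant field passes through unchanged. A
#' radius below one voxel edge is the identity.
#'
#' @param sens per-voxel sensitivity array.
#' @param domain a `design_domain`.
#' @param radius_mm filter radius, mm.
#' @return The smoothed sensitivity array (zero on void voxels).
#' @export
filter_sensitivities <- function(sens, domain, radius_mm) {
  stopifnot(identical(dim(sens), domain$resolution))
  h <- domain$voxel_mm
  if (radius_mm < min(h)) return(sens)
  rng <- floor(radius_mm / h)
  mask <- !domain$void
  num <- array(0, dim(sens))
  den <- array(0, dim(sens))
  res <- domain$resolution
  for (di in -rng[1]:rng[1]) for (dj in -rng[2]:rng[2])
    for (dk in -rng[3]:rng[3]) {
      dist <- sqrt((di * h[1])^2 + (dj * h[2])^2 + (dk * h[3])^2)
      w <- radius_mm - dist
      if (w <= 0) next
      sx <- shift_ranges(res[1], di); sy <- shift_ranges(res[2], dj)
      sz <- shift_ranges(res[3], dk)
      m <- mask[sx$from, sy$from, sz$from, drop = FALSE]
      num[sx$to, sy$to, sz$to] <- num[sx$to, sy$to, sz$to, drop = FALSE] +
        w * sens[sx$from, sy$from, sz$from, drop = FALSE] * m
      den[sx$to, sy$to, sz$to] <- den[sx$to, sy$to, sz$to, drop = FALSE] +
        w * m
    }
  out <- array(0, dim(sens))
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# index windows for shifting an array by d along an axis of length n
shift_ranges <- function(n, d) {
  if (d >= 0) list(from = seq_len(n - d), to = seq_len(n - d) + d)
  else list(from = seq_len(n + d) - d, to = seq_len(n + d))
}

#' Optimality-criteria density update
#'
#' Multiplicative optimality-criteria step with move limit and damping,
#' bisecting the volume-constraint Lagrange multiplier until the target
#' volume fraction is met. Void voxels stay empty, frozen voxels stay at
#' density 1, and the updated field is re-symmetrised about the mid-sagittal
#' plane (exactly, by averaging with its mirror image).
#'
#' @param domain a `design_domain`.
#' @param sens per-voxel compliance sensitivities (non-positive on design
#'   voxels), usually filtered.
#' @param volume_target target volume fraction of the initial solid volume.
#' @param move move limit per update.
#' @param damping damping exponent.
#' @param rho_min lower density bound for design voxels.
#' @return The updated `design_domain`.
#' @export
update_densities <- function(domain, sens, volume_target, move = 0.2,
                             damping = 0.5, rho_min = 1e-3) {
  stopifnot(identical(dim(sens), domain$resolution))
  design <- !domain$void & !domain$frozen
  n_solid <- domain$n_solid
  x <- domain$density
  fixed_vol <- sum(x[domain$frozen])
  xd <- as.numeric(x[design])
  B <- pmax(-as.numeric(sens[design]), 1e-30)
  lo <- pmax(rho_min, xd - move)
  hi <- pmin(1, xd + move)
  vol_of <- function(xnew) (fixed_vol + sum(xnew)) / n_solid
  vmin <- vol_of(lo); vmax <- vol_of(hi)
  if (volume_target > vmax + 1e-9 || volume_target < vmin - 1e-9)
    stop(sprintf(paste0("infeasible volume target %.4f: reachable range ",
                        "[%.4f, %.4f] under the move limit and frozen/void ",
                        "structure"), volume_target, vmin, vmax))
  l1 <- 1e-30; l2 <- max(B) * 1e6 + 1
  xnew <- xd
  for (it in 1:200) {
    lm <- sqrt(l1 * l2)
    xnew <- pmin(hi, pmax(lo, xd * (B / lm)^damping))
    v <- vol_of(xnew)
    if (abs(v - volume_target) < 1e-10 || (l2 - l1) / (l1 + l2) < 1e-12) break
    if (v > volume_target) l1 <- lm else l2 <- lm
  }
  x[design] <- xnew
  if (isTRUE(domain$symmetric)) {
    x <- (x + mirror_lateral(x)) / 2
    x[domain$void] <- 0
    x[domain$frozen] <- 1
  }
  out <- domain
  out$density <- x
  out
}

# ---- lateral-symmetry reduction ------------------------------------------
# The pad geometry and shear load are mirror-symmetric about the
# mid-sagittal plane, so the state problem is solved on the lateral half
# with a symmetry condition (uy = 0 on the mirror plane) and expanded back;
# the design update stays on the full domain.

# is the (domain, load case) pair reducible to the lateral half?
symmetry_reducible <- function(domain, lc) {
  res <- domain$resolution
  if (!isTRUE(domain$symmetric) || res[2] %% 2L != 0L) return(FALSE)
  if (!identical(domain$void, mirror_lateral(domain$void))) return(FALSE)
  if (!identical(domain$frozen, mirror_lateral(domain$frozen))) return(FALSE)
  sym_faces <- c("ventral", "dorsal", "proximal", "distal")
  for (fx in lc$fixed)
    if (fx$type != "face_fixed" || !(fx$face %in% sym_faces)) return(FALSE)
  for (tr in lc$tractions) {
    if (!(tr$face %in% sym_faces) || tr$force[2] != 0) return(FALSE)
  }
  TRUE
}

# half design_domain (lateral voxel layers 1..ny/2)
half_domain <- function(domain) {
  res <- domain$resolution
  nyh <- res[2] %/% 2L
  new_design_domain(c(res[1], nyh, res[3]), domain$voxel_mm,
                    density = domain$density[, 1:nyh, , drop = FALSE],
                    void = domain$void[, 1:nyh, , drop = FALSE],
                    frozen = domain$frozen[, 1:nyh, , drop = FALSE],
                    params = NULL, symmetric = FALSE)
}

# half load case: forces halved, symmetry lock on the mirror plane
half_load_case <- function(lc) {
  tr <- lapply(lc$tractions, function(t) { t$force <- t$force / 2; t })
  load_case(fixed = c(lc$fixed, list(face_fixed("lateral_max", dirs = 2))),
            tractions = tr)
}

# DOF index map and sign flips expanding a half solution to the full grid
half_expand_map <- function(res) {
  nyh <- res[2] %/% 2L
  res_h <- c(res[1], nyh, res[3])
  g <- expand.grid(i = 0:res[1], j = 0:res[2], k = 0:res[3])
  jh <- pmin(g$j, res[2] - g$j)
  nh <- node_id(g$i, jh, g$k, res_h)
  idx <- as.vector(t(cbind(3L * nh - 2L, 3L * nh - 1L, 3L * nh)))
  sgn <- as.vector(t(cbind(1, ifelse(g$j > nyh, -1, 1), 1)))
  list(idx = idx, sgn = sgn)
}

#' Stiffness-maximising topology optimisation of the pad model
#'
#' Compliance minimisation by SIMP with optimality-criteria updates,
#' following the stepped schedule: each stage removes `schedule$step` of the
#' initial solid volume and iterates until the density field settles (max
#' density change below `convergence_tol`) or `inner_iters_max` is reached.
#' Sensitivities are smoothed with a linear-decay filter
#' (`filter_radius_factor` voxel edges) and mirrored about the mid-sagittal
#' plane before each update. The ventral voxel layer can be frozen at full
#' density, implementing the prohibition on removing the ventral model
#' surface. The algorithm is deterministic: no randomness is involved.
#'
#' @inheritParams solve_displacement
#' @param schedule an [optimisation_schedule()].
#' @param freeze_ventral freeze the ventral (z = 0) solid voxel layer at
#'   density 1.
#' @param keep_history store the per-stage density snapshots.
#' @param verbose print per-stage progress.
#' @return An object of class `optimisation_result`: final `domain`,
#'   per-stage `history` (data.frame with stage, volume_fraction,
#'   compliance_Nmm, inner_iters, max_change), `compliance_final`
#'   (re-solved on the final densities), optional `density_history`, and
#'   the schedule.
#' @export
optimise_topology <- function(domain, mat, lc, schedule = optimisation_schedule(),
                              penalty_p = 3, solver = "auto",
                              freeze_ventral = TRUE, use_symmetry = TRUE,
                              keep_history = FALSE, verbose = FALSE) {
  stopifnot(inherits(schedule, "optimisation_schedule"))
  dom <- domain
  if (freeze_ventral) {
    frozen <- array(FALSE, dom$resolution)
    frozen[, , 1] <- !dom$void[, , 1]
    dom$frozen <- frozen
  }
  radius <- schedule$filter_radius_factor * mean(dom$voxel_mm)
  use_sym <- isTRUE(use_symmetry) && symmetry_reducible(dom, lc)
  if (use_sym) {
    dom_h <- half_domain(dom)
    lc_h <- half_load_case(lc)
    emap <- half_expand_map(dom$resolution)
    edof_full <- element_dofs(dom$resolution)
    KE1 <- hex_stiffness(dom$voxel_mm[1], dom$voxel_mm[2], dom$voxel_mm[3],
                         E = 1, nu = mat$nu)
    nyh <- dom$resolution[2] %/% 2L
  }
  cache <- NULL
  hist <- vector("list", schedule$n_stages)
  dens_hist <- if (keep_history) vector("list", schedule$n_stages)
  for (s in seq_len(schedule$n_stages)) {
    target <- schedule$targets[s]
    comp <- NA_real_; iters <- 0L; dmax <- NA_real_
    for (j in seq_len(schedule$inner_iters_max)) {
      if (use_sym) {
        dom_h$density <- dom$density[, 1:nyh, , drop = FALSE]
        sol_h <- solve_displacement(dom_h, mat, lc_h, penalty_p = penalty_p,
                                    solver = solver, cache = cache)
        cache <- sol_h$cache
        u_full <- sol_h$u[emap$idx] * emap$sgn
        comp <- 2 * sol_h$compliance
        Ue <- matrix(u_full[t(edof_full)], 24)
        energy <- colSums(Ue * (KE1 %*% Ue))
        rho <- as.numeric(dom$density)
        dC <- -penalty_p * rho^(penalty_p - 1) * (1 - E_MIN_REL) *
          mat$E_MPa * energy
        dC[as.vector(dom$void)] <- 0
        cs <- list(compliance = comp,
                   sensitivity = array(dC, dom$resolution))
      } else {
        cs <- compliance_and_sensitivity(dom, mat, lc, penalty_p = penalty_p,
                                         solver = solver, cache = cache)
        cache <- cs$solution$cache
        comp <- cs$compliance
      }
      sens <- filter_sensitivities(cs$sensitivity, dom, radius)
      if (isTRUE(dom$symmetric))
        sens <- (sens + mirror_lateral(sens)) / 2
      newdom <- update_densities(dom, sens, target,
                                 move = schedule$move,
                                 damping = schedule$damping)
      dmax <- max(abs(newdom$density - dom$density))
      dom <- newdom
      iters <- j
      if (j > 1 && dmax < schedule$convergence_tol) break
    }
    if (dmax >= schedule$convergence_tol && iters >= schedule$inner_iters_max)
      warning(sprintf("stage %d did not fully settle (max change %.3f); %s",
                      s, dmax, "proceeding with the current iterate"))
    hist[[s]] <- data.frame(stage = s, volume_fraction = volume_fraction(dom),
                            compliance_Nmm = comp, inner_iters = iters,
                            max_change = dmax)
    if (keep_history) dens_hist[[s]] <- dom$density
    if (verbose)
      message(sprintf("stage %2d/%d: V = %.4f, C = %.5g N mm (%d iters)",
                      s, schedule$n_stages, volume_fraction(dom), comp, iters))
  }
  final <- solve_displacement(dom, mat, lc, penalty_p = penalty_p,
                              solver = solver,
                              cache = if (use_sym) NULL else cache)
  structure(list(domain = dom, history = do.call(rbind, hist),
                 compliance_final = final$compliance,
                 solution_final = final,
                 density_history = if (keep_history) dens_hist,
                 schedule = schedule),
            class = "optimisation_result")
}

#' @export
print.optimisation_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("optimisation_result: %d stages, volume %.3f -> %.3f\n",
              nrow(h), 1, h$volume_fraction[nrow(h)]))
  cat(sprintf("  compliance %.5g -> %.5g N mm (final re-solve %.5g)\n",
              h$compliance_Nmm[1], h$compliance_Nmm[nrow(h)],
              x$compliance_final))
  invisible(x)
}

# 6-connected component labelling of a logical voxel mask (used to check
# that optimised material forms a connected load path).
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]; i <- rem %% d[1]  # 0-based
      for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                      c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
        if (any(nb < 0) || nb[1] >= d[1] || nb[2] >= d[2] || nb[3] >= d[3])
          next
        lin <- 1L + nb[1] + d[1] * nb[2] + d[1] * d[2] * nb[3]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}
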