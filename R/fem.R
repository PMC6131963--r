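#' Isotropic linear-elastic material
#'
#' @param E_MPa elastic modulus, MPa. The pad model uses 20 MPa, a value in
#'   the published range for collagenous tissue.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param sigma_t_MPa tensile strength, MPa (bookkeeping for strength
#'   budgets; 20 MPa for the pad model, 100 MPa for dense collagen).
#' @return An object of class `material`.
#' @export
material <- function(E_MPa = 20, nu = 0.33, sigma_t_MPa = 20) {
  if (!is.finite(E_MPa) || E_MPa <= 0) stop("E_MPa must be > 0")
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5) stop("nu must be in (0, 0.5)")
  structure(list(E_MPa = E_MPa, nu = nu, sigma_t_MPa = sigma_t_MPa),
            class = "material")
}

# Relative stiffness floor keeping the constrained system nonsingular when
# voxels empty: E(rho) = E0 * (E_MIN_REL + rho^p * (1 - E_MIN_REL)).
E_MIN_REL <- 1e-9

simp_modulus <- function(density, E0, penalty) {
  E0 * (E_MIN_REL + as.numeric(density)^penalty * (1 - E_MIN_REL))
}

#' Element stiffness matrix of a rectangular 8-node hexahedron
#'
#' Trilinear shape functions, full 2x2x2 Gauss integration. Local node order:
#' the four bottom-face nodes counter-clockwise from the (-x,-y) corner, then
#' the four top-face nodes in the same order. DOFs are (ux, uy, uz) per node.
#'
#' @param hx,hy,hz element edge lengths, mm.
#' @param E elastic modulus, MPa.
#' @param nu Poisson's ratio.
#' @return A 24 x 24 symmetric stiffness matrix (N/mm).
#' @export
hex_stiffness <- function(hx, hy, hz, E = 1, nu = 0.33) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- c1 * (1 - 2 * nu) / 2
  g <- 1 / sqrt(3)
  KE <- matrix(0, 24, 24)
  detJ <- hx * hy * hz / 8
  for (a in c(-g, g)) for (b in c(-g, g)) for (cc in c(-g, g)) {
    B <- hex_bmat(a, b, cc, hx, hy, hz)
    KE <- KE + crossprod(B, D %*% B) * detJ
  }
  (KE + t(KE)) / 2
}

# natural coordinates of the 8 local nodes
HEX_XI  <- c(-1, 1, 1, -1, -1, 1, 1, -1)
HEX_ETA <- c(-1, -1, 1, 1, -1, -1, 1, 1)
HEX_ZET <- c(-1, -1, -1, -1, 1, 1, 1, 1)
# grid-index offsets of the local nodes
HEX_OFF <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0),
                 c(0, 0, 1, 1, 0, 0, 1, 1),
                 c(0, 0, 0, 0, 1, 1, 1, 1))

# strain-displacement matrix at natural point (a, b, c); rows are
# (exx, eyy, ezz, gyz, gxz, gxy)
hex_bmat <- function(a, b, cc, hx, hy, hz) {
  dNdx <- HEX_XI  * (1 + HEX_ETA * b) * (1 + HEX_ZET * cc) / 8 * (2 / hx)
  dNdy <- HEX_ETA * (1 + HEX_XI * a) * (1 + HEX_ZET * cc) / 8 * (2 / hy)
  dNdz <- HEX_ZET * (1 + HEX_XI * a) * (1 + HEX_ETA * b) / 8 * (2 / hz)
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, 3); iy <- ix + 1; iz <- ix + 2
  B[1, ix] <- dNdx; B[2, iy] <- dNdy; B[3, iz] <- dNdz
  B[4, iy] <- dNdz; B[4, iz] <- dNdy
  B[5, ix] <- dNdz; B[5, iz] <- dNdx
  B[6, ix] <- dNdy; B[6, iy] <- dNdx
  B
}

# elastic D matrix for E = 1
iso_dmat <- function(nu) {
  c1 <- 1 / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- c1 * (1 - 2 * nu) / 2
  D
}

# ---- mesh bookkeeping -----------------------------------------------------

# 1-based node id for 0-based grid indices
node_id <- function(i, j, k, res) {
  1L + i + (res[1] + 1L) * j + (res[1] + 1L) * (res[2] + 1L) * k
}

# nel x 24 element DOF table; element order = voxel array order (x fastest)
element_dofs <- function(res) {
  nx <- res[1]; ny <- res[2]; nz <- res[3]
  el <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  edof <- matrix(0L, nrow(el), 24)
  for (a in 1:8) {
    n <- node_id(el$i + HEX_OFF[a, 1], el$j + HEX_OFF[a, 2],
                 el$k + HEX_OFF[a, 3], res)
    edof[, 3 * a - 2] <- 3L * n - 2L
    edof[, 3 * a - 1] <- 3L * n - 1L
    edof[, 3 * a]     <- 3L * n
  }
  edof
}

FACES <- c("ventral", "dorsal", "proximal", "distal",
           "lateral_min", "lateral_max")

# local node indices lying on each voxel face
FACE_LOCAL <- list(ventral = c(1, 2, 3, 4), dorsal = c(5, 6, 7, 8),
                   proximal = c(1, 4, 5, 8), distal = c(2, 3, 6, 7),
                   lateral_min = c(1, 2, 5, 6), lateral_max = c(3, 4, 7, 8))

# linear voxel indices of the boundary layer on a face
face_voxels <- function(res, face) {
  nx <- res[1]; ny <- res[2]; nz <- res[3]
  sel <- switch(face,
    ventral     = cbind(rep(1:nx, ny), rep(1:ny, each = nx), 1L),
    dorsal      = cbind(rep(1:nx, ny), rep(1:ny, each = nx), nz),
    proximal    = cbind(1L, rep(1:ny, nz), rep(1:nz, each = ny)),
    distal      = cbind(nx, rep(1:ny, nz), rep(1:nz, each = ny)),
    lateral_min = cbind(rep(1:nx, nz), 1L, rep(1:nz, each = nx)),
    lateral_max = cbind(rep(1:nx, nz), ny, rep(1:nz, each = nx)),
    stop("unknown face: ", face))
  sel[, 1] + nx * (sel[, 2] - 1L) + nx * ny * (sel[, 3] - 1L)
}

# grid node ids on a face of the box
face_nodes <- function(res, face) {
  nx <- res[1]; ny <- res[2]; nz <- res[3]
  g <- switch(face,
    ventral     = expand.grid(i = 0:nx, j = 0:ny, k = 0L),
    dorsal      = expand.grid(i = 0:nx, j = 0:ny, k = nz),
    proximal    = expand.grid(i = 0L, j = 0:ny, k = 0:nz),
    distal      = expand.grid(i = nx, j = 0:ny, k = 0:nz),
    lateral_min = expand.grid(i = 0:nx, j = 0L, k = 0:nz),
    lateral_max = expand.grid(i = 0:nx, j = ny, k = 0:nz),
    stop("unknown face: ", face))
  node_id(g$i, g$j, g$k, res)
}

# ---- load cases -----------------------------------------------------------

#' Boundary-condition and load description
#'
#' A load case combines displacement constraints (`fixed`) with applied
#' tractions. Selectors are built with [face_fixed()], [point_fixed()],
#' [face_traction()] and [line_traction()] and are resolved against a
#' concrete domain at solve time.
#'
#' @param fixed list of fixed-displacement selectors.
#' @param tractions list of traction selectors.
#' @return An object of class `load_case` carrying `total_force_N`, the
#'   component-wise sum of all applied forces.
#' @export
load_case <- function(fixed = list(), tractions = list()) {
  stopifnot(is.list(fixed), is.list(tractions))
  total <- c(0, 0, 0)
  for (tr in tractions) total <- total + tr$force
  fully_fixed <- vapply(fixed, function(fx)
    !is.null(fx$face) && length(fx$dirs) == 3L, logical(1))
  for (tr in tractions) {
    if (!is.null(tr$face) && is.null(tr$x_mm) &&
        tr$face %in% vapply(fixed[fully_fixed],
                            function(fx) fx$face %||% "", character(1)))
      stop("traction applied on a fully fixed face: ", tr$face)
  }
  structure(list(fixed = fixed, tractions = tractions,
                 total_force_N = total), class = "load_case")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_case
#' @param face one of `"ventral"`, `"dorsal"`, `"proximal"`, `"distal"`,
#'   `"lateral_min"`, `"lateral_max"`.
#' @param dirs axis indices to lock (1 = x, 2 = y, 3 = z).
#' @export
face_fixed <- function(face, dirs = 1:3) {
  face <- match.arg(face, FACES)
  list(type = "face_fixed", face = face, dirs = sort(unique(as.integer(dirs))))
}

#' @rdname load_case
#' @param at point (x, y, z) in mm; the nearest grid node is constrained.
#' @export
point_fixed <- function(at, dirs = 1:3) {
  stopifnot(length(at) == 3)
  list(type = "point_fixed", at = as.numeric(at),
       dirs = sort(unique(as.integer(dirs))))
}

#' @rdname load_case
#' @param force total force vector (Fx, Fy, Fz) in N, distributed uniformly
#'   over the solid portion of the face (equal share per solid voxel face,
#'   quarter shares to its four nodes — the consistent nodal load of a
#'   uniform traction on trilinear elements).
#' @export
face_traction <- function(face, force) {
  face <- match.arg(face, FACES)
  stopifnot(length(force) == 3)
  list(type = "face_traction", face = face, force = as.numeric(force))
}

#' @rdname load_case
#' @param x_mm longitudinal position of a cross-lateral nodal line on `face`
#'   (nearest node line is used); the force is split equally over the line
#'   nodes backed by solid material.
#' @export
line_traction <- function(face = "dorsal", x_mm, force) {
  face <- match.arg(face, FACES)
  stopifnot(length(force) == 3, is.finite(x_mm))
  list(type = "line_traction", face = face, x_mm = x_mm,
       force = as.numeric(force))
}

#' Shear load case of the pad model
#'
#' The published loading: the ventral (substrate) face fully fixed and a
#' tensile load applied on the most proximal model surface — a proximally
#' directed axial pull of 3.815 mN by default, the share of a 7 g body
#' weight carried by one of 18 digits.
#'
#' @param force_N pull magnitude in N (applied along -x, the outward normal
#'   of the proximal face).
#' @return A [load_case()].
#' @export
shear_load_case <- function(force_N = 3.815e-3) {
  load_case(fixed = list(face_fixed("ventral")),
            tractions = list(face_traction("proximal",
                                           force = c(-force_N, 0, 0))))
}

# Resolve a load case to fixed DOF indices and a global force vector.
resolve_load_case <- function(domain, lc) {
  stopifnot(inherits(lc, "load_case"))
  res <- domain$resolution
  ndof <- 3L * prod(res + 1L)
  fixed <- integer(0)
  for (fx in lc$fixed) {
    nodes <- if (fx$type == "face_fixed") {
      face_nodes(res, fx$face)
    } else {
      idx <- pmin(pmax(round(fx$at / domain$voxel_mm), 0), res)
      node_id(idx[1], idx[2], idx[3], res)
    }
    fixed <- c(fixed, as.vector(outer(3L * nodes, 3L - fx$dirs, `-`)))
  }
  fixed <- sort(unique(fixed))
  f <- numeric(ndof)
  edof <- element_dofs(res)
  for (tr in lc$tractions) {
    if (tr$type == "face_traction") {
      vox <- face_voxels(res, tr$face)
      vox <- vox[!domain$void[vox]]
      if (length(vox) == 0) stop("no solid voxels on face ", tr$face)
      share <- tr$force / length(vox) / 4
      loc <- FACE_LOCAL[[tr$face]]
      for (a in loc) {
        for (d in 1:3) {
          if (share[d] != 0) {
            ii <- edof[vox, 3 * a - 3 + d]
            agg <- rowsum(rep(share[d], length(ii)), ii)
            f[as.integer(rownames(agg))] <-
              f[as.integer(rownames(agg))] + agg[, 1]
          }
        }
      }
    } else if (tr$type == "line_traction") {
      ix <- round(tr$x_mm / domain$voxel_mm[1])
      if (ix < 0 || ix > res[1]) stop("line_traction x_mm outside the domain")
      k <- if (tr$face == "dorsal") res[3] else 0L
      nodes <- node_id(ix, 0:res[2], k, res)
      # keep nodes backed by solid material in the adjacent voxel layer
      kvox <- if (tr$face == "dorsal") res[3] else 1L
      keep <- vapply(0:res[2], function(j) {
        iv <- intersect(c(ix, ix + 1L), 1:res[1])
        jv <- intersect(c(j, j + 1L), 1:res[2])
        any(!domain$void[iv, jv, kvox])
      }, logical(1))
      nodes <- nodes[keep]
      if (length(nodes) == 0) stop("line_traction attachment line is void")
      for (d in 1:3) {
        f[3L * nodes - 3L + d] <- f[3L * nodes - 3L + d] +
          tr$force[d] / length(nodes)
      }
    } else stop("unknown traction type")
  }
  # bookkeeping invariant: nodal forces sum to the declared total
  got <- c(sum(f[seq(1, ndof, 3)]), sum(f[seq(2, ndof, 3)]),
           sum(f[seq(3, ndof, 3)]))
  if (any(abs(got - lc$total_force_N) >
          1e-12 * max(1e-300, sum(abs(lc$total_force_N)))))
    stop("internal error: nodal forces do not sum to total_force_N")
  list(fixed = fixed, f = f)
}

# ---- assembly and solution ------------------------------------------------

# Persistent per-(domain, load case, material) solver state reused across
# SIMP iterations: DOF tables, triplet index template, symbolic factor,
# previous solution for PCG warm starts.
fem_cache <- function(domain, mat, lc) {
  env <- new.env(parent = emptyenv())
  res <- domain$resolution
  env$res <- res
  env$edof <- element_dofs(res)
  env$KE1 <- hex_stiffness(domain$voxel_mm[1], domain$voxel_mm[2],
                           domain$voxel_mm[3], E = 1, nu = mat$nu)
  rl <- resolve_load_case(domain, lc)
  env$fixed <- rl$fixed
  env$f <- rl$f
  ndof <- 3L * prod(res + 1L)
  env$ndof <- ndof
  free <- setdiff(seq_len(ndof), rl$fixed)
  env$free <- free
  map <- integer(ndof); map[free] <- seq_along(free)
  iK <- map[env$edof[, rep(1:24, each = 24)]]
  jK <- map[env$edof[, rep(1:24, times = 24)]]
  keep <- which(iK > 0 & jK > 0 & iK <= jK)
  env$keep <- keep
  env$iKk <- iK[keep]
  env$jKk <- jK[keep]
  env$KEvec_row <- matrix(as.vector(env$KE1), nrow(env$edof), 576,
                          byrow = TRUE)
  env$ch <- NULL
  env$u_prev <- NULL
  env
}

# reduced (free-DOF) stiffness as symmetric sparse matrix
assemble_reduced <- function(cache, Ev) {
  sK <- as.vector(matrix(Ev, length(Ev), 576) * cache$KEvec_row)[cache$keep]
  Matrix::sparseMatrix(i = cache$iKk, j = cache$jKk, x = sK,
                       dims = c(length(cache$free), length(cache$free)),
                       symmetric = TRUE)
}

#' Assemble the global stiffness operator
#'
#' Sums density-modulated trilinear-hexahedron element matrices over all
#' voxels. Element stiffness follows the SIMP interpolation
#' `E(rho) = E0 * (1e-9 + rho^p * (1 - 1e-9))`; the small floor keeps the
#' constrained system nonsingular when voxels empty.
#'
#' @param domain a `design_domain`.
#' @param mat a [material()].
#' @param penalty_p SIMP penalisation exponent (3 by default).
#' @return The unconstrained symmetric sparse stiffness matrix
#'   (`3 * n_nodes` square, N/mm). Rigid-body translations lie in its null
#'   space; constrain DOFs before solving.
#' @export
assemble_stiffness <- function(domain, mat, penalty_p = 3) {
  stopifnot(inherits(domain, "design_domain"), inherits(mat, "material"))
  if (domain$n_solid == 0) stop("fully void domain: no solid voxel to assemble")
  res <- domain$resolution
  edof <- element_dofs(res)
  KE1 <- hex_stiffness(domain$voxel_mm[1], domain$voxel_mm[2],
                       domain$voxel_mm[3], E = 1, nu = mat$nu)
  Ev <- simp_modulus(domain$density, mat$E_MPa, penalty_p)
  iK <- edof[, rep(1:24, each = 24)]
  jK <- edof[, rep(1:24, times = 24)]
  sK <- matrix(Ev, length(Ev), 576) *
    matrix(as.vector(KE1), length(Ev), 576, byrow = TRUE)
  ndof <- 3L * prod(res + 1L)
  K <- Matrix::sparseMatrix(i = as.vector(iK), j = as.vector(jK),
                            x = as.vector(sK), dims = c(ndof, ndof))
  Matrix::forceSymmetric(K)
}

# K %*% u without forming K: element-level product accumulated globally.
stiffness_apply <- function(cache, Ev, u) {
  Ue <- matrix(u[t(cache$edof)], 24)
  Fe <- (cache$KE1 %*% Ue) * rep(Ev, each = 24)
  idx <- as.vector(t(cache$edof))
  out <- numeric(cache$ndof)
  agg <- rowsum(as.vector(Fe), idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

pcg_solve <- function(K, f, x0 = NULL, tol = 1e-8, max_iter = 30000L) {
  d <- Matrix::diag(K)
  if (any(d <= 0)) stop("singular stiffness operator (zero diagonal); ",
                        "check constraints and densities")
  nf <- sqrt(sum(f * f))
  if (nf == 0) return(list(x = numeric(length(f)), iters = 0L, res = 0))
  x <- if (is.null(x0)) numeric(length(f)) else x0
  r <- f - as.numeric(K %*% x)
  z <- r / d; p <- z; rz <- sum(r * z); it <- 0L
  while (sqrt(sum(r * r)) / nf > tol) {
    if (it >= max_iter)
      stop(sprintf(paste0("PCG did not converge in %d iterations ",
                          "(relative residual %.3e)"),
                   max_iter, sqrt(sum(r * r)) / nf))
    Ap <- as.numeric(K %*% p)
    pAp <- sum(p * Ap)
    if (pAp <= 0)
      stop("operator not positive definite: unconstrained rigid-body modes? ",
           "Fix at least one face or apply minimal point constraints.")
    al <- rz / pAp
    x <- x + al * p
    r <- r - al * Ap
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
    it <- it + 1L
  }
  list(x = x, iters = it, res = sqrt(sum(r * r)) / nf)
}

#' Solve the elastic boundary-value problem on a design domain
#'
#' Small-strain isotropic elasticity on the voxel hexahedral mesh with
#' SIMP-modulated stiffness. Systems are solved either by sparse Cholesky
#' factorisation (small systems) or by Jacobi-preconditioned conjugate
#' gradients (large systems); both are run to a relative residual of at
#' most `tol` (default 1e-8).
#'
#' @param domain a `design_domain`.
#' @param mat a [material()].
#' @param lc a [load_case()].
#' @param penalty_p SIMP penalisation exponent.
#' @param solver `"auto"` (direct up to ~25k free DOFs, PCG above),
#'   `"direct"`, or `"pcg"`.
#' @param tol relative-residual contract for the linear solve.
#' @param cache internal solver state from a previous call on the same mesh
#'   and load case (reused by the optimiser); `NULL` builds it fresh.
#' @return An object of class `fem_solution`: displacement vector `u`
#'   (3 DOFs per node, mm), nodal displacement matrix `U` (n_nodes x 3),
#'   applied forces `f`, `fixed_dofs`, full `reactions` vector (nonzero on
#'   fixed DOFs only, N), `compliance` (N mm), `residual_rel`, `iterations`
#'   and the `solver` used.
#' @export
solve_displacement <- function(domain, mat, lc, penalty_p = 3,
                               solver = c("auto", "direct", "pcg"),
                               tol = 1e-8, cache = NULL) {
  stopifnot(inherits(domain, "design_domain"), inherits(mat, "material"))
  solver <- match.arg(solver)
  if (domain$n_solid == 0) stop("fully void domain: nothing to solve")
  if (is.null(cache)) cache <- fem_cache(domain, mat, lc)
  if (length(cache$fixed) == 0)
    stop("no fixed degrees of freedom: the system has rigid-body modes; ",
         "fix at least one face or apply minimal point constraints")
  Ev <- simp_modulus(domain$density, mat$E_MPa, penalty_p)
  K <- assemble_reduced(cache, Ev)
  ff <- cache$f[cache$free]
  if (solver == "auto")
    solver <- if (length(cache$free) <= 25000L) "direct" else "pcg"
  iters <- NA_integer_
  if (solver == "direct") {
    uf <- tryCatch({
      if (is.null(cache$ch)) {
        cache$ch <- Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
      } else {
        cache$ch <- Matrix::update(cache$ch, K, mult = 0)
      }
      as.numeric(Matrix::solve(cache$ch, ff))
    }, error = function(e) {
      stop("direct factorisation failed (singular system -- unconstrained ",
           "rigid-body modes or fully void structure): ",
           conditionMessage(e))
    })
  } else {
    x0 <- if (!is.null(cache$u_prev)) cache$u_prev[cache$free] else NULL
    sol <- pcg_solve(K, ff, x0 = x0, tol = tol)
    uf <- sol$x
    iters <- sol$iters
  }
  rres <- {
    rr <- as.numeric(K %*% uf) - ff
    nf <- sqrt(sum(ff * ff))
    if (nf > 0) sqrt(sum(rr * rr)) / nf else 0
  }
  if (rres > 10 * tol)
    stop(sprintf("solver failed the residual contract: %.3e > %.1e",
                 rres, tol))
  u <- numeric(cache$ndof)
  u[cache$free] <- uf
  cache$u_prev <- u
  Ku <- stiffness_apply(cache, Ev, u)
  reactions <- numeric(cache$ndof)
  reactions[cache$fixed] <- Ku[cache$fixed] - cache$f[cache$fixed]
  structure(list(u = u,
                 U = matrix(u, ncol = 3, byrow = TRUE),
                 f = cache$f, fixed_dofs = cache$fixed,
                 reactions = reactions,
                 compliance = sum(cache$f * u),
                 residual_rel = rres, iterations = iters,
                 solver = solver, cache = cache),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf(
    "fem_solution: %d DOFs (%d fixed), solver %s, rel. residual %.2e\n",
    length(x$u), length(x$fixed_dofs), x$solver, x$residual_rel))
  cat(sprintf("  compliance %.6g N mm, max |u| %.4g mm\n",
              x$compliance, max(abs(x$u))))
  invisible(x)
}

# ---- stress recovery ------------------------------------------------------

von_mises_from_S <- function(S) {
  # S: 6 x n matrix, rows (xx, yy, zz, yz, xz, xy)
  sqrt(0.5 * ((S[1, ] - S[2, ])^2 + (S[2, ] - S[3, ])^2 +
              (S[3, ] - S[1, ])^2) +
       3 * (S[4, ]^2 + S[5, ]^2 + S[6, ]^2))
}

tensor_from_col <- function(s6) {
  matrix(c(s6[1], s6[6], s6[5],
           s6[6], s6[2], s6[4],
           s6[5], s6[4], s6[3]), 3, 3)
}

principal_from_S <- function(S) {
  n <- ncol(S)
  vals <- matrix(0, 3, n)
  dirs <- array(0, c(3, 3, n))
  for (e in seq_len(n)) {
    eg <- eigen(tensor_from_col(S[, e]), symmetric = TRUE)
    vals[, e] <- eg$values          # descending: sigma1 >= sigma2 >= sigma3
    dirs[, , e] <- eg$vectors       # columns are the principal directions
  }
  list(values = vals, directions = dirs)
}

#' Recover element stresses from a displacement solution
#'
#' Element-centroid stresses from the strain-displacement operator and
#' Hooke's law, with the same SIMP modulus used in the solve. Populates the
#' von Mises scalar (used to locate lightly loaded material) and the ordered
#' principal decomposition (the maximum principal direction field underlies
#' the force-transmission trajectories). Tension is positive; "maximum
#' principal stress" is the algebraically largest eigenvalue.
#'
#' @param domain a `design_domain`.
#' @param mat a [material()].
#' @param solution a `fem_solution` for this domain.
#' @param penalty_p SIMP exponent used in the solve.
#' @return An object of class `stress_field`: `S` (6 x n_elements, MPa, rows
#'   xx, yy, zz, yz, xz, xy), `von_mises`, `principal` (3 x n_elements,
#'   descending), `directions` (3 x 3 x n_elements, orthonormal columns),
#'   and the element `solid` mask.
#' @export
recover_stress <- function(domain, mat, solution, penalty_p = 3) {
  stopifnot(inherits(domain, "design_domain"),
            inherits(solution, "fem_solution"))
  res <- domain$resolution
  edof <- element_dofs(res)
  B0 <- hex_bmat(0, 0, 0, domain$voxel_mm[1], domain$voxel_mm[2],
                 domain$voxel_mm[3])
  D1 <- iso_dmat(mat$nu)
  Ue <- matrix(solution$u[t(edof)], 24)
  Ev <- simp_modulus(domain$density, mat$E_MPa, penalty_p)
  S <- (D1 %*% (B0 %*% Ue)) * rep(Ev, each = 6)
  pr <- principal_from_S(S)
  structure(list(S = S, von_mises = von_mises_from_S(S),
                 principal = pr$values, directions = pr$directions,
                 solid = as.vector(!domain$void), resolution = res,
                 voxel_mm = domain$voxel_mm),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  vm <- x$von_mises[x$solid]
  cat(sprintf("stress_field on %d elements (%d solid)\n",
              ncol(x$S), sum(x$solid)))
  cat(sprintf("  von Mises (solid): mean %.4g, max %.4g MPa\n",
              mean(vm), max(vm)))
  invisible(x)
}
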