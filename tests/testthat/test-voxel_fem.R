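test_that("element stiffness has the translation null space", {
  KE <- hex_stiffness(0.1, 0.1, 0.1, E = 20, nu = 0.33)
  expect_equal(dim(KE), c(24L, 24L))
  expect_equal(KE, t(KE))
  # rigid translations produce no force
  for (d in 1:3) {
    u <- rep(0, 24); u[seq(d, 24, 3)] <- 1
    expect_lt(max(abs(KE %*% u)), 1e-12 * max(abs(KE)))
  }
})

test_that("global assembly equals a brute-force overlap of element matrices", {
  dom <- toy_domain(c(2L, 1L, 1L), c(0.2, 0.1, 0.1))
  mat <- material(E_MPa = 20, nu = 0.33)
  K <- as.matrix(assemble_stiffness(dom, mat))
  # independent dense assembly: loop the two elements by hand
  KE <- hex_stiffness(0.1, 0.1, 0.1, E = 20, nu = 0.33)
  nid <- function(i, j, k) 1 + i + 3 * j + 6 * k  # (nx+1)=3, (ny+1)=2
  off <- cbind(c(0, 1, 1, 0, 0, 1, 1, 0), c(0, 0, 1, 1, 0, 0, 1, 1),
               c(0, 0, 0, 0, 1, 1, 1, 1))
  Kref <- matrix(0, 36, 36)
  for (e in 0:1) {
    gdof <- integer(24)
    for (a in 1:8) {
      n <- nid(e + off[a, 1], off[a, 2], off[a, 3])
      gdof[(3 * a - 2):(3 * a)] <- (3 * n - 2):(3 * n)
    }
    Kref[gdof, gdof] <- Kref[gdof, gdof] + KE
  }
  expect_equal(K, Kref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("SIMP interpolation scales the operator algebraically", {
  res <- c(3L, 2L, 2L); box <- c(0.3, 0.2, 0.2)
  mat <- material(E_MPa = 20)
  K1 <- assemble_stiffness(toy_domain(res, box), mat)
  Kh <- assemble_stiffness(toy_domain(res, box, density = 0.5), mat)
  emin <- 1e-9
  scale <- emin + 0.125 * (1 - emin)
  expect_equal(as.matrix(Kh), scale * as.matrix(K1), tolerance = 1e-12)
})

test_that("constant-stress patch test is exact", {
  box <- c(0.8, 0.6, 0.6)
  dom <- solid_box(c(4L, 3L, 3L), box)
  mat <- material(E_MPa = 20, nu = 0.33)
  s0 <- 2.5
  sol <- solve_displacement(dom, mat, patch_load(box, s0))
  st <- recover_stress(dom, mat, sol)
  expect_lt(max(abs(st$S[1, ] - s0)), 1e-9 * s0)
  expect_lt(max(abs(st$S[2:6, ])), 1e-9 * s0)
  expect_lt(max(abs(st$von_mises - s0)), 1e-8 * s0)
  expect_lt(max(abs(st$principal[1, ] - s0)), 1e-8 * s0)
  # principal direction of sigma1 is +/- x everywhere
  expect_lt(max(abs(abs(st$directions[1, 1, ]) - 1)), 1e-8)
})

test_that("sparse solution matches a dense brute-force solve on tiny domains", {
  for (res in list(c(2L, 2L, 2L), c(3L, 3L, 3L))) {
    box <- res * 0.1
    dom <- solid_box(res, box)
    mat <- material(E_MPa = 20, nu = 0.33)
    lc <- load_case(fixed = list(face_fixed("ventral")),
                    tractions = list(face_traction("dorsal",
                                                   force = c(1e-3, 5e-4, 2e-3))))
    rl <- padmech:::resolve_load_case(dom, lc)
    K <- as.matrix(assemble_stiffness(dom, mat))
    free <- setdiff(seq_len(nrow(K)), rl$fixed)
    u_ref <- numeric(nrow(K))
    u_ref[free] <- solve(K[free, free], rl$f[free])
    for (solver in c("direct", "pcg")) {
      sol <- solve_displacement(dom, mat, lc, solver = solver, tol = 1e-12)
      expect_lt(max(abs(sol$u - u_ref)) / max(abs(u_ref)), 1e-10)
    }
  }
})

test_that("reactions balance the applied load on the pad model", {
  dom <- build_design_domain(pad_params(), pad_small_res)
  mat <- material()
  sol <- solve_displacement(dom, mat, shear_load_case())
  R <- colSums(matrix(sol$reactions, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(R - c(3.815e-3, 0, 0))), 1e-6 * 3.815e-3)
  expect_lt(sol$residual_rel, 1e-8)
  # fixed DOFs carry zero displacement
  expect_equal(max(abs(sol$u[sol$fixed_dofs])), 0)
})

test_that("displacements scale linearly with modulus and load", {
  dom <- solid_box(c(4L, 3L, 3L), c(0.4, 0.3, 0.3))
  lc <- load_case(fixed = list(face_fixed("ventral")),
                  tractions = list(face_traction("distal",
                                                 force = c(1e-3, 0, 2e-3))))
  u1 <- solve_displacement(dom, material(E_MPa = 20), lc)$u
  u2 <- solve_displacement(dom, material(E_MPa = 40), lc)$u
  expect_equal(u2, u1 / 2, tolerance = 1e-12)
})

test_that("degenerate systems fail with explanatory errors", {
  dom <- solid_box(c(3L, 3L, 3L), c(0.3, 0.3, 0.3))
  mat <- material()
  free_lc <- load_case(tractions = list(face_traction("distal",
                                                      force = c(1e-3, 0, 0))))
  expect_error(solve_displacement(dom, mat, free_lc), "rigid-body")
  void_dom <- dom
  void_dom$void[] <- TRUE
  void_dom$density[] <- 0
  void_dom$n_solid <- 0L
  expect_error(solve_displacement(void_dom, mat, shear_load_case()),
               "void")
  expect_error(assemble_stiffness(void_dom, mat), "void")
  expect_error(load_case(fixed = list(face_fixed("ventral")),
                         tractions = list(face_traction("ventral",
                                                        force = c(0, 0, 1)))),
               "fully fixed")
})

test_that("stress invariants behave under constructed displacement fields", {
  res <- c(3L, 3L, 3L); box <- c(0.3, 0.3, 0.3)
  dom <- solid_box(res, box)
  mat <- material(E_MPa = 20, nu = 0.3)
  g <- expand.grid(i = 0:res[1], j = 0:res[2], k = 0:res[3])
  coords <- cbind(g$i, g$j, g$k) * matrix(box / res, nrow(g), 3, byrow = TRUE)
  fake_sol <- function(U) structure(list(u = as.vector(t(U))),
                                    class = "fem_solution")
  # uniform volumetric strain: zero von Mises everywhere
  eps <- 1e-3
  st <- recover_stress(dom, mat, fake_sol(eps * coords))
  expect_lt(max(abs(st$von_mises)), 1e-12)
  # pure shear gamma_xz: von Mises = sqrt(3) * tau
  gam <- 1e-3
  U <- cbind(gam * coords[, 3], 0, 0)
  st2 <- recover_stress(dom, mat, fake_sol(U))
  tau <- mat$E_MPa / (2 * (1 + mat$nu)) * gam
  expect_equal(unname(st2$von_mises), rep(sqrt(3) * tau, prod(res)),
               tolerance = 1e-10)
})

test_that("von Mises and sorted principal values are frame invariant", {
  set.seed(42)
  for (trial in 1:20) {
    A <- matrix(rnorm(9), 3)
    S <- A + t(A)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    Sr <- Q %*% S %*% t(Q)
    to6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[2, 3], M[1, 3], M[1, 2])
    S6 <- cbind(to6(S)); Sr6 <- cbind(to6(Sr))
    expect_equal(padmech:::von_mises_from_S(S6),
                 padmech:::von_mises_from_S(Sr6), tolerance = 1e-8)
    p1 <- padmech:::principal_from_S(S6)
    p2 <- padmech:::principal_from_S(Sr6)
    expect_equal(p1$values, p2$values, tolerance = 1e-8)
    expect_true(all(diff(p1$values[, 1]) <= 1e-12))  # descending order
    V <- p1$directions[, , 1]
    expect_equal(crossprod(V), diag(3), tolerance = 1e-8)
  }
})

test_that("slender-cantilever tip displacement is mesh converged", {
  mat <- material(E_MPa = 20)
  tip <- function(res) {
    dom <- solid_box(res, c(1.6, 0.4, 0.4))
    lc <- load_case(fixed = list(face_fixed("proximal")),
                    tractions = list(face_traction("distal",
                                                   force = c(0, 0, -1e-4))))
    min(solve_displacement(dom, mat, lc)$U[, 3])
  }
  t1 <- tip(c(24L, 6L, 6L))
  t2 <- tip(c(48L, 12L, 12L))
  expect_lt(abs(t2 - t1) / abs(t2), 0.02)
})
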