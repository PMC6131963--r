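#' Trace maximum-principal-stress trajectories
#'
#' Integral curves of the unit eigenvector field of the largest principal
#' stress, the paths along which tensile force is transmitted through the
#' pad. The stress tensor is interpolated trilinearly between element
#' centroids and eigen-decomposed at each sample point; integration is
#' fixed-step RK4 with sign continuity (the eigenvector is flipped whenever
#' it reverses relative to the previous step, resolving the inherent sign
#' ambiguity of eigenvectors). A trajectory terminates when it leaves the
#' domain box, enters void or low-density material, or exhausts
#' `max_steps`.
#'
#' @param stress a `stress_field` from [recover_stress()].
#' @param domain the `design_domain` the field was computed on.
#' @param seeds matrix of seed points (n x 3, mm); `NULL` places a regular
#'   `seed_grid` x `seed_grid` grid on the loaded proximal face.
#' @param step_mm integration step (default half the smallest voxel edge).
#' @param seed_grid seeds per axis for the default proximal-face grid.
#' @param max_steps integration step limit.
#' @param density_threshold material below this density counts as empty.
#' @return A list of trajectories (class `trajectory_set`); each has
#'   `points` (m x 3), `seed`, and a `termination` reason (`"left_domain"`,
#'   `"entered_void"` or `"max_steps"`). Seeds placed in void are skipped
#'   with a warning.
#' @export
trace_trajectories <- function(stress, domain, seeds = NULL, step_mm = NULL,
                               seed_grid = 5, max_steps = 2000L,
                               density_threshold = 0.5) {
  stopifnot(inherits(stress, "stress_field"),
            inherits(domain, "design_domain"))
  res <- domain$resolution; h <- domain$voxel_mm
  box <- res * h
  if (is.null(step_mm)) step_mm <- min(h) / 2
  if (is.null(seeds)) {
    ys <- box[2] * (seq_len(seed_grid) - 0.5) / seed_grid
    zs <- box[3] * (seq_len(seed_grid) - 0.5) / seed_grid
    seeds <- cbind(x = h[1] / 2, expand.grid(y = ys, z = zs))
    seeds <- as.matrix(seeds)
  }
  interp <- make_tensor_interp(stress, domain)
  solid_at <- function(p) {
    iv <- pmin(pmax(ceiling(p / h), 1), res)
    !domain$void[iv[1], iv[2], iv[3]] &&
      domain$density[iv[1], iv[2], iv[3]] >= density_threshold
  }
  inside <- function(p) all(p >= 0) && all(p <= box)
  dir_at <- function(p, prev) {
    S <- interp(p)
    eg <- eigen(S, symmetric = TRUE)
    v <- eg$vectors[, 1]
    if (sum(v * prev) < 0) v <- -v
    v
  }
  out <- list()
  skipped <- 0L
  for (s in seq_len(nrow(seeds))) {
    p <- as.numeric(seeds[s, ])
    if (!inside(p) || !solid_at(p)) { skipped <- skipped + 1L; next }
    # initial orientation: into the domain (+x for proximal-face seeds)
    v0 <- {
      S <- interp(p)
      v <- eigen(S, symmetric = TRUE)$vectors[, 1]
      if (v[1] < 0) -v else v
    }
    pts <- matrix(p, 1, 3)
    prev <- v0
    term <- "max_steps"
    for (it in seq_len(max_steps)) {
      k1 <- dir_at(p, prev)
      k2 <- dir_at(clamp_box(p + step_mm / 2 * k1, box), prev)
      k3 <- dir_at(clamp_box(p + step_mm / 2 * k2, box), prev)
      k4 <- dir_at(clamp_box(p + step_mm * k3, box), prev)
      dstep <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
      nrm <- sqrt(sum(dstep^2))
      if (nrm < 1e-12) { term <- "entered_void"; break }
      pnew <- p + step_mm * dstep / nrm
      if (!inside(pnew)) { term <- "left_domain"; pts <- rbind(pts, clamp_box(pnew, box)); break }
      if (!solid_at(pnew)) { term <- "entered_void"; break }
      pts <- rbind(pts, pnew)
      prev <- dir_at(pnew, prev)
      p <- pnew
    }
    out[[length(out) + 1L]] <- list(points = pts,
                                    seed = as.numeric(seeds[s, ]),
                                    termination = term)
  }
  if (skipped > 0)
    warning(skipped, " seed(s) in void or outside the domain were skipped")
  structure(out, class = "trajectory_set")
}

clamp_box <- function(p, box) pmin(pmax(p, 0), box)

# trilinear interpolation of the 6 stress components between cell centres;
# returns a function p -> 3x3 symmetric tensor
make_tensor_interp <- function(stress, domain) {
  res <- domain$resolution; h <- domain$voxel_mm
  S <- stress$S
  function(p) {
    # continuous cell-centre coordinates
    t3 <- p / h - 0.5
    i0 <- pmin(pmax(floor(t3), 0), res - 2)  # 0-based lower cell, clamped
    w <- pmin(pmax(t3 - i0, 0), 1)
    acc <- numeric(6)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx == 1) w[1] else 1 - w[1]) *
            (if (dy == 1) w[2] else 1 - w[2]) *
            (if (dz == 1) w[3] else 1 - w[3])
      if (wt == 0) next
      lin <- 1L + (i0[1] + dx) + res[1] * (i0[2] + dy) +
        res[1] * res[2] * (i0[3] + dz)
      acc <- acc + wt * S[, lin]
    }
    tensor_from_col(acc)
  }
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d trajectories\n", length(x)))
  if (length(x) > 0) {
    tr <- table(vapply(x, `[[`, character(1), "termination"))
    cat("  terminations:",
        paste(names(tr), tr, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export trajectories as a CSV table
#'
#' @param trajectories a `trajectory_set`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  rows <- lapply(seq_along(trajectories), function(i) {
    p <- trajectories[[i]]$points
    data.frame(trajectory_id = i, x = p[, 1], y = p[, 2], z = p[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Von Mises stress contrasts of the holed pad model
#'
#' Quantifies the two published stress patterns of the shear-loaded model:
#' material between the longitudinal hole rows carries more load than the
#' webs between holes within a row, and stress decays from proximal to
#' distal. Web voxels are classified within the duct band (the longitudinal
#' interval spanned by the hole field): intra-row webs lie within half a
#' hole pitch laterally of a row ordinate and between consecutive holes of
#' that row; inter-row webs lie laterally between adjacent row ordinates,
#' beyond half a pitch from either. Both exclude hole cylinders and span the
#' full height.
#'
#' @param stress a `stress_field`.
#' @param domain the pad `design_domain` (must carry `pad_params`).
#' @return A list (class `vm_contrast_report`): `inter_row_mean`,
#'   `intra_row_mean`, `ratio` (inter/intra; `NA` with `no_holes = TRUE`
#'   when the layout has no holes), voxel counts, and
#'   `quartile_means` — mean von Mises per longitudinal quarter, proximal
#'   to distal.
#' @export
von_mises_contrasts <- function(stress, domain) {
  stopifnot(inherits(stress, "stress_field"),
            inherits(domain, "design_domain"))
  vm <- stress$von_mises
  solid <- !as.vector(domain$void)
  ctr <- domain_centres(domain)
  L <- domain$resolution[1] * domain$voxel_mm[1]
  q <- findInterval(ctr[, "x"], L * c(0.25, 0.5, 0.75)) + 1
  quart <- vapply(1:4, function(k) mean(vm[solid & q == k]), numeric(1))
  params <- domain$params
  hc <- if (!is.null(params)) hole_centres(params) else
    data.frame(x_mm = numeric(), y_mm = numeric())
  if (nrow(hc) == 0) {
    return(structure(list(inter_row_mean = NA_real_,
                          intra_row_mean = NA_real_, ratio = NA_real_,
                          n_inter = 0L, n_intra = 0L, no_holes = TRUE,
                          quartile_means = quart),
                     class = "vm_contrast_report"))
  }
  r <- params$hole_diameter_mm / 2
  band <- c(min(hc$x_mm) - r, max(hc$x_mm) + r)
  rows_y <- sort(unique(hc$y_mm))
  half_pitch <- params$hole_pitch_mm / 2
  in_band <- ctr[, "x"] >= band[1] & ctr[, "x"] <= band[2]
  dist_row <- do.call(pmin, lapply(rows_y, function(y) abs(ctr[, "y"] - y)))
  between_rows <- if (length(rows_y) > 1)
    ctr[, "y"] > min(rows_y) & ctr[, "y"] < max(rows_y) else
    rep(FALSE, nrow(ctr))
  # intra-row: near a row ordinate, longitudinally between consecutive holes
  xs <- sort(unique(hc$x_mm))
  between_holes <- ctr[, "x"] > min(xs) & ctr[, "x"] < max(xs)
  intra <- solid & in_band & dist_row <= half_pitch & between_holes
  inter <- solid & in_band & between_rows & dist_row > half_pitch
  inter_mean <- mean(vm[inter])
  intra_mean <- mean(vm[intra])
  structure(list(inter_row_mean = inter_mean, intra_row_mean = intra_mean,
                 ratio = inter_mean / intra_mean,
                 n_inter = sum(inter), n_intra = sum(intra),
                 no_holes = FALSE, quartile_means = quart),
            class = "vm_contrast_report")
}

#' @export
print.vm_contrast_report <- function(x, ...) {
  if (isTRUE(x$no_holes)) {
    cat("vm_contrast_report: layout without holes;",
        "inter/intra ratio undefined\n")
  } else {
    cat(sprintf(
      "vm_contrast_report: inter-row %.4g / intra-row %.4g MPa (ratio %.3f)\n",
      x$inter_row_mean, x$intra_row_mean, x$ratio))
  }
  cat("  proximal->distal quartile means (MPa):",
      paste(signif(x$quartile_means, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Lateral density profile of the duct region
#'
#' Averages the optimised density over the duct band (the longitudinal
#' interval spanned by the hole field, full height) for each lateral voxel
#' ordinate, and locates the local minima (troughs, expected in line with
#' the hole rows) and maxima (the longitudinal ridges between and outside
#' the rows). Runs of equal values are treated as one plateau; a constant
#' profile has no internal extrema.
#'
#' @param domain a (typically optimised) pad `design_domain`.
#' @param duct_band longitudinal interval `c(x_min, x_max)` in mm; default
#'   is the hole-field span (the whole length if there are no holes).
#' @return A list (class `ridge_profile`): `y_mm`, `profile`, `minima_y`,
#'   `maxima_y`, and the hole-row ordinates `row_y`.
#' @export
ridge_profile <- function(domain, duct_band = NULL) {
  stopifnot(inherits(domain, "design_domain"))
  res <- domain$resolution; h <- domain$voxel_mm
  params <- domain$params
  hc <- if (!is.null(params)) hole_centres(params) else
    data.frame(x_mm = numeric(), y_mm = numeric())
  if (is.null(duct_band)) {
    duct_band <- if (nrow(hc) > 0) {
      r <- params$hole_diameter_mm / 2
      c(min(hc$x_mm) - r, max(hc$x_mm) + r)
    } else c(0, res[1] * h[1])
  }
  xc <- (seq_len(res[1]) - 0.5) * h[1]
  sel <- xc >= duct_band[1] & xc <= duct_band[2]
  if (!any(sel)) stop("duct band contains no voxel column")
  prof <- apply(domain$density[sel, , , drop = FALSE], 2, mean)
  y_mm <- (seq_len(res[2]) - 0.5) * h[2]
  ext <- profile_extrema(prof)
  structure(list(y_mm = y_mm, profile = prof,
                 minima_y = y_mm[ext$minima], maxima_y = y_mm[ext$maxima],
                 minima_idx = ext$minima, maxima_idx = ext$maxima,
                 row_y = sort(unique(hc$y_mm)), duct_band = duct_band),
            class = "ridge_profile")
}

# interior local extrema of a 1-D profile with plateau handling; returns
# centre indices of extremal runs
profile_extrema <- function(p) {
  r <- rle(p)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  minima <- integer(0); maxima <- integer(0)
  if (length(v) >= 3) {
    for (m in 2:(length(v) - 1)) {
      centre <- as.integer(round((starts[m] + ends[m]) / 2))
      if (v[m] < v[m - 1] && v[m] < v[m + 1]) minima <- c(minima, centre)
      if (v[m] > v[m - 1] && v[m] > v[m + 1]) maxima <- c(maxima, centre)
    }
  }
  list(minima = minima, maxima = maxima)
}

#' @export
print.ridge_profile <- function(x, ...) {
  cat(sprintf("ridge_profile over x in [%.3f, %.3f] mm\n",
              x$duct_band[1], x$duct_band[2]))
  cat("  troughs at y =", paste(signif(x$minima_y, 4), collapse = ", "),
      "mm\n")
  cat("  ridges at y =", paste(signif(x$maxima_y, 4), collapse = ", "),
      "mm\n")
  invisible(x)
}
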