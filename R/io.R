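#' Write voxel fields as a legacy ASCII VTK structured-points file
#'
#' Cell data live on the voxel grid, point data on the node grid, so the
#' files load directly in standard VTK viewers for inspection of density,
#' stress and displacement fields.
#'
#' @param domain a `design_domain`.
#' @param path output `.vtk` file.
#' @param cell_data named list of per-voxel arrays/vectors (length
#'   `prod(resolution)`), scalars or 3-column matrices.
#' @param point_data named list of per-node vectors or `n_nodes x 3`
#'   matrices (e.g. displacements).
#' @return The path, invisibly.
#' @export
write_vtk_fields <- function(domain, path, cell_data = list(),
                             point_data = list()) {
  res <- domain$resolution; h <- domain$voxel_mm
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("padmech voxel fields")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS %d %d %d", res[1] + 1, res[2] + 1, res[3] + 1)
  wl("ORIGIN 0 0 0")
  wl("SPACING %.9g %.9g %.9g", h[1], h[2], h[3])
  emit <- function(data, n, kind) {
    wl("%s %d", kind, n)
    first <- TRUE
    for (nm in names(data)) {
      v <- data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        wl("VECTORS %s double", nm)
        writeLines(paste(format(v[, 1], digits = 9),
                         format(v[, 2], digits = 9),
                         format(v[, 3], digits = 9)), con)
      } else {
        v <- as.numeric(v)
        stopifnot(length(v) == n)
        wl("SCALARS %s double 1", nm)
        wl("LOOKUP_TABLE default")
        writeLines(format(v, digits = 12), con)
      }
      first <- FALSE
    }
  }
  if (length(cell_data) > 0) emit(cell_data, prod(res), "CELL_DATA")
  if (length(point_data) > 0) emit(point_data, prod(res + 1L), "POINT_DATA")
  invisible(path)
}

#' Read back a scalar cell array from a structured-points VTK file
#'
#' Companion reader for [write_vtk_fields()] output (round-trip checks and
#' lightweight post-processing without a VTK installation).
#'
#' @param path a `.vtk` file written by [write_vtk_fields()].
#' @param name scalar array name.
#' @return Numeric vector of cell values.
#' @export
read_vtk_cell_array <- function(path, name) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
    lines[grep("^DIMENSIONS", lines)])), "\\s+")[[1]])
  ncell <- prod(dims - 1L)
  at <- grep(paste0("^SCALARS ", name, " "), lines)
  if (length(at) == 0) stop("array not found: ", name)
  start <- at[1] + 2  # skip LOOKUP_TABLE line
  as.numeric(lines[start:(start + ncell - 1)])
}

#' Blocky surface mesh of thresholded densities
#'
#' Exposed boundary faces of voxels with density above `threshold`, each
#' split into two triangles — a faithful voxel-resolution surface of the
#' optimised shape for export.
#'
#' @param domain a `design_domain`.
#' @param threshold density binarisation threshold (default 0.5).
#' @return List with `vertices` (n x 3 mm) and `triangles` (m x 3 vertex
#'   indices, outward-oriented).
#' @export
threshold_surface <- function(domain, threshold = 0.5) {
  res <- domain$resolution; h <- domain$voxel_mm
  solid <- domain$density > threshold & !domain$void
  pad <- array(FALSE, res + 2L)
  pad[2:(res[1] + 1), 2:(res[2] + 1), 2:(res[3] + 1)] <- solid
  verts <- list(); tris <- list(); nv <- 0L
  corner <- function(i, j, k) c(i, j, k) * h  # grid corner (0-based)
  dirs <- list(
    list(d = c(-1, 0, 0), quad = rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1))),
    list(d = c(1, 0, 0),  quad = rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 1), c(1, 1, 0))),
    list(d = c(0, -1, 0), quad = rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 0, 0))),
    list(d = c(0, 1, 0),  quad = rbind(c(0, 1, 0), c(1, 1, 0), c(1, 1, 1), c(0, 1, 1))),
    list(d = c(0, 0, -1), quad = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))),
    list(d = c(0, 0, 1),  quad = rbind(c(0, 0, 1), c(0, 1, 1), c(1, 1, 1), c(1, 0, 1))))
  idx <- which(solid, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v0 <- idx[r, ] - 1L  # 0-based voxel corner
    for (dd in dirs) {
      nb <- idx[r, ] + dd$d + 1L  # into padded array
      if (pad[nb[1], nb[2], nb[3]]) next
      q <- sweep(dd$quad, 2, as.numeric(v0), `+`)
      pts <- q * matrix(h, 4, 3, byrow = TRUE)
      verts[[length(verts) + 1L]] <- pts
      tris[[length(tris) + 1L]] <- rbind(nv + c(1L, 2L, 3L),
                                         nv + c(1L, 3L, 4L))
      nv <- nv + 4L
    }
  }
  list(vertices = do.call(rbind, verts), triangles = do.call(rbind, tris))
}

#' Write a surface mesh as ASCII STL
#'
#' @param surface list with `vertices` and `triangles` as returned by
#'   [threshold_surface()].
#' @param path output `.stl` file.
#' @param name solid name recorded in the file.
#' @return The path, invisibly.
#' @export
write_stl <- function(surface, path, name = "padmech") {
  v <- surface$vertices; tr <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(tr))) {
    p1 <- v[tr[i, 1], ]; p2 <- v[tr[i, 2], ]; p3 <- v[tr[i, 3], ]
    nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
             (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
             (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", p1[1], p1[2], p1[3]),
                 sprintf("      vertex %g %g %g", p2[1], p2[2], p2[3]),
                 sprintf("      vertex %g %g %g", p3[1], p3[2], p3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Pipeline configuration
#'
#' One plain-data object drives the whole pipeline; it serialises losslessly
#' to YAML via [write_pipeline_config()] / [read_pipeline_config()]. Every
#' published model constant appears here rather than hidden in code paths.
#'
#' @param geometry a [pad_params()] object.
#' @param material_ a [material()] object.
#' @param force_N proximal shear pull, N.
#' @param resolution voxel counts `(nx, ny, nz)`.
#' @param schedule an [optimisation_schedule()].
#' @param analyses character vector of optional stages to run, any of
#'   `"optimise"`, `"trajectories"`, `"contrasts"`, `"ridge"`, `"budget"`,
#'   `"peel"`.
#' @param penalty_p SIMP exponent.
#' @param kendall a [peel_config()] for the peel-force sweep.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = pad_params(),
                            material_ = material(),
                            force_N = 3.815e-3,
                            resolution = c(30, 20, 9),
                            schedule = optimisation_schedule(),
                            analyses = c("optimise", "trajectories",
                                         "contrasts", "ridge", "budget",
                                         "peel"),
                            penalty_p = 3,
                            kendall = peel_config()) {
  if (length(analyses) > 0)
    analyses <- match.arg(analyses, c("optimise", "trajectories",
                                      "contrasts", "ridge", "budget",
                                      "peel"), several.ok = TRUE)
  structure(list(geometry = geometry, material = material_,
                 force_N = force_N, resolution = as.integer(resolution),
                 schedule = schedule, analyses = analyses,
                 penalty_p = penalty_p, kendall = kendall),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- rapply(unclass(config), identity, how = "list")
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  rec <- y$geometry$recess
  pipeline_config(
    geometry = pad_params(
      length_mm = y$geometry$length_mm, width_mm = y$geometry$width_mm,
      height_mm = y$geometry$height_mm,
      hole_diameter_mm = y$geometry$hole_diameter_mm,
      hole_pitch_mm = y$geometry$hole_pitch_mm,
      row_spacing_mm = y$geometry$row_spacing_mm,
      n_rows = y$geometry$n_rows, holes_per_row = y$geometry$holes_per_row,
      hole_field_offset_mm = y$geometry$hole_field_offset_mm,
      recess = recess_params(rec$shape, rec$radius_mm)),
    material_ = material(y$material$E_MPa, y$material$nu,
                         y$material$sigma_t_MPa),
    force_N = y$force_N,
    resolution = unlist(y$resolution),
    schedule = optimisation_schedule(
      total_reduction = y$schedule$total_reduction, step = y$schedule$step,
      inner_iters_max = y$schedule$inner_iters_max,
      convergence_tol = y$schedule$convergence_tol,
      filter_radius_factor = y$schedule$filter_radius_factor,
      move = y$schedule$move, damping = y$schedule$damping),
    analyses = unlist(y$analyses),
    penalty_p = y$penalty_p,
    kendall = peel_config(y$kendall$width_b_mm, y$kendall$thickness_d_mm,
                          y$kendall$E_MPa, y$kendall$R_Jm2,
                          y$kendall$theta_deg))
}

#' Run the full pad-mechanics pipeline
#'
#' Executes geometry building, the elastic solve of the non-optimised model,
#' and the enabled analyses (topology optimisation, stress trajectories,
#' von Mises contrasts, ridge profile, strength budget, peel models),
#' writing VTK fields, CSV tables and a JSON manifest into `out_dir`. The
#' manifest lists every output file with its MD5 checksum, the resolved
#' configuration, per-stage timings and completion status; a stage error
#' still writes the partial manifest (marking completed stages) before the
#' error propagates. The pipeline is deterministic: identical configurations
#' produce bit-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = rapply(unclass(config), identity, how = "list"),
                   stages = list(), files = list())
  state <- new.env()
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<-
      list(path = basename(path), md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    fun()
    manifest$stages[[name]] <<- list(status = "completed",
                                     seconds = round(proc.time()[3] - t0, 3))
    if (verbose) message(sprintf("stage %s done (%.1f s)", name,
                                 proc.time()[3] - t0))
  }
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(finish())
  want <- function(a) a %in% config$analyses

  run_stage("geometry", function() {
    state$domain <- build_design_domain(config$geometry, config$resolution)
    p <- file.path(out_dir, "geometry.vtk")
    write_vtk_fields(state$domain, p,
                     cell_data = list(density = state$domain$density,
                                      void = as.numeric(state$domain$void)))
    add_file(p)
  })
  run_stage("solve", function() {
    state$lc <- shear_load_case(config$force_N)
    state$sol <- solve_displacement(state$domain, config$material, state$lc,
                                    penalty_p = config$penalty_p)
    state$stress <- recover_stress(state$domain, config$material, state$sol,
                                   penalty_p = config$penalty_p)
    p <- file.path(out_dir, "solution.vtk")
    write_vtk_fields(state$domain, p,
      cell_data = list(density = state$domain$density,
                       von_mises = state$stress$von_mises,
                       sigma1 = state$stress$principal[1, ],
                       sigma2 = state$stress$principal[2, ],
                       sigma3 = state$stress$principal[3, ]),
      point_data = list(displacement = state$sol$U))
    add_file(p)
  })
  if (want("optimise")) run_stage("optimise", function() {
    opt <- optimise_topology(state$domain, config$material, state$lc,
                             schedule = config$schedule,
                             penalty_p = config$penalty_p)
    state$opt <- opt
    p <- file.path(out_dir, "compliance_history.csv")
    utils::write.csv(opt$history[, c("stage", "volume_fraction",
                                     "compliance_Nmm")],
                     p, row.names = FALSE)
    add_file(p)
    p <- file.path(out_dir, "optimised.vtk")
    write_vtk_fields(opt$domain, p,
                     cell_data = list(density = opt$domain$density))
    add_file(p)
    p <- file.path(out_dir, "optimised.stl")
    write_stl(threshold_surface(opt$domain), p)
    add_file(p)
  })
  if (want("contrasts")) run_stage("contrasts", function() {
    ct <- von_mises_contrasts(state$stress, state$domain)
    p <- file.path(out_dir, "vm_contrasts.json")
    jsonlite::write_json(unclass(ct), p, auto_unbox = TRUE, digits = NA)
    add_file(p)
  })
  if (want("trajectories")) run_stage("trajectories", function() {
    tr <- trace_trajectories(state$stress, state$domain)
    p <- file.path(out_dir, "trajectories.csv")
    write_trajectories_csv(tr, p)
    add_file(p)
  })
  if (want("ridge")) run_stage("ridge", function() {
    dom <- if (!is.null(state$opt)) state$opt$domain else state$domain
    rp <- ridge_profile(dom)
    p <- file.path(out_dir, "ridge_profile.csv")
    utils::write.csv(data.frame(y_mm = rp$y_mm, density = rp$profile),
                     p, row.names = FALSE)
    add_file(p)
  })
  if (want("budget")) run_stage("budget", function() {
    bd <- budget_report()
    p <- file.path(out_dir, "load_budget.csv")
    utils::write.csv(as.data.frame(bd), p, row.names = FALSE)
    add_file(p)
  })
  if (want("peel")) run_stage("peel", function() {
    th <- seq(10, 180, by = 5)
    p <- file.path(out_dir, "kendall_peel.csv")
    utils::write.csv(data.frame(
      theta_deg = th,
      force_N = kendall_peel_force(config$kendall, theta_deg = th)),
      p, row.names = FALSE)
    add_file(p)
    rep <- septum_loadcase_comparison(peel_pad_domain(), config$material,
                                      force_N = config$force_N)
    p <- file.path(out_dir, "septum_comparison.json")
    jsonlite::write_json(
      lapply(rep$cases, function(cs)
        cs[c("max_tensile", "max_location", "mean_tensile", "mean_signed")]),
      p, auto_unbox = TRUE, digits = NA)
    add_file(p)
  })
  invisible(manifest)
}
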