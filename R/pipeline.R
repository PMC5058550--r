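#' Pipeline run configuration
#'
#' A declarative description of one end-to-end run: which subject-like
#' waveform preset drives the flow, which idealized geometry is used, and the
#' solver settings. All physical quantities carry unit suffixes in their key
#' names.
#'
#' @param subject Subject label (free text).
#' @param waveform Waveform preset name ([waveform_presets()]) or a
#'   [waveform_preset()].
#' @param aqueduct `NULL`, or `list(delay = , ratio = )` for a delayed, scaled
#'   aqueduct waveform (used by branched geometries).
#' @param geometry Geometry preset name ([geometry_presets()]) or a
#'   [geometry_preset()].
#' @param solver List of arguments for [solver_config()] (e.g.
#'   `list(mode = "paper")` for the reference dt = 1e-4 s setting).
#' @param seed Integer seed recorded in all outputs and used for any noisy
#'   waveform generation.
#' @return Object of class `run_config`.
#' @export
run_config <- function(subject = "CON1", waveform = "CON1_CS",
                       aqueduct = NULL, geometry = "annulus_stenosed",
                       solver = list(), seed = 1L) {
  structure(
    list(
      subject = subject, waveform = waveform, aqueduct = aqueduct,
      geometry = geometry, solver = solver, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with keys matching [run_config()] arguments; waveform
#'   and geometry may be preset names or full field lists.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  wf <- y$waveform
  if (is.list(wf)) wf <- do.call(waveform_preset, wf)
  ge <- y$geometry
  if (is.list(ge)) ge <- do.call(geometry_preset, ge)
  run_config(
    subject = y$subject %||% "subject",
    waveform = wf %||% "CON1_CS",
    aqueduct = y$aqueduct,
    geometry = ge %||% "annulus_stenosed",
    solver = y$solver %||% list(),
    seed = y$seed %||% 1L
  )
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  # version-stable-enough serialization for a provenance stamp
  saveRDS(
    lapply(unclass(config), function(x) if (is.function(x)) NULL else x),
    f,
    version = 2
  )
  unname(tools::md5sum(f))
}

build_pipeline_inputs <- function(config) {
  mesh <- make_geometry(config$geometry)
  waves <- if (!is.null(config$aqueduct) &&
    "aqueduct" %in% names(mesh$boundaries)) {
    pr <- make_aqueduct_pair(config$waveform,
      delay = config$aqueduct$delay %||% 0.28,
      flux_ratio = config$aqueduct$ratio %||% 0.10,
      seed = config$seed
    )
    list(cervical = pr$cervical, aqueduct = pr$aqueduct)
  } else {
    list(cervical = make_waveform(config$waveform, seed = config$seed))
  }
  scfg <- do.call(solver_config, config$solver)
  list(mesh = mesh, waves = waves, solver = scfg)
}

#' Run the full pipeline for one configuration
#'
#' Waveform synthesis -> geometry -> pulsatile IPCS solve -> hydrodynamic
#' summary, with all reports written to `outdir`: `traces.csv` (probe time
#' series), `summary.csv` / `summary.json` (the per-run measure table),
#' `mesh.vtk` (legacy-VTK snapshot for visualization), `run.log`. Every
#' output carries the config hash and seed; a rerun with the same config and
#' seed is bit-identical.
#'
#' @param config A [run_config()] (or YAML path).
#' @param outdir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @return List with `run` (`flow_run`), `summary` ([hydro_summary()]),
#'   `hash`, `files`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  inp <- build_pipeline_inputs(config)
  run <- run_cycles(inp$mesh, inp$waves, inp$solver)
  summary <- hydro_summary(run)
  summary <- cbind(subject = config$subject, summary)
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# config %s seed %d", hash, config$seed)
    tf <- file.path(outdir, "traces.csv")
    writeLines(stamp, tf)
    suppressWarnings(utils::write.table(run$traces,
      tf,
      append = TRUE, sep = ",",
      row.names = FALSE, qmethod = "double"
    ))
    sf <- file.path(outdir, "summary.csv")
    writeLines(stamp, sf)
    suppressWarnings(utils::write.table(format_hydro_summary(summary),
      sf,
      append = TRUE, sep = ",", row.names = FALSE
    ))
    jf <- file.path(outdir, "summary.json")
    jsonlite::write_json(
      list(
        config_hash = hash, seed = config$seed,
        subject = config$subject,
        summary = as.list(summary),
        periodicity_residual = run$periodicity_residual,
        max_cfl = run$cfl_max, max_divergence = run$div_max
      ),
      jf,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    vf <- file.path(outdir, "mesh.vtk")
    ksnap <- which.max(vapply(run$snapshots, function(s) max(s$umag), numeric(1)))
    write_mesh_vtk(inp$mesh, vf, cell_data = list(
      umag_mms = run$snapshots[[ksnap]]$umag
    ))
    lf <- file.path(outdir, "run.log")
    writeLines(c(stamp, run$log), lf)
    files <- c(tf, sf, jf, vf, lf)
  }
  list(run = run, summary = summary, hash = hash, files = files)
}

#' Mesh-convergence comparison for a configuration
#'
#' Runs the configured scenario on the configured mesh and on a mesh refined
#' by `factor` in total cell count (i.e. `sqrt(factor)` per direction), then
#' evaluates the two mesh-independence metrics (relative peak pressure-drop
#' difference; maximum relative velocity discrepancy along the default
#' transects).
#'
#' @param config A [run_config()] (or YAML path).
#' @param factor Cell-count refinement factor (> 1; default 2, mirroring a
#'   coarse-to-fine mesh doubling).
#' @param outdir Optional directory for `convergence.json`.
#' @return A `convergence_report`.
#' @export
compare_meshes <- function(config, factor = 2, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (factor <= 1) stop("refinement factor must be > 1")
  inp <- build_pipeline_inputs(config)
  mesh_f <- make_geometry(config$geometry, refine = sqrt(factor))
  run_c <- run_cycles(inp$mesh, inp$waves, inp$solver)
  run_f <- run_cycles(mesh_f, inp$waves, inp$solver)
  rep <- convergence_report(run_c, run_f)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        config_hash = config_hash(config),
        e_dp_percent = rep$e_dp_percent,
        e_u_percent = rep$e_u_percent,
        e_u_by_line = as.list(rep$e_u_by_line),
        cells = as.list(rep$cells)
      ),
      file.path(outdir, "convergence.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  rep
}

#' Write a mesh (and optional cell data) as legacy ASCII VTK
#'
#' Exports the fluid cells as an unstructured quad mesh in physical
#' coordinates (axial z, transverse r/x; mm) for visualization.
#'
#' @param mesh A `csf_mesh`.
#' @param path Output `.vtk` path.
#' @param cell_data Named list of nz x nr matrices of cell values.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = list()) {
  nz <- mesh$nz
  nr <- mesh$nr
  # corner points of the mapped grid
  zc <- matrix(rep(mesh$z_f, nr + 1), nz + 1, nr + 1)
  rc <- mesh_r(mesh, 1:(nz + 1), 1:(nr + 1), "f", "f")
  pid <- matrix(seq_len((nz + 1) * (nr + 1)) - 1L, nz + 1, nr + 1)
  cells <- which(mesh$mask, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("csfflow %s mesh", mesh$kind),
    "ASCII", "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d float", (nz + 1) * (nr + 1))
  ), con)
  writeLines(paste(as.vector(zc), as.vector(rc), 0), con)
  nc <- nrow(cells)
  writeLines(sprintf("CELLS %d %d", nc, 5 * nc), con)
  i <- cells[, 1]
  j <- cells[, 2]
  writeLines(paste(
    4, pid[cbind(i, j)], pid[cbind(i + 1L, j)],
    pid[cbind(i + 1L, j + 1L)], pid[cbind(i, j + 1L)]
  ), con)
  writeLines(sprintf("CELL_TYPES %d", nc), con)
  writeLines(as.character(rep(9L, nc)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nc), con)
    for (nm in names(cell_data)) {
      writeLines(c(
        sprintf("SCALARS %s float 1", nm),
        "LOOKUP_TABLE default"
      ), con)
      writeLines(as.character(cell_data[[nm]][cbind(i, j)]), con)
    }
  }
  invisible(path)
}
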