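#' Closed-form oscillatory (Womersley-type) planar channel velocity
#'
#' Fully developed oscillatory flow between parallel plates at `y = 0` and
#' `y = gap`, driven by a harmonic axial pressure gradient
#' `-dp/dz = K cos(omega t)`. The complex solution is
#' `u(y, t) = Re[ K/(i rho omega) (1 - cosh(lambda (y - h/2)) / cosh(lambda h/2)) e^{i omega t} ]`
#' with `lambda = sqrt(i omega / nu)`. It reduces to steady Poiseuille flow as
#' `omega -> 0` and develops a flat inertial core with thin Stokes boundary
#' layers at high Womersley number `alpha = (h/2) sqrt(omega/nu)`.
#'
#' @param gap_mm Channel gap h, mm.
#' @param nu Kinematic viscosity, m^2/s.
#' @param omega Angular frequency, rad/s.
#' @param K Pressure-gradient amplitude, Pa/m (real) or a complex amplitude.
#' @param y_mm Wall-normal positions, mm (0 at one wall).
#' @param t Times, s (recycled against `y_mm`).
#' @param rho Density, kg/m^3.
#' @return Axial velocity in mm/s.
#' @export
womersley_planar <- function(gap_mm, nu, omega, K, y_mm, t, rho = 1000) {
  if (gap_mm <= 0 || nu <= 0 || omega < 0) stop("parameters must be positive")
  h <- gap_mm * 1e-3
  y <- y_mm * 1e-3
  if (omega == 0) {
    return(Re(K) / (2 * rho * nu) * y * (h - y) * 1e3)
  }
  lam <- sqrt(1i * omega / nu)
  uhat <- K / (1i * rho * omega) *
    (1 - cosh(lam * (y - h / 2)) / cosh(lam * h / 2))
  Re(uhat * exp(1i * omega * t)) * 1e3
}

#' Complex flux amplitude of the oscillatory channel solution
#'
#' @inheritParams womersley_planar
#' @param depth_mm Out-of-plane depth, mm.
#' @return Complex flux amplitude in m^3/s per unit `K` scaling (i.e. the flux
#'   amplitude for the given `K`).
#' @export
womersley_planar_flux <- function(gap_mm, nu, omega, K, depth_mm = 1,
                                  rho = 1000) {
  h <- gap_mm * 1e-3
  D <- depth_mm * 1e-3
  if (omega == 0) {
    return(Re(K) * h^3 * D / (12 * rho * nu))
  }
  lam <- sqrt(1i * omega / nu)
  K / (1i * rho * omega) * D * (h - (2 / lam) * tanh(lam * h / 2))
}

#' Oscillatory-channel boundary/oracle for a sinusoidal flux
#'
#' Given a target flux waveform `Q(t) = -Q0 sin(omega t)` (mm^3/s; systolic
#' negative first), returns the matching closed-form velocity field as a
#' function `u(y_mm, t)` in mm/s, for use both as a Dirichlet boundary profile
#' and as the analytic oracle.
#'
#' @param Q0 Flux amplitude, mm^3/s.
#' @param gap_mm,depth_mm Channel gap and depth, mm.
#' @param period Cycle period, s.
#' @param nu Kinematic viscosity, m^2/s.
#' @param rho Density, kg/m^3.
#' @return List with `fun(y_mm, t)` (mm/s), `flux(t)` (mm^3/s), the complex
#'   gradient amplitude `K` (Pa/m) and `omega`.
#' @export
womersley_channel_oracle <- function(Q0, gap_mm, depth_mm = 1, period,
                                     nu = 7e-7, rho = 1000) {
  omega <- 2 * pi / period
  Qhat <- 1i * Q0 * 1e-9 # Re[Qhat e^{i w t}] = -Q0 sin(w t)
  Kunit <- womersley_planar_flux(gap_mm, nu, omega, 1, depth_mm, rho)
  K <- Qhat / Kunit
  list(
    fun = function(y_mm, t) womersley_planar(gap_mm, nu, omega, K, y_mm, t, rho),
    flux = function(t) Re(Qhat * exp(1i * omega * t)) / 1e-9,
    K = K, omega = omega
  )
}

#' Sample the velocity magnitude along a transect
#'
#' Extracts `|u|` along a constant-z line across the gap from a stored
#' snapshot, for mesh-comparison purposes. Positions are the physical
#' transverse coordinates (mm).
#'
#' @param run A `flow_run`.
#' @param z_mm Axial position of the transect.
#' @param snapshot Which snapshot: `"peak_systole"` (default: the snapshot
#'   with the largest domain peak velocity) or an index.
#' @return A list of class `line_sample` with `pos` (mm), `umag` (mm/s),
#'   `u_axial` (mm/s, signed), `z_mm`, `t`.
#' @export
sample_line <- function(run, z_mm, snapshot = "peak_systole") {
  snaps <- run$snapshots
  if (identical(snapshot, "peak_systole")) {
    k <- which.max(vapply(snaps, function(s) max(s$umag), numeric(1)))
  } else {
    k <- snapshot
  }
  sn <- snaps[[k]]
  mesh <- run$mesh
  ic <- which.min(abs(mesh$z_c - z_mm))
  pos <- drop(mesh_r(mesh, ic, seq_len(mesh$nr), "c", "c"))
  keep <- mesh$mask[ic, ]
  structure(
    list(
      pos = pos[keep], umag = sn$umag[ic, keep],
      u_axial = sn$uc[ic, keep], z_mm = mesh$z_c[ic], t = sn$t
    ),
    class = "line_sample"
  )
}

# Interpolate a (finer) line sample onto reference positions.
interp_line <- function(sample, pos) {
  list(
    pos = pos,
    umag = stats::approx(sample$pos, sample$umag, pos, rule = 2)$y,
    u_axial = stats::approx(sample$pos, sample$u_axial, pos, rule = 2)$y
  )
}

#' Maximum relative velocity-magnitude discrepancy between two meshes
#'
#' The mesh-independence velocity metric: the fine-run transect is
#' interpolated to the coarse positions and the maximum of
#' `100 * | |u|_coarse - |u|_fine | / |u|_fine` is taken over the retained
#' points. Near-wall points where the fine `|u|` falls below `floor_frac` of
#' the transect peak are excluded (relative differences blow up where the
#' velocity is small), as are vortex regions, detected as sign changes of the
#' axial velocity along the line.
#'
#' @param coarse,fine `line_sample`s of the same transect from two runs.
#' @param floor_frac Near-wall exclusion floor as a fraction of the fine
#'   transect's peak `|u|` (default 0.01).
#' @param exclude_vortices Mask points on the minority side of an axial-flow
#'   sign change.
#' @return Percentage error (scalar) with attribute `n_used`.
#' @export
velocity_line_error <- function(coarse, fine, floor_frac = 0.01,
                                exclude_vortices = TRUE) {
  fi <- interp_line(fine, coarse$pos)
  if (max(fi$umag) <= 0) stop("all transect points excluded: fine field is zero")
  keep <- fi$umag >= floor_frac * max(fi$umag)
  if (exclude_vortices) {
    sgn <- sign(fi$u_axial)
    dom <- if (sum(sgn < 0) >= sum(sgn > 0)) -1 else 1
    keep <- keep & (sgn == dom | sgn == 0)
  }
  if (!any(keep)) stop("all transect points excluded")
  err <- 100 * max(abs(coarse$umag[keep] - fi$umag[keep]) / fi$umag[keep])
  attr(err, "n_used") <- sum(keep)
  err
}

#' Relative pressure-drop discrepancy between two meshes
#'
#' The mesh-independence pressure metric: the signed percentage difference of
#' the cycle-maximum pressure drop between the coarse and fine runs,
#' `100 * (dp_max_coarse - dp_max_fine) / dp_max_fine`.
#'
#' @param coarse_dp_max,fine_dp_max Cycle-maximum pressure drops, Pa.
#' @return Signed percentage difference.
#' @export
pressure_drop_error <- function(coarse_dp_max, fine_dp_max) {
  if (fine_dp_max == 0) stop("fine-mesh pressure drop is zero")
  100 * (coarse_dp_max - fine_dp_max) / fine_dp_max
}

#' Space-time relative L2 error of a run against an analytic oracle
#'
#' Compares the axial velocity at cell centres over the final cycle's
#' snapshots against `oracle(y_mm, t)` (mm/s), with cell-volume weighting.
#'
#' @param run A `flow_run` (channel geometry).
#' @param oracle `function(y_mm, t)` returning the analytic axial velocity in
#'   mm/s, e.g. from [womersley_channel_oracle()].
#' @param z_range Optional axial window (mm) to exclude boundary columns.
#' @return Relative L2 error (dimensionless).
#' @export
compare_run_to_analytic <- function(run, oracle, z_range = NULL) {
  mesh <- run$mesh
  nr <- mesh$nr
  nz <- mesh$nz
  cols <- seq_len(nz)
  if (!is.null(z_range)) {
    cols <- which(mesh$z_c >= z_range[1] & mesh$z_c <= z_range[2])
  }
  num <- 0
  den <- 0
  for (sn in run$snapshots) {
    pos <- drop(mesh_r(mesh, cols[1], seq_len(nr), "c", "c"))
    ue <- oracle(pos, sn$t)
    for (ic in cols) {
      d <- sn$uc[ic, ] - ue
      num <- num + sum(d^2)
      den <- den + sum(ue^2)
    }
  }
  if (den == 0) {
    return(if (num == 0) 0 else Inf)
  }
  sqrt(num / den)
}

#' Mesh-convergence report between a coarse and a refined run
#'
#' Evaluates the two mesh-independence metrics on a matched pair of runs:
#' the signed percentage difference of the cycle-maximum pressure drop
#' between two stations, and the maximum relative velocity-magnitude
#' discrepancy along transects (with near-wall and vortex exclusions).
#'
#' @param coarse,fine `flow_run`s of the same scenario at two resolutions.
#' @param stations Character vector of length 2, upstream then downstream
#'   station labels for the pressure drop (default `c("PC", "CS")`).
#' @param lines_z_mm Axial transect positions (mm); default mid-stenosis and
#'   mid-cervical.
#' @param floor_frac Near-wall exclusion floor for the velocity metric.
#' @return Object of class `convergence_report`.
#' @export
convergence_report <- function(coarse, fine, stations = c("PC", "CS"),
                               lines_z_mm = NULL, floor_frac = 0.01) {
  if (is.null(lines_z_mm)) {
    p <- coarse$mesh$preset
    lines_z_mm <- c(p$stenosis_centre_mm, p$length_mm / 6)
  }
  dp_c <- pressure_drop_series(coarse, stations[1], stations[2])
  dp_f <- pressure_drop_series(fine, stations[1], stations[2])
  e_dp <- pressure_drop_error(max(dp_c$dp_Pa), max(dp_f$dp_Pa))
  e_u <- vapply(lines_z_mm, function(z) {
    as.numeric(velocity_line_error(
      sample_line(coarse, z), sample_line(fine, z),
      floor_frac = floor_frac
    ))
  }, numeric(1))
  structure(
    list(
      e_dp_percent = e_dp, e_u_percent = max(e_u),
      e_u_by_line = stats::setNames(e_u, paste0("z", lines_z_mm)),
      cells = c(coarse = coarse$mesh$cells, fine = fine$mesh$cells),
      stations = stations, lines_z_mm = lines_z_mm,
      floor_frac = floor_frac
    ),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> cells %d -> %d\n  e_dp = %+.3f %% (signed), e_|u| = %.2f %% (max over %d lines)\n",
    x$cells["coarse"], x$cells["fine"], x$e_dp_percent, x$e_u_percent,
    length(x$e_u_by_line)
  ))
  invisible(x)
}
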