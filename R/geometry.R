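#' Geometry presets for idealized craniospinal domains
#'
#' Three idealized domain kinds stand in for the segmented patient anatomy:
#' \describe{
#'   \item{plane_channel}{2-D planar channel (the verification geometry;
#'     closed-form Poiseuille/oscillatory solutions exist).}
#'   \item{axisymmetric_annulus}{annular gap between spinal cord and dura,
#'     optionally narrowed by a cosine-bump stenosis on the inner wall
#'     (the tonsillar obstruction analogue); the default solver geometry.}
#'   \item{branched_two_inlet}{planar domain with the craniospinal topology:
#'     cervical SAS below, a constriction at the foramen-magnum level, a
#'     pontine-cistern segment above, and a side arm representing the
#'     aqueduct.}
#' }
#'
#' @param kind One of `"plane_channel"`, `"axisymmetric_annulus"`,
#'   `"branched_two_inlet"`.
#' @param length_mm Axial length of the main duct.
#' @param gap_mm Nominal gap (channel width, annular gap, or main-channel
#'   width).
#' @param inner_radius_mm Inner (cord) radius; annulus only.
#' @param occlusion Stenosis occlusion fraction in `[0, 1)`: the minimum gap is
#'   `(1 - occlusion) * gap_mm`.
#' @param stenosis_centre_mm,stenosis_extent_mm Axial centre and extent of the
#'   cosine stenosis bump (C1 profile, so no slope-discontinuity pressure
#'   spikes).
#' @param depth_mm Out-of-plane depth for planar kinds (flux = velocity
#'   integral times depth).
#' @param cell_mm Target transverse cell size.
#' @param axial_cell_mm Target axial cell size (default `2.5 * cell_mm` for the
#'   mapped kinds; equal to `cell_mm` for the branched kind, which needs
#'   grid-aligned walls).
#' @param arm_length_mm,arm_width_mm,arm_z_mm Aqueduct side-arm dimensions and
#'   axial centre (branched kind).
#' @param cistern_split Fraction of the unmeasured (mass-balance) flux assigned
#'   to the cistern inlet when several unmeasured inlets exist; exposed as a
#'   parameter rather than fixed.
#' @return A list of class `geometry_preset`.
#' @export
geometry_preset <- function(kind = c(
                              "axisymmetric_annulus", "plane_channel",
                              "branched_two_inlet"
                            ),
                            length_mm = 60, gap_mm = 3, inner_radius_mm = 4,
                            occlusion = 0, stenosis_centre_mm = 30,
                            stenosis_extent_mm = 20, depth_mm = 30,
                            cell_mm = 0.25, axial_cell_mm = NULL,
                            arm_length_mm = 15, arm_width_mm = 3,
                            arm_z_mm = 42, cistern_split = 1) {
  kind <- match.arg(kind)
  if (!(occlusion >= 0 && occlusion < 1)) {
    stop("occlusion must be in [0, 1) (never fully closed)")
  }
  for (v in c(length_mm, gap_mm, depth_mm, cell_mm)) {
    if (!is.finite(v) || v <= 0) stop("all lengths must be positive")
  }
  min_gap <- (1 - occlusion) * gap_mm
  if (cell_mm > min_gap / 2) {
    stop(sprintf(
      "stenosis unresolved: cell size %.3g mm exceeds half the narrowest gap (%.3g mm)",
      cell_mm, min_gap / 2
    ))
  }
  if (is.null(axial_cell_mm)) {
    axial_cell_mm <- if (kind == "branched_two_inlet") cell_mm else 2.5 * cell_mm
  }
  structure(
    list(
      kind = kind, length_mm = length_mm, gap_mm = gap_mm,
      inner_radius_mm = inner_radius_mm, occlusion = occlusion,
      stenosis_centre_mm = stenosis_centre_mm,
      stenosis_extent_mm = stenosis_extent_mm, depth_mm = depth_mm,
      cell_mm = cell_mm, axial_cell_mm = axial_cell_mm,
      arm_length_mm = arm_length_mm, arm_width_mm = arm_width_mm,
      arm_z_mm = arm_z_mm, cistern_split = cistern_split
    ),
    class = "geometry_preset"
  )
}

#' Shipped geometry presets
#'
#' @return Named list of [geometry_preset]s: `annulus_stenosed` (the default
#'   solver geometry, occlusion 0.6), `annulus_straight`, `channel_verif`
#'   (straight planar verification channel) and `branched_small`.
#' @export
geometry_presets <- function() {
  list(
    annulus_stenosed = geometry_preset("axisymmetric_annulus",
      length_mm = 60, gap_mm = 3, inner_radius_mm = 4, occlusion = 0.6,
      stenosis_centre_mm = 30, stenosis_extent_mm = 20, cell_mm = 0.15
    ),
    annulus_straight = geometry_preset("axisymmetric_annulus",
      length_mm = 60, gap_mm = 3, inner_radius_mm = 4, occlusion = 0,
      cell_mm = 0.15
    ),
    channel_verif = geometry_preset("plane_channel",
      length_mm = 20, gap_mm = 4, depth_mm = 1, occlusion = 0,
      cell_mm = 0.125, axial_cell_mm = 1.25
    ),
    branched_small = geometry_preset("branched_two_inlet",
      length_mm = 60, gap_mm = 6, occlusion = 0.5,
      stenosis_centre_mm = 28.5, stenosis_extent_mm = 9, depth_mm = 30,
      cell_mm = 0.75, arm_length_mm = 15, arm_width_mm = 3, arm_z_mm = 42
    )
  )
}

# Cosine stenosis bump height and its first two axial derivatives (mm units).
stenosis_bump <- function(z, height, centre, extent) {
  inside <- abs(z - centre) <= extent / 2
  ph <- 2 * pi * (z - centre) / extent
  list(
    h = ifelse(inside, height / 2 * (1 + cos(ph)), 0),
    dh = ifelse(inside, -height * pi / extent * sin(ph), 0),
    d2h = ifelse(inside, -height * 2 * pi^2 / extent^2 * cos(ph), 0)
  )
}

resolve_geometry_preset <- function(preset) {
  if (inherits(preset, "geometry_preset")) {
    return(preset)
  }
  if (is.character(preset)) {
    gp <- geometry_presets()
    if (!preset %in% names(gp)) {
      stop(sprintf(
        "unknown geometry preset '%s'; known: %s",
        preset, paste(names(gp), collapse = ", ")
      ))
    }
    return(gp[[preset]])
  }
  stop("preset must be a geometry_preset or a preset name")
}

#' Build a structured staggered-grid mesh from a geometry preset
#'
#' Mapped kinds (channel/annulus) use a boundary-fitted column-stretched grid
#' `r(z, eta) = Rin(z) + eta * gap(z)` with `eta` uniform in `[0, 1]`, so the
#' stenosis wall is resolution-independent (no stair-stepping). The branched
#' kind uses an identity mapping with an axis-aligned solid-cell mask, so its
#' walls also fall on grid lines at every resolution.
#'
#' @param preset A [geometry_preset] or shipped preset name.
#' @param refine Linear refinement factor (> 0): cell counts in each direction
#'   are scaled by `refine`, so total cell count scales by `refine^2`.
#' @return An object of class `csf_mesh`.
#' @export
make_geometry <- function(preset, refine = 1) {
  p <- resolve_geometry_preset(preset)
  stopifnot(refine > 0)
  axisym <- p$kind == "axisymmetric_annulus"
  masked <- p$kind == "branched_two_inlet"

  if (!masked) {
    nr <- max(4L, as.integer(round(p$gap_mm / p$cell_mm * refine)))
    nz <- max(4L, as.integer(round(p$length_mm / p$axial_cell_mm * refine)))
    dz <- p$length_mm / nz
    z_f <- (0:nz) * dz
    z_c <- (z_f[-1] + z_f[-(nz + 1)]) / 2
    R0 <- if (axisym) p$inner_radius_mm else 0
    Rout <- R0 + p$gap_mm
    bf <- stenosis_bump(
      z_f, p$occlusion * p$gap_mm,
      p$stenosis_centre_mm, p$stenosis_extent_mm
    )
    bc <- stenosis_bump(
      z_c, p$occlusion * p$gap_mm,
      p$stenosis_centre_mm, p$stenosis_extent_mm
    )
    mesh <- list(
      kind = p$kind, coord = if (axisym) "axisym" else "planar",
      depth_mm = if (axisym) NA_real_ else p$depth_mm,
      nz = nz, nr = nr, dz = dz, deta = 1 / nr,
      z_f = z_f, z_c = z_c,
      eta_f = (0:nr) / nr, eta_c = ((1:nr) - 0.5) / nr,
      Rout = Rout,
      Rin_f = R0 + bf$h, Rin_c = R0 + bc$h,
      dRin_f = bf$dh, dRin_c = bc$dh,
      d2Rin_f = bf$d2h, d2Rin_c = bc$d2h,
      gap_f = Rout - (R0 + bf$h), gap_c = Rout - (R0 + bc$h),
      mask = matrix(TRUE, nz, nr),
      preset = p
    )
    mesh$boundaries <- list(
      cervical = list(comp = "u", i = 1L, j = seq_len(nr), outward = -1),
      cranial = list(comp = "u", i = nz + 1L, j = seq_len(nr), outward = +1)
    )
  } else {
    # branched: bounding box [0, L] x [0, w_main + arm_length], square cells
    dz <- p$length_mm / round(p$length_mm / (p$cell_mm / refine))
    nz <- as.integer(round(p$length_mm / dz))
    wtot <- p$gap_mm + p$arm_length_mm
    nr <- as.integer(round(wtot / dz))
    z_f <- (0:nz) * dz
    z_c <- (z_f[-1] + z_f[-(nz + 1)]) / 2
    x_f <- (0:nr) * dz
    x_c <- (x_f[-1] + x_f[-(nr + 1)]) / 2
    mask <- matrix(FALSE, nz, nr)
    # main channel
    main_j <- which(x_c < p$gap_mm)
    mask[, main_j] <- TRUE
    # constriction: solid block narrows the main channel from the far side
    w_con <- (1 - p$occlusion) * p$gap_mm
    con_i <- which(abs(z_c - p$stenosis_centre_mm) <= p$stenosis_extent_mm / 2)
    mask[con_i, which(x_c > w_con & x_c < p$gap_mm)] <- FALSE
    # aqueduct side arm
    arm_i <- which(abs(z_c - p$arm_z_mm) <= p$arm_width_mm / 2)
    arm_j <- which(x_c > p$gap_mm)
    mask[arm_i, arm_j] <- TRUE
    mesh <- list(
      kind = p$kind, coord = "planar", depth_mm = p$depth_mm,
      nz = nz, nr = nr, dz = dz, deta = 1 / nr,
      z_f = z_f, z_c = z_c,
      eta_f = (0:nr) / nr, eta_c = ((1:nr) - 0.5) / nr,
      Rout = wtot,
      Rin_f = rep(0, nz + 1), Rin_c = rep(0, nz),
      dRin_f = rep(0, nz + 1), dRin_c = rep(0, nz),
      d2Rin_f = rep(0, nz + 1), d2Rin_c = rep(0, nz),
      gap_f = rep(wtot, nz + 1), gap_c = rep(wtot, nz),
      mask = mask,
      preset = p
    )
    mesh$boundaries <- list(
      cervical = list(comp = "u", i = 1L, j = main_j, outward = -1),
      cistern = list(comp = "u", i = nz + 1L, j = main_j, outward = +1),
      aqueduct = list(comp = "v", i = arm_i, j = nr + 1L, outward = +1)
    )
  }
  class(mesh) <- "csf_mesh"
  mesh$cells <- sum(mesh$mask)
  mesh
}

#' @export
print.csf_mesh <- function(x, ...) {
  cat(sprintf(
    "<csf_mesh> %s (%s), %d x %d grid (%d fluid cells), dz = %.3g mm\n",
    x$kind, x$coord, x$nz, x$nr, x$cells, x$dz
  ))
  cat(sprintf(
    "  boundaries: %s\n",
    paste(names(x$boundaries), collapse = ", ")
  ))
  invisible(x)
}

# Physical transverse coordinate at (z index set, eta value set).
# which: "f" faces or "c" centers for each direction.
mesh_r <- function(mesh, zi, etaj, z_at = c("f", "c"), eta_at = c("f", "c")) {
  z_at <- match.arg(z_at)
  eta_at <- match.arg(eta_at)
  Rin <- if (z_at == "f") mesh$Rin_f[zi] else mesh$Rin_c[zi]
  gap <- if (z_at == "f") mesh$gap_f[zi] else mesh$gap_c[zi]
  eta <- if (eta_at == "f") mesh$eta_f[etaj] else mesh$eta_c[etaj]
  outer(Rin, rep(1, length(eta))) + outer(gap, eta)
}

#' Boundary quadrature: positions, wall-distance weights, face areas
#'
#' Returns, for a tagged open boundary, the transverse positions of its faces
#' (mm), the tent-shaped wall-distance weight `tau` (mm; zero at the wall
#' junctions), and the discrete face areas (mm^2) used in all flux quadratures.
#'
#' @param mesh A `csf_mesh`.
#' @param tag Boundary name.
#' @return A list with `pos`, `tau`, `area` (vectors over boundary faces) and
#'   the boundary spec itself.
#' @keywords internal
boundary_quadrature <- function(mesh, tag) {
  b <- mesh$boundaries[[tag]]
  if (is.null(b)) {
    stop(sprintf(
      "unknown boundary '%s'; mesh has: %s",
      tag, paste(names(mesh$boundaries), collapse = ", ")
    ))
  }
  if (b$comp == "u") {
    i <- b$i
    j <- b$j
    r <- drop(mesh_r(mesh, i, j, "f", "c"))
    lo <- mesh$Rin_f[i] + min(mesh$eta_f[j]) * mesh$gap_f[i]
    hi <- mesh$Rin_f[i] + (max(mesh$eta_f[j + 1])) * mesh$gap_f[i]
    tau <- pmin(r - lo, hi - r)
    dwidth <- mesh$gap_f[i] * mesh$deta
    area <- if (mesh$coord == "axisym") {
      2 * pi * r * dwidth
    } else {
      rep(mesh$depth_mm * dwidth, length(j))
    }
    pos <- r
  } else {
    i <- b$i
    j <- b$j
    pos <- mesh$z_c[i]
    lo <- min(mesh$z_f[i])
    hi <- max(mesh$z_f[i + 1])
    tau <- pmin(pos - lo, hi - pos)
    area <- rep(mesh$depth_mm * mesh$dz, length(i))
  }
  list(pos = pos, tau = tau, area = area, spec = b)
}

#' Total area of a tagged boundary
#'
#' @param mesh A `csf_mesh`.
#' @param tag Boundary name.
#' @return Area in mm^2.
#' @export
boundary_area <- function(mesh, tag) {
  sum(boundary_quadrature(mesh, tag)$area)
}
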