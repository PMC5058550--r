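#' Extract a single-station probe trace over the final (settled) cycle
#'
#' @param run A `flow_run`.
#' @param station Station label (e.g. `"CS"`, `"PC"`, `"Aq"`).
#' @return Object of class `probe_trace`: data.frame columns `t_s` (rebased to
#'   `[0, period)`), `p_Pa` (slice-averaged pressure), `Q_mm3s` (slice flux),
#'   `uslice_mms` (slice peak velocity magnitude), plus attributes `label` and
#'   `pos_mm`.
#' @export
probe_trace <- function(run, station) {
  if (!station %in% names(run$stations)) {
    stop(sprintf(
      "unknown station '%s'; run has: %s",
      station, paste(names(run$stations), collapse = ", ")
    ))
  }
  n <- nrow(run$traces)
  idx <- (n - run$n_per_cycle + 1):n
  tr <- run$traces[idx, ]
  out <- data.frame(
    t_s = tr$t_s - tr$t_s[1],
    p_Pa = tr[[paste0("p_", station, "_Pa")]],
    Q_mm3s = tr[[paste0("Q_", station, "_mm3s")]],
    uslice_mms = tr[[paste0("us_", station, "_mms")]]
  )
  attr(out, "label") <- station
  attr(out, "pos_mm") <- run$stations[[station]]$pos
  attr(out, "period") <- run$period
  class(out) <- c("probe_trace", "data.frame")
  out
}

#' Pressure-drop time series between two stations
#'
#' Pointwise difference `p_upstream - p_downstream` over the shared cycle time
#' grid; e.g. the pontine-cistern-to-cervical drop is `p_PC - p_CS`, and the
#' aqueduct-to-pontine drop is `p_Aq - p_PC`.
#'
#' @param a Upstream `probe_trace`, or a `flow_run` (then `b` and `...` give
#'   the two station labels).
#' @param b Downstream `probe_trace`, or the upstream label when `a` is a run.
#' @param downstream Downstream label when `a` is a `flow_run`.
#' @return data.frame with `t_s` and `dp_Pa`, with attribute `pair`.
#' @export
pressure_drop_series <- function(a, b, downstream = NULL) {
  if (inherits(a, "flow_run")) {
    run <- a
    up <- b
    dn <- downstream
    a <- probe_trace(run, up)
    b <- probe_trace(run, dn)
  }
  stopifnot(inherits(a, "data.frame"), inherits(b, "data.frame"))
  if (nrow(a) != nrow(b) || max(abs(a$t_s - b$t_s)) > 1e-12) {
    stop("probe traces are not on a shared time grid")
  }
  out <- data.frame(t_s = a$t_s, dp_Pa = a$p_Pa - b$p_Pa)
  attr(out, "pair") <- paste0(attr(a, "label"), "-", attr(b, "label"))
  out
}

#' Pressure gradient between two stations
#'
#' @param dp Pressure drop, Pa (scalar or vector).
#' @param z_upstream_mm,z_downstream_mm Station axial positions, mm.
#' @return Gradient in Pa/cm.
#' @export
pressure_gradient <- function(dp, z_upstream_mm, z_downstream_mm) {
  d_cm <- abs(z_upstream_mm - z_downstream_mm) / 10
  if (any(d_cm == 0)) stop("stations have zero separation")
  dp / d_cm
}

#' Hydrodynamic resistance
#'
#' Peak pressure drop divided by peak flux. With the drop in Pa and the flux
#' in mm^3/s the numeric ratio is already in g/(mm^4 s), since
#' 1 Pa = 1 kg/(m s^2) = 1 g/(mm s^2).
#'
#' @param dp_max Peak pressure drop, Pa.
#' @param Q_max Peak flux, mm^3/s (nonzero; use the magnitude of the systolic
#'   or diastolic extremum for the corresponding variant).
#' @return Resistance in g/(mm^4 s).
#' @export
resistance <- function(dp_max, Q_max) {
  if (any(Q_max == 0)) stop("Q_max must be nonzero")
  dp_max / Q_max
}

#' Phase difference between peak velocity and peak pressure drop
#'
#' `theta = (t_umax - t_dpmax) / T_caudal`, where `t_umax` is the time of peak
#' systolic velocity at the cervical station, `t_dpmax` the time of the peak
#' differential pressure, and `T_caudal` the duration of caudal flow during
#' systole.
#'
#' @param t_umax,t_dpmax Times, s (same cycle origin).
#' @param T_caudal Caudal-flow duration, s (> 0).
#' @return Dimensionless phase difference.
#' @export
phase_difference <- function(t_umax, t_dpmax, T_caudal) {
  if (T_caudal <= 0) stop("T_caudal must be > 0")
  (t_umax - t_dpmax) / T_caudal
}

#' Peak velocity magnitude in a region during systole
#'
#' Scans the final-cycle snapshots restricted to the systolic phase (caudal
#' cervical flux) and an axial window, and reports the maximum velocity
#' magnitude with its location and time. The foramen-magnum (FM) region of the
#' idealized geometry is the stenosis throat plus/minus one nominal gap width.
#'
#' @param run A `flow_run`.
#' @param region `NULL` (whole domain), an axial window `c(z1, z2)` in mm, or
#'   `"FM"` for the stenosis-throat region.
#' @param cs_station Station whose flux defines the systolic phase.
#' @return List: `umax_mms`, `t`, `z_mm`, `r_mm`.
#' @export
peak_velocity <- function(run, region = NULL, cs_station = "CS") {
  mesh <- run$mesh
  if (identical(region, "FM")) {
    p <- mesh$preset
    region <- p$stenosis_centre_mm + c(-1, 1) * (p$stenosis_extent_mm / 2 + p$gap_mm)
  }
  cols <- if (is.null(region)) {
    seq_len(mesh$nz)
  } else {
    which(mesh$z_c >= region[1] & mesh$z_c <= region[2])
  }
  if (!length(cols) || !any(mesh$mask[cols, ])) stop("empty region")
  tr <- probe_trace(run, cs_station)
  sys_win <- range(tr$t_s[tr$Q_mm3s < 0])
  best <- list(umax_mms = -Inf)
  for (sn in run$snapshots) {
    t_in_cycle <- (sn$t - run$period * (run$cycles - 1))
    if (t_in_cycle < sys_win[1] - run$dt || t_in_cycle > sys_win[2] + run$dt) next
    sub <- sn$umag[cols, , drop = FALSE]
    sub[!mesh$mask[cols, , drop = FALSE]] <- -Inf
    m <- max(sub)
    if (m > best$umax_mms) {
      w <- which(sub == m, arr.ind = TRUE)[1, ]
      ic <- cols[w[1]]
      best <- list(
        umax_mms = m, t = sn$t,
        z_mm = mesh$z_c[ic],
        r_mm = drop(mesh_r(mesh, ic, w[2], "c", "c"))
      )
    }
  }
  if (!is.finite(best$umax_mms)) stop("no snapshot falls inside systole")
  best
}

#' Fraction of the cycle with synchronous bidirectional slice flow
#'
#' For each final-cycle snapshot, the axial velocity along a transect is
#' examined; the snapshot counts as bidirectional if both flow directions are
#' simultaneously present above a noise floor (default 1 % of the slice's peak
#' speed over the cycle). Vortices shed at an obstruction show up as a large
#' bidirectional fraction.
#'
#' @param run A `flow_run`, or a numeric matrix of axial slice velocities
#'   (rows = positions across the slice, columns = time samples).
#' @param z_mm Transect axial position, mm (ignored for matrix input).
#' @param floor_frac Noise floor as a fraction of the slice's cycle-peak
#'   speed.
#' @return Fraction of the cycle in `[0, 1]`.
#' @export
bidirectional_fraction <- function(run, z_mm = NULL, floor_frac = 0.01) {
  if (is.matrix(run) && is.numeric(run)) {
    ua <- run
  } else {
    mesh <- run$mesh
    ic <- which.min(abs(mesh$z_c - z_mm))
    keep <- mesh$mask[ic, ]
    ua <- vapply(
      run$snapshots, function(sn) sn$uc[ic, keep],
      numeric(sum(keep))
    )
  }
  if (nrow(ua) < 8) stop("need at least 8 sample points across the slice")
  floor <- floor_frac * max(abs(ua))
  bid <- apply(ua, 2, function(x) any(x > floor) && any(x < -floor))
  mean(bid)
}

#' Per-run hydrodynamic summary
#'
#' Computes the published summary measures for one run: peak systolic
#' velocities by region (cervical slice, aqueduct slice when present, and the
#' stenosis-throat/foramen-magnum region), the extrema of the station-pair
#' pressure drops, the drop at the time of peak systolic flux, the axial
#' pressure gradient, systolic and diastolic resistances, and the
#' velocity/pressure phase difference.
#'
#' @param run A `flow_run` with stations `CS` and `PC` (and optionally `Aq`).
#' @return Object of class `hydro_summary` (a one-row data.frame).
#' @export
hydro_summary <- function(run) {
  has_aq <- "Aq" %in% names(run$stations)
  cs <- probe_trace(run, "CS")
  dp1 <- pressure_drop_series(run, "PC", "CS")
  period <- run$period

  iQs <- which.min(cs$Q_mm3s) # systolic (most negative) flux
  Q_sys <- cs$Q_mm3s[iQs]
  Q_dia <- max(cs$Q_mm3s)
  t_Qmax <- cs$t_s[iQs]
  caudal_s <- sum(cs$Q_mm3s < 0) / nrow(cs) * period

  i_dpmax <- which.max(dp1$dp_Pa)
  # peak systolic slice velocity at CS
  sysmask <- cs$Q_mm3s < 0
  t_umax <- cs$t_s[sysmask][which.max(cs$uslice_mms[sysmask])]
  theta <- phase_difference(t_umax, dp1$t_s[i_dpmax], caudal_s)

  z_cs <- run$stations$CS$pos
  z_pc <- run$stations$PC$pos
  out <- data.frame(
    umax_CS_mms = max(cs$uslice_mms),
    umax_FM_mms = if (run$mesh$preset$occlusion > 0) {
      peak_velocity(run, "FM")$umax_mms
    } else {
      NA_real_
    },
    Q_CS_sys_mm3s = Q_sys,
    Q_CS_dia_mm3s = Q_dia,
    dp_PC_CS_max_Pa = max(dp1$dp_Pa),
    dp_PC_CS_min_Pa = min(dp1$dp_Pa),
    dp_PC_CS_tQmax_Pa = dp1$dp_Pa[iQs],
    grad_PC_CS_Pa_cm = pressure_gradient(max(dp1$dp_Pa), z_pc, z_cs),
    R_PC_CS_sys = resistance(max(dp1$dp_Pa), abs(Q_sys)),
    R_PC_CS_dia = resistance(abs(min(dp1$dp_Pa)), Q_dia),
    theta = theta,
    caudal_fraction = sum(cs$Q_mm3s < 0) / nrow(cs)
  )
  if (has_aq) {
    aq <- probe_trace(run, "Aq")
    dp2 <- pressure_drop_series(run, "Aq", "PC")
    out$umax_Aq_mms <- max(aq$uslice_mms)
    out$dp_Aq_PC_max_Pa <- max(dp2$dp_Pa)
    out$dp_Aq_PC_min_Pa <- min(dp2$dp_Pa)
    out$R_Aq_PC_sys <- resistance(max(dp2$dp_Pa), abs(min(aq$Q_mm3s)))
    out$R_Aq_PC_dia <- resistance(abs(min(dp2$dp_Pa)), max(aq$Q_mm3s))
  }
  class(out) <- c("hydro_summary", "data.frame")
  out
}

#' Format a hydro summary for reporting
#'
#' Applies the table rounding conventions: velocities to whole mm/s,
#' pressures to 0.1 Pa, resistances to 3 decimals, theta to 2 decimals.
#'
#' @param s A `hydro_summary`.
#' @return A one-row data.frame of formatted values.
#' @export
format_hydro_summary <- function(s) {
  f <- as.data.frame(s)
  for (nm in names(f)) {
    if (grepl("_mms$|_mm3s$", nm)) f[[nm]] <- round(f[[nm]])
    if (grepl("_Pa$|_Pa_cm$", nm)) f[[nm]] <- round(f[[nm]], 1)
    if (grepl("^R_", nm)) f[[nm]] <- round(f[[nm]], 3)
    if (nm == "theta") f[[nm]] <- round(f[[nm]], 2)
  }
  f
}

#' Across-subject ratio statistics
#'
#' For each metric, the max/min ratio across subjects (reported to one decimal
#' place, as in the published abstract-style comparisons), together with the
#' full pairwise ratio matrices.
#'
#' @param summaries A data.frame with one row per subject (e.g. rbind of
#'   [hydro_summary()] rows, or a bundled reference table), or a list of such
#'   rows. Non-numeric columns are used as subject labels where present.
#' @return A list with `ratios` (named vector, 1 d.p.), `undefined` (metrics
#'   with a zero minimum) and `pairwise` (list of labelled ratio matrices).
#' @export
subject_ratio_stats <- function(summaries) {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  if (nrow(summaries) < 2) stop("need at least 2 subjects")
  labs <- if ("subject" %in% names(summaries)) {
    as.character(summaries$subject)
  } else {
    paste0("S", seq_len(nrow(summaries)))
  }
  num <- summaries[vapply(summaries, is.numeric, logical(1))]
  ratios <- numeric(0)
  undef <- character(0)
  pairwise <- list()
  for (nm in names(num)) {
    x <- abs(num[[nm]]) # compare magnitudes (some drops are negative extrema)
    if (anyNA(x)) next
    if (min(x) == 0) {
      undef <- c(undef, nm)
      ratios[nm] <- NA_real_
      next
    }
    ratios[nm] <- round(max(x) / min(x), 1)
    m <- outer(x, x, `/`)
    dimnames(m) <- list(labs, labs)
    pairwise[[nm]] <- round(m, 1)
  }
  list(ratios = ratios, undefined = undef, pairwise = pairwise)
}
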