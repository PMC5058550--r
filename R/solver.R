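#' CSF fluid properties
#'
#' Cerebrospinal fluid is water-like at body temperature: density
#' 1000 kg/m^3 and dynamic viscosity 7.0e-4 Pa s.
#'
#' @param density Fluid density, kg/m^3.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return List of class `fluid_properties` with `density`, `viscosity` and
#'   the derived `kinematic_viscosity` (m^2/s).
#' @export
fluid_properties <- function(density = 1000, viscosity = 7.0e-4) {
  if (density <= 0 || viscosity <= 0) stop("density and viscosity must be > 0")
  structure(
    list(
      density = density, viscosity = viscosity,
      kinematic_viscosity = viscosity / density
    ),
    class = "fluid_properties"
  )
}

#' Solver configuration
#'
#' @param mode `"test"` (default; coarse time step for desk-scale runs) or
#'   `"paper"` (dt = 1e-4 s, the reference setting).
#' @param dt Time step in seconds. Defaults: 4e-4 s in test mode, 1e-4 s in
#'   paper mode. The step actually used divides the cardiac period exactly.
#' @param cycles Number of cardiac cycles to run from zero initial velocity
#'   (default 3; the flow is periodic from the second cycle).
#' @param convection Include the nonlinear convective term (disable for
#'   Stokes-limit linearity checks).
#' @param p_tol Divergence tolerance (1/s) used by the post-step invariant
#'   check; the direct pressure solve drives divergence far below this.
#' @param periodicity_tol Tolerance for the cycle-to-cycle periodicity
#'   residual; exceeding it is logged as a warning in the run log, not fatal.
#' @param stations Named list of probe stations. Each entry is an axial
#'   position in mm (a slice normal to the duct axis), or a list
#'   `list(axis = "z"|"x", pos = , lo = , hi = )` with optional transverse
#'   limits in mm. `NULL`: kind-appropriate defaults.
#' @param snapshots_per_cycle Field snapshots stored during the final cycle.
#' @param profile Inflow profile shape: `"tent"` (wall-distance weighting,
#'   the default) or `"parabolic"`.
#' @param ipcs_variant Only `"standard"` (non-rotational incremental
#'   pressure correction) is implemented.
#' @return List of class `solver_config`.
#' @export
solver_config <- function(mode = c("test", "paper"), dt = NULL, cycles = 3,
                          convection = TRUE, p_tol = 1e-8,
                          periodicity_tol = 0.01, stations = NULL,
                          snapshots_per_cycle = 32,
                          profile = c("tent", "parabolic"),
                          ipcs_variant = "standard") {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (!identical(ipcs_variant, "standard")) {
    stop("only the standard incremental pressure-correction variant is implemented")
  }
  if (is.null(dt)) dt <- if (mode == "paper") 1e-4 else 4e-4
  if (dt <= 0) stop("dt must be > 0")
  if (cycles < 1) stop("cycles must be >= 1")
  structure(
    list(
      mode = mode, dt = dt, cycles = as.integer(cycles),
      convection = convection, p_tol = p_tol,
      periodicity_tol = periodicity_tol, stations = stations,
      snapshots_per_cycle = as.integer(snapshots_per_cycle),
      profile = profile, ipcs_variant = ipcs_variant
    ),
    class = "solver_config"
  )
}

#' Distribute a volume flux over a boundary as a velocity profile
#'
#' Implements the wall-distance weighting used to turn a measured volumetric
#' flux into a pointwise Dirichlet velocity: the boundary-normal velocity is
#' `Q * tau(x) / integral(tau dGamma)` with `tau` the distance to the nearest
#' wall junction (zero at the walls, increasing linearly away from them). The
#' normalization is discrete, so the discrete surface integral of `u . n`
#' reproduces `Q` to rounding error.
#'
#' @param boundary Boundary tag (e.g. `"cervical"`).
#' @param Q Volumetric flux in mm^3/s (sign: along the outward normal).
#' @param mesh A `csf_mesh`.
#' @param profile `"tent"` (wall-distance) or `"parabolic"`.
#' @return List with `values` (outward-normal velocity at each boundary face,
#'   mm/s), `pos` (face positions, mm), `area` (face areas, mm^2) and `flux`
#'   (the discrete flux, mm^3/s).
#' @export
build_inflow_profile <- function(boundary, Q, mesh, profile = "tent") {
  bq <- boundary_quadrature(mesh, boundary)
  tau <- if (identical(profile, "parabolic")) {
    hw <- (max(bq$pos) - min(bq$pos)) / 2 + 0 # parabola over the span
    lo <- min(bq$pos - bq$tau)
    hi <- max(bq$pos + bq$tau)
    (bq$pos - lo) * (hi - bq$pos)
  } else {
    bq$tau
  }
  denom <- sum(tau * bq$area)
  if (denom <= 0) stop(sprintf("degenerate boundary '%s': integral of tau is zero", boundary))
  vals <- Q * tau / denom
  list(values = vals, pos = bq$pos, area = bq$area, flux = sum(vals * bq$area))
}

#' Split unmeasured inlet fluxes by mass conservation
#'
#' In a rigid, incompressible domain the flux measured at the cervical SAS
#' must equal the aqueduct flux plus the flux through any unmeasured inlets
#' (cisterns). The aqueduct flux is subtracted from the cervical flux and the
#' remainder is divided over the unmeasured inlets proportionally to their
#' areas.
#'
#' @param Q_CS Cervical flux, mm^3/s.
#' @param Q_Aq Aqueduct flux, mm^3/s.
#' @param areas Numeric vector of unmeasured inlet areas, mm^2 (all > 0).
#' @return Per-inlet fluxes (mm^3/s), same sign convention as the inputs;
#'   they sum to `Q_CS - Q_Aq`.
#' @export
mass_balance_split <- function(Q_CS, Q_Aq, areas) {
  if (!length(areas)) {
    if (any(abs(Q_CS - Q_Aq) > 0)) {
      stop("mass not conservable: no unmeasured inlet to carry Q_CS - Q_Aq")
    }
    return(numeric(0))
  }
  if (any(areas <= 0)) stop("inlet areas must be > 0")
  (Q_CS - Q_Aq) * areas / sum(areas)
}

#' Assemble the discrete IPCS operators for a mesh
#'
#' Builds and factorizes (once; they are reused every step) the implicit
#' viscous operators, the pressure-Poisson operator (the product of the
#' conservative divergence and the discrete gradient, so the projection is
#' exact), and the convection/interpolation matrices.
#'
#' @param mesh A `csf_mesh`.
#' @param props [fluid_properties()].
#' @param dt Time step, s.
#' @param convection Include convective terms.
#' @return An opaque operator set for [ipcs_step()].
#' @export
assemble_operators <- function(mesh, props = fluid_properties(), dt,
                               convection = TRUE) {
  assemble_ops(mesh, props, dt, convection)
}

#' Initial (zero-flow) solver state
#'
#' @param ops Operator set from [assemble_operators()].
#' @return A `flow_state`: velocity fields `u`, `v` (m/s, staggered), pressure
#'   `p` (Pa, cell centres), time `t` (s).
#' @export
flow_state_zero <- function(ops) {
  structure(
    list(
      u = numeric(ops$Nu), v = numeric(ops$Nv), p = numeric(ops$Np),
      t = 0, conv_u = NULL, conv_v = NULL
    ),
    class = "flow_state"
  )
}

# Convective term (advective form) at interior points; zero rows elsewhere.
convective_term <- function(ops, u, v) {
  cu <- u * (ops$Dz_u %*% u) + (ops$Iv2u %*% v) * (ops$De_u %*% u)
  cv <- (ops$Iu2v %*% u) * (ops$Dz_v %*% v) + v * (ops$De_v %*% v)
  list(u = as.numeric(cu), v = as.numeric(cv))
}

#' One IPCS fractional step
#'
#' Advances the state by one time step of the semi-implicit incremental
#' pressure-correction scheme: (1) tentative velocity with implicit viscosity
#' and explicit (Adams-Bashforth 2) central-difference convection under the
#' previous pressure gradient; (2) pressure-increment Poisson solve with
#' homogeneous Neumann conditions (nullspace pinned, zero-mean pressure);
#' (3) projection of the velocity onto the discretely divergence-free space.
#'
#' @param state A `flow_state`.
#' @param ops Operator set from [assemble_operators()].
#' @param bc_u,bc_v Full-length Dirichlet value vectors (m/s) for the new time
#'   level; only entries at non-interior faces are used (walls are zero).
#' @return The advanced `flow_state` (with the convective term stored for the
#'   next step's Adams-Bashforth extrapolation).
#' @export
ipcs_step <- function(state, ops, bc_u = NULL, bc_v = NULL) {
  dt <- ops$dt
  rho <- ops$props$density
  if (is.null(bc_u)) bc_u <- numeric(ops$Nu)
  if (is.null(bc_v)) bc_v <- numeric(ops$Nv)
  u <- state$u
  v <- state$v
  p <- state$p

  if (ops$convection) {
    cv <- convective_term(ops, u, v)
    ab_u <- if (is.null(state$conv_u)) cv$u else 1.5 * cv$u - 0.5 * state$conv_u
    ab_v <- if (is.null(state$conv_v)) cv$v else 1.5 * cv$v - 0.5 * state$conv_v
  } else {
    cv <- list(u = NULL, v = NULL)
    ab_u <- 0
    ab_v <- 0
  }

  gp_u <- as.numeric(ops$Gz %*% p)
  gp_v <- as.numeric(ops$Gr %*% p)
  rhs_u <- u / dt - ab_u - gp_u / rho
  rhs_v <- v / dt - ab_v - gp_v / rho
  ni_u <- !as.vector(ops$int_u)
  ni_v <- !as.vector(ops$int_v)
  rhs_u[ni_u] <- bc_u[ni_u]
  rhs_v[ni_v] <- bc_v[ni_v]
  ustar <- as.numeric(Matrix::solve(ops$LUu, rhs_u))
  vstar <- as.numeric(Matrix::solve(ops$LUv, rhs_v))

  div <- as.numeric(ops$Dmat %*% c(ustar, vstar)) # m^3/s per cell
  rhs_p <- (rho / dt) * div
  rhs_p[ops$fluid_idx] <- rhs_p[ops$fluid_idx] - mean(rhs_p[ops$fluid_idx])
  rhs_p[-ops$fluid_idx] <- 0
  rhs_p[ops$pin] <- 0
  phi <- as.numeric(Matrix::solve(ops$LUp, rhs_p))

  u_new <- ustar - (dt / rho) * as.numeric(ops$Gz %*% phi)
  v_new <- vstar - (dt / rho) * as.numeric(ops$Gr %*% phi)
  p_new <- p + phi
  volv <- as.vector(ops$Vol)
  p_new <- p_new - sum(p_new * volv) / sum(volv)
  p_new[volv == 0] <- 0

  structure(
    list(
      u = u_new, v = v_new, p = p_new, t = state$t + dt,
      conv_u = cv$u, conv_v = cv$v
    ),
    class = "flow_state"
  )
}

# Maximum cell divergence (1/s) of a state: the post-projection invariant.
max_divergence <- function(ops, state) {
  div <- as.numeric(ops$Dmat %*% c(state$u, state$v))
  max(abs(div[ops$fluid_idx]) / ops$Vol[ops$fluid_idx])
}

# CFL number of a state (advective).
cfl_number <- function(ops, state) {
  dr_min <- min(ops$map_v$G) * ops$deta
  ops$dt * max(
    max(abs(state$u)) / ops$dxi,
    max(abs(state$v)) / dr_min
  )
}

#' A time-varying Dirichlet velocity profile for one boundary
#'
#' Used in place of a flux waveform to drive a boundary with an exact velocity
#' profile (e.g. the closed-form oscillatory solution in verification runs).
#'
#' @param fun `function(pos_mm, t_s)` returning the boundary-face velocity
#'   component (mm/s) at transverse positions `pos_mm` and time `t_s`, signed
#'   as the grid component (axial `u` for z-boundaries, transverse `v` for
#'   x-boundaries).
#' @return Object of class `boundary_profile`.
#' @export
boundary_profile <- function(fun) {
  structure(list(fun = fun), class = "boundary_profile")
}

# Resolve waveforms argument into per-boundary outward-flux functions (m^3/s)
# and/or direct profile functions. Unmeasured open boundaries share the
# mass-balance remainder proportionally to their areas.
boundary_drivers <- function(mesh, waveforms) {
  tags <- names(mesh$boundaries)
  wf <- lapply(waveforms, function(w) {
    if (inherits(w, "flux_series")) {
      if (!is.null(w$wave)) w$wave else fit_periodic_spline(w)
    } else {
      w
    }
  })
  unknown <- setdiff(names(wf), tags)
  if (length(unknown)) {
    stop(sprintf("waveform assigned to unknown boundary: %s", paste(unknown, collapse = ", ")))
  }
  drivers <- list()
  measured <- character(0)
  for (tg in tags) {
    w <- wf[[tg]]
    if (is.null(w)) next
    if (inherits(w, "boundary_profile")) {
      drivers[[tg]] <- list(type = "profile", fun = w$fun)
      measured <- c(measured, tg)
    } else if (inherits(w, "spline_waveform")) {
      sgn <- if (tg == "cervical") -1 else +1 # outward flux vs measured Q
      local({
        f <- w$fun
        s <- sgn
        drivers[[tg]] <<- list(type = "flux", fun = function(t) s * f(t) * 1e-9)
      })
      measured <- c(measured, tg)
    } else {
      stop("waveforms entries must be flux_series, spline_waveform or boundary_profile")
    }
  }
  un <- setdiff(tags, measured)
  if (length(un)) {
    flux_tags <- names(Filter(function(d) d$type == "flux", drivers))
    if (!length(flux_tags) && length(measured)) {
      stop("cannot mass-balance unmeasured boundaries against profile-driven boundaries")
    }
    areas <- vapply(un, function(tg) boundary_area(mesh, tg), numeric(1))
    fr <- areas / sum(areas)
    meas_funs <- lapply(flux_tags, function(tg) drivers[[tg]]$fun)
    for (k in seq_along(un)) {
      local({
        frk <- fr[k]
        drivers[[un[k]]] <<- list(
          type = "flux",
          fun = function(t) -frk * Reduce(`+`, lapply(meas_funs, function(f) f(t)))
        )
      })
    }
  }
  drivers
}

# Precompute per-boundary face indices, signed weights and positions for fast
# per-step Dirichlet assembly (all SI).
boundary_applicators <- function(mesh, ops, drivers, profile = "tent") {
  out <- list()
  for (tg in names(drivers)) {
    b <- mesh$boundaries[[tg]]
    bq <- boundary_quadrature(mesh, tg)
    if (b$comp == "u") {
      idx <- b$i + (b$j - 1L) * ops$NIu
      area <- ops$Au[cbind(b$i, b$j)]
      comp_sign <- b$outward # u . n_out = u * outward
    } else {
      idx <- b$i + (b$j - 1L) * ops$nz
      area <- ops$Av[cbind(b$i, b$j)]
      comp_sign <- b$outward
    }
    tau <- if (identical(profile, "parabolic")) {
      lo <- min(bq$pos - bq$tau)
      hi <- max(bq$pos + bq$tau)
      (bq$pos - lo) * (hi - bq$pos)
    } else {
      bq$tau
    }
    w <- tau / sum(tau * area) # 1/m^2 (tau units cancel)
    out[[tg]] <- list(
      comp = b$comp, idx = idx, pos = bq$pos, area = area,
      outward = b$outward, weight = w * comp_sign, driver = drivers[[tg]]
    )
  }
  out
}

# Dirichlet vectors (m/s) at time t for all driven boundaries.
dirichlet_values <- function(ops, apps, t) {
  bu <- numeric(ops$Nu)
  bv <- numeric(ops$Nv)
  for (ap in apps) {
    vals <- if (ap$driver$type == "profile") {
      ap$driver$fun(ap$pos, t) * MM # mm/s -> m/s, already component-signed
    } else {
      ap$driver$fun(t) * ap$weight
    }
    if (ap$comp == "u") bu[ap$idx] <- vals else bv[ap$idx] <- vals
  }
  list(u = bu, v = bv)
}

# Default probe stations by mesh kind.
default_stations <- function(mesh) {
  L <- mesh$preset$length_mm
  if (mesh$kind == "branched_two_inlet") {
    g <- mesh$preset$gap_mm
    list(
      CS = list(axis = "z", pos = L / 6, lo = 0, hi = g),
      PC = list(axis = "z", pos = 5 * L / 6, lo = 0, hi = g),
      Aq = list(axis = "x", pos = g + mesh$preset$arm_length_mm / 2)
    )
  } else {
    list(
      CS = list(axis = "z", pos = L / 6),
      PC = list(axis = "z", pos = 5 * L / 6)
    )
  }
}

normalize_station <- function(st) {
  if (is.numeric(st)) {
    return(list(axis = "z", pos = st, lo = -Inf, hi = Inf))
  }
  if (is.null(st$axis)) st$axis <- "z"
  if (is.null(st$lo)) st$lo <- -Inf
  if (is.null(st$hi)) st$hi <- Inf
  st
}

# Precompute weight vectors for slice-averaged pressure (over p DOFs) and
# slice flux (over u or v DOFs) at a station.
station_applicator <- function(mesh, ops, st) {
  st <- normalize_station(st)
  nz <- ops$nz
  nr <- ops$nr
  if (st$axis == "z") {
    iface <- which.min(abs(mesh$z_f - st$pos))
    ic <- which.min(abs(mesh$z_c - st$pos))
    xc <- drop(mesh_r(mesh, ic, seq_len(nr), "c", "c"))
    sel_c <- which(mesh$mask[ic, ] & xc >= st$lo & xc <= st$hi)
    pw <- numeric(ops$Np)
    pw[ic + (sel_c - 1L) * nz] <- ops$Vol[cbind(ic, sel_c)]
    pw <- pw / sum(pw)
    adj <- function(j) {
      W <- iface > 1 & mesh$mask[max(iface - 1, 1), j]
      E <- iface <= nz & mesh$mask[min(iface, nz), j]
      W | E
    }
    xf <- drop(mesh_r(mesh, iface, seq_len(nr), "f", "c"))
    sel_f <- which(vapply(seq_len(nr), adj, logical(1)) & xf >= st$lo & xf <= st$hi)
    qw <- numeric(ops$Nu)
    qw[iface + (sel_f - 1L) * ops$NIu] <- ops$Au[cbind(iface, sel_f)]
    list(comp = "u", pweight = pw, qweight = qw, cells = cbind(ic, sel_c))
  } else {
    # transverse station (e.g. inside the branched side arm)
    x_c <- mesh$eta_c * mesh$Rout
    x_f <- mesh$eta_f * mesh$Rout
    jface <- which.min(abs(x_f - st$pos))
    jc <- which.min(abs(x_c - st$pos))
    sel_c <- which(mesh$mask[, jc] & mesh$z_c >= st$lo & mesh$z_c <= st$hi)
    pw <- numeric(ops$Np)
    pw[sel_c + (jc - 1L) * nz] <- ops$Vol[cbind(sel_c, jc)]
    pw <- pw / sum(pw)
    adj <- function(i) {
      S <- jface > 1 & mesh$mask[i, max(jface - 1, 1)]
      N <- jface <= nr & mesh$mask[i, min(jface, nr)]
      S | N
    }
    sel_f <- which(vapply(seq_len(nz), adj, logical(1)) &
      mesh$z_c >= st$lo & mesh$z_c <= st$hi)
    qw <- numeric(ops$Nv)
    qw[sel_f + (jface - 1L) * nz] <- ops$Av[cbind(sel_f, jface)]
    list(comp = "v", pweight = pw, qweight = qw, cells = cbind(sel_c, jc))
  }
}

#' Run a pulsatile simulation over full cardiac cycles
#'
#' Starts from zero velocity and advances `config$cycles` cardiac cycles with
#' the IPCS scheme, recording slice-averaged pressure, slice flux and the
#' domain peak velocity magnitude at every step for each probe station. The
#' final two cycles are compared to give a periodicity residual (relative L2
#' difference per recorded series; the flow is periodic from the second cycle,
#' so the default 3 cycles leave one settled cycle for analysis). Only the
#' final cycle is used by downstream measures.
#'
#' @param mesh A `csf_mesh`.
#' @param waveforms Named list (by boundary tag) of [flux_series],
#'   `spline_waveform` or [boundary_profile] drivers. Unassigned open
#'   boundaries receive the mass-balance remainder split by area. Flux
#'   waveforms should be origin-aligned.
#' @param config [solver_config()].
#' @param props [fluid_properties()].
#' @return A `flow_run` object: `traces` (data.frame, one row per step of all
#'   cycles), `snapshots` (final-cycle cell-centred fields), `periodicity`
#'   (per-series residuals), `log`, plus grid/config echoes.
#' @export
run_cycles <- function(mesh, waveforms, config = solver_config(),
                       props = fluid_properties()) {
  wf1 <- waveforms[[1]]
  period <- if (inherits(wf1, "boundary_profile")) {
    attr(wf1, "period") %||% stop("profile-driven runs need attr(profile, 'period')")
  } else if (inherits(wf1, "flux_series")) {
    wf1$period
  } else {
    wf1$period
  }
  n_per_cycle <- max(2L, as.integer(round(period / config$dt)))
  dt <- period / n_per_cycle
  ops <- assemble_ops(mesh, props, dt, convection = config$convection)
  drivers <- boundary_drivers(mesh, waveforms)
  apps <- boundary_applicators(mesh, ops, drivers, profile = config$profile)
  stations <- config$stations %||% default_stations(mesh)
  stations <- lapply(stations, normalize_station)
  st_apps <- lapply(stations, function(s) station_applicator(mesh, ops, s))

  n_steps <- n_per_cycle * config$cycles
  nst <- length(st_apps)
  tr_t <- numeric(n_steps)
  tr_p <- matrix(0, n_steps, nst)
  tr_q <- matrix(0, n_steps, nst)
  tr_us <- matrix(0, n_steps, nst)
  tr_umax <- numeric(n_steps)
  colnames(tr_p) <- names(st_apps)
  colnames(tr_q) <- names(st_apps)
  colnames(tr_us) <- names(st_apps)

  snap_every <- max(1L, n_per_cycle %/% config$snapshots_per_cycle)
  snap_steps <- seq(n_steps - n_per_cycle + snap_every, n_steps, by = snap_every)
  snapshots <- vector("list", length(snap_steps))
  names(snapshots) <- as.character(snap_steps)

  state <- flow_state_zero(ops)
  mass_res_max <- 0
  div_max <- 0
  cfl_max <- 0
  log <- character(0)
  peak_flux <- 0

  for (n in seq_len(n_steps)) {
    t_new <- n * dt
    bc <- dirichlet_values(ops, apps, t_new)
    state <- ipcs_step(state, ops, bc$u, bc$v)
    tr_t[n] <- t_new
    cc <- cell_velocities(ops, state$u, state$v)
    umag <- sqrt(cc$uc^2 + cc$vc^2)
    tr_umax[n] <- max(umag)
    for (k in seq_len(nst)) {
      tr_p[n, k] <- sum(st_apps[[k]]$pweight * state$p)
      qv <- if (st_apps[[k]]$comp == "u") {
        sum(st_apps[[k]]$qweight * state$u)
      } else {
        sum(st_apps[[k]]$qweight * state$v)
      }
      tr_q[n, k] <- qv
      tr_us[n, k] <- max(umag[st_apps[[k]]$cells])
    }
    # invariant tracking (cheap)
    bflux <- boundary_net_flux(ops, apps, state, bc)
    peak_flux <- max(peak_flux, bflux$peak)
    mass_res_max <- max(mass_res_max, abs(bflux$net))
    cfl <- cfl_number(ops, state)
    cfl_max <- max(cfl_max, cfl)
    if (cfl > 1) {
      stop(sprintf(
        "CFL violation (%.2f) at t = %.4g s: reduce dt below %.3g s",
        cfl, t_new, dt / cfl
      ))
    }
    if (n %in% snap_steps) {
      snapshots[[as.character(n)]] <- list(
        t = t_new, uc = cc$uc / MM, vc = cc$vc / MM, umag = umag / MM
      )
    }
    if (n %% n_per_cycle == 0) {
      dv <- max_divergence(ops, state)
      div_max <- max(div_max, dv)
      log <- c(log, sprintf(
        "cycle %d: max CFL %.3f, max divergence %.3g 1/s",
        n %/% n_per_cycle, cfl_max, dv
      ))
    }
  }

  # periodicity: relative L2 difference of the last two cycles, per series
  i3 <- (n_steps - n_per_cycle + 1):n_steps
  i2 <- i3 - n_per_cycle
  rel_l2 <- function(a, b) {
    nb <- sqrt(sum(b^2))
    if (nb == 0) {
      return(0)
    }
    sqrt(sum((a - b)^2)) / nb
  }
  periodicity <- c(
    stats::setNames(
      lapply(seq_len(nst), function(k) rel_l2(tr_p[i2, k], tr_p[i3, k])),
      paste0("p_", names(st_apps))
    ),
    stats::setNames(
      lapply(seq_len(nst), function(k) rel_l2(tr_q[i2, k], tr_q[i3, k])),
      paste0("Q_", names(st_apps))
    ),
    stats::setNames(
      lapply(seq_len(nst), function(k) rel_l2(tr_us[i2, k], tr_us[i3, k])),
      paste0("us_", names(st_apps))
    ),
    list(umax = rel_l2(tr_umax[i2], tr_umax[i3]))
  )
  res <- max(unlist(periodicity))
  if (config$cycles >= 2 && res > config$periodicity_tol) {
    log <- c(log, sprintf(
      "WARNING: periodicity residual %.3g exceeds tolerance %.3g",
      res, config$periodicity_tol
    ))
  } else {
    log <- c(log, sprintf("periodicity residual %.3g", res))
  }

  traces <- data.frame(t_s = tr_t)
  for (k in seq_len(nst)) {
    traces[[paste0("p_", names(st_apps)[k], "_Pa")]] <- tr_p[, k]
    traces[[paste0("Q_", names(st_apps)[k], "_mm3s")]] <- tr_q[, k] / 1e-9
    traces[[paste0("us_", names(st_apps)[k], "_mms")]] <- tr_us[, k] / MM
  }
  traces$umax_mms <- tr_umax / MM

  structure(
    list(
      traces = traces, snapshots = snapshots,
      periodicity = lapply(periodicity, as.numeric),
      periodicity_residual = res,
      n_per_cycle = n_per_cycle, dt = dt, period = period,
      cycles = config$cycles, stations = stations, mesh = mesh,
      config = config, props = props,
      mass_residual = mass_res_max, peak_flux = peak_flux,
      div_max = div_max, cfl_max = cfl_max, log = log,
      final_state = state, ops_meta = list(
        cells = mesh$cells, Nu = ops$Nu, Nv = ops$Nv
      )
    ),
    class = "flow_run"
  )
}

#' @export
print.flow_run <- function(x, ...) {
  cat(sprintf(
    "<flow_run> %s, %d cells, %d cycles x %d steps (dt = %.3g s)\n",
    x$mesh$kind, x$mesh$cells, x$cycles, x$n_per_cycle, x$dt
  ))
  cat(sprintf(
    "  periodicity residual %.3g, max CFL %.3f, max divergence %.3g 1/s\n",
    x$periodicity_residual, x$cfl_max, x$div_max
  ))
  invisible(x)
}

# Net and peak outward boundary flux of the imposed Dirichlet values (m^3/s).
boundary_net_flux <- function(ops, apps, state, bc) {
  net <- 0
  peak <- 0
  for (ap in apps) {
    vals <- if (ap$comp == "u") state$u[ap$idx] else state$v[ap$idx]
    f <- sum(vals * ap$area) * ap$outward
    net <- net + f
    peak <- max(peak, abs(f))
  }
  list(net = net, peak = peak)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
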