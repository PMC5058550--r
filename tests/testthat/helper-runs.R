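# Shared, lazily computed simulation fixtures. The heavy runs (the stenosed
# coarse/fine mesh pair, the oscillatory channel) are computed once and reused
# across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache, inherits = FALSE)
}

con1_wave <- function() cached("con1_wave", make_waveform("CON1_CS"))

# Oscillatory planar channel driven by the closed-form profile.
womersley_fixture <- function(nr = 32) {
  cached(paste0("womersley_", nr), {
    period <- 60 / 71
    orc <- womersley_channel_oracle(
      Q0 = 120, gap_mm = 4, depth_mm = 1,
      period = period
    )
    prof <- boundary_profile(function(pos, t) orc$fun(pos, t))
    attr(prof, "period") <- period
    mesh <- make_geometry(geometry_preset("plane_channel",
      length_mm = 20, gap_mm = 4, depth_mm = 1,
      cell_mm = 4 / nr, axial_cell_mm = 1.25
    ))
    run <- run_cycles(
      mesh, list(cervical = prof, cranial = prof),
      solver_config(cycles = 3, snapshots_per_cycle = 64)
    )
    list(run = run, oracle = orc, period = period)
  })
}

# The shipped stenosed-annulus coarse/fine mesh-independence pair.
stenosed_pair <- function() {
  cached("stenosed_pair", {
    wave <- con1_wave()
    cfg <- solver_config(mode = "test", cycles = 3)
    run_c <- run_cycles(
      make_geometry("annulus_stenosed"),
      list(cervical = wave), cfg
    )
    run_f <- run_cycles(
      make_geometry("annulus_stenosed", refine = sqrt(2)),
      list(cervical = wave), cfg
    )
    list(coarse = run_c, fine = run_f, report = convergence_report(run_c, run_f))
  })
}

branched_run <- function() {
  cached("branched_run", {
    pair <- make_aqueduct_pair("CON1_CS", delay = 0.28, flux_ratio = 0.10)
    run_cycles(
      make_geometry("branched_small"),
      list(cervical = pair$cervical, aqueduct = pair$aqueduct),
      solver_config(mode = "test", cycles = 3)
    )
  })
}

# Small paired stenosed/straight annulus runs for vortex/bidirectional-flow
# comparison (coarser than the shipped presets; the comparison is paired).
bidir_pair <- function() {
  cached("bidir_pair", {
    wave <- con1_wave()
    cfg <- solver_config(mode = "test", cycles = 2)
    mk <- function(occ) {
      make_geometry(geometry_preset("axisymmetric_annulus",
        length_mm = 60, gap_mm = 3, inner_radius_mm = 4, occlusion = occ,
        stenosis_centre_mm = 30, stenosis_extent_mm = 20, cell_mm = 0.3
      ))
    }
    list(
      stenosed = run_cycles(mk(0.6), list(cervical = wave), cfg),
      straight = run_cycles(mk(0), list(cervical = wave), cfg)
    )
  })
}

# Steady Poiseuille channel solved to stationarity in the Stokes limit with a
# parabolic inlet profile. Returns the state, operators and helpers.
poiseuille_steady <- function(nr = 64, Q = 20, length_mm = 10) {
  cached(paste0("pois_", nr, "_", Q), {
    gap <- 4
    mesh <- make_geometry(geometry_preset("plane_channel",
      length_mm = length_mm, gap_mm = gap, depth_mm = 1,
      cell_mm = gap / nr, axial_cell_mm = 1.25
    ))
    props <- fluid_properties()
    ops <- csfflow:::assemble_ops(mesh, props, dt = 0.1, convection = FALSE)
    w <- gap * 1e-3
    D <- 1e-3
    Qsi <- Q * 1e-9
    ubc_ms <- function(pos_mm) {
      y <- pos_mm * 1e-3
      6 * Qsi / (w^3 * D) * y * (w - y)
    }
    bu <- numeric(ops$Nu)
    for (tg in c("cervical", "cranial")) {
      b <- mesh$boundaries[[tg]]
      bq <- csfflow:::boundary_quadrature(mesh, tg)
      bu[b$i + (b$j - 1) * ops$NIu] <- ubc_ms(bq$pos)
    }
    st <- flow_state_zero(ops)
    for (n in 1:300) st <- ipcs_step(st, ops, bu, numeric(ops$Nv))
    list(
      mesh = mesh, ops = ops, state = st, Q = Q, w = w, D = D,
      props = props, ubc_ms = ubc_ms,
      station_p = function(z_mm) {
        ap <- csfflow:::station_applicator(
          mesh, ops, list(axis = "z", pos = z_mm, lo = -Inf, hi = Inf)
        )
        sum(ap$pweight * st$p)
      }
    )
  })
}
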