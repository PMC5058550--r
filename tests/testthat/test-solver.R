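test_that("inflow profile distributes flux with the tent weighting", {
  mesh <- make_geometry("channel_verif") # gap 4 mm, depth 1 mm
  pr0 <- build_inflow_profile("cervical", 0, mesh)
  expect_true(all(pr0$values == 0))

  w <- 4
  D <- 1
  Q <- 57.3
  pr <- build_inflow_profile("cervical", Q, mesh)
  # tent profile: peak speed 2 Q / (w D) at the midpoint (discretely, within
  # one cell of the apex)
  expect_equal(max(pr$values), 2 * Q / (w * D), tolerance = 2 / mesh$nr)
  expect_equal(pr$values[1], pr$values[mesh$nr], tolerance = 1e-12)
  # discrete flux identity for random Q
  set.seed(7)
  for (Qr in stats::runif(4, -5000, 5000)) {
    prr <- build_inflow_profile("cervical", Qr, mesh)
    expect_equal(prr$flux, Qr, tolerance = 1e-10)
  }
})

test_that("mass-balance split conserves flux and scales by area", {
  expect_equal(mass_balance_split(-4000, -400, 100), -3600)
  expect_equal(mass_balance_split(-4000, -400, c(50, 50)), c(-1800, -1800))
  s <- mass_balance_split(-3000, -300, c(200, 100))
  expect_equal(s, c(-1800, -900)) # 2:1 by area
  expect_equal(sum(s) + (-300), -3000)
  expect_error(mass_balance_split(-4000, -400, numeric(0)), "mass not conservable")
  expect_equal(mass_balance_split(-400, -400, numeric(0)), numeric(0))
  expect_error(mass_balance_split(-4000, -400, c(10, -1)), "> 0")
})

test_that("zero state with zero boundary flux stays exactly zero", {
  mesh <- make_geometry(geometry_preset("plane_channel",
    length_mm = 10, gap_mm = 4, depth_mm = 1, cell_mm = 0.5, axial_cell_mm = 1
  ))
  ops <- assemble_operators(mesh, fluid_properties(), dt = 1e-3)
  st <- flow_state_zero(ops)
  for (k in 1:5) st <- ipcs_step(st, ops)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$v)), 0)
  expect_equal(max(abs(st$p)), 0)
})

test_that("steady channel flow reproduces Poiseuille to within 1 %", {
  px <- poiseuille_steady(nr = 64)
  ops <- px$ops
  st <- px$state
  expect_lt(csfflow:::max_divergence(ops, st), 1e-10)
  um <- matrix(st$u, ops$NIu, ops$nr)
  imid <- round(ops$NIu / 2)
  yc <- csfflow:::mesh_r(px$mesh, imid, 1:ops$nr, "f", "c") * 1e-3
  uex <- 6 * (px$Q * 1e-9) / (px$w^3 * px$D) * yc * (px$w - yc)
  expect_lt(max(abs(um[imid, ] - uex)) / max(uex), 0.01)
  # peak/mean velocity ratio of the parabolic profile
  expect_equal(max(um[imid, ]) / mean(um[imid, ]), 1.5, tolerance = 0.01)
  # pressure drop and resistance against the closed form
  zs <- c(0.25, 0.75) * px$mesh$preset$length_mm
  dp_num <- px$station_p(zs[1]) - px$station_p(zs[2])
  Lsep <- diff(zs) * 1e-3
  dp_ex <- 12 * px$props$viscosity * Lsep * (px$Q * 1e-9) / (px$w^3 * px$D)
  expect_lt(abs(dp_num - dp_ex) / dp_ex, 0.01)
  R_num <- resistance(dp_num, px$Q)
  R_ex <- dp_ex / px$Q
  expect_lt(abs(R_num - R_ex) / R_ex, 0.01)
})

test_that("Poiseuille error converges at 2nd order in the cell size", {
  err_for <- function(nr) {
    px <- poiseuille_steady(nr = nr)
    ops <- px$ops
    um <- matrix(px$state$u, ops$NIu, ops$nr)
    imid <- round(ops$NIu / 2)
    yc <- csfflow:::mesh_r(px$mesh, imid, 1:ops$nr, "f", "c") * 1e-3
    uex <- 6 * (px$Q * 1e-9) / (px$w^3 * px$D) * yc * (px$w - yc)
    max(abs(um[imid, ] - uex)) / max(uex)
  }
  e8 <- err_for(8)
  e16 <- err_for(16)
  expect_gt(e8 / e16, 3) # 2nd order: factor 4 expected
})

test_that("Stokes-limit response is exactly linear in the driving flux", {
  mesh <- make_geometry(geometry_preset("plane_channel",
    length_mm = 10, gap_mm = 4, depth_mm = 1, cell_mm = 0.25, axial_cell_mm = 1
  ))
  period <- 60 / 71
  run_for <- function(Q0) {
    s <- make_waveform(waveform_preset(71, Q0, 0.26, 0.08))
    run_cycles(
      mesh, list(cervical = s),
      solver_config(cycles = 1, convection = FALSE, dt = 2e-3)
    )
  }
  r1 <- run_for(100)
  r2 <- run_for(200)
  expect_equal(2 * r1$traces$p_CS_Pa, r2$traces$p_CS_Pa, tolerance = 1e-8)
  expect_equal(2 * r1$traces$umax_mms, r2$traces$umax_mms, tolerance = 1e-8)
  # resistance is amplitude-independent in the Stokes limit
  dp1 <- pressure_drop_series(r1, "PC", "CS")
  dp2 <- pressure_drop_series(r2, "PC", "CS")
  R1 <- resistance(max(dp1$dp_Pa), 100)
  R2 <- resistance(max(dp2$dp_Pa), 200)
  expect_equal(R1, R2, tolerance = 1e-8)
})

test_that("kinetic energy decays without boundary forcing", {
  mesh <- make_geometry(geometry_preset("plane_channel",
    length_mm = 10, gap_mm = 4, depth_mm = 1, cell_mm = 0.25, axial_cell_mm = 0.5
  ))
  ops <- assemble_operators(mesh, fluid_properties(), dt = 5e-3)
  nz <- ops$nz
  nr <- ops$nr
  # divergence-free initial field from a stream function on the corners
  zf <- mesh$z_f / mesh$preset$length_mm
  ef <- mesh$eta_f
  psi <- outer(sin(pi * zf)^2, sin(pi * ef)^2) * 1e-10 # m^3/s flux scale
  u0 <- matrix(0, ops$NIu, nr)
  v0 <- matrix(0, nz, nr + 1)
  u0[, ] <- (psi[, 2:(nr + 1)] - psi[, 1:nr]) / matrix(ops$Au, ops$NIu, nr)
  v0[, ] <- -(psi[2:(nz + 1), ] - psi[1:nz, ]) / matrix(ops$Av, nz, nr + 1)
  st <- flow_state_zero(ops)
  st$u <- as.vector(u0)
  st$v <- as.vector(v0)
  st$u[!as.vector(ops$int_u)] <- 0
  st$v[!as.vector(ops$int_v)] <- 0
  ke <- function(s) sum(s$u^2) + sum(s$v^2)
  k_prev <- ke(st)
  for (n in 1:20) {
    st <- ipcs_step(st, ops)
    k_now <- ke(st)
    expect_lte(k_now, k_prev * (1 + 1e-12))
    k_prev <- k_now
  }
})

test_that("an absurdly large time step triggers the CFL guard", {
  mesh <- make_geometry(geometry_preset("plane_channel",
    length_mm = 10, gap_mm = 4, depth_mm = 1, cell_mm = 0.5, axial_cell_mm = 1
  ))
  s <- make_waveform(waveform_preset(71, 2e5, 0.26, 0.08))
  expect_error(
    run_cycles(mesh, list(cervical = s), solver_config(cycles = 1, dt = 0.05)),
    "CFL"
  )
})

test_that("shipped-preset runs satisfy the discrete conservation invariants", {
  sp <- stenosed_pair()
  br <- branched_run()
  for (run in list(sp$coarse, sp$fine, br)) {
    expect_lt(run$div_max, run$config$p_tol)
    expect_lt(run$mass_residual, 1e-8 * run$peak_flux)
    expect_lt(run$cfl_max, 1)
  }
})
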