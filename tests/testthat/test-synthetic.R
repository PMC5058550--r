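test_that("cervical presets hit their published timing targets", {
  tab <- waveform_presets()
  cs <- tab[is.na(tab$base_cs), ]
  for (k in seq_len(nrow(cs))) {
    s <- make_waveform(cs$name[k])
    m <- cycle_metrics(align_cycle_origin(fit_periodic_spline(s)))
    expect_equal(m$caudal_fraction, cs$caudal_fraction[k],
      tolerance = 0.01 / cs$caudal_fraction[k], label = cs$name[k]
    )
    expect_equal(m$t_peak_systole, cs$peak_time[k],
      tolerance = 0.01 / cs$peak_time[k], label = cs$name[k]
    )
    expect_equal(abs(m$Q_max_systolic), cs$amplitude[k],
      tolerance = 0.01, label = cs$name[k]
    )
    expect_equal(s$heart_rate, cs$heart_rate[k])
  }
})

test_that("symmetric half-cycle target with one harmonic is a pure sinusoid", {
  s <- make_waveform(waveform_preset(60, 100, 0.5, 0.25, harmonics = 1))
  tg <- seq(0, 1, length.out = 333)
  expect_equal(eval_waveform(s$wave, tg), -100 * sin(2 * pi * tg),
    tolerance = 0.01 * 100
  )
})

test_that("infeasible targets fail with the violated target named", {
  expect_error(
    make_waveform(waveform_preset(60, 100, 0.99, 0.5, harmonics = 2)),
    "caudal_fraction"
  )
})

test_that("generation is deterministic and noise-free output is seed-independent", {
  p1 <- waveform_preset(71, 4000, 0.26, 0.08, noise_snr = 20, seed = 5)
  expect_identical(make_waveform(p1)$fluxes, make_waveform(p1)$fluxes)
  p2 <- waveform_preset(71, 4000, 0.26, 0.08, noise_snr = 20, seed = 6)
  expect_false(identical(make_waveform(p1)$fluxes, make_waveform(p2)$fluxes))
  # noise-free: seed irrelevant
  q1 <- make_waveform(waveform_preset(71, 4000, 0.26, 0.08, seed = 1))
  q2 <- make_waveform(waveform_preset(71, 4000, 0.26, 0.08, seed = 99))
  expect_identical(q1$fluxes, q2$fluxes)
  # generation does not disturb the caller's RNG stream
  set.seed(42)
  r1 <- runif(1)
  set.seed(42)
  invisible(make_waveform(p1))
  expect_identical(runif(1), r1)
})

test_that("noise-free waveforms have the configured net flow (zero mean)", {
  for (nm in c("CON1_CS", "P1_CS", "P2_CS")) {
    s <- make_waveform(nm)
    tg <- (0:16383) / 16384 * s$period
    expect_lt(abs(mean(eval_waveform(s$wave, tg))), 1e-6 * max(abs(s$fluxes)))
  }
})

test_that("aqueduct pair has exact flux ratio and the requested delay", {
  pair <- make_aqueduct_pair("CON1_CS", delay = 0.28, flux_ratio = 0.10)
  pk_cs <- csfflow:::waveform_extremum(pair$cervical$wave)[2]
  pk_aq <- csfflow:::waveform_extremum(pair$aqueduct$wave)[2]
  expect_equal(abs(pk_aq / pk_cs), 0.10, tolerance = 1e-12)
  d <- delay_between(
    fit_periodic_spline(pair$cervical),
    fit_periodic_spline(pair$aqueduct)
  )
  expect_equal(d, 0.28, tolerance = 0.01)

  same <- make_aqueduct_pair("CON1_CS", delay = 0, flux_ratio = 1)
  expect_equal(same$aqueduct$fluxes, same$cervical$fluxes, tolerance = 1e-9)
})

test_that("annulus mesh reports exact end areas and the stenosis min gap", {
  mesh <- make_geometry("annulus_stenosed")
  p <- mesh$preset
  a_exact <- pi * ((p$inner_radius_mm + p$gap_mm)^2 - p$inner_radius_mm^2)
  expect_equal(boundary_area(mesh, "cervical"), a_exact, tolerance = 1e-10)
  expect_equal(boundary_area(mesh, "cranial"), a_exact, tolerance = 1e-10)
  expect_equal(min(mesh$gap_f), (1 - p$occlusion) * p$gap_mm, tolerance = 1e-10)
  # resolution convergence of reported areas (exact here)
  mesh2 <- make_geometry("annulus_stenosed", refine = 2)
  expect_equal(boundary_area(mesh2, "cervical"), a_exact, tolerance = 1e-10)
})

test_that("branched mesh has the requested topology and inlet areas", {
  mesh <- make_geometry("branched_small")
  p <- mesh$preset
  expect_setequal(
    names(mesh$boundaries),
    c("cervical", "cistern", "aqueduct")
  )
  expect_equal(boundary_area(mesh, "cervical"), p$gap_mm * p$depth_mm)
  expect_equal(boundary_area(mesh, "aqueduct"), p$arm_width_mm * p$depth_mm)
  # equal cistern/aqueduct areas when the arm is as wide as the main channel
  pe <- geometry_preset("branched_two_inlet",
    length_mm = 60, gap_mm = 6, occlusion = 0.5,
    stenosis_centre_mm = 28.5, stenosis_extent_mm = 9, depth_mm = 30,
    cell_mm = 0.75, arm_length_mm = 15, arm_width_mm = 6, arm_z_mm = 42
  )
  me <- make_geometry(pe)
  expect_equal(boundary_area(me, "cistern"), boundary_area(me, "aqueduct"),
    tolerance = 0.75 * 30 / boundary_area(me, "aqueduct")
  )
})

test_that("unresolvable stenoses and invalid presets are rejected", {
  expect_error(
    geometry_preset("axisymmetric_annulus",
      gap_mm = 3, occlusion = 0.9,
      cell_mm = 0.25
    ),
    "stenosis unresolved"
  )
  expect_error(geometry_preset(occlusion = 1), "occlusion")
  expect_error(geometry_preset(gap_mm = -1), "positive")
  expect_error(make_geometry("nope"), "unknown geometry preset")
})
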