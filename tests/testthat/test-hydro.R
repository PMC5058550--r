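test_that("pressure-drop series is the pointwise upstream-downstream difference", {
  t <- seq(0, 1, by = 0.1)
  a <- data.frame(t_s = t, p_Pa = rep(5, 11))
  b <- data.frame(t_s = t, p_Pa = rep(2, 11))
  expect_equal(pressure_drop_series(a, a)$dp_Pa, rep(0, 11))
  expect_equal(pressure_drop_series(a, b)$dp_Pa, rep(3, 11))
  bad <- data.frame(t_s = t + 0.05, p_Pa = rep(2, 11))
  expect_error(pressure_drop_series(a, bad), "shared time grid")
})

test_that("all pressure measures are invariant to a constant pressure offset", {
  run <- branched_run()
  a <- probe_trace(run, "PC")
  b <- probe_trace(run, "CS")
  d0 <- pressure_drop_series(a, b)
  a$p_Pa <- a$p_Pa + 123.4
  b$p_Pa <- b$p_Pa + 123.4
  d1 <- pressure_drop_series(a, b)
  expect_equal(d1$dp_Pa, d0$dp_Pa, tolerance = 1e-12)
})

test_that("the telescoping station identity holds pointwise", {
  run <- branched_run()
  d1 <- pressure_drop_series(run, "PC", "CS")
  d2 <- pressure_drop_series(run, "Aq", "PC")
  pa <- probe_trace(run, "Aq")
  pc <- probe_trace(run, "CS")
  expect_equal(d1$dp_Pa + d2$dp_Pa, pa$p_Pa - pc$p_Pa, tolerance = 1e-12)
})

test_that("pressure gradients reproduce the reference worked values", {
  # 75 mm between the cervical (35 mm) and pontine (110 mm) stations
  expect_equal(round(pressure_gradient(33.6, 110, 35), 1), 4.5)
  expect_equal(round(pressure_gradient(44.4, 110, 35), 1), 5.9)
  expect_equal(round(pressure_gradient(83.9, 110, 35), 1), 11.2)
  expect_equal(pressure_gradient(0, 110, 35), 0)
  expect_error(pressure_gradient(10, 50, 50), "zero separation")
})

test_that("resistance has the dimensionally fixed unit conversion", {
  # 1 Pa = 1 g/(mm s^2), so Pa per (mm^3/s) is g/(mm^4 s) with factor 1
  expect_equal(resistance(7.5, 7.5), 1)
  # hand-computed reference-scale case: 33.6 Pa at 4200 mm^3/s
  expect_equal(resistance(33.6, 4200), 0.008)
  expect_error(resistance(10, 0), "nonzero")
})

test_that("phase difference follows its definition and sign convention", {
  expect_equal(phase_difference(0.2, 0.2, 0.3), 0)
  # pressure peak lagging the velocity peak by half the caudal time
  expect_equal(phase_difference(0.2, 0.2 + 0.15, 0.3), -0.5)
  expect_error(phase_difference(0.1, 0.2, 0), "T_caudal")
})

test_that("inertia-dominated oscillatory channel phase matches the closed form", {
  wf <- womersley_fixture(32)
  run <- wf$run
  orc <- wf$oracle
  s <- hydro_summary(run)
  # analytic peak times: dp(PC-CS) = -Re[K e^{iwt}] * Lsep (PC above CS);
  # systolic speed peak from the centreline velocity phase
  T <- wf$period
  w <- orc$omega
  t_dp_ex <- ((pi - Arg(orc$K)) / w) %% T
  uc <- function(t) orc$fun(2, t) # centreline, gap/2 = 2 mm
  tg <- seq(0, T / 2, length.out = 4001) # systole: Q = -Q0 sin < 0 here
  t_u_ex <- tg[which.max(abs(uc(tg)))]
  theta_ex <- (t_u_ex - t_dp_ex) / (T / 2)
  expect_lt(abs(s$theta - theta_ex), 0.05)
  # at Womersley number ~6.5 the drop is inertia-dominated: theta near +1/2
  expect_equal(theta_ex, 0.5, tolerance = 0.1)
})

test_that("peak stenosed velocity sits in the throat/jet region", {
  run <- stenosed_pair()$coarse
  pk_all <- peak_velocity(run, NULL)
  pk_fm <- peak_velocity(run, "FM")
  expect_equal(pk_all$umax_mms, pk_fm$umax_mms)
  p <- run$mesh$preset
  expect_gte(pk_all$z_mm, p$stenosis_centre_mm - p$stenosis_extent_mm / 2 - p$gap_mm)
  expect_lte(pk_all$z_mm, p$stenosis_centre_mm + p$stenosis_extent_mm / 2 + p$gap_mm)
  expect_error(peak_velocity(run, c(1e4, 2e4)), "empty region")
})

test_that("bidirectional fraction detects counter-flow and vortex shedding", {
  # constructed slices: unidirectional pulsatile profile -> 0
  y <- seq(0, 1, length.out = 16)
  prof <- y * (1 - y)
  uni <- outer(prof, sin(2 * pi * (1:32) / 32))
  expect_equal(bidirectional_fraction(uni), 0)
  # superposed counter-flow at all times -> 1
  counter <- outer(sin(2 * pi * y), rep(1, 32))
  expect_equal(bidirectional_fraction(counter), 1)
  expect_error(bidirectional_fraction(uni[1:4, ]), "8 sample points")
  # paired simulations: the stenosed annulus sheds vortices downstream of the
  # throat, the straight annulus does not
  bp <- bidir_pair()
  z_probe <- 38 # downstream half of the stenosis, where the jet separates
  f_sten <- bidirectional_fraction(bp$stenosed, z_probe)
  f_straight <- bidirectional_fraction(bp$straight, z_probe)
  expect_gt(f_sten, f_straight)
})

test_that("across-subject ratios reproduce the reference comparisons", {
  subj <- example_subjects()
  rs <- subject_ratio_stats(subj)
  expect_equal(unname(rs$ratios["umax_CS_mms"]), 2.3)
  expect_equal(unname(rs$ratios["umax_Aq_mms"]), 3.5)
  expect_equal(unname(rs$ratios["dp_Aq_PC_max_Pa"]), 9.4)
  expect_equal(rs$pairwise$dp_Aq_PC_max_Pa["Con1", "P2"], 1.6)
  # identical subjects give unit ratios; zero minima are flagged undefined
  same <- subj[c(1, 1), ]
  rs2 <- subject_ratio_stats(same)
  expect_true(all(rs2$ratios == 1, na.rm = TRUE))
  z <- subj
  z$umax_CS_mms[1] <- 0
  rs3 <- subject_ratio_stats(z)
  expect_true("umax_CS_mms" %in% rs3$undefined)
  expect_error(subject_ratio_stats(subj[1, ]), "at least 2")
})

test_that("hydro summary reports a coherent measure table", {
  run <- branched_run()
  s <- hydro_summary(run)
  expect_gte(s$dp_PC_CS_max_Pa, s$dp_PC_CS_min_Pa)
  expect_gte(s$dp_Aq_PC_max_Pa, s$dp_Aq_PC_min_Pa)
  expect_gt(s$R_PC_CS_sys, 0)
  expect_gt(s$R_Aq_PC_sys, 0)
  expect_equal(s$Q_CS_sys_mm3s, -4000, tolerance = 0.01)
  f <- format_hydro_summary(s)
  expect_equal(f$umax_CS_mms, round(s$umax_CS_mms))
  expect_equal(f$R_PC_CS_sys, round(s$R_PC_CS_sys, 3))
})
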