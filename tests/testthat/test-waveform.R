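test_that("periodic spline interpolates samples exactly and wraps C2-smoothly", {
  T <- 60 / 71
  times <- (0:31) * T / 32
  fl <- 100 * sin(2 * pi * times / T) + 30 * cos(4 * pi * times / T)
  s <- flux_series(times, fl, heart_rate = 71)
  w <- fit_periodic_spline(s)
  expect_equal(eval_waveform(w, times), fl, tolerance = 1e-12)
  # exact periodicity
  tg <- seq(0, T, length.out = 97)
  expect_equal(eval_waveform(w, tg + 5 * T), eval_waveform(w, tg), tolerance = 1e-12)
  # C2 across the seam: second difference continuous through t = 0
  h <- 1e-4
  d2 <- function(t) (eval_waveform(w, t + h) - 2 * eval_waveform(w, t) + eval_waveform(w, t - h)) / h^2
  expect_lt(abs(d2(1e-6) - d2(-1e-6)), 1e-2 * abs(d2(0)) + 1e-6)
})

test_that("spline error on a band-limited signal is small and ~4th order", {
  T <- 1
  err_for <- function(n) {
    times <- (0:(n - 1)) * T / n
    s <- flux_series(times, sin(2 * pi * times / T), heart_rate = 60)
    w <- fit_periodic_spline(s)
    tg <- seq(0, T, length.out = 2001)
    max(abs(eval_waveform(w, tg) - sin(2 * pi * tg / T)))
  }
  e32 <- err_for(32)
  e16 <- err_for(16)
  expect_lt(e32, 0.01) # < 1 % of unit amplitude
  expect_gt(e16 / e32, 8) # 4th-order interpolation (16 expected)
})

test_that("constant samples give a constant spline", {
  times <- (0:15) / 16
  s <- flux_series(times, rep(7.5, 16), heart_rate = 60)
  w <- fit_periodic_spline(s)
  tg <- seq(-1, 2, by = 0.013)
  expect_equal(eval_waveform(w, tg), rep(7.5, length(tg)), tolerance = 1e-12)
})

test_that("waveform CSV round trip is bit-exact and errors are caught", {
  s <- make_waveform("CON1_CS")
  tmp <- tempfile(fileext = ".csv")
  write_flux_csv(s, tmp)
  s2 <- read_flux_csv(tmp)
  expect_identical(s2$times, s$times)
  expect_identical(s2$fluxes, s$fluxes)
  expect_identical(s2$heart_rate, s$heart_rate)
  expect_identical(s2$site, s$site)

  # headerless file: heart rate inferred from the span
  tmp2 <- tempfile(fileext = ".csv")
  times <- seq(0, 0.845, length.out = 32)
  utils::write.csv(data.frame(t = times, q = sin(2 * pi * times / 0.845)),
    tmp2,
    row.names = FALSE
  )
  s3 <- read_flux_csv(tmp2)
  expect_equal(s3$heart_rate, 60 / 0.845, tolerance = 1e-9)

  expect_error(flux_series(sample(1:32), rnorm(32), 60), "increasing")
  expect_error(flux_series((0:6) / 8, rnorm(7), 60), "8 samples.*7")
  expect_error(read_flux_csv(tempfile()), "not found")
})

test_that("cycle-origin alignment finds flow reversal and is idempotent", {
  T <- 0.8
  times <- (0:31) * T / 32
  shift_true <- 0.1 * T
  s <- flux_series(times, -sin(2 * pi * (times - shift_true) / T), heart_rate = 75)
  w <- fit_periodic_spline(s)
  a <- align_cycle_origin(w)
  # root found to 1e-6 of the period in time, so |Q(0)| <~ |Q'| * 1e-6 T
  expect_lt(abs(eval_waveform(a, 0)), 1e-4)
  expect_lt(eval_waveform(a, 1e-3 * T), 0) # enters caudal phase
  expect_equal(a$shift %% T, shift_true, tolerance = 1e-4 * T)
  a2 <- align_cycle_origin(a)
  expect_lt(abs(a2$shift) %% T, 1e-5 * T)
  tg <- seq(0, T, length.out = 101)
  expect_equal(eval_waveform(a2, tg), eval_waveform(a, tg), tolerance = 1e-4)

  s_pos <- flux_series(times, rep(5, 32) + 0.1 * sin(2 * pi * times / T), heart_rate = 75)
  expect_error(align_cycle_origin(fit_periodic_spline(s_pos)), "no flow reversal")
})

test_that("cycle metrics match symmetry and a brute-force dense oracle", {
  T <- 0.9
  times <- (0:31) * T / 32
  s <- flux_series(times, -sin(2 * pi * times / T), heart_rate = 60 / T)
  m <- cycle_metrics(align_cycle_origin(fit_periodic_spline(s)))
  expect_equal(m$caudal_fraction, 0.5, tolerance = 1e-3)
  expect_equal(m$t_peak_systole, 0.25, tolerance = 1e-3)
  expect_lte(m$Q_max_systolic, 0)
  expect_gte(m$Q_max_diastolic, 0)

  # asymmetric two-harmonic waveform vs an independent dense scan of the
  # closed form
  f <- function(t) -sin(2 * pi * t / T) + 0.45 * cos(4 * pi * t / T + 0.6)
  sa <- flux_series(times, f(times), heart_rate = 60 / T)
  wa <- align_cycle_origin(fit_periodic_spline(sa))
  ma <- cycle_metrics(wa)
  tg <- (0:999999) / 1e6 * T
  qg <- f(tg + wa$shift)
  expect_equal(ma$caudal_fraction, mean(qg < 0), tolerance = 2e-3)
  expect_equal(ma$Q_max_systolic, min(qg), tolerance = 2e-3)
  expect_equal(ma$t_peak_systole, tg[which.min(qg)] / T, tolerance = 2e-3)
})

test_that("cycle metrics are invariant under time shift plus re-alignment", {
  s <- make_waveform("P2_CS")
  w <- align_cycle_origin(fit_periodic_spline(s))
  m0 <- cycle_metrics(w)
  for (sh in c(0.13, 0.61)) {
    f0 <- w$fun
    shifted <- csfflow:::new_spline_waveform(
      function(t) f0(t + sh * w$period), w$period
    )
    m1 <- cycle_metrics(align_cycle_origin(shifted))
    expect_equal(m1$caudal_fraction, m0$caudal_fraction, tolerance = 1e-4)
    expect_equal(m1$t_peak_systole, m0$t_peak_systole, tolerance = 1e-4)
  }
})

test_that("systolic-peak delay between waveforms is recovered", {
  s <- make_waveform("CON1_CS")
  w <- fit_periodic_spline(s)
  expect_equal(delay_between(w, w), 0, tolerance = 1e-6)
  f0 <- w$fun
  for (d in c(0.28, 0.8)) {
    ws <- csfflow:::new_spline_waveform(
      function(t) f0(t - d * w$period), w$period
    )
    expect_equal(delay_between(w, ws), d, tolerance = 1e-4)
  }
  wbad <- csfflow:::new_spline_waveform(function(t) sin(t), 1)
  expect_error(delay_between(w, wbad), "unequal periods")
})
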