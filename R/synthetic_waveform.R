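#' Named waveform presets
#'
#' Subject-like cervical (CS) and aqueduct (Aq) waveform presets. The cervical
#' presets target the published per-subject cycle statistics (heart rate,
#' caudal-flow fraction of the cycle, systolic-peak time); the aqueduct presets
#' are delayed, amplitude-scaled copies of the corresponding cervical waveform
#' (delay as a cycle fraction; flux ratio ~0.10, since only about a tenth of
#' the CSF flow below the foramen magnum originates in the ventricular system).
#' Amplitudes are not published as tables; defaults are chosen so that peak
#' velocities in the idealized geometries land in the physiological
#' 10-100 mm/s range.
#'
#' @return A data.frame, one row per preset.
#' @export
waveform_presets <- function() {
  data.frame(
    name = c("CON1_CS", "P1_CS", "P2_CS", "CON1_AQ", "P1_AQ", "P2_AQ"),
    heart_rate = c(71, 86, 77, 71, 86, 77),
    amplitude = c(4000, 3000, 5000, 400, 300, 500),
    caudal_fraction = c(0.26, 0.47, 0.37, 0.26, 0.47, 0.37),
    peak_time = c(0.08, 0.175, 0.14, 0.08, 0.175, 0.14),
    aq_delay = c(NA, NA, NA, 0.28, 0.15, 0.16),
    aq_ratio = c(NA, NA, NA, 0.10, 0.10, 0.10),
    base_cs = c(NA, NA, NA, "CON1_CS", "P1_CS", "P2_CS"),
    stringsAsFactors = FALSE
  )
}

#' Waveform preset constructor
#'
#' @param heart_rate Heart rate, beats/minute.
#' @param amplitude Peak systolic |flux|, mm^3/s (> 0).
#' @param caudal_fraction Target fraction of the cycle with caudal (negative)
#'   flow, in (0, 1).
#' @param peak_time Target cycle fraction (from flow reversal) of the systolic
#'   peak, in (0, caudal_fraction).
#' @param harmonics Number of Fourier harmonics (>= 1; default 12, well below
#'   the 16-harmonic Nyquist limit of 32 samples/cycle).
#' @param noise_snr Signal-to-noise ratio for optional Gaussian sample noise
#'   (`NULL` for noise-free).
#' @param seed Integer seed used only when noise is requested.
#' @param offset Net (cycle-mean) flux, mm^3/s; default 0 for a rigid domain.
#' @param n_samples Samples per cycle (default 32, the usual PC-MRI phase count).
#' @param name Preset label.
#' @return A list of class `waveform_preset`.
#' @export
waveform_preset <- function(heart_rate, amplitude, caudal_fraction, peak_time,
                            harmonics = 12, noise_snr = NULL, seed = 1L,
                            offset = 0, n_samples = 32, name = "custom") {
  if (!(caudal_fraction > 0 && caudal_fraction < 1)) {
    stop("caudal_fraction must be in (0, 1)")
  }
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (!(peak_time > 0 && peak_time < caudal_fraction)) {
    stop("peak_time must lie inside the caudal phase (0, caudal_fraction)")
  }
  if (harmonics < 1) stop("harmonics must be >= 1")
  if (n_samples < 8) stop("n_samples must be >= 8")
  structure(
    list(
      heart_rate = heart_rate, amplitude = amplitude,
      caudal_fraction = caudal_fraction, peak_time = peak_time,
      harmonics = as.integer(harmonics), noise_snr = noise_snr,
      seed = as.integer(seed), offset = offset,
      n_samples = as.integer(n_samples), name = name
    ),
    class = "waveform_preset"
  )
}

resolve_waveform_preset <- function(preset, ...) {
  if (inherits(preset, "waveform_preset")) {
    return(preset)
  }
  if (is.character(preset)) {
    tab <- waveform_presets()
    row <- tab[tab$name == preset, ]
    if (!nrow(row)) {
      stop(sprintf(
        "unknown preset '%s'; known: %s", preset,
        paste(tab$name, collapse = ", ")
      ))
    }
    if (!is.na(row$base_cs)) {
      # aqueduct preset: built from its cervical base via delay/ratio
      return(structure(
        list(
          base_cs = row$base_cs, delay = row$aq_delay,
          ratio = row$aq_ratio, name = row$name
        ),
        class = "aq_preset"
      ))
    }
    return(waveform_preset(
      heart_rate = row$heart_rate, amplitude = row$amplitude,
      caudal_fraction = row$caudal_fraction, peak_time = row$peak_time,
      name = row$name, ...
    ))
  }
  stop("preset must be a waveform_preset or a preset name")
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Asymmetric two-lobe target shape on cycle fraction x in [0,1):
# caudal lobe (negative) on [0, f] peaking (value -1) at x = xp, diastolic
# sine lobe on [f, 1] scaled for zero mean. C1 at the lobe peak; both lobes
# have mean 2/pi times their amplitude, so the zero-mean diastolic amplitude
# is f/(1-f).
target_shape <- function(x, f, xp) {
  x <- x %% 1
  y <- x / f
  yp <- xp / f
  caudal <- ifelse(
    y <= yp,
    sin(pi * y / (2 * yp)),
    cos(pi * (y - yp) / (2 * (1 - yp)))
  )
  dia <- (f / (1 - f)) * sin(pi * (x - f) / (1 - f))
  ifelse(x <= f, -caudal, dia)
}

# Least-squares projection of the target shape onto K harmonics (uniform dense
# grid): returns list(a, b) of cosine/sine coefficients.
fourier_fit_shape <- function(f, xp, K, n = 4096) {
  x <- (0:(n - 1)) / n
  q <- target_shape(x, f, xp)
  a <- numeric(K)
  b <- numeric(K)
  for (k in seq_len(K)) {
    a[k] <- 2 * mean(q * cos(2 * pi * k * x))
    b[k] <- 2 * mean(q * sin(2 * pi * k * x))
  }
  list(a = a, b = b)
}

fourier_eval <- function(tfrac, a, b, offset = 0) {
  out <- rep(offset, length(tfrac))
  for (k in seq_along(a)) {
    out <- out + a[k] * cos(2 * pi * k * tfrac) + b[k] * sin(2 * pi * k * tfrac)
  }
  out
}

#' Generate a synthetic flux waveform from a preset
#'
#' Builds a truncated Fourier series (offset plus `harmonics` harmonics) whose
#' coefficients are obtained by least-squares projection of an asymmetric
#' two-lobe target shape, with the shape parameters iterated (deterministically)
#' until the dense-grid caudal fraction and systolic-peak time of the series
#' match the preset targets to within 0.002 of a cycle, and the amplitude
#' matches exactly by scaling. The result is sampled at `n_samples` uniform
#' phases; optional Gaussian noise (sd = amplitude / noise_snr) is added using
#' the preset seed without disturbing the caller's RNG state.
#'
#' @param preset A [waveform_preset], or a preset name from
#'   [waveform_presets()].
#' @param ... Passed to [waveform_preset()] when `preset` is a name
#'   (e.g. `noise_snr`, `seed`).
#' @return A [flux_series] with an extra field `wave`: the exact continuous
#'   `spline_waveform` of the Fourier synthesis.
#' @export
make_waveform <- function(preset, ...) {
  p <- resolve_waveform_preset(preset, ...)
  if (inherits(p, "aq_preset")) {
    pair <- make_aqueduct_pair(p$base_cs, delay = p$delay, flux_ratio = p$ratio, ...)
    return(pair$aqueduct)
  }
  T <- 60 / p$heart_rate
  f_used <- p$caudal_fraction
  xp_used <- p$peak_time
  tol <- 2e-3
  coef <- NULL
  meas <- NULL
  for (it in seq_len(50)) {
    if (f_used <= 0.02 || f_used >= 0.98 || xp_used <= 0.2 * f_used ||
      xp_used >= 0.98 * f_used) {
      break
    }
    coef <- fourier_fit_shape(f_used, xp_used, p$harmonics)
    wv <- new_spline_waveform(
      function(t) fourier_eval(t / T, coef$a, coef$b), T
    )
    wv <- align_cycle_origin(wv)
    meas <- cycle_metrics(wv)
    err_f <- p$caudal_fraction - meas$caudal_fraction
    err_p <- p$peak_time - meas$t_peak_systole
    if (abs(err_f) < tol && abs(err_p) < tol) break
    f_used <- f_used + 0.8 * err_f
    xp_used <- xp_used + 0.8 * err_p
  }
  if (is.null(meas) ||
    abs(p$caudal_fraction - meas$caudal_fraction) > 0.01) {
    stop(sprintf(
      "cannot meet target caudal_fraction = %g with %d harmonics",
      p$caudal_fraction, p$harmonics
    ))
  }
  if (abs(p$peak_time - meas$t_peak_systole) > 0.01) {
    stop(sprintf(
      "cannot meet target peak_time = %g with %d harmonics",
      p$peak_time, p$harmonics
    ))
  }
  # scale harmonics so the systolic peak equals -amplitude exactly, then add
  # the net-flow offset; align the origin of the final series
  scale <- p$amplitude / abs(meas$Q_max_systolic)
  a <- coef$a * scale
  b <- coef$b * scale
  wv <- new_spline_waveform(
    function(t) fourier_eval(t / T, a, b, offset = p$offset), T,
    heart_rate = p$heart_rate, site = p$name
  )
  wv <- align_cycle_origin(wv)
  times <- (0:(p$n_samples - 1)) * T / p$n_samples
  fluxes <- wv$fun(times)
  if (!is.null(p$noise_snr)) {
    fluxes <- fluxes + with_local_seed(
      p$seed,
      stats::rnorm(length(fluxes), sd = p$amplitude / p$noise_snr)
    )
  }
  out <- flux_series(times, fluxes, heart_rate = p$heart_rate, site = p$name)
  out$wave <- wv
  out
}

#' Generate a matched cervical/aqueduct waveform pair
#'
#' The aqueduct waveform is a time-shifted (by `delay` cycle fractions),
#' amplitude-scaled (by `flux_ratio`) copy of the cervical waveform, emulating
#' the observed lag of aqueduct flow behind cervical flow and the ~10% flux
#' share of the ventricular route.
#'
#' @param cs_preset Cervical preset ([waveform_preset] or name).
#' @param delay Cycle-fraction delay of the aqueduct systolic peak, in `[0, 1)`.
#' @param flux_ratio Peak-flux ratio aqueduct/cervical (> 0; default 0.10).
#' @param ... Passed to [make_waveform()] for the cervical series.
#' @return A list with elements `cervical` and `aqueduct`, both [flux_series]
#'   with continuous `wave` fields.
#' @export
make_aqueduct_pair <- function(cs_preset, delay = 0.28, flux_ratio = 0.10, ...) {
  if (!(delay >= 0 && delay < 1)) stop("delay must be in [0, 1)")
  if (!(flux_ratio > 0)) stop("flux_ratio must be > 0")
  cs <- make_waveform(cs_preset, ...)
  T <- cs$period
  cs_fun <- cs$wave$fun
  aq_fun <- function(t) flux_ratio * cs_fun(t - delay * T)
  aq_wave <- new_spline_waveform(aq_fun, T,
    origin_aligned = FALSE,
    heart_rate = cs$heart_rate,
    site = paste0(cs$site, "_AQ")
  )
  aq <- flux_series(cs$times, aq_fun(cs$times),
    heart_rate = cs$heart_rate,
    site = aq_wave$site
  )
  aq$wave <- aq_wave
  list(cervical = cs, aqueduct = aq)
}
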