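#' Sampled periodic volumetric flux waveform
#'
#' Container for one cardiac cycle of volumetric flux samples as measured by
#' phase-contrast MRI at a single site (e.g. the cervical subarachnoid space at
#' C1, or the aqueduct). Negative flux is caudal (systolic) flow; positive flux
#' is cranial (diastolic) flow.
#'
#' @param times Numeric vector of sample times in seconds, strictly increasing,
#'   covering one cardiac cycle.
#' @param fluxes Numeric vector of volumetric fluxes in mm^3/s, same length as
#'   `times`, all finite.
#' @param heart_rate Heart rate in beats per minute. If `NULL`, it is inferred
#'   from the sample span as `60 / (max(times) - min(times))`, which is
#'   approximate (it ignores the gap between the last sample and the cycle
#'   wrap).
#' @param site Free-text site label, e.g. `"CS"` or `"Aq"`.
#'
#' @return An object of class `flux_series` with fields `times`, `fluxes`,
#'   `heart_rate`, `period` (seconds) and `site`.
#' @export
flux_series <- function(times, fluxes, heart_rate = NULL, site = "") {
  if (!is.numeric(times) || !is.numeric(fluxes)) {
    stop("times and fluxes must be numeric")
  }
  if (length(times) != length(fluxes)) {
    stop("times and fluxes must have equal length")
  }
  n <- length(times)
  if (n < 8) {
    stop(sprintf("at least 8 samples are required, got %d", n))
  }
  if (anyNA(times) || any(!is.finite(times))) stop("times must be finite")
  if (anyNA(fluxes) || any(!is.finite(fluxes))) stop("fluxes must be finite")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times not strictly increasing")
  span <- times[n] - times[1]
  if (is.null(heart_rate)) {
    heart_rate <- 60 / span
  }
  if (!is.finite(heart_rate) || heart_rate <= 0) {
    stop("heart_rate must be a positive number")
  }
  period <- 60 / heart_rate
  # The samples must cover the cycle: span and period may differ by at most one
  # sample spacing (the wrap gap).
  if (abs(period - span) > max(dt) * (1 + 1e-8)) {
    stop(sprintf(
      "sample span %.6g s inconsistent with period %.6g s (60/heart_rate): difference exceeds one sample spacing",
      span, period
    ))
  }
  structure(
    list(
      times = as.numeric(times), fluxes = as.numeric(fluxes),
      heart_rate = heart_rate, period = period, site = as.character(site)[1]
    ),
    class = "flux_series"
  )
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf(
    "<flux_series> site='%s', %d samples, heart rate %.1f bpm (period %.4g s)\n",
    x$site, length(x$times), x$heart_rate, x$period
  ))
  cat(sprintf(
    "  flux range [%.4g, %.4g] mm^3/s\n",
    min(x$fluxes), max(x$fluxes)
  ))
  invisible(x)
}

#' Read a flux waveform from CSV
#'
#' Reads a two-column CSV (`time_s`, `flux_mm3_per_s`; header optional; comment
#' lines start with `#`). A comment header of the form `# heart_rate_bpm: 71`
#' is honoured; otherwise the heart rate is inferred from the sample span.
#' A `# site: CS` comment sets the site label.
#'
#' @param path Path to the CSV file.
#' @return A [flux_series].
#' @export
read_flux_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  comments <- grep("^\\s*#", lines, value = TRUE)
  hr <- NULL
  site <- ""
  m <- grep("heart_rate_bpm", comments, value = TRUE)
  if (length(m)) hr <- as.numeric(sub(".*heart_rate_bpm\\s*[:=]\\s*", "", m[1]))
  m <- grep("site", comments, value = TRUE)
  if (length(m)) site <- trimws(sub(".*site\\s*[:=]\\s*", "", m[1]))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows found")
  has_header <- !grepl("^\\s*[-+0-9.eE]", body[1])
  df <- utils::read.csv(
    text = paste(body, collapse = "\n"),
    header = has_header, stringsAsFactors = FALSE
  )
  if (ncol(df) < 2) stop("expected two numeric columns (time, flux)")
  times <- suppressWarnings(as.numeric(df[[1]]))
  fluxes <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(times) || anyNA(fluxes)) stop("non-numeric values in time/flux columns")
  flux_series(times, fluxes, heart_rate = hr, site = site)
}

#' Write a flux waveform to CSV
#'
#' Writes the standard waveform CSV format (`time_s`, `flux_mm3_per_s`) with
#' `# heart_rate_bpm` and `# site` comment headers, at full double precision so
#' a written-then-read round trip is bit-exact.
#'
#' @param series A [flux_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(series, path) {
  stopifnot(inherits(series, "flux_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# site: %s", series$site),
    sprintf("# heart_rate_bpm: %s", format(series$heart_rate, digits = 17)),
    "time_s,flux_mm3_per_s"
  ), con)
  writeLines(paste(
    format(series$times, digits = 17, scientific = FALSE, trim = TRUE),
    format(series$fluxes, digits = 17, trim = TRUE),
    sep = ","
  ), con)
  invisible(path)
}

#' Construct a periodic waveform object from an evaluator function
#'
#' Internal-facing constructor shared by the spline fit and the synthetic
#' Fourier generator. `fun` must already be periodic with period `period`.
#' @keywords internal
#' @noRd
new_spline_waveform <- function(fun, period, origin_aligned = FALSE,
                                heart_rate = 60 / period, site = "",
                                knots = NULL) {
  structure(
    list(
      fun = fun, period = period, origin_aligned = origin_aligned,
      heart_rate = heart_rate, site = site, knots = knots
    ),
    class = "spline_waveform"
  )
}

#' @export
print.spline_waveform <- function(x, ...) {
  cat(sprintf(
    "<spline_waveform> site='%s', period %.4g s, origin %s\n",
    x$site, x$period,
    if (isTRUE(x$origin_aligned)) "aligned to flow reversal" else "as sampled"
  ))
  invisible(x)
}

#' Evaluate a periodic waveform
#'
#' @param wave A `spline_waveform`.
#' @param t Times in seconds (any real values; evaluation is periodic).
#' @return Flux in mm^3/s.
#' @export
eval_waveform <- function(wave, t) {
  stopifnot(inherits(wave, "spline_waveform"))
  wave$fun(t)
}

#' Fit a periodic cubic interpolating spline to flux samples
#'
#' Fits a cubic spline with periodic end conditions through the samples
#' (C2-continuous across the cycle seam), so the waveform can be evaluated at
#' any time, as needed to drive a solver at a much finer time resolution than
#' the 32 phases per cycle typical of PC-MRI.
#'
#' @param series A [flux_series].
#' @return A `spline_waveform`: an evaluable periodic function `Q(t)` (mm^3/s)
#'   that interpolates every sample exactly.
#' @export
fit_periodic_spline <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  t0 <- series$times[1]
  period <- series$period
  kt <- c(series$times, t0 + period)
  kq <- c(series$fluxes, series$fluxes[1])
  sf <- stats::splinefun(kt, kq, method = "periodic")
  fun <- function(t) sf(t0 + (t - t0) %% period)
  new_spline_waveform(fun, period,
    origin_aligned = FALSE,
    heart_rate = series$heart_rate, site = series$site,
    knots = list(times = kt, fluxes = kq)
  )
}

# Refine a sign change of f in [a, b] (f(a), f(b) of opposite sign) by
# bisection to absolute tolerance tol.
bisect_root <- function(f, a, b, tol) {
  fa <- f(a)
  for (i in seq_len(200)) {
    m <- (a + b) / 2
    if ((b - a) / 2 < tol) break
    fm <- f(m)
    if (fm == 0) {
      return(m)
    }
    if (sign(fm) == sign(fa)) {
      a <- m
      fa <- fm
    } else {
      b <- m
    }
  }
  (a + b) / 2
}

# Locate all zero crossings of the waveform over one period starting at `from`.
# Returns a data.frame with columns t (refined time) and dir (-1 down, +1 up).
waveform_crossings <- function(wave, n = 4096, from = 0) {
  T <- wave$period
  tg <- from + (0:(n - 1)) * T / n
  q <- wave$fun(tg)
  qn <- c(q[-1], q[1])
  tn <- c(tg[-1], from + T)
  idx <- which(sign(q) != sign(qn) & !(q == 0 & qn == 0))
  if (!length(idx)) {
    return(data.frame(t = numeric(0), dir = numeric(0)))
  }
  tol <- 1e-6 * T
  out <- lapply(idx, function(i) {
    a <- tg[i]
    b <- tn[i]
    r <- if (q[i] == 0) a else bisect_root(wave$fun, a, b, tol)
    data.frame(t = r, dir = ifelse(qn[i] < q[i], -1, +1))
  })
  do.call(rbind, out)
}

# Refine a local extremum near dense-grid index: returns c(t, value).
refine_extremum <- function(fun, t_lo, t_hi, maximum) {
  opt <- stats::optimize(fun,
    interval = c(t_lo, t_hi), maximum = maximum,
    tol = .Machine$double.eps^0.5 * max(abs(t_hi), 1)
  )
  if (maximum) c(opt$maximum, opt$objective) else c(opt$minimum, opt$objective)
}

# Global minimum (or maximum) of the waveform over one cycle, refined from a
# dense grid. Ties broken by earliest time (which.min/max take the first hit).
waveform_extremum <- function(wave, n = 4096, maximum = FALSE) {
  T <- wave$period
  tg <- (0:(n - 1)) * T / n
  q <- wave$fun(tg)
  i <- if (maximum) which.max(q) else which.min(q)
  h <- T / n
  refine_extremum(wave$fun, tg[i] - h, tg[i] + h, maximum)
}

#' Shift a waveform's time origin to flow reversal
#'
#' Returns a pure time shift of the waveform such that `Q(0) = 0` with the flow
#' entering the caudal (negative) phase for small positive times. This is the
#' cycle-origin convention used for all reported cycle fractions (t = 0 at the
#' reversal of cervical flow). Idempotent: an already-aligned wave is shifted
#' by (numerically) zero.
#'
#' @param wave A `spline_waveform` with at least one sign change.
#' @param n Dense-grid size used to bracket crossings.
#' @return The shifted `spline_waveform`, with attribute field `shift` (s).
#' @export
align_cycle_origin <- function(wave, n = 4096) {
  stopifnot(inherits(wave, "spline_waveform"))
  cr <- waveform_crossings(wave, n = n)
  down <- cr[cr$dir < 0, , drop = FALSE]
  if (!nrow(down)) stop("no flow reversal found")
  T <- wave$period
  # pick the down-crossing closest to the current origin (wrapped), so that
  # aligning twice is a no-op
  d <- down$t %% T
  d_w <- pmin(d, T - d)
  shift <- down$t[which.min(d_w)]
  if (min(d_w) == (T - d)[which.min(d_w)]) shift <- shift - T
  f0 <- wave$fun
  fun <- function(t) f0(t + shift)
  out <- new_spline_waveform(fun, T,
    origin_aligned = TRUE,
    heart_rate = wave$heart_rate, site = wave$site, knots = wave$knots
  )
  out$shift <- shift
  out
}

#' Cycle-timing metrics of a flux waveform
#'
#' Computes, on a dense grid of the interpolated waveform (not the raw
#' samples), the fraction of the cycle with caudal (negative) flow, the cycle
#' fraction of the systolic peak, the systolic and diastolic flux extrema and
#' the zero-crossing times. The waveform should be origin-aligned
#' ([align_cycle_origin]) so fractions are measured from flow reversal.
#'
#' @param wave A `spline_waveform`.
#' @param n Dense-grid size (>= 4096 recommended).
#' @return A list of class `cycle_metrics` with fields `caudal_fraction`,
#'   `t_peak_systole` (cycle fraction), `Q_max_systolic` (mm^3/s, <= 0),
#'   `Q_max_diastolic` (mm^3/s, >= 0) and `zero_crossings` (cycle fractions).
#' @export
cycle_metrics <- function(wave, n = 4096) {
  stopifnot(inherits(wave, "spline_waveform"))
  T <- wave$period
  cr <- waveform_crossings(wave, n = n)
  if (nrow(cr)) {
    # measure of {Q < 0} from the refined crossing times: walk the circle
    ts <- sort(cr$t %% T)
    edges <- c(ts, ts[1] + T)
    mids <- (edges[-length(edges)] + edges[-1]) / 2
    neg <- wave$fun(mids) < 0
    caudal <- sum((edges[-1] - edges[-length(edges)])[neg]) / T
  } else {
    caudal <- if (wave$fun(0) < 0) 1 else 0
  }
  pk_s <- waveform_extremum(wave, n = n, maximum = FALSE)
  pk_d <- waveform_extremum(wave, n = n, maximum = TRUE)
  structure(
    list(
      caudal_fraction = caudal,
      t_peak_systole = (pk_s[1] %% T) / T,
      Q_max_systolic = pk_s[2],
      Q_max_diastolic = pk_d[2],
      zero_crossings = sort(cr$t %% T) / T
    ),
    class = "cycle_metrics"
  )
}

#' @export
print.cycle_metrics <- function(x, ...) {
  cat(sprintf(
    "<cycle_metrics> caudal fraction %.3f, systolic peak at %.3f of cycle\n",
    x$caudal_fraction, x$t_peak_systole
  ))
  cat(sprintf(
    "  Q systolic %.4g, diastolic %.4g mm^3/s; %d zero crossings\n",
    x$Q_max_systolic, x$Q_max_diastolic, length(x$zero_crossings)
  ))
  invisible(x)
}

#' Cycle-fraction delay between the systolic peaks of two waveforms
#'
#' Computes `(t_peakB - t_peakA) / period`, wrapped to `[0, 1)`, where the
#' peaks are the systolic (most negative) flux extrema. Used e.g. for the lag
#' of the aqueduct waveform behind the cervical waveform.
#'
#' @param waveA,waveB `spline_waveform`s with equal periods.
#' @return Delay as a fraction of the cycle in `[0, 1)`.
#' @export
delay_between <- function(waveA, waveB) {
  stopifnot(inherits(waveA, "spline_waveform"), inherits(waveB, "spline_waveform"))
  if (abs(waveA$period - waveB$period) > 1e-9 * waveA$period) {
    stop("waveforms have unequal periods")
  }
  ta <- waveform_extremum(waveA, maximum = FALSE)[1]
  tb <- waveform_extremum(waveB, maximum = FALSE)[1]
  ((tb - ta) / waveA$period) %% 1
}
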