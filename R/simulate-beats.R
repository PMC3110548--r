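#' Specification for a synthetic beat series
#'
#' Describes the ground truth of a simulated beat-to-beat recording: a mean
#' pulse interval modulated by one low-frequency (LF) and one high-frequency
#' (HF) sinusoid plus white Gaussian noise, and a systolic pressure series
#' built the same way around `sap_mean`. The LF oscillation emulates
#' sympathetic vasomotor (Mayer-wave) activity, the HF oscillation
#' respiration-linked modulation; in the rat these fall in 0.2-0.75 Hz and
#' 0.75-3.0 Hz respectively.
#'
#' @param mean_pi Mean pulse interval (ms); must be > 0. The default
#'   155.92 ms corresponds to a heart rate of ~384.8 bpm, typical of the
#'   conscious spontaneously hypertensive rat.
#' @param lf_freq,hf_freq LF and HF oscillation frequencies (Hz);
#'   `0 < lf_freq < hf_freq` required.
#' @param lf_amp,hf_amp Sinusoid amplitudes on the pulse-interval series
#'   (ms); a sinusoid of amplitude A contributes A^2/2 to the tachogram
#'   variance.
#' @param noise_sd SD of white Gaussian beat-to-beat noise on the pulse
#'   interval (ms).
#' @param sap_mean,dap_mean Mean systolic and diastolic pressure (mmHg);
#'   `sap_mean > dap_mean` required.
#' @param sap_lf_amp,sap_hf_amp,sap_noise_sd Same roles for the systolic
#'   pressure series (mmHg).
#' @param n_beats Number of cardiac cycles (pulse intervals) to generate.
#' @param seed Optional integer seed; identical spec + seed gives identical
#'   output.
#' @return An object of class `beat_spec`.
#' @seealso [simulate_beat_series()]
#' @export
beat_spec <- function(mean_pi = 155.92,
                      lf_freq = 0.45, lf_amp = 3.2,
                      hf_freq = 2.0, hf_amp = 5.4,
                      noise_sd = 7.0,
                      sap_mean = 178.4, dap_mean = 141.2,
                      sap_lf_amp = 6.1, sap_hf_amp = 3.1,
                      sap_noise_sd = 6.7,
                      n_beats = 300, seed = NULL) {
  check_number(mean_pi, "mean_pi", lower = 0, strict_lower = TRUE)
  check_number(lf_freq, "lf_freq", lower = 0, strict_lower = TRUE)
  check_number(hf_freq, "hf_freq", lower = lf_freq, strict_lower = TRUE)
  for (nm in c("lf_amp", "hf_amp", "noise_sd",
               "sap_lf_amp", "sap_hf_amp", "sap_noise_sd")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(sap_mean, "sap_mean")
  check_number(dap_mean, "dap_mean", upper = sap_mean)
  if (dap_mean >= sap_mean) {
    ratvar_error("`sap_mean` must exceed `dap_mean`", "ratvar_invalid_spec")
  }
  check_number(n_beats, "n_beats", lower = 1)
  structure(
    list(mean_pi = mean_pi, lf_freq = lf_freq, lf_amp = lf_amp,
         hf_freq = hf_freq, hf_amp = hf_amp, noise_sd = noise_sd,
         sap_mean = sap_mean, dap_mean = dap_mean,
         sap_lf_amp = sap_lf_amp, sap_hf_amp = sap_hf_amp,
         sap_noise_sd = sap_noise_sd,
         n_beats = as.integer(n_beats), seed = seed),
    class = "beat_spec"
  )
}

#' Construct a beat series
#'
#' Container for beat-to-beat data: systolic peak times, pulse intervals
#' (the tachogram), per-beat systolic pressures (the systogram) and
#' per-interval diastolic minima. With `m` systolic peaks there are `m - 1`
#' pulse intervals; `pi_ms` must equal `diff(beat_times) * 1000`.
#'
#' @param beat_times Systolic peak times (s), strictly increasing.
#' @param sap Per-peak systolic pressure (mmHg), length `m`.
#' @param dap Per-interval diastolic pressure (mmHg), length `m - 1`.
#' @param map Optional per-interval mean pressure (mmHg), length `m - 1`.
#' @return An object of class `beat_series` with elements `beat_times`,
#'   `pi_ms`, `sap`, `dap`, `map`.
#' @export
beat_series <- function(beat_times, sap, dap, map = NULL) {
  m <- length(beat_times)
  if (m < 2L) {
    ratvar_error("a beat series needs at least 2 systolic peaks",
                 "ratvar_invalid_beats")
  }
  if (any(diff(beat_times) <= 0)) {
    ratvar_error("beat times must be strictly increasing",
                 "ratvar_invalid_beats")
  }
  if (length(sap) != m || length(dap) != m - 1L) {
    ratvar_error("lengths must be: sap = m, dap = m - 1 for m peaks",
                 "ratvar_invalid_beats")
  }
  if (any(dap >= pmin(sap[-m], sap[-1]))) {
    ratvar_error("each diastolic minimum must lie below its flanking systolic peaks",
                 "ratvar_invalid_beats")
  }
  structure(
    list(beat_times = as.numeric(beat_times),
         pi_ms = diff(beat_times) * 1000,
         sap = as.numeric(sap),
         dap = as.numeric(dap),
         map = if (is.null(map)) rep(NA_real_, m - 1L) else as.numeric(map)),
    class = "beat_series"
  )
}

# normalized decay shape used by the waveform morphology: C1-smooth
# kernel exp(1 - sqrt(1 + x^2)) over x in [0, 5], rescaled to run from 1
# to exactly 0; `frac` is the elapsed fraction of the decay
decay_kernel <- function(frac) {
  dk <- function(x) exp(1 - sqrt(1 + x^2))
  dk0 <- dk(5)
  (dk(frac * 5) - dk0) / (1 - dk0)
}

# time average of the decay shape over the full decay (constant)
decay_kernel_mean <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- integrate(decay_kernel, 0, 1, rel.tol = 1e-10)$value
    }
    val
  }
})

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> %d beats, mean PI %.1f ms (HR %.1f bpm), SAP %.1f / DAP %.1f mmHg\n",
    length(x$pi_ms), mean(x$pi_ms), 60000 / mean(x$pi_ms),
    mean(x$sap), mean(x$dap)))
  invisible(x)
}

#' Simulate a beat-to-beat series with known oscillatory content
#'
#' Generates `n_beats` pulse intervals
#' `PI_k = mean_pi + lf_amp sin(2 pi lf_freq t_k + phi_LF) +
#' hf_amp sin(2 pi hf_freq t_k + phi_HF) + e_k`, with beat times accumulated
#' from the successive intervals, and a systolic pressure series built
#' analogously around `sap_mean`. Phases are drawn uniformly (seeded);
#' each diastolic value follows the smaller of its flanking systolic
#' values at 70% amplitude around `dap_mean`, a phenomenological coupling
#' that keeps every cycle's pulse pressure near its configured mean.
#' Pulse-interval realizations that would be non-positive are clipped at
#' 10 ms with a warning.
#'
#' @param spec A [beat_spec()].
#' @return A [beat_series()] carrying `n_beats` pulse intervals
#'   (`n_beats + 1` systolic peaks). The generating spec is attached as
#'   attribute `"spec"`.
#' @examples
#' b <- simulate_beat_series(beat_spec(n_beats = 300, seed = 1))
#' mean(b$pi_ms)
#' @export
simulate_beat_series <- function(spec) {
  if (!inherits(spec, "beat_spec")) {
    ratvar_error("`spec` must be a beat_spec", "ratvar_invalid_spec")
  }
  with_seed(spec$seed, {
    n <- spec$n_beats
    m <- n + 1L
    ph <- runif(4, 0, 2 * pi)  # PI LF/HF, SAP LF/HF
    t <- numeric(m)
    pi_ms <- numeric(n)
    n_clip <- 0L
    for (k in seq_len(n)) {
      v <- spec$mean_pi +
        spec$lf_amp * sin(2 * pi * spec$lf_freq * t[k] + ph[1]) +
        spec$hf_amp * sin(2 * pi * spec$hf_freq * t[k] + ph[2]) +
        rnorm(1, 0, spec$noise_sd)
      if (v <= 0) {
        n_clip <- n_clip + 1L
        v <- 10
      }
      pi_ms[k] <- v
      t[k + 1L] <- t[k] + v / 1000
    }
    if (n_clip > 0L) {
      warning(sprintf("%d non-positive pulse interval(s) clipped at 10 ms",
                      n_clip))
    }
    sap_dev <- spec$sap_lf_amp * sin(2 * pi * spec$lf_freq * t + ph[3]) +
      spec$sap_hf_amp * sin(2 * pi * spec$hf_freq * t + ph[4]) +
      rnorm(m, 0, spec$sap_noise_sd)
    sap <- spec$sap_mean + sap_dev
    # diastole follows the smaller flanking systole at 70% amplitude, so
    # pulse pressure stays near its configured mean on every cycle
    flank <- pmin(sap[-m], sap[-1])
    dap <- spec$dap_mean + 0.7 * (flank - spec$sap_mean)
    dap <- pmin(dap, flank - 1)
    # per-beat mean pressure: analytic time average of the waveform
    # morphology (85% decay at the kernel mean level, 15% half-cosine rise)
    map <- 0.85 * (dap + (sap[-m] - dap) * decay_kernel_mean()) +
      0.15 * (dap + (sap[-1] - dap) * 0.5)
    out <- beat_series(t, sap, dap, map = map)
    attr(out, "spec") <- spec
    out
  })
}

#' Render a beat series as a pulsatile arterial-pressure waveform
#'
#' Builds a continuous pressure trace in which each cardiac cycle decays
#' smoothly from its systolic peak toward the diastolic level and then
#' rises (half-cosine upstroke, 15% of the cycle) to the next systolic
#' peak. The decay uses the C1-smooth kernel `exp(1 - sqrt(1 + x^2))`
#' rescaled to reach the diastolic value exactly at the foot of the next
#' upstroke, so the waveform has zero slope at every systolic peak and its
#' per-beat extrema equal the beat-series values up to one sample of
#' interpolation error.
#'
#' @param beats A [beat_series()].
#' @param sampling_rate Samples per second (Hz), >= 100; default 2000
#'   (2 kHz), the standard acquisition rate for rat arterial pressure.
#' @return An object of class `waveform`: list with `samples` (mmHg),
#'   `sampling_rate` (Hz) and `start_time` (s).
#' @seealso [detect_beats()] for the inverse operation.
#' @export
simulate_bp_waveform <- function(beats, sampling_rate = 2000) {
  if (!inherits(beats, "beat_series")) {
    ratvar_error("`beats` must be a beat_series", "ratvar_invalid_beats")
  }
  check_number(sampling_rate, "sampling_rate", lower = 100)
  tp <- beats$beat_times
  m <- length(tp)
  if (any(diff(tp) <= 0)) {
    ratvar_error("beat times must be strictly increasing",
                 "ratvar_invalid_beats")
  }
  d <- diff(tp)                      # cycle lengths (s)
  rise <- 0.15 * d                   # upstroke duration per cycle
  tail_d <- 0.85 * stats::median(d)  # decay appended after the last peak
  t0 <- tp[1] - rise[1]
  t_end <- tp[m] + tail_d
  ts <- seq(t0, t_end, by = 1 / sampling_rate)

  decay <- function(frac) decay_kernel(frac)

  p <- numeric(length(ts))
  # opening upstroke into the first peak
  seg <- ts < tp[1]
  u <- (ts[seg] - t0) / rise[1]
  p[seg] <- beats$dap[1] + (beats$sap[1] - beats$dap[1]) * (1 - cos(pi * u)) / 2
  # cycles
  idx <- findInterval(ts, tp)  # 0 before first peak, k in [tp_k, tp_{k+1})
  for (k in seq_len(m - 1L)) {
    seg <- which(idx == k)
    if (!length(seg)) next
    tau <- ts[seg] - tp[k]
    Dk <- d[k] - rise[k]
    dap_k <- beats$dap[k]
    pk <- numeric(length(seg))
    dec <- tau < Dk
    pk[dec] <- dap_k + (beats$sap[k] - dap_k) * decay(tau[dec] / Dk)
    u <- (tau[!dec] - Dk) / rise[k]
    pk[!dec] <- dap_k + (beats$sap[k + 1L] - dap_k) * (1 - cos(pi * u)) / 2
    p[seg] <- pk
  }
  # closing decay after the last peak
  seg <- which(idx == m)
  if (length(seg)) {
    dap_last <- beats$dap[m - 1L]
    p[seg] <- dap_last +
      (beats$sap[m] - dap_last) * decay((ts[seg] - tp[m]) / tail_d)
  }
  structure(list(samples = p, sampling_rate = sampling_rate,
                 start_time = t0),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.1f s), %.1f-%.1f mmHg\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              min(x$samples), max(x$samples)))
  invisible(x)
}
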