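#' Sonic feature bundle for one motif
#'
#' Container for the four per-motif sonic time series on a shared frame
#' grid: fundamental frequency `f0` (Hz), its estimated first derivative
#' `delta_f0` (Hz per frame), `loudness` (dB relative to the reference
#' maximum, always <= 0) and spectral `centroid` (Hz).
#'
#' @param f0,delta_f0,loudness,centroid Numeric series of equal length.
#' @param voiced Logical voicing mask (same length as `f0`).
#' @param rate Frame rate in Hz.
#' @param ok `FALSE` when the pitch track retains an interior gap longer
#'   than the interpolation limit; such motifs are excluded from distance
#'   tables.
#' @return An object of class `sonic_features`.
#' @export
sonic_features <- function(f0, delta_f0, loudness, centroid,
                           voiced = rep(TRUE, length(f0)), rate, ok = TRUE) {
  n <- length(f0)
  stopifnot(length(delta_f0) == n, length(loudness) == n,
            length(centroid) == n, length(voiced) == n, rate > 0)
  if (any(loudness > 1e-9, na.rm = TRUE))
    stopf("loudness must be <= 0 dB (re max); max found %g", max(loudness))
  if (any(f0[voiced] <= 0, na.rm = TRUE))
    stopf("f0 must be positive on voiced frames")
  structure(list(f0 = as.numeric(f0), delta_f0 = as.numeric(delta_f0),
                 loudness = as.numeric(loudness), centroid = as.numeric(centroid),
                 voiced = as.logical(voiced), rate = rate, ok = isTRUE(ok)),
            class = "sonic_features")
}

#' @export
print.sonic_features <- function(x, ...) {
  cat(sprintf("<sonic_features> %d frames @ %g Hz (%.2f s), %d%% voiced%s\n",
              length(x$f0), x$rate, length(x$f0) / x$rate,
              round(100 * mean(x$voiced)),
              if (x$ok) "" else ", UNBRIDGED GAP"))
  invisible(x)
}

#' Estimate the fundamental frequency contour
#'
#' Frame-based autocorrelation pitch tracker: each analysis frame is Hann
#' windowed, its normalised autocorrelation is computed via FFT, and the
#' strongest peak in the candidate lag range is refined by parabolic
#' interpolation. Frames whose periodicity peak falls below
#' `voicing_threshold`, or whose energy is more than 60 dB below the
#' loudest frame, are marked unvoiced.
#'
#' @param waveform Mono numeric waveform.
#' @param sample_rate Audio sampling rate (Hz).
#' @param frame_rate Output frame rate (Hz); default 100 (10 ms hop).
#' @param f_min,f_max Candidate pitch range in Hz.
#' @param window_s Analysis window length in seconds.
#' @param voicing_threshold Minimum normalised autocorrelation peak.
#' @return List with `f0` (Hz, `NA` on unvoiced frames) and logical `voiced`.
#' @export
estimate_f0 <- function(waveform, sample_rate, frame_rate = 100,
                        f_min = 80, f_max = 1000, window_s = 0.04,
                        voicing_threshold = 0.5) {
  stopifnot(sample_rate > 0, frame_rate > 0, f_min > 0, f_max > f_min)
  x <- as.numeric(waveform)
  if (length(x) < 2) stopf("estimate_f0: waveform too short")
  hop <- sample_rate / frame_rate
  win <- max(32L, 2L * floor(window_s * sample_rate / 2))
  nfft <- 2^ceiling(log2(2L * win))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  starts <- seq(1, max(1, length(x) - win + 1L), by = hop)
  n_frames <- length(starts)
  lag_min <- max(2L, floor(sample_rate / f_max))
  lag_max <- min(win - 2L, ceiling(sample_rate / f_min))
  f0 <- rep(NA_real_, n_frames); peak <- numeric(n_frames); energy <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    s <- floor(starts[t])
    seg <- x[s:min(length(x), s + win - 1L)]
    if (length(seg) < win) seg <- c(seg, numeric(win - length(seg)))
    seg <- (seg - mean(seg)) * hann
    energy[t] <- sum(seg^2)
    if (energy[t] <= 0) next
    # zero-padded FFT of length nfft for linear (not circular) autocorrelation
    X <- fft(c(seg, numeric(nfft - win)))
    ac <- Re(fft(X * Conj(X), inverse = TRUE))[1:(lag_max + 2L)]
    ac <- ac / ac[1L]
    if (lag_max < lag_min + 1L) next
    lag_rng <- lag_min:lag_max
    k <- lag_rng[which.max(ac[lag_rng + 1L])]
    peak[t] <- ac[k + 1L]
    if (peak[t] >= voicing_threshold && k > lag_min && k < lag_max) {
      # parabolic refinement around the autocorrelation peak
      y0 <- ac[k]; y1 <- ac[k + 1L]; y2 <- ac[k + 2L]
      denom <- y0 - 2 * y1 + y2
      delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
      f0[t] <- sample_rate / (k + delta)
    } else if (peak[t] >= voicing_threshold) {
      f0[t] <- sample_rate / k
    }
  }
  emax <- max(energy)
  voiced <- !is.na(f0) & (if (emax > 0) energy > emax * 1e-6 else FALSE)
  f0[!voiced] <- NA_real_
  if (!any(voiced)) warnf("estimate_f0: no voiced frames detected")
  list(f0 = f0, voiced = voiced)
}

#' Bridge short gaps in a pitch track
#'
#' Interior unvoiced runs of at most `max_gap_s` are filled by linear
#' interpolation between the flanking voiced values and marked voiced;
#' longer interior runs are left untouched and flagged. Short pitch breaks
#' occur naturally within vocal ornaments and are not perceived as breaks
#' in the phrase, while DTW cannot align series with holes — hence the
#' bridge-or-flag rule.
#'
#' @param f0 Numeric series (Hz; `NA` allowed on unvoiced frames).
#' @param voiced Logical mask, same length.
#' @param rate Frame rate (Hz).
#' @param max_gap_s Longest bridgeable gap in seconds (default 0.350).
#' @return List with filled `f0`, updated `voiced`, and `ok = FALSE` iff an
#'   interior gap longer than `max_gap_s` remains.
#' @export
interpolate_gaps <- function(f0, voiced, rate, max_gap_s = 0.350) {
  n <- length(f0)
  stopifnot(length(voiced) == n, rate > 0)
  if (!any(voiced)) return(list(f0 = f0, voiced = voiced, ok = FALSE))
  max_gap <- max_gap_s * rate
  r <- rle(!voiced)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- TRUE
  for (g in which(r$values)) {
    a <- starts[g]; b <- ends[g]
    if (a == 1L || b == n) next                       # edge gap: not interior
    if (r$lengths[g] <= max_gap) {
      lo <- a - 1L; hi <- b + 1L
      f0[a:b] <- f0[lo] + (f0[hi] - f0[lo]) * (a:b - lo) / (hi - lo)
      voiced[a:b] <- TRUE
    } else ok <- FALSE
  }
  list(f0 = f0, voiced = voiced, ok = ok)
}

#' Gaussian smoothing of a univariate series
#'
#' Convolution with a truncated discrete Gaussian kernel (truncation radius
#' `4 * sigma` samples), normalised to unit sum, with reflective edge
#' handling. Being a convex combination, the filter preserves constants and
#' never produces values outside the input range (up to round-off).
#'
#' @param x Numeric series.
#' @param sigma Kernel standard deviation in samples (default 2.5).
#' @return Smoothed series, same length.
#' @export
smooth_gaussian <- function(x, sigma = 2.5) {
  n <- length(x)
  if (n == 0L) stopf("smooth_gaussian: empty series")
  if (anyNA(x)) stopf("smooth_gaussian: series contains NA; interpolate gaps first")
  if (sigma <= 0) return(as.numeric(x))
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  # reflective index map: ... 3 2 |1 2 ... n| n-1 n-2 ...
  reflect <- function(i) {
    period <- if (n > 1L) 2L * n - 2L else 1L
    i <- (i - 1L) %% period
    ifelse(i >= n, period - i, i) + 1L
  }
  padded <- x[reflect((1L - r):(n + r))]
  out <- stats::filter(padded, k, method = "convolution", sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Estimated first derivative of the pitch curve
#'
#' The estimated-derivative transform of Keogh and Pazzani:
#' `D_i = ((q_i - q_{i-1}) + (q_{i+1} - q_{i-1}) / 2) / 2` for interior
#' frames, blending the left difference with the centred difference.
#' Endpoints replicate their nearest interior value.
#'
#' @param q Numeric series (a gap-bridged, smoothed f0 track), length >= 3.
#' @return Series of the same length, in input units per frame.
#' @export
delta_f0 <- function(q) {
  n <- length(q)
  if (n < 3L) stopf("delta_f0: need at least 3 frames, got %d", n)
  i <- 2L:(n - 1L)
  d <- numeric(n)
  d[i] <- ((q[i] - q[i - 1L]) + (q[i + 1L] - q[i - 1L]) / 2) / 2
  d[1L] <- d[2L]; d[n] <- d[n - 1L]
  d
}

# Short-time power spectra: rows = frames, cols = bins 0..nfft/2.
stft_power <- function(x, sample_rate, frame_rate, window_s = 0.046) {
  hop <- sample_rate / frame_rate
  win <- max(16L, 2L * floor(window_s * sample_rate / 2))
  nfft <- 2^ceiling(log2(win))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  starts <- seq(1, max(1, length(x) - win + 1L), by = hop)
  P <- matrix(0, nrow = length(starts), ncol = nfft / 2 + 1L)
  for (t in seq_along(starts)) {
    s <- floor(starts[t])
    seg <- x[s:min(length(x), s + win - 1L)]
    if (length(seg) < win) seg <- c(seg, numeric(win - length(seg)))
    X <- fft(c(seg * hann, numeric(nfft - win)))[1:(nfft / 2 + 1L)]
    P[t, ] <- Mod(X)^2
  }
  list(power = P, freqs = (0:(nfft / 2)) * sample_rate / nfft)
}

#' Frame-wise loudness in dB relative to the maximum frame
#'
#' Per frame, the total short-time spectral power `P_t` is converted to
#' `L_t = 10 * log10(P_t / ref)` where `ref` is the maximum frame power over
#' the reference extent, so the loudest frame sits at 0 dB. When motifs are
#' cut from a longer performance, pass the performance-wide maximum as
#' `ref_power` to keep motifs comparable. Values are floored at `floor_db`.
#'
#' @param waveform Mono numeric waveform.
#' @param sample_rate,frame_rate Sampling and output frame rates (Hz).
#' @param ref_power Optional external reference power (the maximum frame
#'   power of the parent performance); default: this waveform's maximum.
#' @param floor_db Lower clamp in dB (default -80).
#' @return Numeric dB series, all values <= 0.
#' @export
loudness <- function(waveform, sample_rate, frame_rate = 100,
                     ref_power = NULL, floor_db = -80) {
  st <- stft_power(as.numeric(waveform), sample_rate, frame_rate)
  P <- rowSums(st$power)
  ref <- ref_power %||% max(P)
  if (ref <= 0) {
    warnf("loudness: silent input; all frames at floor")
    return(rep(floor_db, length(P)))
  }
  pmin(0, pmax(floor_db, 10 * log10(pmax(P, .Machine$double.xmin) / ref)))
}

#' Frame-wise spectral centroid
#'
#' Magnitude-weighted mean frequency of the short-time spectrum,
#' `sum(f * |X(f)|) / sum(|X(f)|)`, a coarse brightness/timbre descriptor.
#' Bins below `floor_rel` of the frame's peak magnitude are gated out
#' before weighting, so window-leakage sidelobes (about -31 dB for the
#' Hann window used) do not drag the centroid toward mid-spectrum; a pure
#' tone's centroid then sits at its frequency to within a bin. Frames with
#' (near-)zero spectral energy have no defined centroid and carry the
#' previous frame's value (the first such frames take the first defined
#' value); an attribute `undefined` marks them.
#'
#' @inheritParams loudness
#' @param floor_rel Relative magnitude gate (default 0.05).
#' @return Numeric Hz series in `[0, sample_rate / 2]`.
#' @export
spectral_centroid <- function(waveform, sample_rate, frame_rate = 100,
                              floor_rel = 0.05) {
  st <- stft_power(as.numeric(waveform), sample_rate, frame_rate)
  mag <- sqrt(st$power)
  mag[mag < floor_rel * apply(mag, 1L, max)] <- 0
  tot <- rowSums(mag)
  cen <- as.numeric(mag %*% st$freqs)
  eps <- max(tot) * 1e-12
  defined <- tot > eps
  cen[defined] <- cen[defined] / tot[defined]
  cen[!defined] <- NA_real_
  if (!all(defined)) {
    if (!any(defined)) {
      cen[] <- 0
    } else {
      first <- which(defined)[1L]
      if (first > 1L) cen[1:(first - 1L)] <- cen[first]
      for (t in seq_along(cen)) if (is.na(cen[t])) cen[t] <- cen[t - 1L]
    }
  }
  structure(cen, undefined = !defined)
}

#' Full sonic feature pipeline for one motif waveform
#'
#' Runs the fixed conditioning chain on a motif's audio: pitch tracking,
#' gap bridging (350 ms rule), Gaussian smoothing (sigma = 2.5 frames) of
#' all four series, and the estimated pitch derivative. Frames outside the
#' voiced span (leading/trailing unvoiced frames) are trimmed from all four
#' series so they share one time base.
#'
#' @param waveform Mono numeric waveform of the motif.
#' @param sample_rate Audio sampling rate (Hz).
#' @param frame_rate Sonic frame rate (Hz), default 100.
#' @param sigma Gaussian smoothing SD in frames, default 2.5.
#' @param max_gap_s Pitch-gap bridging limit (s), default 0.350.
#' @param ref_power Optional performance-level loudness reference power.
#' @return A [sonic_features] object (`ok = FALSE` if an interior pitch gap
#'   exceeded `max_gap_s`).
#' @export
extract_sonic_features <- function(waveform, sample_rate, frame_rate = 100,
                                   sigma = 2.5, max_gap_s = 0.350,
                                   ref_power = NULL) {
  pt <- estimate_f0(waveform, sample_rate, frame_rate)
  gi <- interpolate_gaps(pt$f0, pt$voiced, frame_rate, max_gap_s)
  loud <- loudness(waveform, sample_rate, frame_rate, ref_power = ref_power)
  cen <- as.numeric(spectral_centroid(waveform, sample_rate, frame_rate))
  n <- min(length(gi$f0), length(loud), length(cen))
  f0 <- gi$f0[1:n]; voiced <- gi$voiced[1:n]
  loud <- loud[1:n]; cen <- cen[1:n]
  if (!any(voiced)) stopf("extract_sonic_features: no voiced frames")
  span <- range(which(voiced))
  keep <- span[1]:span[2]
  f0 <- f0[keep]; voiced <- voiced[keep]; loud <- loud[keep]; cen <- cen[keep]
  if (!gi$ok || any(!voiced)) {
    # remaining interior holes: fill numerically so the series is usable for
    # smoothing, but keep ok = FALSE so the motif is excluded downstream
    f0[!voiced] <- approx(which(voiced), f0[voiced], xout = which(!voiced),
                          rule = 2)$y
  }
  f0s <- smooth_gaussian(f0, sigma)
  sonic_features(f0 = f0s,
                 delta_f0 = delta_f0(f0s),
                 loudness = pmin(0, smooth_gaussian(loud, sigma)),
                 centroid = smooth_gaussian(cen, sigma),
                 voiced = voiced, rate = frame_rate,
                 ok = gi$ok && all(voiced))
}
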