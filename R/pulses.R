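#' Detect pulses and inter-pulse-interval statistics
#'
#' Local-maximum detection with a prominence criterion, the model-side
#' analogue of the inter-pulse interval (IPI) read off experimental LH
#' profiles.  A sample is a peak when it is a local maximum whose topographic
#' prominence is at least `prominence_frac` of the trace's peak-to-peak
#' range; peaks closer than `min_distance` minutes are thinned keeping the
#' higher one.  A trace is classified `"pulsatile"` when it has at least 3
#' such peaks and its range exceeds the amplitude floor; otherwise
#' `"saturated"` when it sits at a high constant level (depolarization
#' block), else `"quiescent"`.
#'
#' @param trace an `mk_trajectory` (the `v` component is used), a two-column
#'   data frame (time, value), or a numeric vector with `times` supplied.
#' @param times sample times when `trace` is a bare numeric vector.
#' @param prominence_frac required prominence as a fraction of the trace
#'   range (default 0.2).
#' @param min_distance minimum peak separation in minutes (default 2).
#' @param amplitude_floor minimum peak-to-peak range for a pulsatile call.
#'   Default: 1% of `v0/d_v` when the trace is a KNDy/coupled trajectory
#'   (the firing-rate ceiling), else 0.
#' @param saturation_level mean level above which a flat trace is called
#'   `"saturated"`; default 50% of `v0/d_v` when known, else `Inf`.
#' @param scale physiological full-pulse scale.  When known (KNDy traces:
#'   `v0/d_v`, the firing-rate ceiling) the prominence requirement is
#'   `prominence_frac * max(range, scale)`, so that small forced ripples of
#'   the firing rate -- the oscillatory MePD input shining through after
#'   genuine relaxation pulses have ceased -- are not mistaken for pulses.
#' @param post_transient drop the trajectory's transient window first?
#' @return An object of class `mk_pulse_stats`: `peak_times`, `peak_heights`,
#'   `ipis`, `mean_ipi`, `n_pulses`, `classification`, `amplitude` (trace
#'   range) and `peak_cv` (coefficient of variation of peak heights, a
#'   quasi-periodicity indicator).
#' @examples
#' tt <- seq(0, 100, by = 0.05)
#' ps <- detect_pulses(data.frame(t = tt, v = sin(2 * pi * tt / 12)))
#' ps$mean_ipi  # ~12
#' @export
detect_pulses <- function(trace, times = NULL, prominence_frac = 0.2,
                          min_distance = 2, amplitude_floor = NULL,
                          saturation_level = NULL, scale = NULL,
                          post_transient = TRUE) {
  if (inherits(trace, "mk_trajectory")) {
    if (post_transient) trace <- post_transient(trace)
    if (!("v" %in% colnames(trace$states)))
      stop("trajectory has no firing-rate component 'v'", call. = FALSE)
    kn <- trace$meta$kndy
    if (is.null(amplitude_floor) && !is.null(kn))
      amplitude_floor <- 0.01 * kn$v0 / kn$d_v
    if (is.null(saturation_level) && !is.null(kn))
      saturation_level <- 0.5 * kn$v0 / kn$d_v
    if (is.null(scale) && !is.null(kn)) scale <- kn$v0 / kn$d_v
    times <- trace$times
    y <- trace$states[, "v"]
  } else if (is.data.frame(trace)) {
    if (ncol(trace) < 2L) stop("trace data frame needs 2 columns", call. = FALSE)
    times <- trace[[1]]
    y <- trace[[2]]
  } else {
    y <- as.numeric(trace)
    if (is.null(times)) stop("supply 'times' with a bare numeric trace",
                             call. = FALSE)
  }
  if (length(y) == 0L || anyNA(y) || anyNA(times))
    stop("empty or NA-containing trace", call. = FALSE)
  if (is.null(amplitude_floor)) amplitude_floor <- 0
  if (is.null(saturation_level)) saturation_level <- Inf
  rng <- diff(range(y))

  prom <- prominence_frac * max(rng, if (is.null(scale)) 0 else scale)
  idx <- find_peaks(y, prominence = prom)
  # enforce minimum separation, keeping the higher peak
  if (length(idx) > 1L) {
    ord <- idx[order(y[idx], decreasing = TRUE)]
    keep <- logical(0)
    for (i in ord)
      if (!length(keep) || all(abs(times[i] - times[keep]) >= min_distance))
        keep <- c(keep, i)
    idx <- sort(keep)
  }
  pt <- times[idx]
  ipis <- diff(pt)
  n <- length(idx)
  cls <- if (n >= 3L && rng >= amplitude_floor) "pulsatile"
         else if (rng < amplitude_floor && mean(y) > saturation_level) "saturated"
         else "quiescent"
  structure(list(peak_times = pt, peak_heights = y[idx], ipis = ipis,
                 mean_ipi = if (length(ipis)) mean(ipis) else NA_real_,
                 n_pulses = n, classification = cls, amplitude = rng,
                 peak_cv = if (n > 1L) stats::sd(y[idx]) / mean(y[idx])
                           else NA_real_),
            class = "mk_pulse_stats")
}

# local maxima with topographic prominence >= `prominence`
find_peaks <- function(y, prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  # local maxima robust to flat tops: last index of a rising->falling plateau
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  cand <- which(diff(s) == -2) + 1L
  if (!length(cand)) return(integer(0))
  ok <- vapply(cand, function(i) {
    h <- y[i]
    lmin <- h; j <- i
    while (j > 1L) { j <- j - 1L; if (y[j] > h) break; lmin <- min(lmin, y[j]) }
    rmin <- h; j <- i
    while (j < n) { j <- j + 1L; if (y[j] > h) break; rmin <- min(rmin, y[j]) }
    (h - max(lmin, rmin)) >= prominence
  }, logical(1))
  cand[ok]
}

# forward-fill NAs (tiny last-observation-carried-forward helper)
zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- x[ok][pmax(idx, 1L)]
  filled[idx == 0L] <- x[which(ok)[1]]
  filled
}

#' @export
print.mk_pulse_stats <- function(x, ...) {
  cat(sprintf("<mk_pulse_stats> %s: %d pulses, mean IPI %s min, amplitude %.4g\n",
              x$classification, x$n_pulses,
              if (is.na(x$mean_ipi)) "NA" else sprintf("%.3f", x$mean_ipi),
              x$amplitude))
  invisible(x)
}

#' Synthetic pulsatile trace with known ground truth
#'
#' Sum of Gaussian bumps at prescribed peak times plus Gaussian noise, used
#' to exercise the pulse detector against a known answer.  Deterministic for
#' a fixed seed.
#'
#' @param peak_times increasing vector of true peak times (min).
#' @param widths Gaussian standard deviations (min); recycled.
#' @param amplitudes bump heights; recycled.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed (required).
#' @param dt sample step (min); the default 0.5 is of the order of
#'   experimental blood-sampling intervals.
#' @param t_span window; defaults to the peak range padded by 5 widths.
#' @return List with `trace` (data frame time/value) and `truth`
#'   (`peak_times`, generator arguments, and `overlap_warning` when bumps sit
#'   closer than one width).
#' @export
make_pulse_fixture <- function(peak_times, widths = 1, amplitudes = 1,
                               noise_sd = 0, seed, dt = 0.5, t_span = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.unsorted(peak_times, strictly = TRUE))
    stop("peak_times must be strictly increasing", call. = FALSE)
  k <- length(peak_times)
  widths <- rep_len(widths, k)
  amplitudes <- rep_len(amplitudes, k)
  overlap <- k > 1L && any(diff(peak_times) < widths[-k])
  if (is.null(t_span))
    t_span <- c(min(peak_times) - 5 * max(widths),
                max(peak_times) + 5 * max(widths))
  tt <- seq(t_span[1], t_span[2], by = dt)
  y <- numeric(length(tt))
  for (i in seq_len(k))
    y <- y + amplitudes[i] * exp(-(tt - peak_times[i])^2 / (2 * widths[i]^2))
  set.seed(seed)
  y <- y + stats::rnorm(length(tt), sd = noise_sd)
  list(trace = data.frame(time = tt, value = y),
       truth = list(peak_times = peak_times, widths = widths,
                    amplitudes = amplitudes, noise_sd = noise_sd,
                    seed = seed, dt = dt, overlap_warning = overlap))
}

#' Read a two-column time/value trace from CSV
#'
#' @param path CSV with a header row; first column time (min), second value.
#' @return A data frame with columns `time`, `value`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("trace CSV needs two columns", call. = FALSE)
  data.frame(time = df[[1]], value = df[[2]])
}
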