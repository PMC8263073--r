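#' Averaged windowed power spectrum (Welch periodogram)
#'
#' Splits the trace into Hann-windowed segments of `window` seconds with
#' the given overlap, computes the one-sided periodogram of each
#' (mean-removed) segment, and averages. The density scaling is such that
#' the integral of the spectrum over frequency equals the time-domain
#' variance up to the windowing constant (the Hann window's power loss is
#' compensated by the `sum(w^2)` normalization); frequency resolution is
#' `1 / window`.
#'
#' @param trace a [CaTrace-class], or a numeric vector (then
#'   `samplingRate` must be given).
#' @param window segment length in seconds; must not exceed the trace
#'   duration.
#' @param overlap fractional overlap between segments in \[0, 1).
#' @param samplingRate sampling rate in Hz when `trace` is a bare vector.
#' @return data.frame with columns `frequency` (Hz) and `power`.
#' @export
powerSpectrum <- function(trace, window = 2, overlap = 0.5,
                          samplingRate = NULL) {
  if (is(trace, "CaTrace")) {
    x <- traceSamples(trace); fs <- samplingRate(trace)
  } else {
    x <- as.numeric(trace); fs <- samplingRate
    if (is.null(fs)) stop("samplingRate required for a bare vector")
  }
  n <- round(window * fs)
  if (n < 4) stop("window too short for the sampling rate")
  if (n > length(x)) stop("window exceeds the trace duration")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must lie in [0, 1)")
  step <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  scale <- fs * sum(w^2)
  nf <- floor(n / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / scale
    # fold the two-sided spectrum: double all bins except DC (and Nyquist
    # when n is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (n %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  data.frame(frequency = (seq_len(nf) - 1) * fs / n,
             power = acc / length(starts))
}

#' Dominant spectral peak frequency
#'
#' Frequency of maximal averaged power above a floor frequency (the floor
#' excludes the 1/f background that otherwise dominates).
#'
#' @param spectrum data.frame from [powerSpectrum()].
#' @param above lower frequency bound in Hz (default 2).
#' @return peak frequency in Hz.
#' @export
peakFrequency <- function(spectrum, above = 2) {
  s <- spectrum[spectrum$frequency > above, ]
  if (!nrow(s)) stop("no frequency bins above ", above, " Hz")
  s$frequency[which.max(s$power)]
}

#' Classify brain state from a calcium trace
#'
#' Band-ratio spike-and-wave detector: per sliding window, the fraction
#' of (DC-free) spectral power falling in the SWD band is compared with a
#' threshold; windows above it are labelled `swd`, merged into segments,
#' and segments shorter than `minDuration` are dropped. The overall label
#' is `"seizure"` if at least one SWD segment survives, otherwise
#' `"preseizure"`. The default threshold was calibrated on the synthetic
#' generator so that pure-background (preseizure) traces yield
#' essentially no false SWD segments while windows inside bursts of the
#' default seizure preset remain well above it; it is a tunable
#' parameter, not a property of the recordings.
#'
#' Segment extents are accounted by each hit window's central half (the
#' step between window starts), so segment boundaries track burst edges
#' to within a quarter window rather than being padded by a full window
#' at each end.
#'
#' @param trace a [CaTrace-class].
#' @param band SWD frequency band in Hz (default c(4, 8), bracketing the
#'   ~6 Hz fundamental).
#' @param ratioThreshold band-power / total-power threshold.
#' @param window sliding-window length in seconds (default 2, 50%
#'   overlap).
#' @param minDuration minimum segment duration in seconds (default 1).
#' @return list with `segments` (data.frame: start, end, label),
#'   `swdFraction` (fraction of the trace labelled swd), `state`
#'   (`"seizure"`/`"preseizure"`) and the per-window `ratios`.
#' @export
classifyBrainState <- function(trace, band = c(4, 8),
                               ratioThreshold = 0.45, window = 2,
                               minDuration = 1) {
  stopifnot(is(trace, "CaTrace"))
  fs <- samplingRate(trace)
  if (band[2] >= fs / 2) stop("band must lie below Nyquist")
  x <- traceSamples(trace)
  n <- round(window * fs)
  if (n > length(x)) stop("window exceeds the trace duration")
  step <- max(1L, round(n / 2))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nf <- floor(n / 2) + 1L
  freqs <- (seq_len(nf) - 1) * fs / n
  inBand <- freqs >= band[1] & freqs <= band[2]
  ratios <- vapply(starts, function(s) {
    seg <- x[s:(s + n - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(nf)])^2
    p[1] <- 0
    tot <- sum(p)
    if (tot == 0) 0 else sum(p[inBand]) / tot
  }, numeric(1))
  hits <- ratios > ratioThreshold
  t0 <- (starts - 1) / fs
  t1 <- t0 + window
  # each hit window contributes its central half (one step), so merged
  # segments track burst edges to ~window/4
  pad <- (window - step / fs) / 2
  segs <- mergeWindows(t0[hits] + pad, t1[hits] - pad, minDuration)
  dur <- length(x) / fs
  swdFrac <- if (nrow(segs)) sum(segs$end - segs$start) / dur else 0
  list(segments = segs, swdFraction = swdFrac,
       state = if (nrow(segs)) "seizure" else "preseizure",
       ratios = data.frame(start = t0, end = t1, ratio = ratios))
}

mergeWindows <- function(t0, t1, minDuration) {
  if (!length(t0))
    return(data.frame(start = numeric(), end = numeric(),
                      label = character()))
  ord <- order(t0)
  t0 <- t0[ord]; t1 <- t1[ord]
  start <- t0[1]; end <- t1[1]
  out <- list()
  for (i in seq_along(t0)[-1]) {
    if (t0[i] <= end) {
      end <- max(end, t1[i])
    } else {
      out[[length(out) + 1L]] <- c(start, end)
      start <- t0[i]; end <- t1[i]
    }
  }
  out[[length(out) + 1L]] <- c(start, end)
  m <- do.call(rbind, out)
  keep <- (m[, 2] - m[, 1]) > minDuration
  data.frame(start = m[keep, 1], end = m[keep, 2],
             label = rep("swd", sum(keep)))
}
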