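#' Generate a synthetic calcium trace with spike-and-wave bursts
#'
#' Emulates a fiber-photometry Ca2+ recording of the two brain states seen
#' in absence-epileptic rats: a 1/f-like slow fluorescence background
#' (preseizure state) on which spike-and-wave discharge (SWD) bursts ride
#' during the seizure state. Bursts are an asymmetric sawtooth at the SWD
#' fundamental (default 6 Hz) plus a second-harmonic spike component, and
#' occupy `burstDuty` of the duration in alternating epochs laid out on a
#' fixed 20 s cycle (burst first, rest after, small seeded jitter of the
#' onset inside each cycle). The exact burst intervals are returned as
#' ground truth.
#'
#' @param duration trace duration in seconds (default 900 = 15 min).
#' @param samplingRate sampling rate in Hz; must exceed twice the highest
#'   generated frequency (the second harmonic, `2 * swdFrequency`);
#'   rates of 10x the fundamental or more are recommended to keep the
#'   waveform shape clean.
#' @param swdFrequency SWD fundamental frequency in Hz (default 6).
#' @param burstDuty fraction of the duration occupied by bursts, in
#'   \[0, 1\]; 0 gives the preseizure preset (background only).
#' @param burstAmplitude burst amplitude in units of the background SD
#'   (default 5, giving clear spectral separation of the two states).
#' @param seed RNG seed.
#' @return A [CaTrace-class] with ground-truth burst intervals.
#' @examples
#' pre <- generateCaTrace(60, burstDuty = 0)      # preseizure
#' sz  <- generateCaTrace(60, burstDuty = 0.5)    # seizure state
#' @export
generateCaTrace <- function(duration = 900, samplingRate = 100,
                            swdFrequency = 6, burstDuty = 0.5,
                            burstAmplitude = 5, seed = 1L) {
  if (samplingRate <= 2 * (2 * swdFrequency))
    stop("sampling rate must exceed twice the highest generated ",
         "frequency, 2 * (2 * swdFrequency) (Nyquist violated)")
  if (burstDuty < 0 || burstDuty > 1)
    stop("'burstDuty' must lie in [0, 1]")
  n <- round(duration * samplingRate)
  withr::with_seed(as.integer(seed), {
    bg <- oneOverFNoise(n, samplingRate)
    tt <- (seq_len(n) - 1) / samplingRate
    bursts <- matrix(numeric(0), 0, 2,
                     dimnames = list(NULL, c("start", "end")))
    x <- bg
    if (burstDuty > 0) {
      cycle <- min(20, duration)
      burstLen <- burstDuty * cycle
      starts <- seq(0, duration - 1e-9, by = cycle)
      jitter <- stats::runif(length(starts), 0,
                             pmax(0, cycle - burstLen))
      if (burstDuty >= 1) jitter <- rep(0, length(starts))
      b0 <- pmin(starts + jitter, duration)
      b1 <- pmin(b0 + burstLen, duration)
      keep <- b1 > b0
      bursts <- cbind(start = b0[keep], end = b1[keep])
      ph <- tt * swdFrequency
      saw <- 2 * (ph - floor(ph)) - 1
      spike <- 0.3 * cos(2 * pi * 2 * swdFrequency * tt)
      wav <- burstAmplitude * (saw + spike)
      inBurst <- rep(FALSE, n)
      for (i in seq_len(nrow(bursts)))
        inBurst[tt >= bursts[i, 1] & tt < bursts[i, 2]] <- TRUE
      x <- bg + wav * inBurst
    }
    new("CaTrace", samples = x, samplingRate = samplingRate,
        bursts = bursts)
  })
}

# 1/f-power background noise with unit SD, built by spectral shaping of
# white noise (amplitude ~ f^(-1/2) for f > 0).
oneOverFNoise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)
  scale <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

#' Read/write a calcium trace as CSV
#'
#' The file carries the sampling rate in a `# sampling_rate: <Hz>` header
#' line followed by a one-column CSV of samples.
#'
#' @param trace a [CaTrace-class]; @param path file path.
#' @return `readCaTrace` returns a [CaTrace-class] (without ground-truth
#'   intervals, which are not serialized).
#' @export
writeCaTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# sampling_rate: ", samplingRate(trace)), con)
  writeLines("value", con)
  writeLines(format(traceSamples(trace), digits = 10, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname writeCaTrace
#' @export
readCaTrace <- function(path) {
  header <- readLines(path, n = 1)
  fs <- as.numeric(sub("^#\\s*sampling_rate:\\s*", "", header))
  if (!is.finite(fs)) stop("missing '# sampling_rate:' header line")
  vals <- read.table(path, sep = ",", skip = 1, header = TRUE)[[1]]
  new("CaTrace", samples = as.numeric(vals), samplingRate = fs,
      bursts = matrix(numeric(0), 0, 2))
}
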