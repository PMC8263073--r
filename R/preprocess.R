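#' Read realignment motion parameters
#'
#' Whitespace-delimited text with one row per volume and six columns:
#' three translations (mm) followed by three rotations (degrees).
#'
#' @param path file path.
#' @return numeric matrix with columns tx, ty, tz, rx, ry, rz.
#' @export
readMotionParams <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("expected 6 columns (3 translations, 3 rotations)")
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Select the earliest motion-stable epoch
#'
#' Scans all contiguous windows of `epochLength` volumes and returns the
#' earliest one whose within-window peak-to-peak excursion stays strictly
#' below the translation threshold (every translation axis) and the
#' rotation threshold (every rotation axis). If the first window
#' qualifies, it is returned, i.e. by default the first 15 min of a run
#' are used unchanged.
#'
#' @param motion T x 6 motion-parameter matrix (translations mm, rotations
#'   degrees), as from [readMotionParams()].
#' @param epochLength window length in volumes.
#' @param maxTranslation peak-to-peak translation threshold (mm).
#' @param maxRotation peak-to-peak rotation threshold (degrees).
#' @return integer vector `c(start, end)` delimiting the half-open 1-based
#'   interval `[start, end)`, or `NULL` when no window qualifies (so the
#'   caller can drop the run).
#' @export
selectStableEpoch <- function(motion, epochLength, maxTranslation = 0.2,
                              maxRotation = 0.3) {
  motion <- as.matrix(motion)
  if (any(!is.finite(motion))) stop("motion parameters must be finite")
  nT <- nrow(motion)
  if (epochLength > nT)
    stop("epochLength (", epochLength, ") exceeds run length (", nT, ")")
  lim <- c(rep(maxTranslation, 3), rep(maxRotation, 3))
  # runs are short (a few thousand volumes), so a direct scan of every
  # window matches the exhaustive definition exactly at negligible cost
  for (s in seq_len(nT - epochLength + 1L)) {
    win <- motion[s:(s + epochLength - 1L), , drop = FALSE]
    ptp <- apply(win, 2, function(x) max(x) - min(x))
    if (all(ptp < lim)) return(c(start = s, end = s + epochLength))
  }
  NULL
}

#' Fourier low-pass filter
#'
#' Hard spectral low-pass: discrete Fourier coefficients at frequencies
#' strictly above the cutoff are set to zero and the series is inverse
#' transformed. The mean (DC component) is preserved exactly. Being a
#' projection onto a set of Fourier bins, the filter is linear and
#' idempotent; as a hard mask it can ring near sharp transients.
#'
#' @param ts a [RoiTimeSeries-class].
#' @param cutoff cutoff frequency in Hz; must be below Nyquist
#'   (`0.5 / tr`).
#' @return filtered [RoiTimeSeries-class].
#' @export
lowpassFourier <- function(ts, cutoff = 0.1) {
  stopifnot(is(ts, "RoiTimeSeries"))
  fs <- 1 / repetitionTime(ts)
  if (cutoff >= fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below Nyquist (", fs / 2, " Hz)")
  v <- tsMatrix(ts)
  n <- nrow(v)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)        # two-sided spectrum folded to [0, fs/2]
  keep <- f <= cutoff + 1e-12
  out <- apply(v, 2, function(x) {
    X <- stats::fft(x)
    X[!keep] <- 0 + 0i
    Re(stats::fft(X, inverse = TRUE)) / n
  })
  roiTimeSeries(out, tr = repetitionTime(ts), labels = regionLabels(ts))
}

#' Regress out the global signal
#'
#' Replaces each region's series by its residual after least-squares
#' regression on an intercept and the global mean signal (the mean across
#' regions at each time point). Residuals are exactly orthogonal to the
#' global mean. If the global signal is constant, the series are returned
#' mean-centered with a warning.
#'
#' @param ts a [RoiTimeSeries-class] with more than 2 time points.
#' @return residual [RoiTimeSeries-class].
#' @export
regressGlobalSignal <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  v <- tsMatrix(ts)
  if (nrow(v) <= 2) stop("need more than 2 time points")
  g <- rowMeans(v)
  if (stats::sd(g) == 0) {
    warning("global signal is constant; returning mean-centered series")
    out <- sweep(v, 2, colMeans(v))
  } else {
    fit <- stats::lm.fit(cbind(1, g), v)
    out <- fit$residuals
  }
  roiTimeSeries(out, tr = repetitionTime(ts), labels = regionLabels(ts))
}

#' In-plane Gaussian smoothing of a 4-D volume series
#'
#' Convolves every slice of every volume with a truncated 2-D Gaussian of
#' the stated full width at half maximum, evaluated in millimetres on the
#' in-plane pixel grid and normalized to unit sum. Boundaries are
#' zero-padded, so the total image sum is preserved up to truncation at
#' the edges.
#'
#' @param volumes 4-D numeric array (x, y, slice, time).
#' @param pixelSize in-plane pixel sizes in mm, length 2; required.
#' @param kernel odd kernel side length in pixels (default 3).
#' @param fwhm full width at half maximum in mm (default 0.6).
#' @return smoothed 4-D array.
#' @export
smoothImage <- function(volumes, pixelSize, kernel = 3, fwhm = 0.6) {
  if (missing(pixelSize) || length(pixelSize) != 2 ||
      any(!is.finite(pixelSize)) || any(pixelSize <= 0))
    stop("in-plane 'pixelSize' (mm, length 2) is required")
  if (kernel %% 2 != 1) stop("'kernel' must be odd")
  d <- dim(volumes)
  if (length(d) != 4) stop("expected a 4-D array (x, y, slice, time)")
  half <- (kernel - 1) / 2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  off <- seq(-half, half)
  K <- outer(off * pixelSize[1], off * pixelSize[2],
             function(dx, dy) exp(-(dx^2 + dy^2) / (2 * sigma^2)))
  K <- K / sum(K)
  out <- volumes
  for (t in seq_len(d[4])) for (z in seq_len(d[3]))
    out[, , z, t] <- convolve2d(volumes[, , z, t], K)
  out
}

# direct zero-padded 2-D convolution with a small centered kernel
convolve2d <- function(img, K) {
  half <- (nrow(K) - 1) / 2
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(0, nx, ny)
  for (i in seq(-half, half)) for (j in seq(-half, half)) {
    w <- K[i + half + 1, j + half + 1]
    if (w == 0) next
    xs <- max(1, 1 - i):min(nx, nx - i)
    ys <- max(1, 1 - j):min(ny, ny - j)
    out[xs, ys] <- out[xs, ys] + w * img[xs + i, ys + j]
  }
  out
}

#' Extract regional mean time series from a labelled volume series
#'
#' For every time point and atlas region, averages the voxels whose label
#' equals that region's (1-based) position in the atlas table.
#'
#' @param volumes 4-D numeric array (x, y, slice, time).
#' @param labelMap 3-D integer array of region labels (0 = background);
#'   label value `i` maps to row `i` of the atlas.
#' @param atlas atlas data.frame.
#' @param tr sampling interval in seconds.
#' @return A [RoiTimeSeries-class] (T x R).
#' @export
extractRoiTimeseries <- function(volumes, labelMap, atlas, tr = 1) {
  validateAtlas(atlas)
  d <- dim(volumes)
  if (!identical(dim(labelMap), d[1:3]))
    stop("label map dimensions must match the spatial volume dimensions")
  R <- nrow(atlas)
  lab <- as.integer(labelMap)
  counts <- tabulate(lab, nbins = R)
  if (any(counts == 0))
    stop("empty region(s): ",
         paste(atlas$region[counts == 0], collapse = ", "))
  nvox <- prod(d[1:3])
  M <- matrix(volumes, nvox, d[4])
  inside <- lab >= 1 & lab <= R
  sums <- rowsum(M[inside, , drop = FALSE], lab[inside])
  ts <- t(sums / counts[as.integer(rownames(sums))])
  roiTimeSeries(ts, tr = tr, labels = atlas$region)
}

#' Temporal signal-to-noise ratio over a mask
#'
#' Mean over masked voxels of (temporal mean / temporal SD). Voxels with
#' zero temporal SD are excluded and counted.
#'
#' @param volumes 4-D numeric array.
#' @param mask 3-D logical (or 0/1) array; must select at least one voxel.
#' @return numeric tSNR with attribute `"nExcluded"` (zero-SD voxels).
#' @export
temporalSNR <- function(volumes, mask) {
  d <- dim(volumes)
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!any(mask)) stop("mask is empty")
  M <- matrix(volumes, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE]
  mu <- rowMeans(M)
  s <- apply(M, 1, stats::sd)
  ok <- s > 0
  if (!any(ok)) stop("all masked voxels have zero temporal SD")
  out <- mean(mu[ok] / s[ok])
  attr(out, "nExcluded") <- sum(!ok)
  out
}

#' Read/write a 4-D NIfTI volume series
#'
#' Thin wrappers over RNifti keeping the voxel data as a plain array plus
#' the voxel sizes needed by [smoothImage()].
#'
#' @param path NIfTI file path; @param volumes 4-D array;
#' @param pixdim voxel sizes (mm), length 3.
#' @return `readVolumeSeries` returns `list(data = 4-D array, pixdim =
#'   voxel sizes in mm)`.
#' @export
readVolumeSeries <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       pixdim = RNifti::pixdim(img)[1:3])
}

#' @rdname readVolumeSeries
#' @export
writeVolumeSeries <- function(volumes, path, pixdim = c(1, 1, 1)) {
  img <- RNifti::asNifti(volumes)
  RNifti::pixdim(img) <- c(pixdim, rep(1, length(dim(volumes)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write ROI time series as CSV
#'
#' A `# tr: <seconds>` comment line followed by a T-row CSV with one
#' labelled column per region.
#'
#' @param ts a [RoiTimeSeries-class]; @param path file path.
#' @return `readTimeSeries` returns a [RoiTimeSeries-class].
#' @export
writeTimeSeries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tr: ", repetitionTime(ts)), con)
  utils::write.csv(as.data.frame(tsMatrix(ts)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  header <- readLines(path, n = 1)
  tr <- as.numeric(sub("^#\\s*tr:\\s*", "", header))
  if (!is.finite(tr)) stop("missing '# tr:' header line")
  v <- utils::read.csv(path, skip = 1, check.names = FALSE)
  roiTimeSeries(as.matrix(v), tr = tr, labels = colnames(v))
}
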