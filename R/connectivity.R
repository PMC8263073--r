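#' Pairwise Pearson connectivity matrix
#'
#' Computes the symmetric R x R matrix of Pearson correlation coefficients
#' between all pairs of regional time courses. Only positive correlations
#' are considered: negative coefficients are set to zero at construction.
#' The diagonal is stored as zero (self-connections carry no information).
#' Regions with constant series produce undefined correlations; their
#' edges are zeroed and the regions flagged.
#'
#' @param ts a [RoiTimeSeries-class] with at least 3 time points.
#' @return an r-domain [ConnectivityMatrix-class].
#' @export
correlationMatrix <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeries"))
  v <- tsMatrix(ts)
  if (nrow(v) < 3) stop("at least 3 time points are required")
  sds <- apply(v, 2, stats::sd)
  flagged <- regionLabels(ts)[sds == 0]
  r <- suppressWarnings(stats::cor(v))
  r[!is.finite(r)] <- 0
  r[r < 0] <- 0
  r[r >= 1] <- 1 - 1e-7
  diag(r) <- 0
  r <- (r + t(r)) / 2
  connectivityMatrix(r, domain = "r", nTimepoints = nrow(v),
                     labels = regionLabels(ts), flagged = flagged)
}

#' Convert a connectivity matrix between r and z domains
#'
#' Fisher transform `z = atanh(r)` (or its inverse). r values at or above
#' 1 off-diagonal are clipped to `1 - 1e-7` with a warning.
#'
#' @param mat a [ConnectivityMatrix-class].
#' @param domain target domain, `"r"` or `"z"`.
#' @return converted [ConnectivityMatrix-class].
#' @export
convertDomain <- function(mat, domain = c("z", "r")) {
  domain <- match.arg(domain)
  if (connDomain(mat) == domain) return(mat)
  w <- connWeights(mat)
  w <- if (domain == "z") atanh(clipUnitR(w)) else tanh(w)
  connectivityMatrix(w, domain = domain, nTimepoints = mat@nTimepoints,
                     labels = regionLabels(mat), flagged = mat@flagged)
}

clipUnitR <- function(w) {
  if (any(w >= 1)) {
    warning("correlation of 1 encountered; clipping to 1 - 1e-7")
    w[w >= 1] <- 1 - 1e-7
  }
  w
}

#' Fisher-domain average of connectivity matrices
#'
#' Per edge, r values are converted to Fisher z (`atanh`), averaged
#' arithmetically over matrices, and converted back (`tanh`). Zero edges
#' participate as z = 0. This is the group (or per-animal) averaging rule
#' for combining runs and subjects.
#'
#' @param matrices list of r-domain [ConnectivityMatrix-class] objects
#'   with identical region labels.
#' @return r-domain [ConnectivityMatrix-class]; `nTimepoints` is the
#'   rounded mean of the inputs'.
#' @export
fisherAverage <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix")
  labs <- regionLabels(matrices[[1]])
  for (m in matrices) {
    if (connDomain(m) != "r") stop("fisherAverage expects r-domain matrices")
    if (!identical(regionLabels(m), labs))
      stop("all matrices must share the same region labels")
  }
  zsum <- Reduce(`+`, lapply(matrices,
                             function(m) atanh(clipUnitR(connWeights(m)))))
  r <- tanh(zsum / length(matrices))
  diag(r) <- 0
  n <- round(mean(vapply(matrices, function(m) m@nTimepoints, 1)))
  connectivityMatrix(r, domain = "r", nTimepoints = n, labels = labs,
                     flagged = unique(unlist(lapply(matrices,
                                                    function(m) m@flagged))))
}

#' FDR-corrected edge significance mask
#'
#' Per unique off-diagonal edge, a two-sided p-value from the t transform
#' of the correlation coefficient, `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with n - 2 degrees of freedom, followed by Benjamini-Hochberg
#' correction across all R(R-1)/2 edges. The mask is TRUE where the
#' adjusted p-value is below `alpha`.
#'
#' @param mat r-domain [ConnectivityMatrix-class].
#' @param nTimepoints sample size per edge; defaults to the matrix's own.
#' @param alpha significance level (default 0.05).
#' @return list with symmetric matrices `mask` (logical), `p` and `pAdj`.
#' @export
fdrSignificanceMask <- function(mat, nTimepoints = mat@nTimepoints,
                                alpha = 0.05) {
  if (connDomain(mat) != "r") mat <- convertDomain(mat, "r")
  if (nTimepoints <= 3) stop("need more than 3 time points")
  w <- connWeights(mat)
  R <- nrow(w)
  ut <- upper.tri(w)
  r <- w[ut]
  df <- nTimepoints - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df)
  pAdj <- stats::p.adjust(p, method = "BH")
  mk <- function(vals, diagFill) {
    m <- matrix(diagFill, R, R, dimnames = dimnames(w))
    m[ut] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(mask = mk(pAdj < alpha, FALSE), p = mk(p, NA_real_),
       pAdj = mk(pAdj, NA_real_))
}

#' Read/write a connectivity matrix as labelled CSV
#'
#' @param mat a [ConnectivityMatrix-class]; @param path file path;
#' @param domain domain flag recorded in the header comment.
#' @return `readConnectivityMatrix` returns a [ConnectivityMatrix-class].
#' @export
writeConnectivityMatrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# domain: ", connDomain(mat), " n: ",
                    mat@nTimepoints), con)
  utils::write.csv(as.data.frame(connWeights(mat)), con, row.names = TRUE)
  invisible(path)
}

#' @rdname writeConnectivityMatrix
#' @export
readConnectivityMatrix <- function(path) {
  header <- readLines(path, n = 1)
  domain <- sub("^#\\s*domain:\\s*(\\w+)\\s+n:.*$", "\\1", header)
  n <- as.integer(sub("^.*n:\\s*(\\d+).*$", "\\1", header))
  m <- utils::read.csv(path, skip = 1, row.names = 1, check.names = FALSE)
  connectivityMatrix(as.matrix(m), domain = domain, nTimepoints = n,
                     labels = colnames(m))
}
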