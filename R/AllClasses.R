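#' @import methods
#' @importFrom stats cor sd fft var t.test wilcox.test p.adjust pt lm anova
#'   quantile median rnorm runif filter setNames aggregate complete.cases
#' @importFrom utils head read.table write.table
NULL

#' Regional signal time courses
#'
#' A T x R matrix of regional signals (one column per brain region) with its
#' sampling interval (TR, seconds) and region labels. This is the unit on
#' which temporal preprocessing and connectivity estimation operate.
#'
#' @slot values numeric matrix, T time points by R regions.
#' @slot tr sampling interval in seconds.
#' @slot labels character vector of unique region abbreviations, one per
#'   column.
#' @export
setClass("RoiTimeSeries",
  slots = c(values = "matrix", tr = "numeric", labels = "character"))

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@values)) msg <- c(msg, "'values' must be numeric")
  if (nrow(object@values) < 2) msg <- c(msg, "need at least 2 time points")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a single positive number")
  if (length(object@labels) != ncol(object@values))
    msg <- c(msg, "one label per region required")
  if (anyDuplicated(object@labels)) msg <- c(msg, "region labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param values T x R numeric matrix of regional signals.
#' @param tr sampling interval (seconds).
#' @param labels region labels; defaults to the column names of `values`.
#' @return A [RoiTimeSeries-class] object.
#' @export
roiTimeSeries <- function(values, tr, labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) labels <- paste0("R", seq_len(ncol(values)))
  colnames(values) <- labels
  new("RoiTimeSeries", values = values, tr = as.numeric(tr),
      labels = as.character(labels))
}

#' Functional connectivity matrix
#'
#' Symmetric R x R matrix of edge weights in the correlation (`"r"`) or
#' Fisher (`"z"`) domain. The diagonal is stored as zero and excluded from
#' all statistics; in the r domain only non-negative weights are retained
#' (negative correlations are zeroed at construction).
#'
#' @slot weights symmetric numeric matrix, zero diagonal.
#' @slot domain `"r"` or `"z"`.
#' @slot nTimepoints number of time points each matrix entry was estimated
#'   from (used as the degrees-of-freedom basis for edge significance).
#' @slot labels region labels.
#' @slot flagged labels of regions whose series were constant and whose
#'   edges were therefore zeroed.
#' @export
setClass("ConnectivityMatrix",
  slots = c(weights = "matrix", domain = "character",
            nTimepoints = "integer", labels = "character",
            flagged = "character"))

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  w <- object@weights
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10)))
    msg <- c(msg, "weights must be symmetric")
  if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be stored as zero")
  if (!object@domain %in% c("r", "z"))
    msg <- c(msg, "domain must be 'r' or 'z'")
  if (object@domain == "r" && (any(w < 0) || any(w >= 1)))
    msg <- c(msg, "r-domain weights must lie in [0, 1)")
  if (any(!is.finite(w))) msg <- c(msg, "weights must be finite")
  if (length(object@labels) != nrow(w))
    msg <- c(msg, "one label per region required")
  if (length(msg)) msg else TRUE
})

connectivityMatrix <- function(weights, domain, nTimepoints, labels,
                               flagged = character()) {
  dimnames(weights) <- list(labels, labels)
  new("ConnectivityMatrix", weights = weights, domain = domain,
      nTimepoints = as.integer(nTimepoints), labels = as.character(labels),
      flagged = flagged)
}

#' Density-thresholded network
#'
#' Undirected weighted graph obtained by retaining the strongest edges of a
#' connectivity matrix at a target mean degree k; the substrate for all
#' graph metrics. The underlying container is an [igraph::igraph] graph
#' carrying all R regions as vertices (isolated vertices allowed) and an
#' edge attribute `weight`.
#'
#' @slot graph an igraph object.
#' @slot k target mean degree (edges per node) requested at thresholding.
#' @slot m realized edge count, `floor(R * k / 2)`.
#' @slot labels region labels in atlas order.
#' @export
setClass("ThresholdedNetwork",
  slots = c(graph = "ANY", k = "numeric", m = "integer", labels = "character"))

setValidity("ThresholdedNetwork", function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) msg <- c(msg, "'graph' must be an igraph object")
  else {
    if (igraph::any_loop(g)) msg <- c(msg, "self-loops are not allowed")
    w <- igraph::E(g)$weight
    if (!is.null(w) && any(w <= 0)) msg <- c(msg, "edge weights must be > 0")
    if (igraph::ecount(g) != object@m)
      msg <- c(msg, "edge count does not match 'm'")
  }
  if (length(msg)) msg else TRUE
})

#' Wrap an igraph graph as a ThresholdedNetwork
#'
#' Convenience constructor used for benchmark topologies (lattices, rewired
#' lattices, random graphs) that enter the metric pipeline without passing
#' through connectivity estimation. Unweighted graphs are given unit
#' weights.
#'
#' @param graph an undirected igraph object without self-loops.
#' @param k nominal mean degree to record; defaults to `2 * m / n`.
#' @return A [ThresholdedNetwork-class] object.
#' @export
thresholdedNetwork <- function(graph, k = 2 * igraph::ecount(graph) /
                                 igraph::vcount(graph)) {
  if (is.null(igraph::E(graph)$weight))
    igraph::E(graph)$weight <- rep(1, igraph::ecount(graph))
  labels <- igraph::V(graph)$name
  if (is.null(labels)) {
    labels <- paste0("R", seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- labels
  }
  new("ThresholdedNetwork", graph = graph, k = k,
      m = as.integer(igraph::ecount(graph)), labels = labels)
}

#' Community partition of a network
#'
#' @slot membership named integer vector mapping each region to a community
#'   id; ids are dense integers starting at 1.
#' @slot Q weighted modularity of the partition.
#' @slot resolution resolution parameter used.
#' @slot seed master seed of the restart schedule.
#' @export
setClass("Partition",
  slots = c(membership = "integer", Q = "numeric", resolution = "numeric",
            seed = "integer"))

setValidity("Partition", function(object) {
  m <- object@membership
  ids <- sort(unique(m))
  if (length(ids) && !identical(ids, seq_along(ids)))
    return("community ids must be dense integers starting at 1")
  TRUE
})

#' Network-based statistic result
#'
#' Edge-wise two-sample t statistics, the supra-threshold edge mask split by
#' contrast direction, connected components of that mask, and each
#' component's permutation probability.
#'
#' @slot tMatrix symmetric matrix of edge t statistics (group A minus B).
#' @slot pMatrix symmetric matrix of two-sided edge p-values.
#' @slot supraMask list of two logical matrices (`AgtB`, `BgtA`).
#' @slot components data.frame with one row per supra-threshold component:
#'   direction, component id, node count, edge count, permutation p.
#' @slot members list (parallel to `components` rows) of the node labels of
#'   each component.
#' @slot nullMax permutation null distribution of the maximal component
#'   edge count.
#' @slot nPerm number of permutations; @slot seed RNG seed;
#' @slot alpha primary edge threshold level.
#' @export
setClass("NbsResult",
  slots = c(tMatrix = "matrix", pMatrix = "matrix", supraMask = "list",
            components = "data.frame", members = "list",
            nullMax = "numeric", nPerm = "integer", seed = "integer",
            alpha = "numeric"))

#' Optical calcium trace
#'
#' A 1-D fluorescence signal (arbitrary units) with its sampling rate and,
#' for synthetic traces, the ground-truth spike-and-wave burst intervals.
#'
#' @slot samples numeric vector.
#' @slot samplingRate sampling rate in Hz.
#' @slot bursts two-column matrix of burst start/end times (seconds);
#'   zero rows when no bursts are present or the truth is unknown.
#' @export
setClass("CaTrace",
  slots = c(samples = "numeric", samplingRate = "numeric", bursts = "matrix"))

setValidity("CaTrace", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (ncol(object@bursts) != 2) msg <- c(msg, "bursts must have 2 columns")
  dur <- length(object@samples) / object@samplingRate
  if (nrow(object@bursts) &&
      (any(object@bursts < 0) || any(object@bursts > dur + 1e-9)))
    msg <- c(msg, "burst intervals must lie within the trace duration")
  if (length(msg)) msg else TRUE
})

## ---- accessors -----------------------------------------------------------

#' @describeIn RoiTimeSeries-class the T x R signal matrix.
#' @param x object.
#' @export
setGeneric("tsMatrix", function(x) standardGeneric("tsMatrix"))
#' @export
setMethod("tsMatrix", "RoiTimeSeries", function(x) x@values)

#' @describeIn RoiTimeSeries-class the sampling interval in seconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @export
setMethod("repetitionTime", "RoiTimeSeries", function(x) x@tr)

#' Region labels of a container
#' @param x object carrying region labels.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @export
setMethod("regionLabels", "RoiTimeSeries", function(x) x@labels)
#' @export
setMethod("regionLabels", "ConnectivityMatrix", function(x) x@labels)
#' @export
setMethod("regionLabels", "ThresholdedNetwork", function(x) x@labels)

#' @describeIn ConnectivityMatrix-class the symmetric weight matrix.
#' @param x object.
#' @export
setGeneric("connWeights", function(x) standardGeneric("connWeights"))
#' @export
setMethod("connWeights", "ConnectivityMatrix", function(x) x@weights)

#' @describeIn ConnectivityMatrix-class the weight domain, `"r"` or `"z"`.
#' @export
setGeneric("connDomain", function(x) standardGeneric("connDomain"))
#' @export
setMethod("connDomain", "ConnectivityMatrix", function(x) x@domain)

#' @describeIn ThresholdedNetwork-class the underlying igraph object.
#' @export
setGeneric("netGraph", function(x) standardGeneric("netGraph"))
#' @export
setMethod("netGraph", "ThresholdedNetwork", function(x) x@graph)

#' Community membership of a Partition
#' @param x a [Partition-class].
#' @return named integer vector of community ids.
#' @export
communityMembership <- function(x) {
  stopifnot(is(x, "Partition"))
  x@membership
}

#' @describeIn CaTrace-class the sample vector.
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))
#' @export
setMethod("traceSamples", "CaTrace", function(x) x@samples)

#' @describeIn CaTrace-class sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "CaTrace", function(x) x@samplingRate)

#' @describeIn CaTrace-class ground-truth burst intervals (seconds).
#' @export
setGeneric("burstIntervals", function(x) standardGeneric("burstIntervals"))
#' @export
setMethod("burstIntervals", "CaTrace", function(x) x@bursts)

## ---- show methods --------------------------------------------------------

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries:", nrow(object@values), "time points x",
      ncol(object@values), "regions, TR =", object@tr, "s\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@weights
  nz <- sum(w[upper.tri(w)] != 0)
  cat("ConnectivityMatrix (", object@domain, "-domain): ", nrow(w), " x ",
      ncol(w), ", ", nz, " nonzero edges, n = ", object@nTimepoints,
      " time points\n", sep = "")
  if (length(object@flagged))
    cat("  flagged constant regions:",
        paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat("ThresholdedNetwork:", igraph::vcount(object@graph), "nodes,",
      object@m, "edges (target mean degree k =", object@k, ")\n")
})

setMethod("show", "Partition", function(object) {
  cat("Partition:", length(unique(object@membership)), "communities over",
      length(object@membership), "nodes, Q =",
      format(object@Q, digits = 4),
      "(resolution", object@resolution, ")\n")
})

setMethod("show", "NbsResult", function(object) {
  cat("NbsResult:", nrow(object@components), "supra-threshold component(s),",
      object@nPerm, "permutations, alpha =", object@alpha, "\n")
  if (nrow(object@components)) print(object@components)
})

setMethod("show", "CaTrace", function(object) {
  cat("CaTrace:", length(object@samples), "samples at",
      object@samplingRate, "Hz (",
      format(length(object@samples) / object@samplingRate, digits = 4),
      "s ),", nrow(object@bursts), "ground-truth burst interval(s)\n")
})
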