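#' Edge-wise two-sample t statistics between groups
#'
#' For every unique edge, a homoscedastic (pooled-variance) two-sample
#' t-test on the subjects' Fisher z values, group A minus group B, with a
#' two-sided p-value. r-domain matrices are converted to z first. Edges
#' with zero pooled variance get t = 0 and are flagged.
#'
#' @param groupA,groupB lists of [ConnectivityMatrix-class] objects (one
#'   per subject) with identical region labels; at least 2 per group.
#' @return list with symmetric matrices `t` and `p`, the degrees of
#'   freedom `df`, and `nZeroVar` (count of zero-variance edges).
#' @export
edgeTMatrix <- function(groupA, groupB) {
  ZA <- stackZ(groupA); ZB <- stackZ(groupB)
  if (nrow(ZA$z) < 2 || nrow(ZB$z) < 2)
    stop("need at least 2 subjects per group")
  if (!identical(ZA$labels, ZB$labels))
    stop("groups must share the same region labels")
  res <- pooledT(ZA$z, ZB$z)
  R <- length(ZA$labels)
  ut <- upper.tri(matrix(0, R, R))
  sym <- function(vals, diagFill) {
    m <- matrix(diagFill, R, R, dimnames = list(ZA$labels, ZA$labels))
    m[ut] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(t = sym(res$t, 0), p = sym(res$p, NA_real_), df = res$df,
       nZeroVar = sum(res$zeroVar))
}

# subjects x unique-edges matrix of Fisher z values
stackZ <- function(group) {
  if (!length(group)) stop("empty group")
  labels <- regionLabels(group[[1]])
  z <- t(vapply(group, function(m) {
    if (!identical(regionLabels(m), labels))
      stop("all matrices must share the same region labels")
    w <- connWeights(convertDomain(m, "z"))
    w[upper.tri(w)]
  }, numeric(length(labels) * (length(labels) - 1) / 2)))
  list(z = z, labels = labels)
}

pooledT <- function(zA, zB) {
  nA <- nrow(zA); nB <- nrow(zB)
  df <- nA + nB - 2
  mA <- colMeans(zA); mB <- colMeans(zB)
  vA <- colSums(sweep(zA, 2, mA)^2)
  vB <- colSums(sweep(zB, 2, mB)^2)
  sp2 <- (vA + vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  zeroVar <- se == 0
  t <- ifelse(zeroVar, 0, (mA - mB) / ifelse(zeroVar, 1, se))
  p <- 2 * stats::pt(-abs(t), df)
  p[zeroVar] <- 1
  list(t = t, p = p, df = df, zeroVar = zeroVar)
}

#' Network-based statistic (NBS) between two groups
#'
#' Edge-wise homoscedastic t-tests in the Fisher z domain, a primary edge
#' threshold, connected-component extraction among supra-threshold edges
#' split by contrast direction (A > B and B > A), and a permutation null
#' for the maximal component size. The default primary threshold keeps
#' edges whose Benjamini-Hochberg-adjusted p-value is below `alpha`
#' (FDR-thresholded NBS); the classic uncorrected-threshold variant is
#' available via `primary = "uncorrected"`. The null distribution is the
#' maximal supra-threshold component edge count over both directions,
#' recomputed with the same thresholding rule for each of `nPerm` random
#' relabelings of the subjects; each observed component's probability is
#' `(1 + #(null >= observed)) / (nPerm + 1)`.
#'
#' @param groupA,groupB lists of per-subject [ConnectivityMatrix-class]
#'   objects; at least 2 per group.
#' @param alpha primary edge threshold level (default 0.05).
#' @param nPerm number of permutations (default 1000; below 100 a warning
#'   is issued since p-value resolution degrades).
#' @param seed RNG seed.
#' @param primary `"fdr"` (BH-adjusted edge p, default) or
#'   `"uncorrected"` (raw edge p).
#' @return An [NbsResult-class].
#' @export
nbsTest <- function(groupA, groupB, alpha = 0.05, nPerm = 1000,
                    seed = 1L, primary = c("fdr", "uncorrected")) {
  primary <- match.arg(primary)
  ZA <- stackZ(groupA); ZB <- stackZ(groupB)
  nA <- nrow(ZA$z); nB <- nrow(ZB$z)
  if (nA < 2 || nB < 2) stop("need at least 2 subjects per group")
  if (!identical(ZA$labels, ZB$labels))
    stop("groups must share the same region labels")
  if (nPerm < 100)
    warning("fewer than 100 permutations limits p-value resolution")
  labels <- ZA$labels
  R <- length(labels)
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  Z <- rbind(ZA$z, ZB$z)
  inA <- seq_len(nA)

  supra <- function(idxA) {
    res <- pooledT(Z[idxA, , drop = FALSE], Z[-idxA, , drop = FALSE])
    pth <- if (primary == "fdr") stats::p.adjust(res$p, "BH") else res$p
    keep <- pth < alpha
    list(pos = which(keep & res$t > 0), neg = which(keep & res$t < 0),
         t = res$t, p = res$p)
  }
  componentsOf <- function(edgeIdx) {
    if (!length(edgeIdx)) return(list())
    g <- igraph::graph_from_edgelist(
      cbind(labels[ut[edgeIdx, 1]], labels[ut[edgeIdx, 2]]),
      directed = FALSE)
    comp <- igraph::components(g)
    lapply(seq_len(comp$no), function(ci) {
      nodes <- names(comp$membership)[comp$membership == ci]
      both <- labels[ut[edgeIdx, 1]] %in% nodes &
        labels[ut[edgeIdx, 2]] %in% nodes
      list(nodes = nodes, nEdges = sum(both))
    })
  }

  obs <- supra(inA)
  obsComp <- list(AgtB = componentsOf(obs$pos), BgtA = componentsOf(obs$neg))

  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nPerm), function(i) {
      idxA <- sample(nA + nB, nA)
      s <- supra(idxA)
      sizes <- c(vapply(componentsOf(s$pos), `[[`, 1, "nEdges"),
                 vapply(componentsOf(s$neg), `[[`, 1, "nEdges"), 0)
      max(sizes)
    }, numeric(1))
  })

  rows <- list(); members <- list()
  for (dir in names(obsComp)) {
    for (ci in seq_along(obsComp[[dir]])) {
      cc <- obsComp[[dir]][[ci]]
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, component = ci, nNodes = length(cc$nodes),
        nEdges = cc$nEdges,
        pPerm = (1 + sum(null >= cc$nEdges)) / (nPerm + 1))
      members[[length(members) + 1L]] <- cc$nodes
    }
  }
  comps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), component = integer(),
               nNodes = integer(), nEdges = integer(), pPerm = numeric())
  sym <- function(vals, diagFill) {
    m <- matrix(diagFill, R, R, dimnames = list(labels, labels))
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  maskOf <- function(idx) {
    v <- logical(nrow(ut)); v[idx] <- TRUE
    sym(v, FALSE)
  }
  new("NbsResult",
      tMatrix = sym(obs$t, 0), pMatrix = sym(obs$p, NA_real_),
      supraMask = list(AgtB = maskOf(obs$pos), BgtA = maskOf(obs$neg)),
      components = comps, members = members, nullMax = null,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      alpha = alpha)
}
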