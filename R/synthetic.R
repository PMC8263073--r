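#' Specify the planted correlation structure of synthetic ROI time series
#'
#' Defines the population correlation matrix from which synthetic subjects
#' are drawn: block-correlated functional groups, a weak global baseline
#' between groups, elevated thalamo-cortical coupling (the thalamus acting
#' as a connector between blocks, as in the cortico-thalamo-cortical
#' circuitry of absence epilepsy), strong homotopic (left-right) coupling,
#' and a fixed per-edge jitter that gives the weight distribution the
#' smooth, heterogeneous profile of real connectivity matrices. Optional
#' group effects add a delta to named block-pair edge sets (e.g. all
#' intrathalamic edges) so that group contrasts have known ground truth.
#'
#' @param atlas atlas data.frame from [generateAtlas()].
#' @param withinBlock within-functional-group correlation target; a scalar
#'   or a vector named by functional group.
#' @param betweenBlock baseline correlation target between groups.
#' @param thalamusBridge correlation target between thalamic and
#'   non-thalamic regions (overrides the baseline); set equal to
#'   `betweenBlock` to disable.
#' @param homotopic correlation target for left-right pairs of the same
#'   region.
#' @param jitterSD standard deviation of the fixed per-edge jitter added to
#'   the targets (0 disables).
#' @param noiseSD marginal standard deviation of each regional signal.
#' @param ar AR(1) coefficient of the temporal smoothing applied to every
#'   region (mimics hemodynamic autocorrelation; 0 disables).
#' @param groupEffects list of effects, each a `list(from=, to=, delta=)`
#'   naming two functional groups and the additive correlation delta
#'   applied to every edge between them (applied before PSD repair).
#' @param jitterSeed seed fixing the jitter realization; part of the
#'   specification, so two specs with the same seed share targets.
#' @return object of class `fcCommunitySpec` (a list) with the atlas, the
#'   parameters, and the repaired target correlation matrix.
#' @export
communitySpec <- function(atlas,
                          withinBlock = 0.45,
                          betweenBlock = 0.15,
                          thalamusBridge = 0.25,
                          homotopic = 0.70,
                          jitterSD = 0.12,
                          noiseSD = 1,
                          ar = 0.3,
                          groupEffects = list(),
                          jitterSeed = 1L) {
  validateAtlas(atlas)
  targets <- c(withinBlock, betweenBlock, thalamusBridge, homotopic)
  if (any(targets < 0) || any(targets >= 1))
    stop("all correlation targets must lie in [0, 1)")
  spec <- structure(list(atlas = atlas, withinBlock = withinBlock,
                         betweenBlock = betweenBlock,
                         thalamusBridge = thalamusBridge,
                         homotopic = homotopic, jitterSD = jitterSD,
                         noiseSD = noiseSD, ar = ar,
                         groupEffects = groupEffects,
                         jitterSeed = as.integer(jitterSeed)),
                    class = "fcCommunitySpec")
  spec$target <- targetCorrelation(spec)
  spec
}

#' Target correlation matrix of a community specification
#'
#' Assembles the raw block-structured target matrix and repairs it to the
#' nearest-in-spirit positive semi-definite correlation matrix (eigenvalue
#' clipping at 1e-8 followed by renormalization to unit diagonal). The
#' maximum absolute adjustment made by the repair is attached as attribute
#' `"maxAdjustment"`.
#'
#' @param spec an `fcCommunitySpec`.
#' @return R x R correlation matrix with unit diagonal, labelled by region.
#' @export
targetCorrelation <- function(spec) {
  atlas <- spec$atlas
  R <- nrow(atlas)
  grp <- atlas$group
  tgt <- matrix(spec$betweenBlock, R, R)
  isThal <- grp == "thalamus"
  if (any(isThal) && any(!isThal)) {
    tgt[isThal, !isThal] <- spec$thalamusBridge
    tgt[!isThal, isThal] <- spec$thalamusBridge
  }
  wb <- spec$withinBlock
  for (g in unique(grp)) {
    idx <- which(grp == g)
    w <- if (length(wb) > 1) {
      if (!g %in% names(wb)) stop("no withinBlock target for group ", g)
      wb[[g]]
    } else wb
    tgt[idx, idx] <- w
  }
  hp <- homotopicPairs(atlas)
  il <- match(hp[, "left"], atlas$region)
  ir <- match(hp[, "right"], atlas$region)
  tgt[cbind(il, ir)] <- spec$homotopic
  tgt[cbind(ir, il)] <- spec$homotopic
  for (eff in spec$groupEffects) {
    a <- which(grp == eff$from); b <- which(grp == eff$to)
    if (!length(a) || !length(b))
      stop("group effect names unknown functional group")
    tgt[a, b] <- tgt[a, b] + eff$delta
    tgt[b, a] <- tgt[b, a] + eff$delta
  }
  if (spec$jitterSD > 0) {
    jit <- withr::with_seed(spec$jitterSeed, {
      j <- matrix(stats::rnorm(R * R, sd = spec$jitterSD), R, R)
      (j + t(j)) / sqrt(2)
    })
    tgt <- tgt + jit
  }
  tgt <- pmin(pmax(tgt, 0), 0.95)
  diag(tgt) <- 1
  if (any(tgt < 0) || any(tgt[upper.tri(tgt)] >= 1))
    stop("targets (after deltas) must remain in [0, 1)")
  out <- psdRepair(tgt)
  dimnames(out) <- list(atlas$region, atlas$region)
  out
}

#' Repair a target matrix to positive semi-definiteness
#'
#' Clips eigenvalues at `minEig` and renormalizes to unit diagonal.
#' Deterministic, with bounded distortion reported via the
#' `"maxAdjustment"` attribute (the largest absolute change to any entry).
#'
#' @param tgt symmetric matrix with unit diagonal.
#' @param minEig eigenvalue floor.
#' @return repaired correlation matrix.
#' @export
psdRepair <- function(tgt, minEig = 1e-8) {
  e <- eigen(tgt, symmetric = TRUE)
  if (min(e$values) >= minEig) {
    attr(tgt, "maxAdjustment") <- 0
    return(tgt)
  }
  v <- pmax(e$values, minEig)
  rep <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(rep))
  rep <- rep / tcrossprod(d)
  rep <- (rep + t(rep)) / 2
  diag(rep) <- 1
  adj <- max(abs(rep - tgt))
  e2 <- eigen(rep, symmetric = TRUE, only.values = TRUE)$values
  if (min(e2) < -1e-10)
    stop("PSD repair failed; smallest eigenvalue ", format(min(e2)))
  attr(rep, "maxAdjustment") <- adj
  rep
}

#' Generate a group of synthetic subjects
#'
#' Draws `nSubjects` independent T x R regional time series from a
#' zero-mean Gaussian process whose population correlation matrix equals
#' the specification's (repaired) target. Correlation is imposed through
#' the symmetric matrix square root of the target; optional AR(1) temporal
#' smoothing is then applied identically to every region, which preserves
#' the contemporaneous correlation structure. Identical seeds reproduce
#' identical output.
#'
#' @param atlas atlas data.frame (must match the spec's atlas).
#' @param spec an `fcCommunitySpec` from [communitySpec()].
#' @param nSubjects number of subjects.
#' @param nTimepoints time points per subject (default 900, i.e. 15 min at
#'   TR = 1 s).
#' @param tr sampling interval in seconds.
#' @param seed RNG seed.
#' @return list of [RoiTimeSeries-class], one per subject.
#' @examples
#' atlas <- generateAtlas(2, c(thalamus = 2))
#' spec <- communitySpec(atlas, jitterSD = 0)
#' ts <- generateGroupTimeseries(atlas, spec, nSubjects = 2,
#'                               nTimepoints = 100, seed = 1)
#' @export
generateGroupTimeseries <- function(atlas, spec, nSubjects,
                                    nTimepoints = 900, tr = 1, seed = 1L) {
  validateAtlas(atlas)
  if (!identical(atlas$region, spec$atlas$region))
    stop("atlas does not match the specification's atlas")
  tgt <- spec$target
  e <- eigen(tgt, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("target correlation is not PSD after repair; smallest eigenvalue ",
         format(min(e$values)))
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  R <- nrow(tgt)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nSubjects), function(s) {
      x <- matrix(stats::rnorm(nTimepoints * R), nTimepoints, R) %*% S
      if (spec$ar > 0)
        x <- apply(x, 2, function(col)
          as.numeric(stats::filter(col, spec$ar, method = "recursive")))
      x <- x * spec$noiseSD
      roiTimeSeries(x, tr = tr, labels = atlas$region)
    })
  })
}
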