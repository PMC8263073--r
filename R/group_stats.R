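#' Compare edge-weight distributions between two group matrices
#'
#' Mann-Whitney (Wilcoxon rank-sum) test on the two sets of nonzero edge
#' Fisher z values of the group-average matrices — the comparison behind
#' "right-shifted z-value histogram" statements. r-domain matrices are
#' converted to z first.
#'
#' @param matA,matB [ConnectivityMatrix-class] objects.
#' @return list with `U` statistic, two-sided `p`, sample sizes `nA` and
#'   `nB`, group medians and the `direction` of the median shift
#'   (`"A>B"`, `"B>A"` or `"none"`).
#' @export
compareZDistributions <- function(matA, matB) {
  za <- edgeSamples(matA); zb <- edgeSamples(matB)
  if (length(za) < 2 || length(zb) < 2)
    stop("need at least 2 nonzero edges per matrix")
  wt <- suppressWarnings(stats::wilcox.test(za, zb, exact = FALSE))
  mA <- stats::median(za); mB <- stats::median(zb)
  list(U = unname(wt$statistic), p = wt$p.value,
       nA = length(za), nB = length(zb),
       medianA = mA, medianB = mB,
       direction = if (mA > mB) "A>B" else if (mB > mA) "B>A" else "none")
}

edgeSamples <- function(mat) {
  w <- connWeights(convertDomain(mat, "z"))
  v <- w[upper.tri(w)]
  v[v != 0]
}

#' Assemble a long-format local-parameter table
#'
#' Combines per-subject node metric tables into the long format used by
#' the group-level ANOVA and post-hoc tests: one row per (subject,
#' region, metric).
#'
#' @param metricTables list of data.frames from [nodeMetrics()] (possibly
#'   with a hub score column added), one per subject.
#' @param subjects subject identifiers (recycled names allowed).
#' @param groups group label per subject.
#' @return long data.frame with columns subject, group, region, metric,
#'   value.
#' @export
localParamTable <- function(metricTables, subjects, groups) {
  stopifnot(length(metricTables) == length(subjects),
            length(subjects) == length(groups))
  out <- do.call(rbind, lapply(seq_along(metricTables), function(i) {
    tb <- metricTables[[i]]
    metrics <- setdiff(names(tb), "region")
    do.call(rbind, lapply(metrics, function(m)
      data.frame(subject = subjects[i], group = groups[i],
                 region = tb$region, metric = m, value = tb[[m]],
                 stringsAsFactors = FALSE)))
  }))
  rownames(out) <- NULL
  out
}

#' Two-factor ANOVA on a local node parameter
#'
#' Fixed-effects ANOVA of a node metric with factors group and brain
#' region and their interaction. Type-II sums of squares are used, which
#' coincide with the standard two-way decomposition for balanced designs
#' and remain well-defined for the unbalanced group sizes typical of
#' animal studies. With a single region the model collapses to a one-way
#' group comparison (F = t^2 against the two-sample t-test).
#'
#' @param table long-format data.frame from [localParamTable()].
#' @param metric metric name to analyze.
#' @return data.frame with rows for group, region (if present) and
#'   group:region: term, df, F, p, plus the residual df as attribute
#'   `"dfResidual"`.
#' @export
anovaLocalParams <- function(table, metric) {
  d <- table[table$metric == metric, ]
  if (!nrow(d)) stop("no rows for metric '", metric, "'")
  d$group <- factor(d$group); d$region <- factor(d$region)
  if (nlevels(d$group) < 2) stop("need at least 2 groups")
  if (nlevels(d$region) >= 2) {
    cells <- table(d$group, d$region)
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE)
      stop("empty cells: ",
           paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                 sep = ":", collapse = ", "))
    }
    fit <- stats::lm(value ~ group * region, data = d)
    a <- car::Anova(fit, type = 2)
    terms <- c("group", "region", "group:region")
    out <- data.frame(term = terms,
                      df = a[terms, "Df"],
                      F = a[terms, "F value"],
                      p = a[terms, "Pr(>F)"])
    attr(out, "dfResidual") <- a["Residuals", "Df"]
  } else {
    fit <- stats::lm(value ~ group, data = d)
    a <- stats::anova(fit)
    out <- data.frame(term = "group", df = a["group", "Df"],
                      F = a["group", "F value"], p = a["group", "Pr(>F)"])
    attr(out, "dfResidual") <- a["Residuals", "Df"]
  }
  rownames(out) <- NULL
  out
}

#' Region-wise post-hoc t-tests between two groups
#'
#' Per region, an unpaired homoscedastic two-sided t-test on the subject
#' values of the chosen metric. Raw p-values are reported (the
#' convention for descriptive post-hoc maps), with a Benjamini-Hochberg
#' adjusted column always emitted alongside. Regions with fewer than 2
#' subjects in either group are skipped and flagged.
#'
#' @param table long-format data.frame from [localParamTable()] with
#'   exactly two groups.
#' @param metric metric name.
#' @return data.frame: region, nA, nB, meanA, meanB, t, df, p, pAdj;
#'   skipped regions in attribute `"skipped"`.
#' @export
posthocTTests <- function(table, metric) {
  d <- table[table$metric == metric, ]
  if (!nrow(d)) stop("no rows for metric '", metric, "'")
  gl <- unique(d$group)
  if (length(gl) != 2) stop("exactly two groups required")
  regions <- unique(d$region)
  skipped <- character()
  rows <- lapply(regions, function(r) {
    a <- d$value[d$region == r & d$group == gl[1]]
    b <- d$value[d$region == r & d$group == gl[2]]
    if (length(a) < 2 || length(b) < 2) {
      skipped <<- c(skipped, r)
      return(NULL)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(region = r, nA = length(a), nB = length(b),
               meanA = mean(a), meanB = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), nA = integer(), nB = integer(),
                      meanA = numeric(), meanB = numeric(), t = numeric(),
                      df = numeric(), p = numeric())
  out$pAdj <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  if (length(skipped)) {
    warning("skipped region(s) with n < 2 per group: ",
            paste(skipped, collapse = ", "))
    attr(out, "skipped") <- skipped
  }
  out
}
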