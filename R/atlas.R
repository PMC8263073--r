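#' Generate a bilateral brain atlas
#'
#' Builds the region table used throughout the pipeline: a set of bilateral
#' regions, each present once per hemisphere with mirrored abbreviations
#' (`_L` / `_R` suffixes) and a functional-group label. The default emulates
#' a 72-region rodent template (36 regions per hemisphere) spanning
#' sensorimotor cortex, association cortex, limbic system, thalamus and
#' basal ganglia.
#'
#' @param nPerHemisphere number of regions per hemisphere.
#' @param groupSizes named integer vector of regions per functional group
#'   (per hemisphere); must sum to `nPerHemisphere`.
#' @return data.frame with columns `region` (unique abbreviation), `base`
#'   (abbreviation without hemisphere suffix), `hemisphere`
#'   (`"left"`/`"right"`) and `group`, ordered left hemisphere first.
#' @examples
#' atlas <- generateAtlas()
#' nrow(atlas)  # 72
#' @export
generateAtlas <- function(nPerHemisphere = 36,
                          groupSizes = c(sensorimotor = 8, association = 6,
                                         limbic = 9, thalamus = 8,
                                         basal_ganglia = 5)) {
  if (is.null(names(groupSizes)) || any(!nzchar(names(groupSizes))))
    stop("'groupSizes' must be a named vector")
  if (sum(groupSizes) != nPerHemisphere)
    stop("group sizes sum to ", sum(groupSizes),
         " but nPerHemisphere is ", nPerHemisphere)
  abbr <- c(sensorimotor = "smc", association = "assoc", limbic = "lim",
            thalamus = "thal", basal_ganglia = "bg")
  base <- unlist(lapply(names(groupSizes), function(g) {
    pre <- if (g %in% names(abbr)) abbr[[g]] else g
    paste0(pre, seq_len(groupSizes[[g]]))
  }), use.names = FALSE)
  group <- rep(names(groupSizes), groupSizes)
  out <- rbind(
    data.frame(region = paste0(base, "_L"), base = base,
               hemisphere = "left", group = group,
               stringsAsFactors = FALSE),
    data.frame(region = paste0(base, "_R"), base = base,
               hemisphere = "right", group = group,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  validateAtlas(out)
  out
}

validateAtlas <- function(atlas) {
  stopifnot(is.data.frame(atlas),
            all(c("region", "base", "hemisphere", "group") %in% names(atlas)))
  if (anyDuplicated(atlas$region)) stop("region abbreviations must be unique")
  left <- atlas$base[atlas$hemisphere == "left"]
  right <- atlas$base[atlas$hemisphere == "right"]
  if (!setequal(left, right))
    stop("every region must have a homotopic partner in the other hemisphere")
  invisible(atlas)
}

#' Homotopic region pairs of an atlas
#'
#' @param atlas an atlas data.frame from [generateAtlas()].
#' @return two-column character matrix of (left, right) region labels.
#' @export
homotopicPairs <- function(atlas) {
  validateAtlas(atlas)
  l <- atlas[atlas$hemisphere == "left", ]
  r <- atlas[atlas$hemisphere == "right", ]
  cbind(left = l$region, right = r$region[match(l$base, r$base)])
}

#' Read/write an atlas table as TSV
#'
#' @param atlas atlas data.frame; @param path file path.
#' @return `readAtlas` returns the atlas data.frame.
#' @export
writeAtlas <- function(atlas, path) {
  validateAtlas(atlas)
  write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  atlas <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  validateAtlas(atlas)
  atlas
}
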