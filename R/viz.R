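#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Three-way color / transparency encoding
## ---------------------------------------------------------------------------

#' Three-way hue from three group intensities
#'
#' Each group's anchor hue is a unit vector on the color wheel; the node
#' hue is the angle of the intensity-weighted vector sum, with weights the
#' three values normalized to sum 1. A node dominated by one group takes
#' that group's anchor hue exactly; balanced nodes fall between anchors.
#' When the weighted vectors cancel (all three values equal, with the
#' default equispaced anchors) the hue is undefined and `NA` is returned
#' (rendered neutral gray).
#'
#' Scale-invariant: multiplying all three values by a positive constant
#' leaves the hue unchanged.
#'
#' @param values numeric(3), non-negative group mean intensities in the
#'   order of `anchorHues(cfg)`; must not be all zero.
#' @param cfg a [ColorConfig-class].
#' @return Hue in degrees in \[0, 360), or `NA` for the neutral case.
#' @examples
#' threeWayHue(c(1, 0, 0))  # 0: the first group's anchor
#' threeWayHue(c(1, 1, 0))  # 60: midway between anchors at 0 and 120
#' @export
threeWayHue <- function(values, cfg = ColorConfig()) {
  stopifnot(length(values) == 3L, all(values >= 0))
  if (sum(values) == 0)
    stop("all-zero intensities: hue undefined")
  w <- values / sum(values)
  rad <- cfg@anchorHues * pi / 180
  x <- sum(w * cos(rad)); y <- sum(w * sin(rad))
  if (sqrt(x * x + y * y) < 1e-9) return(NA_real_)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Node transparency from the between-group intensity range
#'
#' The driving quantity is `d`, the range (max minus min) of a node's
#' three group means. It is normalized to the minimum and maximum mean
#' intensity of the reference group over the displayed node set, clipped
#' to \[0, 1\], and square-root transformed: `alpha = sqrt(clip((d -
#' refMin) / (refMax - refMin)))`. Nodes that are orders of magnitude
#' more intense in one group than another are opaque (alpha near 1);
#' nodes with near-equal intensities across groups are transparent.
#'
#' @param values numeric(3) of group means for one node.
#' @param refMin,refMax minimum and maximum reference-group mean over the
#'   node set; `refMax` must exceed `refMin`.
#' @return Alpha in \[0, 1\].
#' @export
nodeAlpha <- function(values, refMin, refMax) {
  stopifnot(length(values) == 3L)
  if (!(refMax > refMin))
    stop("degenerate reference range: refMax must exceed refMin")
  d <- max(values) - min(values)
  dNorm <- min(max((d - refMin) / (refMax - refMin), 0), 1)
  sqrt(dNorm)
}

#' Style table: hue and alpha for every network node
#'
#' Applies [threeWayHue()] and [nodeAlpha()] to every node of a display
#' network. The transparency reference range is the minimum and maximum
#' of the reference group's means over the displayed nodes. Nodes missing
#' from `means` are treated as all-zero (neutral hue, minimal alpha).
#'
#' @param network a [MolecularNetwork-class] (typically after
#'   [dropSingletons()]).
#' @param means numeric matrix of group means, rownames = node ids,
#'   colnames including the three groups of `cfg@anchorHues`. For merged
#'   cross-polarity nodes, means of member features are averaged.
#' @param cfg a [ColorConfig-class].
#' @return data.frame with columns `node`, `hue`, `alpha`, `neutral`.
#' @export
styleTable <- function(network, means, cfg = ColorConfig()) {
  stopifnot(is(network, "MolecularNetwork"))
  gnames <- names(cfg@anchorHues)
  if (!all(gnames %in% colnames(means)))
    stop("means must have columns: ", paste(gnames, collapse = ", "))
  nd <- networkNodes(network)
  ids <- rownames(nd)

  ## per-node means: direct lookup, or member average for merged nodes
  nodeMeans <- matrix(0, nrow = length(ids), ncol = 3L,
                      dimnames = list(ids, gnames))
  for (i in seq_along(ids)) {
    mem <- if ("members" %in% names(nd))
      strsplit(nd$members[i], ",", fixed = TRUE)[[1L]] else ids[i]
    mem <- mem[mem %in% rownames(means)]
    if (length(mem))
      nodeMeans[i, ] <- colMeans(means[mem, gnames, drop = FALSE])
  }

  refVals <- nodeMeans[, cfg@referenceGroup]
  refMin <- min(refVals); refMax <- max(refVals)
  if (!(refMax > refMin))
    stop("degenerate reference range over displayed nodes")

  hue <- vapply(seq_along(ids), function(i) {
    v <- nodeMeans[i, ]
    if (sum(v) == 0) NA_real_ else threeWayHue(v, cfg)
  }, numeric(1))
  alpha <- vapply(seq_along(ids), function(i)
    nodeAlpha(nodeMeans[i, ], refMin, refMax), numeric(1))

  data.frame(node = ids, hue = hue, alpha = alpha,
             neutral = is.na(hue), row.names = NULL,
             stringsAsFactors = FALSE)
}
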