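#' @include AllGenerics.R
NULL

#' Mass of a proton in daltons
#'
#' Used to convert between measured m/z and neutral mass under the
#' assumption that positive-mode species ionize as \[M+H\]+ and
#' negative-mode species as \[M-H\]-.
#'
#' @export
PROTON_MASS <- 1.007276466

.POLARITIES <- c("positive", "negative")

## ---------------------------------------------------------------------------
## Ms2Spectrum
## ---------------------------------------------------------------------------

#' MS/MS fragmentation spectrum of one LC-MS feature
#'
#' Holds the representative fragmentation spectrum of a single feature:
#' the precursor m/z, ionization polarity, retention time (minutes) and a
#' two-column peak matrix (`mz`, `intensity`) sorted by ascending m/z.
#'
#' @slot featureId character(1), opaque feature identifier.
#' @slot precursorMz numeric(1), precursor m/z in Da, > 0.
#' @slot polarity character(1), `"positive"` or `"negative"`.
#' @slot rt numeric(1), retention time in minutes, >= 0.
#' @slot peaks numeric matrix with columns `mz` and `intensity`; rows
#'   sorted strictly ascending by `mz`; `mz > 0`, `intensity >= 0`.
#'
#' @export
setClass("Ms2Spectrum",
  representation(
    featureId = "character",
    precursorMz = "numeric",
    polarity = "character",
    rt = "numeric",
    peaks = "matrix"
  )
)

setValidity("Ms2Spectrum", function(object) {
  msg <- character()
  if (length(object@featureId) != 1L || is.na(object@featureId))
    msg <- c(msg, "featureId must be a single non-NA string")
  if (length(object@precursorMz) != 1L || !is.finite(object@precursorMz) ||
      object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a single positive number")
  if (length(object@polarity) != 1L || !object@polarity %in% .POLARITIES)
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  if (length(object@rt) != 1L || !is.finite(object@rt) || object@rt < 0)
    msg <- c(msg, "rt must be a single non-negative number (minutes)")
  p <- object@peaks
  if (!is.numeric(p) || ncol(p) != 2L ||
      !identical(colnames(p), c("mz", "intensity")))
    msg <- c(msg, "peaks must be a numeric matrix with columns mz, intensity")
  else if (nrow(p) > 0L) {
    if (any(!is.finite(p))) msg <- c(msg, "peaks must be finite")
    else {
      if (any(p[, "mz"] <= 0)) msg <- c(msg, "all peak mz must be > 0")
      if (any(p[, "intensity"] < 0))
        msg <- c(msg, "all peak intensities must be >= 0")
      if (nrow(p) > 1L && any(diff(p[, "mz"]) <= 0))
        msg <- c(msg, "peaks must be sorted strictly ascending by mz")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Ms2Spectrum
#'
#' @param featureId feature identifier.
#' @param precursorMz precursor m/z in Da.
#' @param polarity `"positive"` or `"negative"`.
#' @param rt retention time in minutes.
#' @param mz,intensity equal-length numeric vectors of fragment peaks;
#'   they are sorted by ascending m/z on construction.
#'
#' @return An [Ms2Spectrum-class] object.
#' @examples
#' s <- Ms2Spectrum("f1", 300.1, "positive", 5.2,
#'                  mz = c(100.0, 150.5), intensity = c(40, 100))
#' peakCount(s)
#' @export
Ms2Spectrum <- function(featureId, precursorMz, polarity, rt,
                        mz = numeric(), intensity = numeric()) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  o <- order(mz)
  peaks <- cbind(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]))
  new("Ms2Spectrum", featureId = as.character(featureId),
      precursorMz = as.numeric(precursorMz),
      polarity = as.character(polarity), rt = as.numeric(rt), peaks = peaks)
}

#' @describeIn Ms2Spectrum feature identifier.
#' @param x an object.
#' @export
setMethod("featureId", "Ms2Spectrum", function(x) x@featureId)

#' @describeIn Ms2Spectrum precursor m/z (Da).
#' @export
setMethod("precursorMz", "Ms2Spectrum", function(x) x@precursorMz)

#' @describeIn Ms2Spectrum ionization polarity.
#' @export
setMethod("polarity", "Ms2Spectrum", function(x) x@polarity)

#' @describeIn Ms2Spectrum retention time in minutes.
#' @export
setMethod("rtMinutes", "Ms2Spectrum", function(x) x@rt)

#' @describeIn Ms2Spectrum two-column peak matrix.
#' @export
setMethod("peakMatrix", "Ms2Spectrum", function(x) x@peaks)

#' @describeIn Ms2Spectrum number of fragment peaks.
#' @export
setMethod("peakCount", "Ms2Spectrum", function(x) nrow(x@peaks))

setMethod("show", "Ms2Spectrum", function(object) {
  cat("Ms2Spectrum '", object@featureId, "' [", object@polarity, "]\n",
      "  precursor m/z: ", format(object@precursorMz), " Da, RT ",
      format(object@rt), " min, ", nrow(object@peaks), " peaks\n", sep = "")
})

## ---------------------------------------------------------------------------
## SimilarityResult
## ---------------------------------------------------------------------------

#' Result of a modified-cosine comparison between two spectra
#'
#' @slot score cosine score in \[0, 1\] (up to floating-point slack).
#' @slot nMatched number of matched peak pairs.
#' @slot pairs integer matrix with columns `a`, `b`: indices (into the peak
#'   matrices of the two spectra) of the accepted one-to-one peak pairs.
#'
#' @export
setClass("SimilarityResult",
  representation(score = "numeric", nMatched = "integer", pairs = "matrix")
)

setValidity("SimilarityResult", function(object) {
  msg <- character()
  if (length(object@score) != 1L || !is.finite(object@score) ||
      object@score < 0 || object@score > 1 + 1e-9)
    msg <- c(msg, "score must lie in [0, 1]")
  if (object@nMatched != nrow(object@pairs))
    msg <- c(msg, "nMatched must equal the number of matched pairs")
  if (nrow(object@pairs) > 0L) {
    if (anyDuplicated(object@pairs[, 1L]) || anyDuplicated(object@pairs[, 2L]))
      msg <- c(msg, "each peak index may appear in at most one pair")
  }
  if (object@nMatched == 0L && object@score != 0)
    msg <- c(msg, "score must be 0 when no peaks match")
  if (length(msg)) msg else TRUE
})

.SimilarityResult <- function(score, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("a", "b")))
  new("SimilarityResult", score = as.numeric(score),
      nMatched = nrow(pairs), pairs = pairs)
}

#' @describeIn SimilarityResult the cosine score.
#' @param x an object.
#' @export
setMethod("similarityScore", "SimilarityResult", function(x) x@score)

#' @describeIn SimilarityResult the matched-peak count.
#' @export
setMethod("nMatched", "SimilarityResult", function(x) x@nMatched)

#' @describeIn SimilarityResult matrix of matched peak index pairs.
#' @export
setMethod("matchedPairs", "SimilarityResult", function(x) x@pairs)

setMethod("show", "SimilarityResult", function(object) {
  cat("SimilarityResult: score ", format(object@score, digits = 4),
      ", ", object@nMatched, " matched peaks\n", sep = "")
})

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Spectral processing tolerances
#'
#' Mass tolerances and filter windows used throughout spectral processing.
#' Defaults are the standard GNPS molecular-networking settings: 0.05 Da
#' fragment and precursor tolerances, removal of fragments within +/- 17 Da
#' of the precursor, and retention of the 6 most intense fragments per
#' +/- 50 Da window.
#'
#' @slot fragmentTolDa fragment ion mass tolerance, Da.
#' @slot precursorTolDa precursor ion mass tolerance, Da.
#' @slot precursorWindowDa half-width of the precursor exclusion window, Da.
#' @slot windowDa half-width of the sliding intensity-filter window, Da.
#' @slot windowTopK number of peaks retained per window.
#'
#' @export
setClass("ToleranceConfig",
  representation(fragmentTolDa = "numeric", precursorTolDa = "numeric",
                 precursorWindowDa = "numeric", windowDa = "numeric",
                 windowTopK = "integer")
)

setValidity("ToleranceConfig", function(object) {
  vals <- c(object@fragmentTolDa, object@precursorTolDa,
            object@precursorWindowDa, object@windowDa, object@windowTopK)
  if (length(vals) != 5L || any(!is.finite(vals)) || any(vals <= 0))
    "all tolerances and window parameters must be single positive numbers"
  else TRUE
})

#' @rdname ToleranceConfig-class
#' @param fragmentTolDa,precursorTolDa,precursorWindowDa,windowDa,windowTopK
#'   see slot documentation.
#' @export
ToleranceConfig <- function(fragmentTolDa = 0.05, precursorTolDa = 0.05,
                            precursorWindowDa = 17, windowDa = 50,
                            windowTopK = 6L) {
  new("ToleranceConfig", fragmentTolDa = fragmentTolDa,
      precursorTolDa = precursorTolDa, precursorWindowDa = precursorWindowDa,
      windowDa = windowDa, windowTopK = as.integer(windowTopK))
}

#' Molecular network construction parameters
#'
#' Defaults follow GNPS feature-based molecular networking: edges require a
#' cosine score above 0.70 and at least 6 matched peaks, each edge must be
#' mutual within the top 10 most similar neighbors of both nodes, and
#' molecular families are capped at 100 nodes by removing lowest-scoring
#' edges.
#'
#' @slot scoreThreshold minimum (exclusive) cosine score for an edge.
#' @slot minMatched minimum (inclusive) matched-peak count for an edge.
#' @slot mutualK neighbor rank cutoff for the mutual top-k rule.
#' @slot maxFamilySize maximum connected-component size.
#'
#' @export
setClass("NetworkConfig",
  representation(scoreThreshold = "numeric", minMatched = "integer",
                 mutualK = "integer", maxFamilySize = "integer")
)

setValidity("NetworkConfig", function(object) {
  msg <- character()
  if (object@scoreThreshold < 0 || object@scoreThreshold > 1)
    msg <- c(msg, "scoreThreshold must lie in [0, 1]")
  if (object@minMatched < 1L || object@mutualK < 1L ||
      object@maxFamilySize < 1L)
    msg <- c(msg, "minMatched, mutualK, maxFamilySize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname NetworkConfig-class
#' @param scoreThreshold,minMatched,mutualK,maxFamilySize see slots.
#' @export
NetworkConfig <- function(scoreThreshold = 0.70, minMatched = 6L,
                          mutualK = 10L, maxFamilySize = 100L) {
  new("NetworkConfig", scoreThreshold = scoreThreshold,
      minMatched = as.integer(minMatched), mutualK = as.integer(mutualK),
      maxFamilySize = as.integer(maxFamilySize))
}

#' Cross-polarity merge parameters
#'
#' Two nodes from opposite ionization modes are considered the same neutral
#' molecule when their adduct-corrected neutral masses differ by less than
#' `ppmTol` parts per million and their retention times by less than
#' `rtTolMin` minutes (both strict inequalities).
#'
#' @slot ppmTol relative neutral-mass tolerance, ppm.
#' @slot rtTolMin retention-time tolerance, minutes.
#'
#' @export
setClass("MergeConfig",
  representation(ppmTol = "numeric", rtTolMin = "numeric")
)

setValidity("MergeConfig", function(object) {
  if (object@ppmTol <= 0 || object@rtTolMin <= 0)
    "ppmTol and rtTolMin must be positive" else TRUE
})

#' @rdname MergeConfig-class
#' @param ppmTol,rtTolMin see slots.
#' @export
MergeConfig <- function(ppmTol = 20, rtTolMin = 0.15) {
  new("MergeConfig", ppmTol = ppmTol, rtTolMin = rtTolMin)
}

#' Enrichment screen parameters
#'
#' @slot fcThreshold minimum fold change of the coculture group mean over
#'   each monoculture group mean (inclusive).
#' @slot alpha one-tailed significance level.
#' @slot rowSumTotal per-sample normalization constant (row-sum target).
#' @slot detectionFloor minimum normalized height counted as detection.
#'
#' @export
setClass("ScreenConfig",
  representation(fcThreshold = "numeric", alpha = "numeric",
                 rowSumTotal = "numeric", detectionFloor = "numeric")
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@fcThreshold < 1) msg <- c(msg, "fcThreshold must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@rowSumTotal <= 0) msg <- c(msg, "rowSumTotal must be positive")
  if (object@detectionFloor < 0)
    msg <- c(msg, "detectionFloor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ScreenConfig-class
#' @param fcThreshold,alpha,rowSumTotal,detectionFloor see slots.
#' @export
ScreenConfig <- function(fcThreshold = 4, alpha = 0.05,
                         rowSumTotal = 1e6, detectionFloor = 0) {
  new("ScreenConfig", fcThreshold = fcThreshold, alpha = alpha,
      rowSumTotal = rowSumTotal, detectionFloor = detectionFloor)
}

#' Three-way node color encoding parameters
#'
#' @slot anchorHues named numeric of length 3: the anchor hue (degrees on
#'   the color wheel) of each experimental group.
#' @slot referenceGroup the group whose minimum and maximum mean intensity
#'   normalize node transparency (default the coculture).
#'
#' @export
setClass("ColorConfig",
  representation(anchorHues = "numeric", referenceGroup = "character")
)

setValidity("ColorConfig", function(object) {
  msg <- character()
  if (length(object@anchorHues) != 3L || is.null(names(object@anchorHues)))
    msg <- c(msg, "anchorHues must be a named numeric of length 3")
  else if (anyDuplicated(object@anchorHues %% 360))
    msg <- c(msg, "anchor hues must be distinct")
  if (length(object@referenceGroup) != 1L ||
      !(object@referenceGroup %in% names(object@anchorHues)))
    msg <- c(msg, "referenceGroup must name one of the anchorHues groups")
  if (length(msg)) msg else TRUE
})

#' @rdname ColorConfig-class
#' @param anchorHues,referenceGroup see slots.
#' @export
ColorConfig <- function(anchorHues = c(fungal_mono = 0, bacterial_mono = 120,
                                       coculture = 240),
                        referenceGroup = "coculture") {
  new("ColorConfig", anchorHues = anchorHues,
      referenceGroup = referenceGroup)
}

## ---------------------------------------------------------------------------
## MolecularNetwork
## ---------------------------------------------------------------------------

#' Molecular network of MS/MS features
#'
#' An undirected weighted graph whose nodes are LC-MS features (with m/z,
#' retention time and polarity metadata) and whose edges carry the modified
#' cosine score and matched-peak count. Connected components are the
#' molecular families, interpreted as sets of structurally related
#' metabolites.
#'
#' @slot nodes a [S4Vectors::DataFrame] keyed by feature id (rownames) with
#'   columns `mz`, `rt`, `polarity` and, after cross-polarity merging,
#'   `neutralMass` and `members`.
#' @slot edges a data.frame with columns `from`, `to`, `score`, `nMatched`;
#'   each row an undirected edge with `from < to` (string order).
#'
#' @export
setClass("MolecularNetwork",
  representation(nodes = "DataFrame", edges = "data.frame")
)

setValidity("MolecularNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "to", "score", "nMatched")
  if (!all(need %in% names(e)))
    return("edges must have columns from, to, score, nMatched")
  ids <- rownames(object@nodes)
  if (anyDuplicated(ids)) msg <- c(msg, "node ids must be unique")
  if (nrow(e) > 0L) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% ids))
      msg <- c(msg, "all edge endpoints must be network nodes")
    if (any(e$from > e$to))
      msg <- c(msg, "edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to)))
      msg <- c(msg, "duplicate edges are not allowed")
    if (any(e$score < 0 | e$score > 1 + 1e-9))
      msg <- c(msg, "edge scores must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MolecularNetwork
#'
#' @param nodes a data.frame or DataFrame of node metadata whose rownames
#'   (or `featureId` column) are the node ids; typically columns `mz`,
#'   `rt`, `polarity`.
#' @param edges a data.frame with columns `from`, `to`, `score`,
#'   `nMatched`; orientation is normalized and duplicates collapsed
#'   (keeping the maximum score).
#'
#' @return A [MolecularNetwork-class].
#' @export
MolecularNetwork <- function(nodes, edges = NULL) {
  nodes <- as(nodes, "DataFrame")
  if (is.null(rownames(nodes))) {
    if (!"featureId" %in% names(nodes))
      stop("nodes must have rownames or a featureId column")
    rownames(nodes) <- nodes$featureId
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        score = numeric(), nMatched = integer(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- .canonicalizeEdges(edges)
  }
  new("MolecularNetwork", nodes = nodes, edges = edges)
}

## normalize orientation (from < to), drop self loops, collapse duplicates
## keeping the max score (ties: max nMatched), sort rows deterministically
.canonicalizeEdges <- function(edges) {
  from <- as.character(edges$from); to <- as.character(edges$to)
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  e <- data.frame(from = from, to = to,
                  score = as.numeric(edges$score),
                  nMatched = as.integer(edges$nMatched),
                  stringsAsFactors = FALSE)
  e <- e[e$from != e$to, , drop = FALSE]
  if (nrow(e) > 1L) {
    key <- paste(e$from, e$to, sep = "\r")
    e <- e[order(key, -e$score, -e$nMatched), , drop = FALSE]
    e <- e[!duplicated(paste(e$from, e$to, sep = "\r")), , drop = FALSE]
  }
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @describeIn MolecularNetwork node metadata DataFrame.
#' @param x an object.
#' @export
setMethod("networkNodes", "MolecularNetwork", function(x) x@nodes)

#' @describeIn MolecularNetwork edge data.frame.
#' @export
setMethod("networkEdges", "MolecularNetwork", function(x) x@edges)

#' @describeIn MolecularNetwork number of nodes.
#' @export
setMethod("numNodes", "MolecularNetwork", function(x) nrow(x@nodes))

#' @describeIn MolecularNetwork number of edges.
#' @export
setMethod("numEdges", "MolecularNetwork", function(x) nrow(x@edges))

#' @describeIn MolecularNetwork molecular families: a named integer vector
#'   mapping each node id to its connected-component index (singletons form
#'   their own family).
#' @export
setMethod("families", "MolecularNetwork", function(x) {
  g <- .asIgraph(x)
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), names(comp))
})

.asIgraph <- function(network) {
  ids <- rownames(network@nodes)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  e <- network@edges
  if (nrow(e) > 0L) {
    g <- igraph::add_edges(g, rbind(e$from, e$to))
    g <- igraph::set_edge_attr(g, "score", value = e$score)
    g <- igraph::set_edge_attr(g, "nMatched", value = e$nMatched)
  }
  g
}

setMethod("show", "MolecularNetwork", function(object) {
  fam <- if (numNodes(object)) families(object) else integer()
  sizes <- if (length(fam)) table(fam) else integer()
  cat("MolecularNetwork: ", numNodes(object), " nodes, ",
      numEdges(object), " edges, ", length(sizes), " families",
      if (length(sizes)) paste0(" (largest ", max(sizes), ")"), "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## FeatureTable
## ---------------------------------------------------------------------------

#' Feature-by-sample peak-height table with experimental design
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay
#' `"heights"` (non-negative peak heights, features in rows, samples in
#' columns). `rowData` carries `mz`, `rt` and `polarity` per feature;
#' `colData` carries `group` (e.g. `coculture`, `fungal_mono`,
#' `bacterial_mono`) and `condition` (e.g. growth substrate) per sample.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"heights" %in% SummarizedExperiment::assayNames(object))
    return("FeatureTable must contain an assay named 'heights'")
  h <- SummarizedExperiment::assay(object, "heights")
  if (any(!is.finite(h)) || any(h < 0))
    msg <- c(msg, "heights must be finite and non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "condition") %in% names(cd)))
    msg <- c(msg, "colData must have 'group' and 'condition' columns")
  else if (any(is.na(cd$group)))
    msg <- c(msg, "every sample must be assigned a group")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mz", "rt", "polarity") %in% names(rd)))
    msg <- c(msg, "rowData must have 'mz', 'rt' and 'polarity' columns")
  else if (!all(rd$polarity %in% .POLARITIES))
    msg <- c(msg, "feature polarity must be 'positive' or 'negative'")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param heights numeric matrix of peak heights, features in rows
#'   (rownames are feature ids), samples in columns (colnames are sample
#'   ids).
#' @param features data.frame with columns `featureId`, `mz`, `rt`,
#'   `polarity`, one row per row of `heights`.
#' @param design data.frame with columns `sampleId`, `group`, `condition`,
#'   one row per column of `heights`.
#'
#' @return A [FeatureTable-class].
#' @export
FeatureTable <- function(heights, features, design) {
  heights <- as.matrix(heights)
  features <- as.data.frame(features)
  design <- as.data.frame(design)
  if (nrow(features) != nrow(heights))
    stop("features must have one row per row of heights")
  if (nrow(design) != ncol(heights))
    stop("design must have one row per column of heights")
  if (anyDuplicated(features$featureId))
    stop("duplicate feature ids: ",
         paste(unique(features$featureId[duplicated(features$featureId)]),
               collapse = ", "))
  rownames(heights) <- features$featureId
  colnames(heights) <- design$sampleId
  rd <- S4Vectors::DataFrame(mz = features$mz, rt = features$rt,
                             polarity = features$polarity,
                             row.names = features$featureId)
  cd <- S4Vectors::DataFrame(group = design$group,
                             condition = design$condition,
                             row.names = design$sampleId)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(heights = heights), rowData = rd, colData = cd)
  new("FeatureTable", se)
}

#' @describeIn FeatureTable the peak-height matrix.
#' @param x an object.
#' @export
setMethod("heights", "FeatureTable",
          function(x) SummarizedExperiment::assay(x, "heights"))

#' @describeIn FeatureTable named character vector: sample id -> group.
#' @export
setMethod("sampleGroups", "FeatureTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$group), rownames(cd))
})

#' @describeIn FeatureTable named character vector: sample id -> condition.
#' @export
setMethod("sampleConditions", "FeatureTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$condition), rownames(cd))
})

#' @describeIn FeatureTable per-feature metadata (mz, rt, polarity).
#' @export
setMethod("featureData", "FeatureTable",
          function(x) SummarizedExperiment::rowData(x))

setMethod("show", "FeatureTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("FeatureTable: ", nrow(object), " features x ", ncol(object),
      " samples\n  groups: ",
      paste(sprintf("%s (%d)", names(table(cd$group)), table(cd$group)),
            collapse = ", "),
      "\n  conditions: ", paste(unique(cd$condition), collapse = ", "),
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## EnrichmentReport
## ---------------------------------------------------------------------------

#' Coculture enrichment screen report
#'
#' One row per feature and condition with group means, fold changes
#' against each monoculture, one-tailed pooled-variance t statistics and
#' p-values, not-detectable flags (the table dash convention: a feature
#' absent from a monoculture passes the fold-change criterion against it),
#' BH-adjusted p-values (informational, not used by the pass flag) and the
#' final pass flag.
#'
#' @slot table the report data.frame.
#' @slot config the [ScreenConfig-class] used.
#'
#' @export
setClass("EnrichmentReport",
  representation(table = "data.frame", config = "ScreenConfig")
)

#' @describeIn EnrichmentReport the full report table.
#' @param x an object.
#' @export
setMethod("reportTable", "EnrichmentReport", function(x) x@table)

#' @describeIn EnrichmentReport ids of features passing the screen.
#' @export
setMethod("passingFeatures", "EnrichmentReport",
          function(x) unique(x@table$featureId[x@table$pass]))

setMethod("show", "EnrichmentReport", function(object) {
  cat("EnrichmentReport: ", nrow(object@table), " feature x condition rows, ",
      sum(object@table$pass), " passing (FC >= ",
      object@config@fcThreshold, ", one-tailed p < ",
      object@config@alpha, " vs both monocultures)\n", sep = "")
})
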