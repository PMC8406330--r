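#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## MGF (Mascot generic format, GNPS dialect)
## ---------------------------------------------------------------------------

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write spectra to an MGF file
#'
#' One `BEGIN IONS`/`END IONS` block per spectrum with `TITLE` (the
#' feature id), `PEPMASS`, `RTINMINUTES` and `CHARGE` (`1+`/`1-` by
#' polarity) headers, followed by `mz intensity` peak lines. Numbers are
#' written with 17 significant digits so reading the file back
#' reconstructs bit-identical values.
#'
#' @param spectra list of [Ms2Spectrum-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeMgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    stopifnot(is(s, "Ms2Spectrum"))
    p <- peakMatrix(s)
    paste(c("BEGIN IONS",
            paste0("TITLE=", featureId(s)),
            paste0("PEPMASS=", .fmtNum(precursorMz(s))),
            paste0("RTINMINUTES=", .fmtNum(rtMinutes(s))),
            paste0("CHARGE=1", if (polarity(s) == "positive") "+" else "-"),
            if (nrow(p)) paste(.fmtNum(p[, "mz"]), .fmtNum(p[, "intensity"])),
            "END IONS"),
          collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Parses `BEGIN IONS` blocks with `PEPMASS` (required), `RTINSECONDS` or
#' `RTINMINUTES` (required; seconds are converted to minutes) and
#' `CHARGE` (`..+`/`..-`) or `IONMODE` headers determining polarity.
#' Malformed entries are reported with their entry index and line number.
#'
#' @param path MGF file path.
#' @return List of [Ms2Spectrum-class].
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(starts > ends))
    stop("malformed MGF '", path, "': unbalanced BEGIN IONS/END IONS")
  lapply(seq_along(starts), function(k) {
    body <- seq(starts[k] + 1L, ends[k] - 1L)
    entry <- lines[body]
    isHeader <- grepl("=", entry, fixed = TRUE)
    hdr <- entry[isHeader]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    getHdr <- function(key) if (key %in% keys) vals[match(key, keys)] else NA

    pep <- getHdr("PEPMASS")
    if (is.na(pep))
      stop("MGF entry ", k, " (line ", starts[k], "): missing PEPMASS")
    pep <- as.numeric(strsplit(trimws(pep), "[ \t]+")[[1L]][1L])

    rt <- getHdr("RTINMINUTES")
    if (is.na(rt)) {
      rts <- getHdr("RTINSECONDS")
      if (is.na(rts))
        stop("MGF entry ", k, " (line ", starts[k],
             "): missing RTINSECONDS/RTINMINUTES (RT is required)")
      rt <- as.numeric(rts) / 60
    } else rt <- as.numeric(rt)

    charge <- getHdr("CHARGE")
    ionmode <- getHdr("IONMODE")
    pol <- if (!is.na(charge)) {
      if (grepl("-", charge, fixed = TRUE)) "negative" else "positive"
    } else if (!is.na(ionmode)) {
      tolower(trimws(ionmode))
    } else
      stop("MGF entry ", k, " (line ", starts[k],
           "): missing CHARGE/IONMODE")

    title <- getHdr("TITLE")
    id <- if (!is.na(title)) title else paste0("spectrum_", k)

    peakLines <- entry[!isHeader]
    peakLines <- peakLines[nzchar(trimws(peakLines))]
    mz <- numeric(0); int <- numeric(0)
    if (length(peakLines)) {
      parts <- strsplit(trimws(peakLines), "[ \t]+")
      bad <- which(vapply(parts, length, integer(1)) < 2L)
      if (length(bad))
        stop("MGF entry ", k, " (line ", body[!isHeader][bad[1L]],
             "): malformed peak line")
      mz <- as.numeric(vapply(parts, `[`, character(1), 1L))
      int <- as.numeric(vapply(parts, `[`, character(1), 2L))
      if (any(is.na(mz)) || any(is.na(int)))
        stop("MGF entry ", k, ": non-numeric peak values")
    }
    Ms2Spectrum(id, pep, pol, rt, mz = mz, intensity = int)
  })
}

## ---------------------------------------------------------------------------
## Feature table CSV
## ---------------------------------------------------------------------------

#' Read a feature table and its design from CSV
#'
#' The feature CSV has columns `feature_id`, `mz`, `rt`, `polarity`
#' followed by one column per sample; the design CSV maps `sample_id` to
#' `group` and `condition`. Samples named in the design must exist in the
#' feature table (extra table columns are ignored). Duplicate feature
#' ids, negative heights and unknown polarity values are errors.
#'
#' @param path feature CSV path.
#' @param designPath design CSV path.
#' @return A [FeatureTable-class].
#' @export
readFeatureCsv <- function(path, designPath) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  design <- read.csv(designPath, stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt", "polarity")
  if (!all(need %in% names(tab)))
    stop("feature CSV must have columns: ", paste(need, collapse = ", "))
  if (!all(c("sample_id", "group", "condition") %in% names(design)))
    stop("design CSV must have columns sample_id, group, condition")
  if (anyDuplicated(tab$feature_id))
    stop("duplicate feature ids: ",
         paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
               collapse = ", "))
  if (!all(tab$polarity %in% .POLARITIES))
    stop("unknown polarity value(s): ",
         paste(setdiff(unique(tab$polarity), .POLARITIES), collapse = ", "))
  missing <- setdiff(design$sample_id, names(tab))
  if (length(missing))
    stop("design sample(s) absent from feature table: ",
         paste(missing, collapse = ", "))
  h <- as.matrix(tab[, design$sample_id, drop = FALSE])
  if (any(h < 0)) {
    bad <- which(h < 0, arr.ind = TRUE)[1L, ]
    stop("negative height at feature '", tab$feature_id[bad[1L]],
         "', sample '", design$sample_id[bad[2L]], "'")
  }
  FeatureTable(h,
               data.frame(featureId = tab$feature_id, mz = tab$mz,
                          rt = tab$rt, polarity = tab$polarity,
                          stringsAsFactors = FALSE),
               data.frame(sampleId = design$sample_id,
                          group = design$group,
                          condition = design$condition,
                          stringsAsFactors = FALSE))
}

#' Write a feature table and its design to CSV
#'
#' Inverse of [readFeatureCsv()].
#'
#' @param table a [FeatureTable-class].
#' @param path feature CSV path.
#' @param designPath design CSV path.
#' @return Invisibly, `path`.
#' @export
writeFeatureCsv <- function(table, path, designPath) {
  rd <- featureData(table)
  out <- data.frame(feature_id = rownames(rd), mz = rd$mz, rt = rd$rt,
                    polarity = rd$polarity, stringsAsFactors = FALSE,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(heights(table), check.names = FALSE))
  write.csv(out, path, row.names = FALSE)
  design <- data.frame(sample_id = names(sampleGroups(table)),
                       group = unname(sampleGroups(table)),
                       condition = unname(sampleConditions(table)),
                       stringsAsFactors = FALSE)
  write.csv(design, designPath, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GraphML
## ---------------------------------------------------------------------------

#' Write a molecular network as GraphML
#'
#' Exports the network with all node metadata (m/z or neutral mass, RT,
#' polarity, members, and optional style and annotation columns) as node
#' attributes and the cosine score and matched-peak count as edge
#' attributes, in GraphML for direct visualization in Cytoscape or any
#' standard graph viewer.
#'
#' @param network a [MolecularNetwork-class].
#' @param path output path.
#' @param styles optional style data.frame from [styleTable()]; `hue`,
#'   `alpha` and `neutral` are attached to matching nodes.
#' @param annotations optional data.frame from [librarySearch()] results
#'   with columns `queryId`, `libraryId`, `score`; the best library match
#'   per node is attached.
#' @return Invisibly, `path`.
#' @export
writeGraphml <- function(network, path, styles = NULL, annotations = NULL) {
  stopifnot(is(network, "MolecularNetwork"))
  nd <- as.data.frame(networkNodes(network))
  nd <- cbind(name = rownames(networkNodes(network)), nd,
              stringsAsFactors = FALSE)
  if (!is.null(styles) && nrow(nd)) {
    m <- match(nd$name, styles$node)
    nd$hue <- styles$hue[m]
    nd$alpha <- styles$alpha[m]
    nd$neutral <- styles$neutral[m]
  }
  if (!is.null(annotations) && nrow(annotations) && nrow(nd)) {
    best <- annotations[!duplicated(annotations$queryId), , drop = FALSE]
    m <- match(nd$name, best$queryId)
    nd$libraryMatch <- best$libraryId[m]
    nd$libraryScore <- best$score[m]
  }
  e <- networkEdges(network)
  g <- igraph::graph_from_data_frame(
    if (nrow(e)) e else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = nd)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file
#'
#' Thin wrapper around [igraph::read_graph()]; used for round-trip
#' verification of exported networks.
#'
#' @param path GraphML file path.
#' @return An igraph graph.
#' @export
readGraphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
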