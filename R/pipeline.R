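#' @include AllClasses.R
NULL

#' Run the full molecular-networking and enrichment pipeline
#'
#' End-to-end composition of the library's stages: read MGF spectra per
#' polarity, apply the two spectral filters, build a molecular network
#' per polarity, merge the networks across polarities by neutral mass,
#' row-sum normalize the feature table, run the coculture enrichment
#' screen, compute the three-way hue/alpha style of every displayed node
#' (singletons truncated), optionally annotate nodes against a spectral
#' library, and write the outputs: a GraphML network, the enrichment
#' report CSV (all features, including singletons), the node style CSV
#' and a log echoing every parameter. All stages are deterministic, so a
#' rerun with identical inputs reproduces identical outputs.
#'
#' @param featureCsv,designCsv feature table and design CSV paths (see
#'   [readFeatureCsv()]).
#' @param outDir output directory (created if missing).
#' @param posMgf,negMgf MGF paths per polarity; at least one required.
#' @param libraryMgf optional spectral library MGF for annotation.
#' @param tol a [ToleranceConfig-class].
#' @param net a [NetworkConfig-class].
#' @param merge a [MergeConfig-class].
#' @param screen a [ScreenConfig-class].
#' @param color a [ColorConfig-class].
#' @param groups role-to-label map passed to [enrichmentScreen()].
#' @return Invisibly, a list with the merged `network`, display network,
#'   `report`, `styles`, `annotations` and output `paths`.
#' @export
runPipeline <- function(featureCsv, designCsv, outDir,
                        posMgf = NULL, negMgf = NULL, libraryMgf = NULL,
                        tol = ToleranceConfig(), net = NetworkConfig(),
                        merge = MergeConfig(), screen = ScreenConfig(),
                        color = ColorConfig(),
                        groups = c(coculture = "coculture",
                                   fungal = "fungal_mono",
                                   bacterial = "bacterial_mono")) {
  if (is.null(posMgf) && is.null(negMgf))
    stop("at least one of posMgf/negMgf is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "pipeline_log.txt")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon))
  logf <- function(...) writeLines(sprintf(...), logCon)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    logf("stage %-22s %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  logf("parameters:")
  logf("  fragmentTolDa=%g precursorTolDa=%g precursorWindowDa=%g windowDa=%g windowTopK=%d",
       tol@fragmentTolDa, tol@precursorTolDa, tol@precursorWindowDa,
       tol@windowDa, tol@windowTopK)
  logf("  scoreThreshold=%g minMatched=%d mutualK=%d maxFamilySize=%d",
       net@scoreThreshold, net@minMatched, net@mutualK, net@maxFamilySize)
  logf("  ppmTol=%g rtTolMin=%g", merge@ppmTol, merge@rtTolMin)
  logf("  fcThreshold=%g alpha=%g rowSumTotal=%g detectionFloor=%g",
       screen@fcThreshold, screen@alpha, screen@rowSumTotal,
       screen@detectionFloor)
  logf("  anchorHues=%s referenceGroup=%s",
       paste(sprintf("%s:%g", names(color@anchorHues), color@anchorHues),
             collapse = ","), color@referenceGroup)

  buildOne <- function(mgf, label) {
    if (is.null(mgf)) return(NULL)
    spectra <- stage(paste0("read_", label), readMgf(mgf))
    spectra <- stage(paste0("filter_", label),
                     lapply(spectra, filterSpectrum, tol = tol))
    stage(paste0("network_", label), buildNetwork(spectra, net, tol))
  }
  posNet <- buildOne(posMgf, "pos")
  negNet <- buildOne(negMgf, "neg")
  network <- if (!is.null(posNet) && !is.null(negNet))
    stage("merge", mergeNetworks(posNet, negNet, merge))
  else if (!is.null(posNet)) posNet else negNet

  tab <- stage("read_features", readFeatureCsv(featureCsv, designCsv))
  normTab <- stage("normalize", rowSumNormalize(tab, screen@rowSumTotal))
  report <- stage("screen",
                  enrichmentScreen(normTab, screen, groups = groups,
                                   normalize = FALSE))

  display <- stage("drop_singletons", dropSingletons(network))
  means <- groupMeans(normTab)
  styles <- if (numNodes(display) > 0L)
    stage("style", styleTable(display, means, color))
  else data.frame(node = character(), hue = numeric(), alpha = numeric(),
                  neutral = logical())

  annotations <- NULL
  if (!is.null(libraryMgf)) {
    annotations <- stage("library_search", {
      lib <- readMgf(libraryMgf)
      queries <- c(if (!is.null(posMgf))
        lapply(readMgf(posMgf), filterSpectrum, tol = tol),
        if (!is.null(negMgf))
          lapply(readMgf(negMgf), filterSpectrum, tol = tol))
      do.call(rbind, lapply(queries, librarySearch, library = lib,
                            tol = tol))
    })
  }

  paths <- list(graphml = file.path(outDir, "network.graphml"),
                report = file.path(outDir, "enrichment_report.csv"),
                styles = file.path(outDir, "node_styles.csv"),
                log = logPath)
  stage("write", {
    writeGraphml(display, paths$graphml, styles = styles,
                 annotations = annotations)
    write.csv(reportTable(report), paths$report, row.names = FALSE)
    write.csv(styles, paths$styles, row.names = FALSE)
  })
  invisible(list(network = network, display = display, report = report,
                 styles = styles, annotations = annotations,
                 paths = paths))
}
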