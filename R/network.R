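#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Molecular network construction
## ---------------------------------------------------------------------------

#' Build a molecular network from filtered MS/MS spectra
#'
#' Scores every pair of spectra with the modified cosine, keeps edges with
#' score above `scoreThreshold` and at least `minMatched` matched peaks,
#' then applies the mutual top-k neighbor rule and the molecular-family
#' size cap, in that fixed order. Deterministic for a fixed input set:
#' all rank and removal ties are broken by node id.
#'
#' @param spectra a list of [Ms2Spectrum-class], all of the same polarity
#'   and already filtered (see [filterSpectrum()]).
#' @param cfg a [NetworkConfig-class].
#' @param tol a [ToleranceConfig-class] passed to [modifiedCosine()].
#' @return A [MolecularNetwork-class]. With fewer than two spectra the
#'   network has nodes only.
#' @seealso [mutualTopkFilter()], [capFamilySize()], [networkFromScores()]
#' @export
buildNetwork <- function(spectra, cfg = NetworkConfig(),
                         tol = ToleranceConfig()) {
  stopifnot(all(vapply(spectra, is, logical(1), "Ms2Spectrum")))
  pol <- vapply(spectra, polarity, character(1))
  if (length(unique(pol)) > 1L)
    stop("all spectra must share one polarity; got: ",
         paste(unique(pol), collapse = ", "))
  ids <- vapply(spectra, featureId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate feature ids among spectra")
  nodes <- S4Vectors::DataFrame(
    mz = vapply(spectra, precursorMz, numeric(1)),
    rt = vapply(spectra, rtMinutes, numeric(1)),
    polarity = pol, row.names = ids)

  n <- length(spectra)
  from <- character(); to <- character(); sc <- numeric(); nm <- integer()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        r <- modifiedCosine(spectra[[i]], spectra[[j]], tol)
        if (r@score > cfg@scoreThreshold && r@nMatched >= cfg@minMatched) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
          sc <- c(sc, r@score); nm <- c(nm, r@nMatched)
        }
      }
    }
  }
  net <- MolecularNetwork(nodes, data.frame(from = from, to = to,
                                            score = sc, nMatched = nm,
                                            stringsAsFactors = FALSE))
  net <- mutualTopkFilter(net, cfg@mutualK)
  capFamilySize(net, cfg@maxFamilySize)
}

#' Build a molecular network from precomputed pairwise similarities
#'
#' Applies the same three edge rules as [buildNetwork()] (score/matched
#' thresholds, mutual top-k, family-size cap) to an externally supplied
#' similarity table — useful when scores come from another scorer or for
#' validating the rule pipeline against an independent implementation.
#'
#' @param nodes node ids (character) or a data.frame/DataFrame of node
#'   metadata with ids as rownames.
#' @param similarities data.frame with columns `from`, `to`, `score`,
#'   `nMatched`, one row per scored pair.
#' @param cfg a [NetworkConfig-class].
#' @return A [MolecularNetwork-class].
#' @export
networkFromScores <- function(nodes, similarities, cfg = NetworkConfig()) {
  if (is.character(nodes))
    nodes <- S4Vectors::DataFrame(row.names = nodes)
  keep <- similarities$score > cfg@scoreThreshold &
    similarities$nMatched >= cfg@minMatched
  net <- MolecularNetwork(nodes, similarities[keep, , drop = FALSE])
  net <- mutualTopkFilter(net, cfg@mutualK)
  capFamilySize(net, cfg@maxFamilySize)
}

#' Mutual top-k neighbor edge filter
#'
#' An edge (a, b) survives iff b is among a's `k` highest-scoring
#' neighbors and a is among b's `k` highest-scoring neighbors, ranks
#' computed on the current edge set. Score ties are broken by ascending
#' neighbor id. The node set is unchanged.
#'
#' @param network a [MolecularNetwork-class].
#' @param k neighbor rank cutoff (default 10).
#' @return The filtered [MolecularNetwork-class].
#' @export
mutualTopkFilter <- function(network, k = 10L) {
  stopifnot(is(network, "MolecularNetwork"), k >= 1L)
  e <- network@edges
  if (nrow(e) == 0L) return(network)
  ## directed view: each undirected edge seen from both endpoints
  half <- data.frame(node = c(e$from, e$to), nbr = c(e$to, e$from),
                     score = c(e$score, e$score), stringsAsFactors = FALSE)
  topk <- unlist(lapply(split(half, half$node), function(d) {
    d <- d[order(-d$score, d$nbr), , drop = FALSE]
    paste(d$node[seq_len(min(k, nrow(d)))],
          d$nbr[seq_len(min(k, nrow(d)))], sep = "\r")
  }), use.names = FALSE)
  keep <- paste(e$from, e$to, sep = "\r") %in% topk &
    paste(e$to, e$from, sep = "\r") %in% topk
  out <- network
  out@edges <- e[keep, , drop = FALSE]
  rownames(out@edges) <- NULL
  out
}

#' Cap molecular family size by removing lowest-scoring edges
#'
#' While any connected component (molecular family) has more than
#' `maxSize` nodes, the lowest-scoring edge of that component is removed
#' (score ties broken by ascending `from` then `to` id) and components
#' are recomputed. Only edges are removed, never nodes.
#'
#' @param network a [MolecularNetwork-class].
#' @param maxSize maximum family size (default 100).
#' @return The capped [MolecularNetwork-class].
#' @export
capFamilySize <- function(network, maxSize = 100L) {
  stopifnot(is(network, "MolecularNetwork"), maxSize >= 1L)
  e <- network@edges
  ids <- rownames(network@nodes)
  repeat {
    if (nrow(e) == 0L) break
    g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                       directed = FALSE, vertices = ids)
    memb <- igraph::components(g)$membership
    sizes <- table(memb)
    big <- as.integer(names(sizes)[sizes > maxSize])
    if (length(big) == 0L) break
    drop <- logical(nrow(e))
    for (comp in big) {
      inComp <- which(memb[e$from] == comp)
      o <- inComp[order(e$score[inComp], e$from[inComp], e$to[inComp])]
      drop[o[1L]] <- TRUE
    }
    e <- e[!drop, , drop = FALSE]
  }
  out <- network
  out@edges <- e
  rownames(out@edges) <- NULL
  out
}

#' Drop unconnected nodes for display
#'
#' Removes degree-zero nodes from the network. Intended for display
#' networks only (self-looping/singleton nodes are truncated from the
#' rendered graph); quantitative feature tables and enrichment reports
#' keep every feature.
#'
#' @param network a [MolecularNetwork-class].
#' @return A [MolecularNetwork-class] without singleton nodes.
#' @export
dropSingletons <- function(network) {
  stopifnot(is(network, "MolecularNetwork"))
  e <- network@edges
  connected <- rownames(network@nodes) %in% c(e$from, e$to)
  out <- network
  out@nodes <- network@nodes[connected, , drop = FALSE]
  out
}

#' Search a query spectrum against a spectral library
#'
#' Every library spectrum is passed through the same two spectral filters
#' applied to networked data, then scored against the query with the
#' modified cosine. Matches require score above `scoreThreshold` and at
#' least `minMatched` matched peaks, and are returned sorted by
#' descending score.
#'
#' @param query a filtered [Ms2Spectrum-class].
#' @param library a list of [Ms2Spectrum-class] library entries (raw;
#'   filtered internally).
#' @param tol a [ToleranceConfig-class].
#' @param scoreThreshold minimum (exclusive) match score (default 0.7).
#' @param minMatched minimum matched peaks (default 6).
#' @return data.frame with columns `queryId`, `libraryId`, `score`,
#'   `nMatched`, best match first; zero rows when nothing matches.
#' @export
librarySearch <- function(query, library, tol = ToleranceConfig(),
                          scoreThreshold = 0.7, minMatched = 6L) {
  stopifnot(is(query, "Ms2Spectrum"))
  res <- lapply(library, function(ls) {
    r <- modifiedCosine(query, filterSpectrum(ls, tol), tol)
    data.frame(queryId = query@featureId, libraryId = ls@featureId,
               score = r@score, nMatched = r@nMatched,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(
    data.frame(queryId = character(), libraryId = character(),
               score = numeric(), nMatched = integer(),
               stringsAsFactors = FALSE))))
  out <- out[out$score > scoreThreshold & out$nMatched >= minMatched, ,
             drop = FALSE]
  out <- out[order(-out$score, out$libraryId), , drop = FALSE]
  rownames(out) <- NULL
  out
}
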