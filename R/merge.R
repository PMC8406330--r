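#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Cross-polarity reconciliation
## ---------------------------------------------------------------------------

#' Adduct-corrected neutral mass
#'
#' Converts a measured m/z to the neutral (uncharged) molecular mass under
#' the protonation assumption: positive-mode species ionize as \[M+H\]+
#' (subtract one proton mass), negative-mode species as \[M-H\]- (add one
#' proton mass).
#'
#' @param mz measured m/z in Da (vectorized).
#' @param polarity `"positive"` or `"negative"` (recycled).
#' @return Neutral mass in Da.
#' @examples
#' neutralMass(454.2791, "positive")  # 453.271824
#' @export
neutralMass <- function(mz, polarity) {
  if (!all(polarity %in% .POLARITIES))
    stop("polarity must be 'positive' or 'negative'")
  m <- ifelse(polarity == "positive", mz - PROTON_MASS, mz + PROTON_MASS)
  if (any(m <= 0))
    stop("neutral mass would be non-positive for m/z ",
         paste(mz[m <= 0], collapse = ", "), "; invalid m/z for ",
         "the assumed adduct")
  m
}

## relative mass difference in parts per million; the reference is the
## mean of the two masses (fixed convention, negligible vs. max/min at
## the 20 ppm scale but required for exact testability)
.ppmDiff <- function(x, y) 1e6 * abs(x - y) / ((x + y) / 2)

#' Merge positive- and negative-mode molecular networks
#'
#' Groups nodes from the two ionization modes that represent the same
#' neutral molecule: a positive node and a negative node are merge
#' candidates when their adduct-corrected neutral masses differ by less
#' than `ppmTol` ppm and their retention times by less than `rtTolMin`
#' minutes (strict inequalities). Candidates are accepted greedily by
#' ascending ppm difference (ties: ascending RT difference, then node
#' ids), each node used at most once. Edges of both input networks are
#' inherited onto the merged nodes; when two input edges collapse onto
#' the same merged pair the higher score is kept, and edges collapsing
#' onto a single merged node are dropped.
#'
#' Argument order is irrelevant: the networks are identified by the
#' polarity of their nodes.
#'
#' @param pos,neg [MolecularNetwork-class] objects of single, opposite
#'   polarities (in either order).
#' @param cfg a [MergeConfig-class].
#' @return A [MolecularNetwork-class] whose node DataFrame carries
#'   `neutralMass`, `rt`, `polarity` (`"both"` for merged nodes) and
#'   `members` (comma-separated member feature ids). Merged node ids are
#'   `<posId>|<negId>`.
#' @export
mergeNetworks <- function(pos, neg, cfg = MergeConfig()) {
  stopifnot(is(pos, "MolecularNetwork"), is(neg, "MolecularNetwork"))
  polOf <- function(x) unique(as.character(networkNodes(x)$polarity))
  pp <- polOf(pos); pn <- polOf(neg)
  if (length(pp) > 1L || length(pn) > 1L)
    stop("each input network must contain a single polarity")
  if (identical(pp, "negative") && identical(pn, "positive")) {
    tmp <- pos; pos <- neg; neg <- tmp
  } else if (length(pp) && length(pn) &&
             !(identical(pp, "positive") && identical(pn, "negative"))) {
    stop("inputs must be one positive- and one negative-mode network")
  }

  np <- networkNodes(pos); nn <- networkNodes(neg)
  pid <- rownames(np); nid <- rownames(nn)
  massP <- neutralMass(np$mz, rep("positive", nrow(np)))
  massN <- neutralMass(nn$mz, rep("negative", nrow(nn)))

  ## candidate (positive, negative) pairs within both tolerances
  cand <- NULL
  if (length(pid) && length(nid)) {
    grid <- expand.grid(p = seq_along(pid), n = seq_along(nid))
    ppm <- .ppmDiff(massP[grid$p], massN[grid$n])
    drt <- abs(np$rt[grid$p] - nn$rt[grid$n])
    ok <- ppm < cfg@ppmTol & drt < cfg@rtTolMin
    cand <- data.frame(p = grid$p[ok], n = grid$n[ok],
                       ppm = ppm[ok], drt = drt[ok])
    cand <- cand[order(cand$ppm, cand$drt, pid[cand$p], nid[cand$n]), ,
                 drop = FALSE]
  }

  usedP <- logical(length(pid)); usedN <- logical(length(nid))
  pairP <- integer(); pairN <- integer()
  if (!is.null(cand) && nrow(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand$p[r]; j <- cand$n[r]
      if (!usedP[i] && !usedN[j]) {
        usedP[i] <- TRUE; usedN[j] <- TRUE
        pairP <- c(pairP, i); pairN <- c(pairN, j)
      }
    }
  }

  ## merged node table; id map: original feature id -> merged node id
  mergedId <- paste(pid[pairP], nid[pairN], sep = "|")
  idMap <- c(setNames(pid, pid), setNames(nid, nid))
  idMap[pid[pairP]] <- mergedId
  idMap[nid[pairN]] <- mergedId

  singleP <- which(!usedP); singleN <- which(!usedN)
  nodes <- S4Vectors::DataFrame(
    neutralMass = c((massP[pairP] + massN[pairN]) / 2,
                    massP[singleP], massN[singleN]),
    rt = c((np$rt[pairP] + nn$rt[pairN]) / 2,
           np$rt[singleP], nn$rt[singleN]),
    polarity = c(rep("both", length(pairP)),
                 rep("positive", length(singleP)),
                 rep("negative", length(singleN))),
    members = c(paste(pid[pairP], nid[pairN], sep = ","),
                pid[singleP], nid[singleN]),
    row.names = c(mergedId, pid[singleP], nid[singleN]))
  nodes <- nodes[order(rownames(nodes)), , drop = FALSE]

  edges <- rbind(networkEdges(pos), networkEdges(neg))
  if (nrow(edges)) {
    edges$from <- unname(idMap[edges$from])
    edges$to <- unname(idMap[edges$to])
  }
  MolecularNetwork(nodes, edges)
}

#' Merged cross-polarity node pairs
#'
#' Convenience accessor: the (positive, negative) feature-id pairs that
#' were grouped into single nodes by [mergeNetworks()].
#'
#' @param network a merged [MolecularNetwork-class].
#' @return data.frame with columns `positive`, `negative`.
#' @export
mergedPairs <- function(network) {
  nd <- networkNodes(network)
  if (!"members" %in% names(nd))
    stop("network has no 'members' column; not a merged network")
  both <- nd$polarity == "both"
  parts <- strsplit(nd$members[both], ",", fixed = TRUE)
  data.frame(positive = vapply(parts, `[`, character(1), 1L),
             negative = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
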