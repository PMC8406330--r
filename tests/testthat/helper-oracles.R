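## Independent oracles and random-case generators shared across tests.
## These deliberately re-derive results by brute force (exhaustive
## enumeration, naive graph search) so they stay independent of the
## package implementations they check.

## centroid spacing: real centroided spectra never contain two peaks
## closer than the fragment tolerance (they would be one centroid), so
## generated peak lists keep a spacing margin above 2 x 0.05 Da
dropCrowded <- function(mz, spacing = 0.12) {
  o <- order(mz)
  keep <- rep(TRUE, length(mz))
  last <- -Inf
  for (i in o) {
    if (mz[i] - last < spacing) keep[i] <- FALSE else last <- mz[i]
  }
  keep
}

## random MS/MS spectrum with peaks spread over a wide m/z range
randomSpectrum <- function(id, nPeaks = sample(2:6, 1),
                           precursor = runif(1, 150, 500),
                           polarity = "positive") {
  mz <- runif(nPeaks, 50, precursor - 20)
  keep <- dropCrowded(mz)
  Ms2Spectrum(id, precursor, polarity, runif(1, 0, 20),
              mz = mz[keep], intensity = runif(sum(keep), 1, 100))
}

## a pair of related spectra: b inherits some of a's peaks (within the
## fragment tolerance), some shifted by the precursor mass difference,
## plus unshared extras -- the structure the modified cosine is built for
randomRelatedPair <- function(maxPeaks = 6) {
  precA <- runif(1, 150, 500)
  precB <- precA + runif(1, -30, 30)
  dprec <- precB - precA
  nA <- sample(2:maxPeaks, 1)
  mzA <- runif(nA, 50, min(precA, precB) - 40)
  intA <- runif(nA, 1, 100)
  nShared <- sample(0:nA, 1)
  shared <- if (nShared > 0) sample(nA, nShared) else integer()
  mzB <- intB <- numeric()
  for (i in shared) {
    if (runif(1) < 0.5) mzB <- c(mzB, mzA[i] + runif(1, -0.03, 0.03))
    else mzB <- c(mzB, mzA[i] + dprec + runif(1, -0.03, 0.03))
    intB <- c(intB, runif(1, 1, 100))
  }
  nExtra <- sample(0:(maxPeaks - nShared), 1)
  mzB <- c(mzB, runif(nExtra, 50, min(precA, precB) - 40))
  intB <- c(intB, runif(nExtra, 1, 100))
  if (length(mzB) == 0) { mzB <- runif(1, 50, 100); intB <- runif(1, 1, 100) }
  mzB <- abs(mzB)
  keepA <- dropCrowded(mzA)
  keepB <- dropCrowded(mzB)
  list(a = Ms2Spectrum("a", precA, "positive", 1,
                       mz = mzA[keepA], intensity = intA[keepA]),
       b = Ms2Spectrum("b", precB, "positive", 1,
                       mz = mzB[keepB], intensity = intB[keepB]))
}

## exhaustive optimal one-to-one pairing for the modified cosine:
## maximizes the sum of normalized intensity products over all matchings
## of candidate peak pairs; also counts optimal matchings (ties within
## 1e-12) so uniqueness of the optimum can be established
bruteModifiedCosine <- function(a, b, tol = ToleranceConfig()) {
  pa <- peakMatrix(a); pb <- peakMatrix(b)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    return(list(score = 0, nMatched = 0L, nOptimal = 1L))
  norm <- function(v) {
    w <- sqrt(as.numeric(v)); n <- sqrt(sum(w^2)); if (n > 0) w / n else w
  }
  wa <- norm(pa[, "intensity"]); wb <- norm(pb[, "intensity"])
  dprec <- precursorMz(b) - precursorMz(a)
  cand <- lapply(seq_len(nrow(pa)), function(i) {
    which(abs(pa[i, "mz"] - pb[, "mz"]) <= tol@fragmentTolDa |
            abs(pa[i, "mz"] + dprec - pb[, "mz"]) <= tol@fragmentTolDa)
  })
  best <- 0; nbest <- 1L; bestSize <- 0L
  recurse <- function(i, usedB, acc, size) {
    if (i > length(cand)) {
      if (acc > best + 1e-12) { best <<- acc; nbest <<- 1L; bestSize <<- size }
      else if (acc > best - 1e-12) nbest <<- nbest + 1L
      return(invisible())
    }
    recurse(i + 1L, usedB, acc, size)
    for (j in setdiff(cand[[i]], usedB))
      recurse(i + 1L, c(usedB, j), acc + wa[i] * wb[j], size + 1L)
  }
  recurse(1L, integer(), 0, 0L)
  list(score = best, nMatched = bestSize, nOptimal = nbest)
}

## ---------------------------------------------------------------------
## independent network-rule oracle (no igraph)

## connected components by breadth-first search over an edge list
bruteComponents <- function(ids, edges) {
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  adj <- setNames(vector("list", length(ids)), ids)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
    adj[[edges$to[r]]] <- c(adj[[edges$to[r]]], edges$from[r])
  }
  k <- 0L
  for (v in ids) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- k
      queue <- c(queue, adj[[u]])
    }
  }
  comp
}

## sequential application of the three edge rules, written directly from
## their definitions
bruteNetworkRules <- function(ids, sims, cfg) {
  e <- sims[sims$score > cfg@scoreThreshold &
              sims$nMatched >= cfg@minMatched, , drop = FALSE]
  ## mutual top-k on the thresholded edge set
  if (nrow(e)) {
    topOf <- function(v) {
      nb <- data.frame(
        other = c(e$to[e$from == v], e$from[e$to == v]),
        score = c(e$score[e$from == v], e$score[e$to == v]))
      nb <- nb[order(-nb$score, nb$other), , drop = FALSE]
      nb$other[seq_len(min(cfg@mutualK, nrow(nb)))]
    }
    keep <- vapply(seq_len(nrow(e)), function(r)
      e$to[r] %in% topOf(e$from[r]) && e$from[r] %in% topOf(e$to[r]),
      logical(1))
    e <- e[keep, , drop = FALSE]
  }
  ## family cap: repeatedly delete the lowest-scoring edge of any
  ## oversized component
  repeat {
    comp <- bruteComponents(ids, e)
    sizes <- table(comp)
    big <- names(sizes)[sizes > cfg@maxFamilySize]
    if (!length(big) || !nrow(e)) break
    for (cc in as.integer(big)) {
      inC <- which(comp[e$from] == cc)
      o <- inC[order(e$score[inC], e$from[inC], e$to[inC])]
      e <- e[-o[1], , drop = FALSE]
    }
  }
  rownames(e) <- NULL
  e
}

## canonical comparable edge key set
edgeKeys <- function(edges) {
  if (nrow(edges) == 0) return(character())
  sort(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
             round(edges$score, 9), sep = "|"))
}

## partition equality up to relabeling
samePartition <- function(p, q) {
  p <- p[sort(names(p))]; q <- q[sort(names(q))]
  identical(as.integer(factor(p, levels = unique(p))),
            as.integer(factor(q, levels = unique(q))))
}
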