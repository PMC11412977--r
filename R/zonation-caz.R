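#' Assemble a feature stack for priority ranking
#'
#' Occurrence-value layers: each taxon's suitability with cells below its
#' binary threshold set to zero, weighted by conservation status
#' (DD = 1, VU = 2, EN = 3, CR = 4).
#'
#' @param ensembles named list of [EnsembleModel-class], or a list of
#'   non-negative [GridRaster-class] layers if `weights` is given directly.
#' @param statuses character vector of conservation statuses (used when
#'   `ensembles` are EnsembleModel objects).
#' @param weights optional explicit numeric weights overriding statuses.
#' @return A [FeatureStack-class].
#' @export
featureStack <- function(ensembles, statuses = NULL, weights = NULL) {
  vals <- lapply(ensembles, function(e) {
    if (is(e, "EnsembleModel")) {
      v <- e@suitability@values
      v[e@binary@values == 0] <- 0
      likeRaster(e@suitability, v)
    } else e
  })
  if (is.null(weights)) {
    stopifnot(!is.null(statuses), length(statuses) == length(vals))
    weights <- unname(statusWeights()[statuses])
  }
  if (is.null(names(vals)))
    names(vals) <- paste0("taxon", seq_along(vals))
  new("FeatureStack", values = vals, weights = as.numeric(weights))
}

#' Apply a condition (human-modification) layer
#'
#' Penalizes cells under higher human influence by multiplying every
#' feature layer by (1 - ghm), cellwise.
#'
#' @param features a [FeatureStack-class].
#' @param ghm [GridRaster-class] in \[0, 1\].
#' @return A [FeatureStack-class].
#' @export
applyCondition <- function(features, ghm) {
  g <- ghm@values
  if (any(g < 0 | g > 1, na.rm = TRUE))
    stop("applyCondition: ghm must lie in [0, 1]")
  vals <- lapply(features@values, function(v) {
    assertCompatible(v, ghm)
    likeRaster(v, v@values * (1 - g))
  })
  new("FeatureStack", values = vals, weights = features@weights)
}

#' Core-area zonation priority ranking
#'
#' Iterative least-marginal-loss cell removal under the core-area rule: at
#' each step, among the cells of the lowest hierarchy level still present,
#' the cell minimizing
#' \deqn{\delta_i = \max_j w_j a_{ij} / \sum_{k \in remaining} a_{kj}}
#' is removed (cell cost 1); ties break at the lowest (row, col) in
#' row-major order. All cells of a hierarchy level are removed before any
#' cell of a higher level, so a protected-area mask (level 2 over level 1)
#' forces protected cells into the top ranks. The rank of a cell is the
#' fraction of analyzed cells removed at or before it, so ranks are a
#' permutation of {1/n, ..., 1}. Cells with nodata in any feature are
#' excluded from the analysis. A taxon whose remaining total reaches zero
#' contributes zero marginal loss thereafter.
#'
#' @param features a [FeatureStack-class].
#' @param mask optional integer [GridRaster-class] of hierarchy levels
#'   (>= 1); NULL means a single level.
#' @return A [PriorityRank-class] with the rank raster, removal order and
#'   per-taxon performance curves.
#' @export
cazRank <- function(features, mask = NULL) {
  vals <- features@values
  ref <- vals[[1]]
  if (!is.null(mask)) assertCompatible(ref, mask)
  A <- sapply(vals, function(v) as.vector(v@values))
  A <- matrix(A, ncol = length(vals), dimnames = list(NULL, names(vals)))
  analyzed <- which(rowSums(!is.finite(A)) == 0)
  n <- length(analyzed)
  if (n == 0) stop("cazRank: no analyzable cells")
  lev <- if (is.null(mask)) rep(1, length(A[, 1])) else as.vector(mask@values)
  if (any(lev[analyzed] < 1, na.rm = TRUE))
    stop("cazRank: mask levels must be >= 1")

  nr <- nrow(ref@values)
  rowMajor <- function(cell) {
    r <- (cell - 1L) %% nr; c <- (cell - 1L) %/% nr
    r * ncol(ref@values) + c
  }

  w <- features@weights
  Asub <- A[analyzed, , drop = FALSE]
  S0 <- colSums(Asub)
  S <- S0
  remaining <- rep(TRUE, n)
  removal <- integer(n)
  curves <- matrix(NA_real_, n, length(vals))
  levSorted <- lev[analyzed]

  for (step in seq_len(n)) {
    curLev <- min(levSorted[remaining])
    cand <- which(remaining & levSorted == curLev)
    fac <- ifelse(S > 0, w / S, 0)
    dmat <- sweep(Asub[cand, , drop = FALSE], 2, fac, `*`)
    delta <- dmat[cbind(seq_len(nrow(dmat)),
                        max.col(dmat, ties.method = "first"))]
    # tie-break: lowest (row, col) among tied minima
    best <- which(delta == min(delta))
    pick <- cand[best[order(rowMajor(analyzed[cand[best]]))[1L]]]
    remaining[pick] <- FALSE
    S <- S - Asub[pick, ]
    S[S < 0] <- 0
    removal[step] <- analyzed[pick]
    curves[step, ] <- ifelse(S0 > 0, S / S0, 0)
  }

  rankVals <- rep(NA_real_, length(A[, 1]))
  rankVals[removal] <- seq_len(n) / n
  curvesDf <- data.frame(fracRemoved = c(0, seq_len(n) / n),
                         rbind(rep(1, length(vals)), curves))
  names(curvesDf)[-1] <- names(vals)
  new("PriorityRank",
      rank = likeRaster(ref, matrix(rankVals, nrow(ref@values))),
      removalOrder = removal, curves = curvesDf)
}

setMethod("show", "PriorityRank", function(object) {
  cat(sprintf("PriorityRank  %d analyzed cells, %d taxa\n",
              length(object@removalOrder), ncol(object@curves) - 1L))
})

#' @describeIn cazRank accessors for the rank raster and performance curves.
#' @param x a PriorityRank.
#' @export
rankLayer <- function(x) x@rank

#' @rdname cazRank
#' @export
performanceCurves <- function(x) x@curves

#' Extract conservation priority areas (top-ranked cells)
#'
#' @param rank a [PriorityRank-class].
#' @param topFraction fraction of analyzed cells to keep, in (0, 1]; cells
#'   with rank strictly above `1 - topFraction` are selected.
#' @return Boolean [GridRaster-class] (NA outside the analyzed area).
#' @export
extractCpa <- function(rank, topFraction) {
  stopifnot(topFraction > 0, topFraction <= 1)
  v <- rank@rank@values
  out <- (v > 1 - topFraction) + 0
  likeRaster(rank@rank, out)
}
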