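#' Derive grid predictors from a landscape bundle
#'
#' Builds the standard predictor stack used for distribution modeling:
#' distances to habitat features (forest edge, large fragments, roads,
#' watercourses, protected areas), moving-window land-cover fractions, and
#' the continuous passthrough layers (tree cover, elevation, temperature
#' range, human modification).
#'
#' @param landscape a [LandscapeBundle-class].
#' @param largeFragKm2 area threshold (km2) defining "large" forest
#'   fragments for `distLargeForests`.
#' @param windowCells odd side length of the square moving window for the
#'   percentage layers; edge cells use the truncated window.
#' @return A [PredictorSet-class] with all layers retained.
#' @export
derivePredictors <- function(landscape, largeFragKm2 = 1, windowCells = 5) {
  codes <- landcoverCodes()
  lc <- landscape@landcover
  forest <- forestMask(landscape)
  nonforest <- likeRaster(lc, 1 - forest@values)

  # distance to the forest/non-forest interface: for each cell, distance to
  # the nearest cell of the opposite class
  dToForest <- euclideanDistance(forest)
  dToNon <- euclideanDistance(nonforest)
  distEdge <- likeRaster(lc, ifelse(forest@values > 0,
                                    dToNon@values, dToForest@values))

  frags <- labelFragments(forest)
  bigIds <- frags@areas$id[frags@areas$areaKm2 >= largeFragKm2]
  if (!length(bigIds))
    stop("derivePredictors: no forest fragment reaches ", largeFragKm2,
         " km2 (distLargeForests undefined)")
  bigMask <- likeRaster(lc, matrix(frags@labels@values %in% bigIds,
                                   nrow(lc@values)))

  agroMask <- likeRaster(lc, lc@values == codes[["agropastoral"]])

  layers <- list(
    distEdge = distEdge,
    distLargeForests = euclideanDistance(bigMask),
    distRoads = euclideanDistance(landscape@roads),
    distWater = euclideanDistance(landscape@waterLines),
    distProtArea = euclideanDistance(landscape@protected),
    percAgropastoral = windowFraction(agroMask, windowCells),
    percOldForest = windowFraction(forest, windowCells),
    treeCover = landscape@predictors$treeCover,
    elevation = landscape@predictors$elevation,
    tempRange = landscape@predictors$tempRange,
    ghm = landscape@ghm)
  new("PredictorSet", layers = layers, retained = names(layers),
      dropped = data.frame(name = character(), stage = character(),
                           statistic = numeric()))
}

setMethod("show", "PredictorSet", function(object) {
  cat(sprintf("PredictorSet  %d layers, %d retained\n",
              length(object@layers), length(object@retained)))
  cat("  retained:", paste(object@retained, collapse = ", "), "\n")
  if (nrow(object@dropped))
    cat("  dropped:",
        paste(object@dropped$name, " (", object@dropped$stage, ")",
              sep = "", collapse = ", "), "\n")
})

#' @describeIn derivePredictors retained layers as a named list.
#' @param x a PredictorSet.
#' @export
retainedLayers <- function(x) x@layers[x@retained]

#' @rdname derivePredictors
#' @export
screeningReport <- function(x) {
  rbind(data.frame(name = x@retained, stage = "retained",
                   statistic = NA_real_),
        x@dropped)
}

# seeded sample of cells where every retained layer is finite
screenSample <- function(pset, sampleCells, seed) {
  M <- sapply(pset@layers[pset@retained], function(r) as.vector(r@values))
  ok <- which(rowSums(!is.finite(M)) == 0)
  idx <- if (length(ok) > sampleCells)
    withr::with_seed(as.integer(seed), sample(ok, sampleCells)) else ok
  M[idx, , drop = FALSE]
}

#' Prune pairwise-correlated predictors
#'
#' Removes predictors until no retained pair has |Pearson r| above `rMax`,
#' computed on a seeded random sample of complete cells. At each step the
#' layer with the highest mean |r| against all remaining layers (among
#' layers participating in a violating pair) is dropped; ties break
#' alphabetically. Correlation is assessed once on the whole landscape
#' sample, not per taxon.
#'
#' @param pset a [PredictorSet-class].
#' @param sampleCells number of cells to sample for the correlation matrix.
#' @param rMax maximum tolerated absolute pairwise Pearson correlation.
#' @param seed integer seed for the cell sample.
#' @return A [PredictorSet-class] with `retained`/`dropped` updated; dropped
#'   entries record the offending |r|.
#' @export
pearsonPrune <- function(pset, sampleCells = 10000, rMax = 0.7, seed = 1) {
  stopifnot(length(pset@retained) >= 2)
  M <- screenSample(pset, sampleCells, seed)
  retained <- pset@retained
  dropped <- pset@dropped
  repeat {
    C <- abs(suppressWarnings(cor(M[, retained, drop = FALSE])))
    C[!is.finite(C)] <- 0
    diag(C) <- 0
    if (max(C) <= rMax || length(retained) <= 1) break
    inPair <- apply(C > rMax, 1, any)
    meanAbs <- rowMeans(C)
    cand <- names(which(inPair))
    drop <- cand[order(-meanAbs[cand], cand)][1L]
    dropped <- rbind(dropped, data.frame(name = drop, stage = "pearson",
                                         statistic = max(C[drop, ])))
    retained <- setdiff(retained, drop)
  }
  new("PredictorSet", layers = pset@layers, retained = retained,
      dropped = dropped)
}

#' Prune multicollinear predictors by variance inflation
#'
#' Iteratively removes the layer with the largest variance inflation factor
#' (VIF_j = 1 / (1 - R2_j) from regressing layer j on all others over the
#' sampled cells) until every VIF is below `vifMax`. Perfect collinearity
#' yields a non-finite VIF, treated as infinite and dropped first.
#'
#' @inheritParams pearsonPrune
#' @param vifMax all retained layers end with VIF strictly below this.
#' @return A [PredictorSet-class]; dropped entries record the VIF at removal.
#' @export
vifPrune <- function(pset, sampleCells = 10000, vifMax = 5, seed = 1) {
  stopifnot(length(pset@retained) >= 2)
  M <- screenSample(pset, sampleCells, seed)
  if (nrow(M) <= length(pset@retained) + 1)
    stop("vifPrune: need more sampled cells than layers + 1")
  retained <- pset@retained
  dropped <- pset@dropped
  repeat {
    v <- vifVector(M[, retained, drop = FALSE])
    if (max(v) < vifMax || length(retained) <= 1) break
    worst <- names(v)[order(-v, names(v))][1L]
    dropped <- rbind(dropped, data.frame(name = worst, stage = "vif",
                                         statistic = v[[worst]]))
    retained <- setdiff(retained, worst)
  }
  new("PredictorSet", layers = pset@layers, retained = retained,
      dropped = dropped)
}

# VIFs for the columns of a numeric matrix; non-finite (singular or
# zero-variance) cases map to +Inf
vifVector <- function(M) {
  vapply(seq_len(ncol(M)), function(j) {
    y <- M[, j]
    if (sd(y) == 0) return(Inf)
    fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    v <- 1 / (1 - r2)
    if (!is.finite(v) || v < 0) Inf else v
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(M))
}
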