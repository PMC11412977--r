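#' Extract conservation-priority fragments (CPFs)
#'
#' Forest fragments strictly larger than `minAreaKm2` whose unweighted mean
#' priority rank over the fragment's cells is strictly above `minMeanRank`.
#'
#' @param rank a [PriorityRank-class].
#' @param fragments a [FragmentMap-class] of forest fragments.
#' @param minAreaKm2 minimum fragment area, km2 (strict).
#' @param minMeanRank minimum mean priority rank (strict).
#' @return data.frame (id, cells, areaKm2, meanRank) with a list attribute
#'   `cellList` mapping each row to the fragment's linear cell indices.
#' @export
extractCpfs <- function(rank, fragments, minAreaKm2 = 1, minMeanRank = 0.95) {
  assertCompatible(rank@rank, fragments@labels)
  lab <- fragments@labels@values
  rk <- rank@rank@values
  out <- fragments@areas
  out$meanRank <- vapply(out$id, function(id)
    mean(rk[lab == id], na.rm = TRUE), numeric(1))
  keep <- out$areaKm2 > minAreaKm2 & !is.na(out$meanRank) &
    out$meanRank > minMeanRank
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "cellList") <- lapply(res$id, function(id) which(lab == id))
  res
}

#' Composite landscape resistance
#'
#' Mean of five movement-resistance layers in \[0, 1\]:
#' \enumerate{
#'   \item forest: 0 on forest, 1 elsewhere;
#'   \item canopy: rescaled inverse of tree canopy cover (low cover = high
#'     resistance);
#'   \item distance: Euclidean distance to forest, rescaled to \[0, 1\]
#'     (farther = higher resistance);
#'   \item restoration: 0 in unforested riparian permanent-preservation
#'     (APP) cells, 1 outside APPs or in APPs already forested — steering
#'     corridors through restorable riparian land;
#'   \item barriers: 1 on roads and watercourses, 0 elsewhere.
#' }
#'
#' @param landscape a [LandscapeBundle-class].
#' @return A [GridRaster-class] in \[0, 1\] with the component layers in
#'   attribute `components`.
#' @export
landscapeResistance <- function(landscape) {
  if (is.null(landscape@predictors$treeCover))
    stop("landscapeResistance: missing layer treeCover")
  forest <- maskMatrix(forestMask(landscape)) > 0
  app <- maskMatrix(landscape@appRiparian) > 0
  barrier <- maskMatrix(landscape@roads) > 0 |
    maskMatrix(landscape@waterLines) > 0
  comp <- list(
    forest = likeRaster(landscape@landcover, (!forest) + 0),
    canopy = rescale01(landscape@predictors$treeCover, invert = TRUE),
    distForest = rescale01(euclideanDistance(forestMask(landscape))),
    appRestoration = likeRaster(landscape@landcover,
                                ifelse(app & !forest, 0, 1)),
    barriers = likeRaster(landscape@landcover, barrier + 0))
  acc <- Reduce(`+`, lapply(comp, function(r) r@values)) / length(comp)
  out <- likeRaster(landscape@landcover, acc)
  attr(out, "components") <- comp
  out
}

#' Taxon resistance from habitat suitability
#'
#' Reflects each habitat-suitability layer between its own extremes:
#' r = (max(hs) - hs) + min(hs), so the most suitable cell gets the layer's
#' minimum resistance and the least suitable its maximum. Layers are then
#' averaged across taxa. A constant layer is returned unchanged (the
#' reflection is the identity there) with a warning.
#'
#' @param suitabilityLayers non-empty list of [GridRaster-class] (or
#'   [EnsembleModel-class], whose suitability is taken).
#' @return A [GridRaster-class].
#' @export
taxonResistance <- function(suitabilityLayers) {
  stopifnot(length(suitabilityLayers) >= 1)
  layers <- lapply(suitabilityLayers, function(x)
    if (is(x, "EnsembleModel")) x@suitability else x)
  do.call(assertCompatible, layers)
  refl <- lapply(layers, function(r) {
    v <- r@values
    fin <- is.finite(v)
    lo <- min(v[fin]); hi <- max(v[fin])
    if (hi == lo)
      warning("taxonResistance: constant suitability layer (identity)")
    likeRaster(r, (hi - v) + lo)
  })
  likeRaster(layers[[1]],
             Reduce(`+`, lapply(refl, function(r) r@values)) / length(refl))
}

#' Combine landscape and taxon resistance
#'
#' The final resistance surface is exactly the mean of the two inputs.
#'
#' @param landscapeR [GridRaster-class] landscape resistance in \[0, 1\].
#' @param taxonR [GridRaster-class] averaged taxon resistance.
#' @return A [ResistanceSurface-class].
#' @export
finalResistance <- function(landscapeR, taxonR) {
  assertCompatible(landscapeR, taxonR)
  comp <- attr(landscapeR, "components")
  new("ResistanceSurface", landscape = landscapeR, taxon = taxonR,
      final = likeRaster(landscapeR, (landscapeR@values + taxonR@values) / 2),
      components = if (is.null(comp)) list() else comp)
}

setMethod("show", "ResistanceSurface", function(object) {
  v <- object@final@values
  cat(sprintf("ResistanceSurface  final range [%.3f, %.3f]\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

#' @describeIn finalResistance accessor for the final combined layer.
#' @param x a ResistanceSurface.
#' @export
finalLayer <- function(x) x@final

#' Cost-weighted distance from a source cell set
#'
#' Single-source-set shortest paths over the 8-connected grid graph: moving
#' between adjacent cells costs the center-to-center distance times the mean
#' of the two cells' resistance (diagonal steps scale distance by sqrt(2)).
#' Source cells get cost 0; backlinks reconstruct least-cost paths. Nodata
#' resistance cells are impassable.
#'
#' @param resistance [GridRaster-class] of non-negative resistances (or a
#'   [ResistanceSurface-class], whose final layer is used).
#' @param sources integer vector of linear (column-major) cell indices.
#' @return list(cwd = [GridRaster-class] of accumulated costs (Inf where
#'   unreachable), backlinks = integer vector of predecessor cell indices,
#'   0 at sources/unreached).
#' @export
costDistance <- function(resistance, sources) {
  r <- if (is(resistance, "ResistanceSurface")) resistance@final else resistance
  if (any(r@values < 0, na.rm = TRUE))
    stop("costDistance: negative resistance")
  if (!length(sources)) stop("costDistance: empty source set")
  out <- .dijkstraGrid(as.vector(r@values), nrow(r@values), ncol(r@values),
                       r@cellSize, as.integer(sources))
  list(cwd = likeRaster(r, matrix(out$cwd, nrow(r@values))),
       backlinks = out$pred)
}

# follow backlinks from a cell down to the source set; returns the cell path
# source -> ... -> cell
tracePath <- function(cell, backlinks) {
  path <- integer()
  while (cell != 0) {
    path <- c(cell, path)
    cell <- backlinks[cell]
  }
  path
}

pathLengthM <- function(raster, path) {
  if (length(path) < 2) return(0)
  rc <- cellRowCol(raster, path)
  dr <- abs(diff(rc$row)); dc <- abs(diff(rc$col))
  sum(ifelse(dr + dc == 2, sqrt(2), 1) * raster@cellSize)
}

#' Plan least-cost corridors between priority fragments
#'
#' Builds one corridor per adjacent CPF pair under cost allocation: every
#' cell is assigned to the CPF reachable at least cost-weighted distance,
#' and pairs whose allocation regions touch (8-adjacency) are linked by the
#' least-cost path between the two fragments (their full cell sets act as
#' sources/targets). Each corridor reports the cost-weighted distance (CWD),
#' the geometric corridor length (CL, summed center-to-center along the
#' path) and the CWD/CL ratio — the mean effective resistance en route. With
#' `allPairs = TRUE` every pair is linked instead (small fragment counts).
#'
#' @param cpfs CPF table from [extractCpfs()] (at least two rows).
#' @param resistance [ResistanceSurface-class] or [GridRaster-class].
#' @return data.frame (cpfA, cpfB, cwd, cl, ratio, reachable) with the cell
#'   paths in attribute `paths`.
#' @param allPairs link all pairs instead of cost-allocation neighbours.
#' @export
planCorridors <- function(cpfs, resistance, allPairs = FALSE) {
  if (nrow(cpfs) < 2)
    stop("planCorridors: need at least two CPFs")
  r <- if (is(resistance, "ResistanceSurface")) resistance@final else resistance
  cellList <- attr(cpfs, "cellList")
  k <- nrow(cpfs)
  cd <- lapply(seq_len(k), function(i) costDistance(r, cellList[[i]]))
  cwdM <- sapply(cd, function(x) as.vector(x$cwd@values))

  pairs <- if (allPairs) {
    which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  } else {
    alloc <- allocationRegions(r, cwdM)
    adjacentRegionPairs(r, alloc)
  }
  if (!nrow(pairs))
    return(emptyCorridors())

  out <- vector("list", nrow(pairs))
  paths <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs[p, 1]; b <- pairs[p, 2]
    tot <- cwdM[, a] + cwdM[, b]
    m <- which.min(tot)
    if (!is.finite(tot[m])) {
      out[[p]] <- data.frame(cpfA = cpfs$id[a], cpfB = cpfs$id[b],
                             cwd = NA_real_, cl = NA_real_,
                             ratio = NA_real_, reachable = FALSE)
      next
    }
    pa <- tracePath(m, cd[[a]]$backlinks)            # A-source .. m
    pb <- rev(tracePath(m, cd[[b]]$backlinks))       # m .. B-source
    path <- c(pa, pb[-1])
    cl <- pathLengthM(r, path)
    cwd <- tot[m]
    out[[p]] <- data.frame(cpfA = cpfs$id[a], cpfB = cpfs$id[b], cwd = cwd,
                           cl = cl, ratio = if (cl > 0) cwd / cl else 0,
                           reachable = TRUE)
    paths[[p]] <- path
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "paths") <- paths
  res
}

emptyCorridors <- function() {
  structure(data.frame(cpfA = integer(), cpfB = integer(), cwd = numeric(),
                       cl = numeric(), ratio = numeric(),
                       reachable = logical()),
            paths = list())
}

# nearest-CPF assignment by CWD (ties to the lowest fragment index);
# 0 where unreachable from every CPF
allocationRegions <- function(raster, cwdM) {
  alloc <- max.col(-cwdM, ties.method = "first")
  alloc[!is.finite(cwdM[cbind(seq_len(nrow(cwdM)), alloc)])] <- 0L
  alloc
}

adjacentRegionPairs <- function(raster, alloc) {
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  A <- matrix(alloc, nr, nc)
  touch <- function(a, b) {
    ok <- a > 0 & b > 0 & a != b
    cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
  }
  prs <- rbind(
    touch(A[, -nc], A[, -1]),             # horizontal
    touch(A[-nr, ], A[-1, ]),             # vertical
    touch(A[-nr, -nc], A[-1, -1]),        # diagonal \
    touch(A[-1, -nc], A[-nr, -1]))        # diagonal /
  unique(prs)
}
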