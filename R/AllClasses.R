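#' @import methods
#' @importFrom stats cor dist median plogis pnorm predict quantile runif rnorm sd setNames
#' @importFrom utils head read.csv write.csv
NULL

#' GridRaster: a single-band raster on a shared projected grid
#'
#' The universal currency of the pipeline. `values` is a numeric matrix in
#' row-major geographic order: row 1 is the northernmost row. Missing cells
#' are held as `NA` internally; the `nodata` slot records the sentinel used
#' when the raster is written to disk.
#'
#' @slot values numeric matrix of cell values (`NA` = nodata).
#' @slot nodata numeric(1), sentinel written on export.
#' @slot cellSize numeric(1), cell edge length in meters (square cells).
#' @slot origin numeric(2), projected (x, y) of the grid's top-left corner.
#' @slot crsTag character(1), opaque CRS identifier carried through I/O.
#' @export
setClass("GridRaster",
  representation(values = "matrix", nodata = "numeric",
                 cellSize = "numeric", origin = "numeric",
                 crsTag = "character"),
  prototype(nodata = -9999, cellSize = 1000, origin = c(0, 0), crsTag = ""))

setValidity("GridRaster", function(object) {
  msg <- character()
  if (length(object@values) == 0L) msg <- c(msg, "values array is empty")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0) msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be finite (x, y)")
  if (length(object@nodata) != 1L) msg <- c(msg, "nodata must be length 1")
  if (length(object@crsTag) != 1L) msg <- c(msg, "crsTag must be length 1")
  if (length(msg)) msg else TRUE
})

#' FragmentMap: labeled habitat fragments with areas
#'
#' @slot labels integer-valued [GridRaster] (0 = background, k > 0 = fragment id).
#' @slot areas data.frame with columns `id` and `areaKm2`.
#' @export
setClass("FragmentMap",
  representation(labels = "GridRaster", areas = "data.frame"))

setValidity("FragmentMap", function(object) {
  ids <- sort(unique(as.vector(object@labels@values)))
  ids <- ids[is.finite(ids) & ids > 0]
  if (!setequal(ids, object@areas$id))
    return("every nonzero label must have exactly one area entry")
  TRUE
})

#' LandscapeBundle: all co-registered layers of a study landscape
#'
#' @slot predictors named list of continuous [GridRaster] layers.
#' @slot landcover categorical [GridRaster]; codes in [landcoverCodes()].
#' @slot protected,roads,waterLines,appRiparian boolean (0/1) [GridRaster] layers.
#' @slot ghm [GridRaster] in \[0, 1\]: global-human-modification proxy.
#' @slot seed integer seed the bundle was generated from (NA for loaded data).
#' @slot params list of generator parameters (empty for loaded data).
#' @export
setClass("LandscapeBundle",
  representation(predictors = "list", landcover = "GridRaster",
                 protected = "GridRaster", roads = "GridRaster",
                 waterLines = "GridRaster", ghm = "GridRaster",
                 appRiparian = "GridRaster", seed = "integer",
                 params = "list"))

setValidity("LandscapeBundle", function(object) {
  layers <- c(object@predictors,
              list(object@landcover, object@protected, object@roads,
                   object@waterLines, object@ghm, object@appRiparian))
  ok <- tryCatch({ do.call(assertCompatible, layers); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  g <- object@ghm@values
  if (any(g < 0 | g > 1, na.rm = TRUE)) return("ghm must lie in [0, 1]")
  lc <- object@landcover@values
  bad <- setdiff(unique(lc[is.finite(lc)]), unname(landcoverCodes()))
  if (length(bad)) return(sprintf("unknown landcover codes: %s",
                                  paste(bad, collapse = ", ")))
  TRUE
})

#' VirtualTaxon: a simulated taxon with known suitability truth
#'
#' @slot name taxon name.
#' @slot trueSuitability [GridRaster] in \[0, 1\], the logistic truth.
#' @slot responseSpec list with `intercept` and named `coefs` on standardized
#'   predictors; the suitability raster is exactly recomputable from it.
#' @slot status conservation status, one of DD, VU, EN, CR.
#' @slot occurrences data.frame (taxon, x, y, year, count, precision_m).
#' @export
setClass("VirtualTaxon",
  representation(name = "character", trueSuitability = "GridRaster",
                 responseSpec = "list", status = "character",
                 occurrences = "data.frame"))

setValidity("VirtualTaxon", function(object) {
  if (!object@status %in% names(statusWeights()))
    return("status must be one of DD, VU, EN, CR")
  v <- object@trueSuitability@values
  if (any(v < 0 | v > 1, na.rm = TRUE)) return("trueSuitability outside [0, 1]")
  TRUE
})

#' OccurrenceSet: cleaned occurrence records with an audit trail
#'
#' @slot taxon taxon name.
#' @slot records data.frame of kept records (x, y, year, count, precision_m, ...).
#' @slot audit data.frame of removed records with a `reason` column; kept
#'   records plus audited removals always partition the input.
#' @export
setClass("OccurrenceSet",
  representation(taxon = "character", records = "data.frame",
                 audit = "data.frame"))

setValidity("OccurrenceSet", function(object) {
  ok <- c("no_coords", "outside_area", "nonvegetated", "precision",
          "count_range", "year", "exclusion_zone", "outlier",
          "duplicate", "thinned")
  if (nrow(object@audit) && !all(object@audit$reason %in% ok))
    return("unknown audit reason code")
  TRUE
})

#' PredictorSet: named predictor layers with a screening trail
#'
#' @slot layers named list of [GridRaster] (all initially derived layers).
#' @slot retained character vector of currently retained layer names.
#' @slot dropped data.frame (name, stage in {pearson, vif}, statistic).
#' @export
setClass("PredictorSet",
  representation(layers = "list", retained = "character",
                 dropped = "data.frame"))

setValidity("PredictorSet", function(object) {
  nm <- names(object@layers)
  if (length(intersect(object@retained, object@dropped$name)))
    return("retained and dropped overlap")
  if (!setequal(union(object@retained, object@dropped$name), nm))
    return("retained + dropped must cover the layer names")
  TRUE
})

#' EnsembleModel: TSS-weighted ensemble of candidate SDMs for one taxon
#'
#' @slot taxon taxon name.
#' @slot members list of candidate records (learner fits kept opaque).
#' @slot weights numeric, one per member, proportional to holdout TSS, sum 1.
#' @slot threshold ensemble-level max-TSS binarization cutoff.
#' @slot suitability [GridRaster] in \[0, 1\].
#' @slot binary boolean [GridRaster]: suitability >= threshold.
#' @slot evalData pooled holdout frame (label + predictor columns) used for
#'   thresholding and permutation importance.
#' @export
setClass("EnsembleModel",
  representation(taxon = "character", members = "list", weights = "numeric",
                 threshold = "numeric", suitability = "GridRaster",
                 binary = "GridRaster", evalData = "data.frame"))

setValidity("EnsembleModel", function(object) {
  if (length(object@weights) != length(object@members))
    return("one weight per member required")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  TRUE
})

#' FeatureStack: weighted occurrence-value layers for priority ranking
#'
#' @slot values named list of non-negative [GridRaster] layers, one per taxon
#'   (suitability with cells below the taxon's binary threshold set to zero).
#' @slot weights numeric per-taxon weights (conservation-status weights 1-4).
#' @export
setClass("FeatureStack",
  representation(values = "list", weights = "numeric"))

setValidity("FeatureStack", function(object) {
  if (length(object@values) != length(object@weights))
    return("one weight per feature layer required")
  for (v in object@values)
    if (any(v@values < 0, na.rm = TRUE)) return("feature values must be >= 0")
  TRUE
})

#' PriorityRank: core-area zonation removal-order ranking
#'
#' @slot rank [GridRaster] with values in (0, 1]; the cell removed last has
#'   rank 1, nodata cells are not ranked.
#' @slot removalOrder integer vector of linear cell indices (column-major, as
#'   returned by [cellIndex()]) in order of removal.
#' @slot curves data.frame of performance curves: `fracRemoved` plus one
#'   column per taxon with the fraction of its weighted distribution remaining.
#' @export
setClass("PriorityRank",
  representation(rank = "GridRaster", removalOrder = "integer",
                 curves = "data.frame"))

#' ResistanceSurface: composite movement-resistance raster
#'
#' @slot landscape [GridRaster] in \[0, 1\]: mean of the five landscape layers.
#' @slot taxon [GridRaster]: averaged taxon resistance.
#' @slot final [GridRaster]: exactly (landscape + taxon) / 2.
#' @slot components named list of the audit layers behind `landscape`.
#' @export
setClass("ResistanceSurface",
  representation(landscape = "GridRaster", taxon = "GridRaster",
                 final = "GridRaster", components = "list"))

setValidity("ResistanceSurface", function(object) {
  d <- object@final@values - (object@landscape@values + object@taxon@values) / 2
  if (max(abs(d), na.rm = TRUE) > 1e-12)
    return("final must equal (landscape + taxon) / 2")
  TRUE
})
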