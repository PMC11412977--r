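#' Suitable-area accounting for one taxon
#'
#' Areas (km2) of the suitable landscape (all suitable cells regardless of
#' cover) and of suitable forest (suitable cells on forest land cover), each
#' split into protected and unprotected parts.
#'
#' @param binary boolean [GridRaster-class] range map of the taxon.
#' @param landcover categorical [GridRaster-class].
#' @param protected boolean [GridRaster-class].
#' @param taxon,status carried into the output row.
#' @return One-row data.frame with columns taxon, status,
#'   suitLandKm2, suitLandProtKm2, suitLandUnprotKm2,
#'   suitForKm2, suitForProtKm2, suitForUnprotKm2.
#' @export
suitableAreas <- function(binary, landcover, protected,
                          taxon = "taxon", status = NA_character_) {
  assertCompatible(binary, landcover, protected)
  cellKm2 <- binary@cellSize^2 / 1e6
  b <- is.finite(binary@values) & binary@values != 0
  f <- landcover@values == landcoverCodes()[["forest"]]
  p <- is.finite(protected@values) & protected@values != 0
  data.frame(taxon = taxon, status = status,
             suitLandKm2 = sum(b) * cellKm2,
             suitLandProtKm2 = sum(b & p) * cellKm2,
             suitLandUnprotKm2 = sum(b & !p) * cellKm2,
             suitForKm2 = sum(b & f) * cellKm2,
             suitForProtKm2 = sum(b & f & p) * cellKm2,
             suitForUnprotKm2 = sum(b & f & !p) * cellKm2)
}

#' Alpha diversity by stacking binary range maps
#'
#' Cellwise integer sum of the binary occurrence layers; the result ranges
#' from 0 to the number of taxa.
#'
#' @param binaries non-empty list of boolean [GridRaster-class], one grid.
#' @return A [GridRaster-class] of per-cell taxon counts.
#' @export
alphaDiversity <- function(binaries) {
  stopifnot(length(binaries) >= 1)
  do.call(assertCompatible, binaries)
  acc <- matrix(0, nrow(binaries[[1]]@values), ncol(binaries[[1]]@values))
  for (b in binaries) {
    v <- b@values
    v[!is.finite(v)] <- 0
    acc <- acc + (v != 0)
  }
  likeRaster(binaries[[1]], acc)
}

#' Aggregate per-taxon values by conservation status
#'
#' Unweighted mean per status group; groups represented by a single taxon
#' are flagged (their mean is reported but should be interpreted with care),
#' and empty groups are omitted.
#'
#' @param values named or unnamed numeric vector, one per taxon.
#' @param statuses matching character vector with values in DD, VU, EN, CR.
#' @return data.frame (status, mean, n, singleton).
#' @export
aggregateByStatus <- function(values, statuses) {
  stopifnot(length(values) == length(statuses))
  bad <- setdiff(unique(statuses), names(statusWeights()))
  if (length(bad)) stop("unknown status: ", paste(bad, collapse = ", "))
  out <- do.call(rbind, lapply(intersect(names(statusWeights()),
                                         unique(statuses)), function(s) {
    v <- values[statuses == s]
    data.frame(status = s, mean = mean(v), n = length(v),
               singleton = length(v) == 1L)
  }))
  rownames(out) <- NULL
  out
}
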