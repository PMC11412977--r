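#' Construct a GridRaster
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param cellSize cell edge length in meters.
#' @param origin projected (x, y) of the top-left corner.
#' @param nodata sentinel value used on export; cells equal to it are
#'   converted to `NA` on construction.
#' @param crsTag opaque CRS string carried through I/O.
#' @return A [GridRaster-class] object.
#' @export
#' @examples
#' r <- gridRaster(matrix(0:8, 3, 3, byrow = TRUE))
#' gridDim(r)
gridRaster <- function(values, cellSize = 1000, origin = c(0, 0),
                       nodata = -9999, crsTag = "") {
  if (is.logical(values)) values <- values + 0
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.na(nodata)) values[values == nodata] <- NA_real_
  new("GridRaster", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), nodata = as.numeric(nodata),
      crsTag = as.character(crsTag))
}

#' @rdname gridRaster
#' @param x,object a GridRaster.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname gridRaster
#' @export
setMethod("values", "GridRaster", function(x) x@values)

#' @rdname gridRaster
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname gridRaster
#' @export
setMethod("cellSize", "GridRaster", function(x) x@cellSize)

#' @rdname gridRaster
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname gridRaster
#' @export
setMethod("origin", "GridRaster", function(x) x@origin)

#' @rdname gridRaster
#' @export
setGeneric("nodataValue", function(x) standardGeneric("nodataValue"))
#' @rdname gridRaster
#' @export
setMethod("nodataValue", "GridRaster", function(x) x@nodata)

#' @rdname gridRaster
#' @export
setGeneric("crsTag", function(x) standardGeneric("crsTag"))
#' @rdname gridRaster
#' @export
setMethod("crsTag", "GridRaster", function(x) x@crsTag)

#' @rdname gridRaster
#' @export
gridDim <- function(x) dim(x@values)

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat(sprintf("GridRaster  %d x %d cells, %.0f m resolution\n",
              nrow(v), ncol(v), object@cellSize))
  cat(sprintf("  origin (%.1f, %.1f)%s\n", object@origin[1], object@origin[2],
              if (nzchar(object@crsTag)) paste0("  crs: ", object@crsTag) else ""))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(fin), max(fin), sum(!is.finite(v))))
  else cat("  values: all nodata\n")
})

#' Derive a new raster on the same grid
#'
#' @param template a [GridRaster-class] supplying grid geometry.
#' @param values replacement matrix (or vector recycled to the grid shape).
#' @return A [GridRaster-class].
#' @export
likeRaster <- function(template, values) {
  v <- matrix(as.numeric(values), nrow(template@values), ncol(template@values))
  new("GridRaster", values = v, nodata = template@nodata,
      cellSize = template@cellSize, origin = template@origin,
      crsTag = template@crsTag)
}

#' Assert that rasters share one grid
#'
#' All layers combined in any operation must share shape, cell size and
#' origin; this assertion fires on the first mismatch.
#'
#' @param ... two or more [GridRaster-class] objects.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
assertCompatible <- function(...) {
  rs <- list(...)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!identical(dim(r@values), dim(ref@values)))
      stop("grid mismatch: shapes differ (", paste(dim(r@values), collapse = "x"),
           " vs ", paste(dim(ref@values), collapse = "x"), ")")
    if (!isTRUE(all.equal(r@cellSize, ref@cellSize)))
      stop("grid mismatch: cell sizes differ")
    if (!isTRUE(all.equal(r@origin, ref@origin)))
      stop("grid mismatch: origins differ")
  }
  invisible(TRUE)
}

#' Cell indexing and coordinates
#'
#' Cells are indexed (row, col), 1-based, row 1 = north; `cellIndex` converts
#' to the linear (column-major) index used throughout, and `cellXY` returns
#' cell-center projected coordinates. `cellFromXY` maps points to linear cell
#' indices (`NA` for off-grid points).
#'
#' @param raster a [GridRaster-class].
#' @param row,col cell row/column indices.
#' @param cell linear cell indices.
#' @param x,y projected coordinates.
#' @return `cellIndex`: integer linear indices; `cellXY`: data.frame (x, y);
#'   `cellFromXY`: integer linear indices with `NA` off grid.
#' @export
cellIndex <- function(raster, row, col) {
  as.integer((col - 1L) * nrow(raster@values) + row)
}

#' @rdname cellIndex
#' @export
cellRowCol <- function(raster, cell) {
  nr <- nrow(raster@values)
  data.frame(row = (cell - 1L) %% nr + 1L, col = (cell - 1L) %/% nr + 1L)
}

#' @rdname cellIndex
#' @export
cellXY <- function(raster, cell) {
  rc <- cellRowCol(raster, cell)
  data.frame(x = raster@origin[1] + (rc$col - 0.5) * raster@cellSize,
             y = raster@origin[2] - (rc$row - 0.5) * raster@cellSize)
}

#' @rdname cellIndex
#' @export
cellFromXY <- function(raster, x, y) {
  col <- floor((x - raster@origin[1]) / raster@cellSize) + 1
  row <- floor((raster@origin[2] - y) / raster@cellSize) + 1
  off <- is.na(row) | is.na(col) | row < 1 | col < 1 |
    row > nrow(raster@values) | col > ncol(raster@values)
  out <- cellIndex(raster, row, col)
  out[off] <- NA_integer_
  out
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange: an `.asc` grid with the
#' standard six-line header plus an optional `.prj` sidecar carrying the CRS
#' tag. A write-then-read round trip preserves values, nodata, cell size and
#' origin exactly.
#'
#' @param path path to the `.asc` file.
#' @return `readRaster`: a [GridRaster-class]; `writeRaster`: the path,
#'   invisibly.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ASCII grid header, missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("malformed ASCII grid: expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  prj <- sub("\\.asc$", ".prj", path)
  crs <- if (file.exists(prj)) readLines(prj, warn = FALSE)[1L] else ""
  gridRaster(m, cellSize = hdr$cellsize,
             origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
             nodata = nodata, crsTag = crs)
}

#' @rdname readRaster
#' @param raster a [GridRaster-class] to write.
#' @export
writeRaster <- function(raster, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  v <- raster@values
  nd <- if (is.na(raster@nodata)) -9999 else raster@nodata
  v[!is.finite(v)] <- nd
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", raster@origin[1]),
           sprintf("yllcorner %.10g", raster@origin[2] - nr * raster@cellSize),
           sprintf("cellsize %.10g", raster@cellSize),
           sprintf("NODATA_value %.10g", nd))
  body <- apply(v, 1L, function(row)
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, body), path)
  if (nzchar(raster@crsTag))
    writeLines(raster@crsTag, sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' Euclidean distance to the nearest mask cell
#'
#' Exact center-to-center Euclidean distance transform, in meters: each cell
#' receives the distance to the nearest TRUE cell of the mask (mask cells
#' themselves receive 0).
#'
#' @param mask a boolean [GridRaster-class] (nonzero = TRUE) with at least
#'   one TRUE cell.
#' @return A [GridRaster-class] of distances in meters.
#' @export
euclideanDistance <- function(mask) {
  m <- maskMatrix(mask)
  if (!any(m > 0)) stop("euclideanDistance: mask has no TRUE cell")
  d <- EBImage::distmap(1 - m, metric = "euclidean")
  likeRaster(mask, as.numeric(d) * mask@cellSize)
}

maskMatrix <- function(raster) {
  v <- raster@values
  m <- is.finite(v) & v != 0
  storage.mode(m) <- "double"
  m
}

#' Label habitat fragments (8-connected components)
#'
#' Connected components of a boolean mask under 8-connectivity (queen moves),
#' labeled 1..K in row-major scan order, with fragment areas in km2.
#'
#' @param forestMask boolean [GridRaster-class].
#' @return A [FragmentMap-class].
#' @export
labelFragments <- function(forestMask) {
  m <- maskMatrix(forestMask) > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  # row-major scan so labels are assigned in geographic reading order
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!m[r, c] || lab[r, c] != 0L) next
    k <- k + 1L
    queue <- matrix(c(r, c), ncol = 2L)
    lab[r, c] <- k
    while (nrow(queue)) {
      cur <- queue
      queue <- matrix(integer(), ncol = 2L)
      for (j in seq_len(nrow(offs))) {
        rr <- cur[, 1] + offs[j, 1]; cc <- cur[, 2] + offs[j, 2]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        rr <- rr[ok]; cc <- cc[ok]
        idx <- (cc - 1L) * nr + rr
        newc <- m[idx] & lab[idx] == 0L
        if (any(newc)) {
          lab[idx[newc]] <- k
          queue <- rbind(queue, cbind(rr[newc], cc[newc]))
        }
      }
      queue <- unique(queue)
    }
  }
  counts <- tabulate(lab, nbins = k)
  areas <- data.frame(id = seq_len(k),
                      cells = counts,
                      areaKm2 = counts * forestMask@cellSize^2 / 1e6)
  new("FragmentMap", labels = likeRaster(forestMask, lab), areas = areas)
}

setMethod("show", "FragmentMap", function(object) {
  cat(sprintf("FragmentMap  %d fragments, total %.2f km2\n",
              nrow(object@areas), sum(object@areas$areaKm2)))
})

#' @describeIn labelFragments accessor for the fragment-area table.
#' @param x a FragmentMap.
#' @export
fragmentAreas <- function(x) x@areas

#' @describeIn labelFragments accessor for the label raster.
#' @export
fragmentLabels <- function(x) x@labels

#' Rescale a raster linearly to \[0, 1\]
#'
#' Minimum maps to 0 and maximum to 1 (`invert = TRUE` reverses the ends).
#' A constant raster maps to all zeros (resistance-neutral convention) with
#' a warning, so degenerate inputs do not halt a pipeline.
#'
#' @param raster a [GridRaster-class].
#' @param invert if TRUE, minimum maps to 1 and maximum to 0.
#' @return A [GridRaster-class] in \[0, 1\].
#' @export
rescale01 <- function(raster, invert = FALSE) {
  v <- raster@values
  fin <- is.finite(v)
  lo <- suppressWarnings(min(v[fin])); hi <- suppressWarnings(max(v[fin]))
  if (!is.finite(lo) || hi == lo) {
    warning("rescale01: constant raster, returning all zeros")
    out <- v; out[fin] <- 0
    return(likeRaster(raster, out))
  }
  out <- (v - lo) / (hi - lo)
  if (invert) out <- 1 - out
  likeRaster(raster, out)
}
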