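#' Generate a synthetic fragmented-forest landscape
#'
#' Builds a co-registered bundle of layers with the statistical structure the
#' downstream analysis assumes: spatially autocorrelated continuous
#' predictors (Gaussian-smoothed white noise), a categorical land-cover map
#' whose forest is laid out as many small and few large fragments, a
#' protected subset of the large fragments, straight road and watercourse
#' transects, a human-modification layer in \[0, 1\] blending road proximity
#' with agropastoral density, and a one-cell riparian permanent-preservation
#' (APP) buffer around watercourses. All randomness comes from one seeded
#' stream, so equal seeds give byte-identical bundles.
#'
#' @param seed integer seed; the determinism contract is per-seed.
#' @param shape integer c(rows, cols), at least 20 x 20.
#' @param cellSize cell edge in meters.
#' @param forestFraction target forest cover fraction in (0, 1); the
#'   realized forest cell count is exact.
#' @param nFragments number of forest fragment seeds; fragment target sizes
#'   are drawn from a right-skewed (lognormal) distribution so most
#'   fragments are small and a few are large.
#' @param autocorrRange Gaussian smoothing radius of the continuous
#'   predictor fields, in cells.
#' @return A [LandscapeBundle-class].
#' @export
makeLandscape <- function(seed, shape = c(100, 100), cellSize = 1000,
                          forestFraction = 0.12, nFragments = 30,
                          autocorrRange = 5) {
  stopifnot(length(shape) == 2, all(shape >= 20),
            forestFraction > 0, forestFraction < 1, nFragments >= 1)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  target <- round(forestFraction * nr * nc)
  if (target < nFragments)
    stop("infeasible: forestFraction gives fewer forest cells (", target,
         ") than nFragments (", nFragments, ")")
  withr::with_seed(as.integer(seed), {
    smoothField <- function() {
      z <- matrix(rnorm(nr * nc), nr, nc)
      as.matrix(EBImage::gblur(z, sigma = autocorrRange))
    }
    lab <- growForest(nr, nc, target, nFragments)
    forest <- lab > 0

    # linear transects: roads (2-3) and watercourses (1-2), edge to edge
    drawTransects <- function(k) {
      m <- matrix(FALSE, nr, nc)
      for (i in seq_len(k)) {
        if (runif(1) < 0.5) {
          pts <- rasterLine(sample(nr, 1), 1, sample(nr, 1), nc)
        } else {
          pts <- rasterLine(1, sample(nc, 1), nr, sample(nc, 1))
        }
        m[cbind(pts[, 1], pts[, 2])] <- TRUE
      }
      m
    }
    roads <- drawTransects(sample(2:3, 1))
    waterL <- drawTransects(sample(1:2, 1))

    codes <- landcoverCodes()
    lc <- matrix(codes[["agropastoral"]], nr, nc)
    nonvegNoise <- smoothField()
    lc[nonvegNoise > quantile(nonvegNoise, 0.95)] <- codes[["nonveg"]]
    lc[waterL] <- codes[["water"]]
    lc[roads] <- codes[["nonveg"]]
    lc[forest] <- codes[["forest"]]

    # protected: a few mid-sized reserves covering a small share of the
    # landscape (protection is sparse in heavily deforested regions)
    counts <- tabulate(lab[lab > 0])
    cap <- max(4, floor(0.04 * nr * nc))
    eligible <- which(counts >= 2 & counts <= floor(cap / 2))
    protIds <- if (length(eligible))
      sort(sample(eligible, min(3L, length(eligible)))) else
        which.min(abs(counts - cap / 2))
    protected <- matrix(lab %in% protIds, nr, nc)

    base <- gridRaster(matrix(0, nr, nc), cellSize = cellSize,
                       origin = c(0, nr * cellSize), crsTag = "local-meters")
    mk <- function(m) likeRaster(base, m)

    agro <- windowFraction(mk(lc == codes[["agropastoral"]]), 5)@values / 100
    distRoad <- euclideanDistance(mk(roads))
    ghm <- clamp(0.5 * rescale01(distRoad, invert = TRUE)@values +
                   0.5 * agro, 0, 1)

    treeCover <- clamp(30 * pnorm(smoothField()) + 65 * forest +
                         5 * pnorm(smoothField()), 0, 100)
    elevation <- 600 + 250 * scale01m(smoothField(), -1, 1) * 2
    tempRange <- 12 + 4 * scale01m(smoothField(), -1, 1)
    percOldForest <- windowFraction(mk(forest), 5)@values
    percAgropastoral <- 100 * agro

    new("LandscapeBundle",
        predictors = list(
          treeCover = mk(treeCover), elevation = mk(elevation),
          tempRange = mk(tempRange), percOldForest = mk(percOldForest),
          percAgropastoral = mk(percAgropastoral)),
        landcover = mk(lc), protected = mk(protected), roads = mk(roads),
        waterLines = mk(waterL), ghm = mk(ghm),
        appRiparian = mk(dilate1(waterL + 0)),
        seed = as.integer(seed),
        params = list(shape = c(nr, nc), cellSize = cellSize,
                      forestFraction = forestFraction,
                      nFragments = nFragments,
                      autocorrRange = autocorrRange))
  })
}

scale01m <- function(m, lo, hi) {
  r <- range(m)
  if (r[1] == r[2]) return(matrix(lo, nrow(m), ncol(m)))
  lo + (hi - lo) * (m - r[1]) / (r[2] - r[1])
}

# Seeded multi-fragment region growing with an exact total cell count.
# Fragments avoid touching each other while growing (no 8-adjacency to a
# different fragment), so the seeded count survives; if growth stalls, the
# remainder is filled by relaxed growth that may merge fragments.
growForest <- function(nr, nc, target, nFragments) {
  lab <- matrix(0L, nr, nc)
  minSep <- max(3L, floor(sqrt(nr * nc / nFragments) / 2))
  seeds <- matrix(integer(), 0, 2)
  tries <- 0L
  while (nrow(seeds) < nFragments) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("infeasible: cannot place ", nFragments,
           " fragment seeds at separation ", minSep)
    r <- sample(2:(nr - 1), 1); c <- sample(2:(nc - 1), 1)
    if (nrow(seeds) == 0 ||
        min(pmax(abs(seeds[, 1] - r), abs(seeds[, 2] - c))) >= minSep)
      seeds <- rbind(seeds, c(r, c))
  }
  # right-skewed size targets summing exactly to `target`
  u <- sort(exp(rnorm(nFragments, 0, 1.2)), decreasing = TRUE)
  sizes <- pmax(1L, floor(u / sum(u) * target))
  sizes[1L] <- sizes[1L] + (target - sum(sizes))
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  neighbors <- function(idx) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    rr <- rep(r, each = 8) + offs[, 1]; cc <- rep(c, each = 8) + offs[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    unique((cc[ok] - 1L) * nr + rr[ok])
  }
  for (f in seq_len(nFragments)) {
    idx0 <- (seeds[f, 2] - 1L) * nr + seeds[f, 1]
    if (lab[idx0] != 0L) next
    lab[idx0] <- f
    need <- sizes[f] - 1L
    frontier <- neighbors(idx0)
    while (need > 0L) {
      frontier <- frontier[lab[frontier] == 0L]
      # keep the fragment isolated: no frontier cell adjacent to another one
      if (length(frontier)) {
        keep <- vapply(frontier, function(i) {
          nb <- lab[neighbors(i)]
          all(nb %in% c(0L, f))
        }, logical(1))
        frontier <- frontier[keep]
      }
      if (!length(frontier)) break
      add <- if (length(frontier) <= need) frontier
             else sample(frontier, need)
      lab[add] <- f
      need <- need - length(add)
      frontier <- unique(c(frontier[!frontier %in% add],
                           unlist(lapply(add, neighbors))))
    }
  }
  # relaxed fill to hit the exact target (may merge fragments)
  deficit <- target - sum(lab > 0)
  while (deficit > 0L) {
    occ <- which(lab > 0L)
    front <- setdiff(unique(unlist(lapply(occ, neighbors))), occ)
    front <- front[lab[front] == 0L]
    if (!length(front)) break
    add <- if (length(front) <= deficit) front else sample(front, deficit)
    # inherit the label of an arbitrary occupied neighbour
    for (i in add) {
      nb <- lab[neighbors(i)]
      lab[i] <- nb[nb > 0L][1L]
    }
    deficit <- deficit - length(add)
  }
  lab
}

#' Accessors for LandscapeBundle layers
#'
#' @param x a [LandscapeBundle-class].
#' @return The requested layer(s).
#' @export
predictors <- function(x) x@predictors
#' @rdname predictors
#' @export
landcover <- function(x) x@landcover
#' @rdname predictors
#' @export
protectedMask <- function(x) x@protected
#' @rdname predictors
#' @export
ghmLayer <- function(x) x@ghm
#' @rdname predictors
#' @export
forestMask <- function(x) {
  likeRaster(x@landcover,
             x@landcover@values == landcoverCodes()[["forest"]])
}

setMethod("show", "LandscapeBundle", function(object) {
  d <- dim(object@landcover@values)
  nF <- sum(object@landcover@values == landcoverCodes()[["forest"]])
  cat(sprintf("LandscapeBundle  %d x %d cells (%.0f m), %.1f%% forest\n",
              d[1], d[2], object@landcover@cellSize, 100 * nF / prod(d)))
  cat("  predictors:", paste(names(object@predictors), collapse = ", "), "\n")
})

#' Simulate a virtual taxon with known suitability truth
#'
#' True habitat suitability is a logistic function of standardized landscape
#' predictors; presences are sampled without replacement with probability
#' proportional to suitability, restricted to vegetated (forest or
#' agropastoral) cells. Generated records pass the occurrence-cleaning
#' filters by construction: years 1946-2020, counts 1-10, coordinate
#' precision at most 1000 m. Optionally injects "dirty" records for testing
#' the cleaning stage.
#'
#' @param landscape a [LandscapeBundle-class].
#' @param responseSpec list with `intercept` (default 0) and named `coefs`
#'   on standardized predictors, e.g. `list(coefs = c(treeCover = 2))`.
#' @param nPresences number of presence records to draw.
#' @param status conservation status: DD, VU, EN or CR.
#' @param seed integer seed (one stream for all draws).
#' @param name taxon name.
#' @param dirty optional named list of dirty-record counts to inject:
#'   `noCoords`, `oldYear`, `zeroCount`, `coarsePrecision`, `offGrid`.
#' @return A [VirtualTaxon-class].
#' @export
makeVirtualTaxon <- function(landscape, responseSpec, nPresences,
                             status = "VU", seed = 1,
                             name = "virtual_taxon", dirty = NULL) {
  coefs <- responseSpec$coefs
  stopifnot(!is.null(coefs), !is.null(names(coefs)))
  missing <- setdiff(names(coefs), names(landscape@predictors))
  if (length(missing))
    stop("responseSpec names unknown predictor(s): ",
         paste(missing, collapse = ", "))
  suit <- trueSuitabilityRaster(landscape, responseSpec)
  lc <- landscape@landcover@values
  codes <- landcoverCodes()
  vegetated <- lc %in% c(codes[["forest"]], codes[["agropastoral"]])
  eligible <- which(vegetated & is.finite(suit@values) & suit@values > 0)
  if (nPresences > length(eligible))
    stop("nPresences (", nPresences, ") exceeds eligible cells (",
         length(eligible), ")")
  withr::with_seed(as.integer(seed), {
    occ <- if (nPresences > 0) {
      cells <- sample(eligible, nPresences, prob = suit@values[eligible])
      xy <- cellXY(suit, cells)
      data.frame(taxon = name, x = xy$x, y = xy$y,
                 year = sample(1946:2020, nPresences, replace = TRUE),
                 count = sample(1:10, nPresences, replace = TRUE),
                 precision_m = sample(c(10, 30, 100, 250, 500, 1000),
                                      nPresences, replace = TRUE))
    } else {
      data.frame(taxon = character(), x = numeric(), y = numeric(),
                 year = integer(), count = numeric(), precision_m = numeric())
    }
    if (!is.null(dirty)) occ <- rbind(occ, dirtyRecords(landscape, name, dirty))
  })
  new("VirtualTaxon", name = name, trueSuitability = suit,
      responseSpec = c(list(intercept = responseSpec$intercept %||% 0),
                       list(coefs = coefs)),
      status = status, occurrences = occ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recompute a virtual taxon's true suitability from its response spec
#'
#' @param landscape a [LandscapeBundle-class].
#' @param responseSpec as in [makeVirtualTaxon()].
#' @return A [GridRaster-class] in \[0, 1\].
#' @export
trueSuitabilityRaster <- function(landscape, responseSpec) {
  coefs <- responseSpec$coefs
  eta <- matrix(responseSpec$intercept %||% 0,
                nrow(landscape@landcover@values),
                ncol(landscape@landcover@values))
  for (nm in names(coefs)) {
    v <- landscape@predictors[[nm]]@values
    z <- (v - mean(v[is.finite(v)])) / sd(v[is.finite(v)])
    eta <- eta + coefs[[nm]] * z
  }
  likeRaster(landscape@landcover, plogis(eta))
}

dirtyRecords <- function(landscape, name, dirty) {
  ext <- dim(landscape@landcover@values) * landscape@landcover@cellSize
  xmax <- landscape@landcover@origin[1] + ext[2]
  ymax <- landscape@landcover@origin[2]
  rnd <- function(n) data.frame(
    taxon = name,
    x = runif(n, landscape@landcover@origin[1], xmax),
    y = runif(n, ymax - ext[1], ymax),
    year = sample(1950:2020, n, replace = TRUE),
    count = sample(1:10, n, replace = TRUE),
    precision_m = 100)
  out <- list()
  if (!is.null(dirty$noCoords) && dirty$noCoords > 0) {
    d <- rnd(dirty$noCoords); d$x <- NA_real_; d$y <- NA_real_
    out <- c(out, list(d))
  }
  if (!is.null(dirty$oldYear) && dirty$oldYear > 0) {
    d <- rnd(dirty$oldYear); d$year <- 1900L
    out <- c(out, list(d))
  }
  if (!is.null(dirty$zeroCount) && dirty$zeroCount > 0) {
    d <- rnd(dirty$zeroCount); d$count <- 0
    out <- c(out, list(d))
  }
  if (!is.null(dirty$coarsePrecision) && dirty$coarsePrecision > 0) {
    d <- rnd(dirty$coarsePrecision); d$precision_m <- 5000
    out <- c(out, list(d))
  }
  if (!is.null(dirty$offGrid) && dirty$offGrid > 0) {
    d <- rnd(dirty$offGrid); d$x <- xmax + 10 * landscape@landcover@cellSize
    out <- c(out, list(d))
  }
  do.call(rbind, out)
}

setMethod("show", "VirtualTaxon", function(object) {
  cat(sprintf("VirtualTaxon '%s' [%s]  %d occurrence records\n",
              object@name, object@status, nrow(object@occurrences)))
})

#' Export a landscape bundle to plain files
#'
#' Writes one ASCII-grid raster per layer plus a YAML manifest listing the
#' layers and the generator seed; occurrence tables of accompanying taxa are
#' written as CSV.
#'
#' @param landscape a [LandscapeBundle-class].
#' @param dir output directory (created if needed).
#' @param taxa optional list of [VirtualTaxon-class] to export alongside.
#' @return The manifest path, invisibly.
#' @export
exportLandscape <- function(landscape, dir, taxa = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layers <- c(landscape@predictors,
              list(landcover = landscape@landcover,
                   protected = landscape@protected, roads = landscape@roads,
                   water_lines = landscape@waterLines, ghm = landscape@ghm,
                   app_riparian = landscape@appRiparian))
  for (nm in names(layers))
    writeRaster(layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  if (length(taxa)) {
    occ <- do.call(rbind, lapply(taxa, function(t) t@occurrences))
    write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  }
  manifest <- list(layers = paste0(names(layers), ".asc"),
                   seed = landscape@seed, params = landscape@params,
                   taxa = vapply(taxa, function(t) t@name, character(1)))
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
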