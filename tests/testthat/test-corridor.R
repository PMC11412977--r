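rankFromMatrix <- function(m) {
  # build a PriorityRank whose rank raster is exactly m (tests only need it
  # for mean-rank extraction)
  new("PriorityRank", rank = gridRaster(m, cellSize = 1000),
      removalOrder = integer(), curves = data.frame())
}

test_that("CPF extraction applies both strict thresholds", {
  forest <- matrix(0, 5, 8)
  forest[2, 1:2] <- 1      # fragment 1: 2 km2
  forest[4, 4:5] <- 1      # fragment 2: 2 km2
  forest[1, 8] <- 1        # fragment 3: 1 km2 (too small)
  fm <- labelFragments(gridRaster(forest, cellSize = 1000))
  rk <- matrix(0.5, 5, 8)
  rk[2, 1:2] <- 0.96       # passes both
  rk[4, 4:5] <- 0.90       # rank too low
  rk[1, 8] <- 0.99         # area too small
  cpfs <- extractCpfs(rankFromMatrix(rk), fm)
  expect_equal(nrow(cpfs), 1)
  expect_equal(cpfs$areaKm2, 2)
  expect_equal(cpfs$meanRank, 0.96)
  # boundary: area exactly 1 km2 or mean rank exactly 0.95 is excluded
  rk[4, 4:5] <- 0.95
  expect_equal(nrow(extractCpfs(rankFromMatrix(rk), fm)), 1)
})

test_that("landscape resistance is the mean of its five quoted layers", {
  codes <- landcoverCodes()
  # 1x4 strip: [forest+APP, pasture+APP, pasture, road]
  lc <- matrix(c(codes[["forest"]], codes[["agropastoral"]],
                 codes[["agropastoral"]], codes[["nonveg"]]), 1, 4)
  tree <- matrix(c(100, 0, 20, 0), 1, 4)
  roads <- matrix(c(0, 0, 0, 1), 1, 4)
  app <- matrix(c(1, 1, 0, 0), 1, 4)
  b <- handBundle(lc, treeCoverM = tree, roadsM = roads, appM = app)
  r <- landscapeResistance(b)
  comp <- attr(r, "components")
  # forested APP cell: only the APP-restoration layer resists
  expect_equal(values(r)[1, 1], mean(c(0, 0, 0, 1, 0)))
  # unforested APP cell in pasture, treeCover 0, max distance class:
  d <- values(comp$distForest)[1, 2]
  expect_equal(values(r)[1, 2], mean(c(1, 1, d, 0, 0)))
  # all component layers stay in [0, 1]
  for (cm in comp)
    expect_true(all(values(cm) >= 0 & values(cm) <= 1))
  expect_equal(values(r),
               Reduce(`+`, lapply(comp, values)) / 5)
})

test_that("taxon resistance reflects suitability between its extremes", {
  hs <- gridRaster(matrix(c(0.2, 0.5, 0.9), 1, 3), cellSize = 1000)
  r <- taxonResistance(list(hs))
  expect_equal(as.vector(values(r)), 1.1 - c(0.2, 0.5, 0.9))
  # endpoints swap: argmax -> min, argmin -> max
  expect_equal(values(r)[1, 3], 0.2)
  expect_equal(values(r)[1, 1], 0.9)
  # binary-like layer: r = 1 - hs
  hb <- gridRaster(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(values(taxonResistance(list(hb))), 1 - values(hb))
  # constant layer is an identity with a warning
  expect_warning(rc <- taxonResistance(list(gridRaster(matrix(0.4, 2, 2)))),
                 "constant")
  expect_equal(values(rc), matrix(0.4, 2, 2))
  # averaging across taxa
  r2 <- taxonResistance(list(hs, hs))
  expect_equal(values(r2), values(r))
})

test_that("final resistance is exactly the two-layer mean", {
  a <- gridRaster(matrix(0.2, 2, 2)); b <- gridRaster(matrix(0.6, 2, 2))
  rs <- finalResistance(a, b)
  expect_equal(values(finalLayer(rs)), matrix(0.4, 2, 2))
  expect_true(validObject(rs))
  same <- finalResistance(a, a)
  expect_equal(values(finalLayer(same)), values(a))
  # bounded by the cellwise envelope of the inputs
  set.seed(3)
  x <- gridRaster(matrix(runif(25), 5, 5)); y <- gridRaster(matrix(runif(25), 5, 5))
  f <- values(finalLayer(finalResistance(x, y)))
  expect_true(all(f >= pmin(values(x), values(y)) - 1e-12))
  expect_true(all(f <= pmax(values(x), values(y)) + 1e-12))
})

test_that("cost distance matches closed forms on uniform surfaces", {
  r1 <- gridRaster(matrix(1, 1, 3), cellSize = 1000)
  cd <- costDistance(r1, sources = 1L)
  expect_equal(as.vector(values(cd$cwd)), c(0, 1000, 2000))
  # uniform resistance r: cwd = r x geometric path length, any target
  for (rr in c(0.33, 0.74)) {
    ru <- gridRaster(matrix(rr, 4, 4), cellSize = 1000)
    cd2 <- costDistance(ru, sources = 1L)
    ru1 <- gridRaster(matrix(1, 4, 4), cellSize = 1000)
    cd1 <- costDistance(ru1, sources = 1L)
    expect_equal(values(cd2$cwd), rr * values(cd1$cwd), tolerance = 1e-12)
  }
  expect_error(costDistance(gridRaster(matrix(-1, 2, 2)), 1L), "negative")
  expect_error(costDistance(r1, integer()), "empty source")
})

test_that("cost distance agrees with the igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(36, 0.05, 1), 6, 6)
    src <- sample(36, sample(1:3, 1))
    cd <- costDistance(gridRaster(m, cellSize = 1000), src)
    expect_equal(as.vector(values(cd$cwd)), igraphCwd(m, 1000, src),
                 tolerance = 1e-9)
  }
})

test_that("cost distance agrees with exhaustive simple-path search", {
  set.seed(22)
  for (i in 1:5) {
    m <- matrix(runif(16, 0.05, 1), 4, 4)
    src <- sample(16, 1)
    cd <- costDistance(gridRaster(m, cellSize = 1000), src)
    expect_equal(as.vector(values(cd$cwd)), enumerateCwd(m, 1000, src),
                 tolerance = 1e-9)
  }
})

test_that("backlinks reconstruct least-cost paths through cheap channels", {
  # zero-resistance channel in row 2 flanked by resistance-1 rows
  m <- matrix(1, 3, 6); m[2, ] <- 0
  r <- gridRaster(m, cellSize = 1000)
  cd <- costDistance(r, sources = cellIndex(r, 2, 1))
  target <- cellIndex(r, 2, 6)
  path <- prioconn:::tracePath(target, cd$backlinks)
  rc <- cellRowCol(r, path)
  expect_true(all(rc$row == 2))                  # stays in the channel
  expect_equal(values(cd$cwd)[2, 6], 0)
  # raising any cell's resistance never decreases any cwd
  m2 <- m; m2[2, 3] <- 0.5
  cd2 <- costDistance(gridRaster(m2, cellSize = 1000), cellIndex(r, 2, 1))
  expect_true(all(values(cd2$cwd) >= values(cd$cwd) - 1e-12))
})

test_that("nodata resistance blocks movement", {
  m <- matrix(1, 3, 3); m[, 2] <- NA   # impassable wall
  cd <- costDistance(gridRaster(m, cellSize = 1000), sources = 1L)
  expect_true(all(is.infinite(values(cd$cwd)[, 3])))
})

test_that("corridors on uniform surfaces have ratio = resistance", {
  forest <- matrix(0, 5, 9); forest[3, 1:2] <- 1; forest[3, 8:9] <- 1
  fm <- labelFragments(gridRaster(forest, cellSize = 1000))
  rk <- matrix(0.99, 5, 9)
  cpfs <- extractCpfs(rankFromMatrix(rk), fm)
  expect_equal(nrow(cpfs), 2)
  for (rr in c(0.33, 0.54, 0.74)) {
    cor <- planCorridors(cpfs, gridRaster(matrix(rr, 5, 9), cellSize = 1000))
    expect_equal(nrow(cor), 1)
    expect_equal(cor$ratio, rr, tolerance = 1e-9)
    expect_equal(cor$cwd, cor$cl * rr, tolerance = 1e-6)
  }
})

test_that("three collinear fragments yield two allocation-adjacent corridors", {
  forest <- matrix(0, 1, 11)
  forest[1, c(1, 6, 11)] <- 1
  fm <- labelFragments(gridRaster(forest, cellSize = 1000))
  cpfs <- extractCpfs(rankFromMatrix(matrix(0.99, 1, 11)), fm,
                      minAreaKm2 = 0.5)
  expect_equal(nrow(cpfs), 3)
  cors <- planCorridors(cpfs, gridRaster(matrix(0.5, 1, 11), cellSize = 1000))
  expect_equal(nrow(cors), 2)                    # ends only reach the middle
  expect_true(all(cors$cpfA != cors$cpfB))
  pairs <- paste(cors$cpfA, cors$cpfB)
  expect_false("1 3" %in% pairs)
  # all-pairs mode links everything
  all3 <- planCorridors(cpfs, gridRaster(matrix(0.5, 1, 11), cellSize = 1000),
                        allPairs = TRUE)
  expect_equal(nrow(all3), 3)
})

test_that("corridor endpoints lie in their fragments and cwd is symmetric", {
  set.seed(23)
  m <- matrix(runif(11 * 11, 0.1, 1), 11, 11)
  forest <- matrix(0, 11, 11)
  forest[2:3, 2:3] <- 1; forest[9:10, 8:10] <- 1
  r <- gridRaster(m, cellSize = 1000)
  fm <- labelFragments(gridRaster(forest, cellSize = 1000))
  cpfs <- extractCpfs(rankFromMatrix(matrix(0.99, 11, 11)), fm)
  cors <- planCorridors(cpfs, r)
  expect_equal(nrow(cors), 1)
  path <- attr(cors, "paths")[[1]]
  cellsA <- attr(cpfs, "cellList")[[1]]; cellsB <- attr(cpfs, "cellList")[[2]]
  expect_true(path[1] %in% c(cellsA, cellsB))
  expect_true(path[length(path)] %in% c(cellsA, cellsB))
  # geometric length bounds: at least the straight-line endpoint distance
  xy <- cellXY(r, c(path[1], path[length(path)]))
  straight <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  expect_gte(cors$cl, straight - 1e-9)
  # cwd symmetric under endpoint swap
  cpfsRev <- cpfs[2:1, ]
  attr(cpfsRev, "cellList") <- attr(cpfs, "cellList")[2:1]
  corsRev <- planCorridors(cpfsRev, r)
  expect_equal(corsRev$cwd, cors$cwd, tolerance = 1e-9)
  # ratio equals the resistance-weighted mean along the path
  expect_lte(cors$ratio, max(m)); expect_gte(cors$ratio, min(m))
})

test_that("unreachable fragment pairs are flagged, not fatal", {
  m <- matrix(1, 3, 7); m[, 4] <- NA
  forest <- matrix(0, 3, 7); forest[2, 1:2] <- 1; forest[2, 6:7] <- 1
  fm <- labelFragments(gridRaster(forest, cellSize = 1000))
  cpfs <- extractCpfs(rankFromMatrix(matrix(0.99, 3, 7)), fm)
  cors <- planCorridors(cpfs, gridRaster(m, cellSize = 1000), allPairs = TRUE)
  expect_equal(nrow(cors), 1)
  expect_false(cors$reachable)
  expect_true(is.na(cors$cwd))
  expect_error(planCorridors(cpfs[1, ], gridRaster(m)), "at least two")
})
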