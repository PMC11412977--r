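qcGrid <- function() {
  # 10x10 km grid; row 10 (south) is non-vegetated, col 10 is water
  codes <- landcoverCodes()
  lc <- matrix(codes[["forest"]], 10, 10)
  lc[10, ] <- codes[["nonveg"]]
  lc[, 10] <- codes[["water"]]
  gridRaster(lc, cellSize = 1000, origin = c(0, 10000))
}

rec <- function(x, y, year = 2000, count = 1, precision_m = 100) {
  n <- length(x)
  data.frame(taxon = rep("t", n), x = x, y = y,
             year = rep(year, length.out = n),
             count = rep(count, length.out = n),
             precision_m = rep(precision_m, length.out = n))
}

test_that("cleaning boundaries are strict as specified", {
  sa <- likeRaster(qcGrid(), 1)
  runOne <- function(r) filterRecords(r, sa, qcGrid())
  # year: before 1945 removed, 1945 kept
  expect_equal(auditTrail(runOne(rec(500, 5500, year = 1944)))$reason, "year")
  expect_equal(nrow(keptRecords(runOne(rec(500, 5500, year = 1945)))), 1)
  # counts: [1, 99] kept inclusive
  expect_equal(auditTrail(runOne(rec(500, 5500, count = 0)))$reason, "count_range")
  expect_equal(nrow(keptRecords(runOne(rec(500, 5500, count = 99)))), 1)
  expect_equal(auditTrail(runOne(rec(500, 5500, count = 100)))$reason, "count_range")
  # precision: > 1000 m removed, exactly 1000 kept
  expect_equal(auditTrail(runOne(rec(500, 5500, precision_m = 1001)))$reason,
               "precision")
  expect_equal(nrow(keptRecords(runOne(rec(500, 5500, precision_m = 1000)))), 1)
})

test_that("each removed record carries the first-triggered reason", {
  sa <- likeRaster(qcGrid(), 1)
  # record that violates no_coords AND year -> no_coords wins
  r1 <- rec(NA, NA, year = 1900)
  # off-grid AND bad count -> outside_area wins
  r2 <- rec(-5000, 500, count = 0)
  # non-vegetated (southern row) AND old year -> nonvegetated wins
  r3 <- rec(500, 500 * 1, year = 1900); r3$y <- 500  # row 10 is y in [0,1000)
  # coarse precision AND old year -> precision wins
  r4 <- rec(500, 5500, year = 1900, precision_m = 5000)
  out <- filterRecords(rbind(r1, r2, r3, r4), sa, qcGrid())
  expect_equal(auditTrail(out)$reason,
               c("no_coords", "outside_area", "nonvegetated", "precision"))
})

test_that("study-area, water and exclusion-zone rules remove records", {
  sa <- likeRaster(qcGrid(), 1)
  v <- values(sa); v[, 1] <- 0
  saMasked <- likeRaster(sa, v)   # west column outside study area
  out <- filterRecords(rbind(
    rec(500, 5500),      # in masked column -> outside_area
    rec(9500, 5500),     # water column -> nonvegetated
    rec(5500, 5500)), saMasked, qcGrid())
  expect_equal(auditTrail(out)$reason, c("outside_area", "nonvegetated"))
  expect_equal(nrow(keptRecords(out)), 1)

  # exclusion point removes records within one cell (8-neighborhood)
  out2 <- filterRecords(rbind(rec(4500, 4500), rec(5500, 5500),
                              rec(7500, 7500)),
                        sa, qcGrid(),
                        exclusionPoints = data.frame(x = 5500, y = 5500))
  expect_equal(auditTrail(out2)$reason, c("exclusion_zone", "exclusion_zone"))
  expect_equal(keptRecords(out2)$x, 7500)
})

test_that("distance outliers are flagged by the median-distance rule", {
  sa <- likeRaster(qcGrid(), 1)
  cluster <- rec(c(4500, 5500, 4500, 5500, 4600), c(4500, 4500, 5500, 5500, 4600))
  # a tight cluster has no outliers
  out0 <- filterRecords(cluster, sa, qcGrid())
  expect_equal(nrow(auditTrail(out0)), 0)
  # the same cluster plus one very remote point: remote point flagged
  far <- rec(500, 9500)
  out <- filterRecords(rbind(cluster, far), sa, qcGrid())
  expect_equal(auditTrail(out)$reason, "outlier")
  expect_equal(auditTrail(out)$x, 500)
})

test_that("empty input yields an empty set without error", {
  sa <- likeRaster(qcGrid(), 1)
  out <- filterRecords(rec(numeric(), numeric()), sa, qcGrid())
  expect_equal(nrow(keptRecords(out)), 0)
  expect_equal(nrow(auditTrail(out)), 0)
  expect_error(filterRecords(data.frame(x = 1, y = 1), sa, qcGrid()),
               "year")
})

test_that("thinning keeps the most recent record within the buffer", {
  sa <- likeRaster(qcGrid(), 1)
  mkset <- function(df) filterRecords(df, sa, qcGrid())
  # 500 m apart: only the 2010 record survives
  two <- mkset(rec(c(4500, 5000), c(4500, 4500), year = c(1990, 2010)))
  th <- thinSpatial(two)
  expect_equal(keptRecords(th)$year, 2010)
  expect_equal(auditTrail(th)$reason, "thinned")
  # exactly 1000 m apart: both kept (strictly-within deletion)
  pair <- mkset(rec(c(4500, 5500), c(4500, 4500), year = c(1990, 2010)))
  expect_equal(nrow(keptRecords(thinSpatial(pair))), 2)
  # 999 vs 1001 m boundaries
  near <- mkset(rec(c(4500, 4500 + 999), c(4500, 4500), year = c(1990, 2010)))
  expect_equal(nrow(keptRecords(thinSpatial(near))), 1)
  far <- mkset(rec(c(4500, 4500 + 1001), c(4500, 4500), year = c(1990, 2010)))
  expect_equal(nrow(keptRecords(thinSpatial(far))), 2)
  # three mutually conflicting records: only the most recent survives
  three <- mkset(rec(c(4500, 4900, 4700), c(4500, 4500, 4800),
                     year = c(2000, 2005, 2010)))
  expect_equal(keptRecords(thinSpatial(three))$year, 2010)
})

test_that("exact duplicates collapse to the most recent copy", {
  sa <- likeRaster(qcGrid(), 1)
  dup <- filterRecords(rec(c(4500, 4500), c(4500, 4500), year = c(1990, 2010)),
                       sa, qcGrid())
  th <- thinSpatial(dup)
  expect_equal(nrow(keptRecords(th)), 1)
  expect_equal(keptRecords(th)$year, 2010)
  expect_equal(auditTrail(th)$reason, "duplicate")
})

test_that("thinning is idempotent and audit-conserving", {
  land <- smallLandscape()
  tx <- makeVirtualTaxon(land, list(coefs = c(treeCover = 2)), 100, seed = 11,
                         dirty = list(oldYear = 5, coarsePrecision = 3))
  s0 <- filterRecords(tx@occurrences, allOnes(land), landcover(land))
  s1 <- thinSpatial(s0)
  s2 <- thinSpatial(s1)
  expect_identical(keptRecords(s2)[, c("x", "y", "year")],
                   keptRecords(s1)[, c("x", "y", "year")])
  expect_equal(nrow(keptRecords(s1)) + nrow(auditTrail(s1)),
               nrow(tx@occurrences))
})

test_that("kept set ignores input row order when years are distinct", {
  sa <- likeRaster(qcGrid(), 1)
  df <- rec(c(1500, 2200, 5500, 5900, 8500),
            c(1500, 1500, 5500, 5700, 2500),
            year = c(1990, 2005, 1980, 2012, 1999))
  key <- function(d) {
    k <- keptRecords(d)[, c("x", "y", "year")]
    k[order(k$x, k$y), ]
  }
  a <- thinSpatial(filterRecords(df, sa, qcGrid()))
  set.seed(2)
  for (i in 1:5) {
    b <- thinSpatial(filterRecords(df[sample(nrow(df)), ], sa, qcGrid()))
    expect_equal(key(b), key(a), ignore_attr = TRUE)
  }
})

test_that("taxon screening keeps >= 5 records, boundary inclusive", {
  mk <- function(n) new("OccurrenceSet", taxon = paste0("t", n),
                        records = rec(seq_len(n) * 2000, rep(500, n)),
                        audit = data.frame())
  out <- screenTaxa(list(mk(4), mk(5), mk(20)))
  expect_equal(length(out$included), 2)
  expect_equal(length(out$excluded), 1)
  # 34 taxa of which 4 are sparse -> 30 retained
  sets <- c(lapply(5:34, function(i) mk(5 + i)), lapply(1:4, function(i) mk(4)))
  out2 <- screenTaxa(sets)
  expect_equal(length(out2$included), 30)
  empty <- screenTaxa(list())
  expect_equal(length(empty$included), 0)
  expect_equal(length(empty$excluded), 0)
})
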