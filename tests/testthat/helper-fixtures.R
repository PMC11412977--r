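# Shared fixtures, built in code at test time.

gr <- function(m, cellSize = 1000, ...) gridRaster(m, cellSize = cellSize, ...)

# hand-assembled landscape bundle with fully controlled layers
handBundle <- function(landcoverM, treeCoverM = NULL, roadsM = NULL,
                       waterM = NULL, protectedM = NULL, appM = NULL,
                       ghmM = NULL, cellSize = 1000,
                       extraPredictors = list()) {
  nr <- nrow(landcoverM); nc <- ncol(landcoverM)
  z <- matrix(0, nr, nc)
  base <- gridRaster(z, cellSize = cellSize, origin = c(0, nr * cellSize))
  mk <- function(m) if (is.null(m)) likeRaster(base, z) else likeRaster(base, m)
  preds <- c(list(
    treeCover = mk(if (is.null(treeCoverM))
      (landcoverM == landcoverCodes()[["forest"]]) * 90 else treeCoverM)),
    lapply(extraPredictors, mk))
  methods::new("LandscapeBundle",
    predictors = preds, landcover = mk(landcoverM),
    protected = mk(protectedM), roads = mk(roadsM), waterLines = mk(waterM),
    ghm = mk(ghmM), appRiparian = mk(appM),
    seed = NA_integer_, params = list())
}

# small cached landscape + virtual taxon shared across SDM-ish tests
fixtureEnv <- new.env()

smallLandscape <- function() {
  if (is.null(fixtureEnv$land))
    fixtureEnv$land <- makeLandscape(42, shape = c(40, 40),
                                     forestFraction = 0.2, nFragments = 10,
                                     autocorrRange = 3)
  fixtureEnv$land
}

smallTaxon <- function() {
  if (is.null(fixtureEnv$taxon))
    fixtureEnv$taxon <- makeVirtualTaxon(
      smallLandscape(), list(coefs = c(elevation = 4)),
      nPresences = 120, status = "EN", seed = 7, name = "fixture_taxon")
  fixtureEnv$taxon
}

allOnes <- function(landscape) likeRaster(landcover(landscape), 1)

cleanedFixtureOccs <- function() {
  if (is.null(fixtureEnv$occ)) {
    land <- smallLandscape()
    fixtureEnv$occ <- thinSpatial(filterRecords(
      smallTaxon()@occurrences, allOnes(land), landcover(land)))
  }
  fixtureEnv$occ
}

# brute-force nearest-TRUE-cell distance (independent oracle)
bruteDistance <- function(mask) {
  v <- mask@values
  idx <- which(is.finite(v) & v != 0)
  stopifnot(length(idx) > 0)
  xy <- cellXY(mask, seq_along(v))
  tx <- xy$x[idx]; ty <- xy$y[idx]
  d <- vapply(seq_along(v), function(i)
    sqrt(min((tx - xy$x[i])^2 + (ty - xy$y[i])^2)), numeric(1))
  likeRaster(mask, matrix(d, nrow(v)))
}

# naive core-area-zonation ranking that recomputes every marginal loss from
# scratch each iteration (independent oracle for cazRank)
naiveCaz <- function(valueList, weights, maskM = NULL) {
  A <- sapply(valueList, as.vector)
  A <- matrix(A, ncol = length(valueList))
  n <- nrow(A)
  nr <- nrow(valueList[[1]])
  nc <- ncol(valueList[[1]])
  lev <- if (is.null(maskM)) rep(1, n) else as.vector(maskM)
  rowMajor <- function(cell) ((cell - 1) %% nr) * nc + (cell - 1) %/% nr
  remaining <- rep(TRUE, n)
  order_removed <- integer(0)
  while (any(remaining)) {
    S <- colSums(A[remaining, , drop = FALSE])
    curLev <- min(lev[remaining])
    cand <- which(remaining & lev == curLev)
    delta <- vapply(cand, function(i) {
      terms <- ifelse(S > 0, weights * A[i, ] / S, 0)
      max(terms)
    }, numeric(1))
    tied <- cand[delta == min(delta)]
    pick <- tied[which.min(rowMajor(tied))]
    remaining[pick] <- FALSE
    order_removed <- c(order_removed, pick)
  }
  order_removed
}

# independent shortest-path oracle on the 8-connected grid graph (igraph)
igraphCwd <- function(resM, cellSize, sources) {
  skip_if_not_installed("igraph")
  nr <- nrow(resM); nc <- ncol(resM)
  n <- nr * nc
  edges <- NULL; w <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rows <- seq_len(nr); cols <- seq_len(nc)
    r1 <- rep(rows, times = nc); c1 <- rep(cols, each = nr)
    r2 <- r1 + dr; c2 <- c1 + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    i <- (c1[ok] - 1) * nr + r1[ok]
    j <- (c2[ok] - 1) * nr + r2[ok]
    keep <- i < j & is.finite(resM[i]) & is.finite(resM[j])
    step <- cellSize * ifelse(dr != 0 & dc != 0, sqrt(2), 1)
    edges <- c(edges, rbind(i[keep], j[keep]))
    w <- c(w, (step * (resM[i[keep]] + resM[j[keep]]) / 2))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  d <- igraph::distances(g, v = sources, weights = w, algorithm = "dijkstra")
  apply(d, 2, min)
}

# exhaustive simple-path search from one source (DFS; only provably
# suboptimal prefixes are pruned, so every optimal simple path is explored)
enumerateCwd <- function(resM, cellSize, source) {
  nr <- nrow(resM); nc <- ncol(resM)
  n <- nr * nc
  best <- rep(Inf, n)
  best[source] <- 0
  neigh <- function(i) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      out <- rbind(out, c((cc - 1) * nr + rr,
                          cellSize * ifelse(dr != 0 && dc != 0, sqrt(2), 1)))
    }
    out
  }
  visited <- rep(FALSE, n)
  dfs <- function(i, cost) {
    visited[i] <<- TRUE
    nb <- neigh(i)
    for (k in seq_len(nrow(nb))) {
      j <- nb[k, 1]
      if (visited[j]) next
      cj <- cost + nb[k, 2] * (resM[i] + resM[j]) / 2
      if (cj > best[j]) next
      best[j] <<- cj
      dfs(j, cj)
    }
    visited[i] <<- FALSE
  }
  dfs(source, 0)
  best
}
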