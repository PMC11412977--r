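#' Sample pseudo-absence (background) point sets
#'
#' Draws `nSets` independent sets of background points on non-nodata cells,
#' with a minimum point-to-point distance within each set. If the grid
#' cannot host the requested number at the requested spacing the set is
#' returned short, with a warning (documented shortfall).
#'
#' @param landscape a [LandscapeBundle-class].
#' @param n points per set.
#' @param minDistM minimum pairwise distance within a set, in meters.
#' @param nSets number of independent sets.
#' @param seed integer seed; all sets are drawn from one seeded stream.
#' @return List of data.frames (x, y, setId).
#' @export
samplePseudoAbsences <- function(landscape, n = 10000, minDistM = 1000,
                                 nSets = 3, seed = 1) {
  if (n <= 0) stop("samplePseudoAbsences: n must be positive")
  lc <- landscape@landcover
  eligible <- which(is.finite(lc@values))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nSets), function(s) {
      cells <- if (minDistM <= lc@cellSize) {
        # distinct cells are automatically at least one cell size apart
        if (n > length(eligible)) {
          warning("pseudo-absence shortfall: requested ", n, ", grid offers ",
                  length(eligible))
          sample(eligible, length(eligible))
        } else sample(eligible, n)
      } else {
        greedySpacedSample(lc, eligible, n, minDistM)
      }
      xy <- cellXY(lc, cells)
      data.frame(x = xy$x, y = xy$y, setId = s)
    })
  })
}

greedySpacedSample <- function(raster, eligible, n, minDistM) {
  perm <- sample(eligible)
  xy <- cellXY(raster, perm)
  keep <- integer(); kx <- numeric(); ky <- numeric()
  for (i in seq_along(perm)) {
    if (length(keep) &&
        any((kx - xy$x[i])^2 + (ky - xy$y[i])^2 < minDistM^2)) next
    keep <- c(keep, perm[i]); kx <- c(kx, xy$x[i]); ky <- c(ky, xy$y[i])
    if (length(keep) == n) break
  }
  if (length(keep) < n)
    warning("pseudo-absence shortfall: placed ", length(keep), " of ", n,
            " at spacing ", minDistM, " m")
  keep
}

#' True Skill Statistic
#'
#' TSS = sensitivity + specificity - 1 at a given score cutoff
#' (prediction = score >= threshold). `maxTss` scans every unique score as a
#' candidate cutoff and returns the maximizer.
#'
#' @param labels binary vector (0/1 or logical).
#' @param scores numeric prediction scores.
#' @param threshold score cutoff.
#' @return `tss`: a number in \[-1, 1\]; `maxTss`: list(threshold, tss).
#' @export
tss <- function(labels, scores, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("tss: both classes must be present in labels")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' @rdname tss
#' @export
maxTss <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("maxTss: both classes must be present in labels")
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  # at cutoff t = s[i]: predictions >= t; sweep cutoffs over unique scores
  uq <- !duplicated(s)
  cumPos <- cumsum(y == 1); cumNeg <- cumsum(y == 0)
  i <- which(uq)
  sens <- (nPos - c(0, cumPos)[i]) / nPos
  spec <- c(0, cumNeg)[i] / nNeg
  val <- sens + spec - 1
  best <- which.max(val)
  list(threshold = s[i[best]], tss = val[best])
}

#' Built-in candidate learners
#'
#' Pluggable learner roster for the candidate models. Each learner is a list
#' with `fit(X, y, w)` and `predict(model, X)` returning presence
#' probabilities. Available: `glm` (ridge-regularized logistic regression),
#' `gbm` (gradient-boosted shallow trees), `cta` (single classification
#' tree), `ann` (one-hidden-layer neural network), and `constant` (a
#' constant-score baseline, useful to exercise the replication design
#' cheaply). Any user list with the same two functions can join a roster.
#'
#' @param names which learners to return.
#' @return Named list of learner definitions.
#' @export
defaultLearners <- function(names = c("glm", "gbm", "cta", "ann")) {
  all <- list(
    glm = list(
      fit = function(X, y, w) {
        X2 <- if (ncol(X) < 2) cbind(X, .pad = 0) else X
        glmnet::glmnet(X2, y, family = "binomial", alpha = 0,
                       lambda = 0.01, weights = w)
      },
      predict = function(m, X) {
        X2 <- if (ncol(X) < 2) cbind(X, .pad = 0) else X
        as.numeric(predict(m, X2, s = 0.01, type = "response"))
      }),
    gbm = list(
      fit = function(X, y, w) {
        dm <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 2,
                        eta = 0.3, nthread = 1),
          data = dm, nrounds = 30, verbose = 0)
      },
      predict = function(m, X)
        as.numeric(predict(m, xgboost::xgb.DMatrix(X, nthread = 1)))),
    cta = list(
      fit = function(X, y, w) {
        df <- data.frame(.y = factor(y, levels = c(0, 1)), X)
        rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                     control = rpart::rpart.control(cp = 0.01, minbucket = 5))
      },
      predict = function(m, X)
        as.numeric(predict(m, data.frame(X), type = "prob")[, "1"])),
    ann = list(
      fit = function(X, y, w) {
        Xs <- scale(X)
        m <- nnet::nnet(Xs, y, weights = w, size = 3, decay = 0.01,
                        maxit = 200, trace = FALSE, entropy = TRUE)
        list(net = m, center = attr(Xs, "scaled:center"),
             scale = attr(Xs, "scaled:scale"))
      },
      predict = function(m, X) {
        sc <- ifelse(m$scale == 0, 1, m$scale)
        as.numeric(predict(m$net, scale(X, m$center, sc)))
      }),
    constant = list(
      fit = function(X, y, w) sum(w * y) / sum(w),
      predict = function(m, X) rep(m, nrow(X))))
  all[names]
}

#' Fit candidate distribution models
#'
#' One candidate per (pseudo-absence set x learner x replicate): records are
#' split 80/20 stratified by class, the learner is fitted on the calibration
#' fraction with class-balanced weights (presences and background points
#' each contribute `prevalence` and `1 - prevalence` of the total weight),
#' and the holdout yields the TSS (at its max-TSS cutoff) and ROC AUC. A
#' learner failure on a replicate is recorded as a failed candidate and
#' skipped downstream, never fatal. The candidate count is always
#' `length(paSets) * length(roster) * nReplicates`.
#'
#' @param occset an [OccurrenceSet-class] of presences (post screening).
#' @param pset a [PredictorSet-class]; retained layers become covariates.
#' @param paSets list of pseudo-absence data.frames from
#'   [samplePseudoAbsences()].
#' @param roster named list of learners ([defaultLearners()]) or a character
#'   vector of built-in learner names.
#' @param nReplicates replicates per (set x learner).
#' @param trainFrac calibration fraction of each class.
#' @param prevalence total weight share given to the presence class.
#' @param seed integer seed for splits and learner randomness.
#' @return An object of class `sdmCandidates`: list with `candidates`,
#'   per-set `data` frames, `predictorNames`, `taxon`.
#' @export
fitCandidates <- function(occset, pset, paSets, roster = defaultLearners(),
                          nReplicates = 100, trainFrac = 0.8,
                          prevalence = 0.5, seed = 1) {
  if (is.character(roster)) roster <- defaultLearners(roster)
  stopifnot(length(roster) >= 1, !is.null(names(roster)))
  predNames <- pset@retained
  ref <- pset@layers[[predNames[1]]]

  extract <- function(x, y) {
    cells <- cellFromXY(ref, x, y)
    M <- sapply(pset@layers[predNames],
                function(r) r@values[cells])
    matrix(M, nrow = length(cells), dimnames = list(NULL, predNames))
  }
  pres <- occset@records
  Xp <- extract(pres$x, pres$y)
  data <- lapply(paSets, function(pa) {
    Xa <- extract(pa$x, pa$y)
    df <- data.frame(label = c(rep(1L, nrow(Xp)), rep(0L, nrow(Xa))),
                     rbind(Xp, Xa))
    df[stats::complete.cases(df), , drop = FALSE]
  })

  candidates <- vector("list", length(paSets) * length(roster) * nReplicates)
  k <- 0L
  withr::with_seed(as.integer(seed), {
    for (s in seq_along(paSets)) {
      df <- data[[s]]
      ip <- which(df$label == 1L); ia <- which(df$label == 0L)
      w <- numeric(nrow(df))
      w[ip] <- prevalence / length(ip) * nrow(df)
      w[ia] <- (1 - prevalence) / length(ia) * nrow(df)
      X <- as.matrix(df[, -1, drop = FALSE])
      for (lname in names(roster)) {
        lrn <- roster[[lname]]
        for (r in seq_len(nReplicates)) {
          k <- k + 1L
          trn <- c(sample(ip, floor(trainFrac * length(ip))),
                   sample(ia, floor(trainFrac * length(ia))))
          hold <- setdiff(seq_len(nrow(df)), trn)
          cand <- tryCatch({
            m <- lrn$fit(X[trn, , drop = FALSE], df$label[trn], w[trn])
            sc <- lrn$predict(m, X[hold, , drop = FALSE])
            mt <- maxTss(df$label[hold], sc)
            auc <- as.numeric(pROC::auc(
              response = df$label[hold], predictor = sc,
              levels = c(0, 1), direction = "<", quiet = TRUE))
            list(learner = lname, paSet = s, replicate = r, status = "ok",
                 model = m, predictFun = lrn$predict, holdoutIdx = hold,
                 tss = mt$tss, roc = auc, threshold = mt$threshold)
          }, error = function(e)
            list(learner = lname, paSet = s, replicate = r,
                 status = "failed", message = conditionMessage(e),
                 tss = NA_real_, roc = NA_real_, threshold = NA_real_))
          candidates[[k]] <- cand
        }
      }
    }
  })
  structure(list(candidates = candidates, data = data,
                 predictorNames = predNames, taxon = occset@taxon),
            class = "sdmCandidates")
}

#' @export
print.sdmCandidates <- function(x, ...) {
  ok <- sum(vapply(x$candidates, function(c) c$status == "ok", logical(1)))
  cat(sprintf("sdmCandidates '%s'  %d candidates (%d ok)\n",
              x$taxon, length(x$candidates), ok))
  invisible(x)
}

#' Candidate evaluation table
#'
#' @param cands an `sdmCandidates` object.
#' @return data.frame (learner, paSet, replicate, status, tss, roc,
#'   threshold).
#' @export
candidateEvals <- function(cands) {
  do.call(rbind, lapply(cands$candidates, function(c)
    data.frame(learner = c$learner, paSet = c$paSet, replicate = c$replicate,
               status = c$status, tss = c$tss, roc = c$roc,
               threshold = c$threshold)))
}

#' Build a TSS-weighted ensemble
#'
#' Candidates with holdout TSS strictly above `tssMin` become members; each
#' member's weight is its TSS divided by the members' TSS sum, so the
#' ensemble suitability is the proportionally weighted sum of member
#' probabilities (a convex combination). The ensemble binarization threshold
#' is the max-TSS cutoff of the ensemble's own scores on the pooled holdout
#' records of its members.
#'
#' @param cands an `sdmCandidates` object from [fitCandidates()].
#' @param pset the [PredictorSet-class] used for fitting (supplies the grid
#'   for the suitability and binary layers).
#' @param tssMin minimum holdout TSS for ensemble membership (strict).
#' @return An [EnsembleModel-class].
#' @export
buildEnsemble <- function(cands, pset, tssMin = 0.8) {
  ok <- Filter(function(c) c$status == "ok" && is.finite(c$tss) &&
                 c$tss > tssMin, cands$candidates)
  if (!length(ok))
    stop("no ensemble members: no candidate has TSS > ", tssMin)
  tssv <- vapply(ok, `[[`, numeric(1), "tss")
  weights <- if (sum(tssv) > 0) tssv / sum(tssv)
             else rep(1 / length(tssv), length(tssv))  # all-zero-skill edge

  predNames <- cands$predictorNames
  ref <- pset@layers[[predNames[1]]]
  G <- sapply(pset@layers[predNames], function(r) as.vector(r@values))
  G <- matrix(G, ncol = length(predNames),
              dimnames = list(NULL, predNames))
  finite <- rowSums(!is.finite(G)) == 0

  suit <- rep(NA_real_, nrow(G))
  suit[finite] <- 0
  memberPredict <- function(c, X) c$predictFun(c$model, X)
  for (i in seq_along(ok))
    suit[finite] <- suit[finite] +
      weights[i] * memberPredict(ok[[i]], G[finite, , drop = FALSE])
  suitability <- likeRaster(ref, matrix(suit, nrow(ref@values)))

  # pooled holdout rows (unique per pa set) for ensemble-level thresholding
  pooled <- unique(do.call(rbind, lapply(ok, function(c)
    data.frame(set = c$paSet, idx = c$holdoutIdx))))
  evalData <- do.call(rbind, lapply(split(pooled, pooled$set), function(p)
    cands$data[[p$set[1]]][p$idx, , drop = FALSE]))
  rownames(evalData) <- NULL
  Xe <- as.matrix(evalData[, predNames, drop = FALSE])
  scores <- numeric(nrow(Xe))
  for (i in seq_along(ok))
    scores <- scores + weights[i] * memberPredict(ok[[i]], Xe)
  mt <- maxTss(evalData$label, scores)

  binary <- likeRaster(ref, (suitability@values >= mt$threshold) + 0)
  binary@values[!is.finite(suitability@values)] <- NA_real_

  members <- lapply(ok, function(c)
    c[c("learner", "paSet", "replicate", "model", "predictFun",
        "tss", "roc", "threshold")])
  new("EnsembleModel", taxon = cands$taxon, members = members,
      weights = as.numeric(weights), threshold = mt$threshold,
      suitability = suitability, binary = binary, evalData = evalData)
}

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel '%s'  %d members, threshold %.3f\n",
              object@taxon, length(object@members), object@threshold))
  tb <- table(vapply(object@members, `[[`, character(1), "learner"))
  cat("  members:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
})

#' Predict ensemble suitability for new data
#'
#' @param ensemble an [EnsembleModel-class].
#' @param newdata matrix or data.frame with the predictor columns.
#' @return Numeric vector of weighted-ensemble probabilities.
#' @export
ensemblePredict <- function(ensemble, newdata) {
  X <- as.matrix(newdata)
  out <- numeric(nrow(X))
  for (i in seq_along(ensemble@members)) {
    m <- ensemble@members[[i]]
    out <- out + ensemble@weights[i] * m$predictFun(m$model, X)
  }
  out
}

#' @describeIn ensemblePredict accessors for the ensemble rasters and cutoff.
#' @export
suitabilityLayer <- function(ensemble) ensemble@suitability

#' @rdname ensemblePredict
#' @export
binaryLayer <- function(ensemble) ensemble@binary

#' @rdname ensemblePredict
#' @export
ensembleThreshold <- function(ensemble) ensemble@threshold

#' Permutation variable importance
#'
#' Importance of a variable is 1 minus the Pearson correlation between
#' ensemble predictions on the evaluation sample before and after permuting
#' that variable (mean over `nPerm` permutations), clamped to \[0, 1\]. A
#' variable the ensemble never uses leaves predictions unchanged (r = 1,
#' importance 0).
#'
#' @param ensemble an [EnsembleModel-class].
#' @param nPerm number of permutations per variable.
#' @param seed integer seed.
#' @return Named numeric vector of importances in \[0, 1\].
#' @export
variableImportance <- function(ensemble, nPerm = 5, seed = 1) {
  X <- as.matrix(ensemble@evalData[, setdiff(names(ensemble@evalData),
                                             "label"), drop = FALSE])
  p0 <- ensemblePredict(ensemble, X)
  withr::with_seed(as.integer(seed), {
    imp <- vapply(colnames(X), function(v) {
      rs <- vapply(seq_len(nPerm), function(i) {
        Xp <- X
        Xp[, v] <- sample(Xp[, v])
        p1 <- ensemblePredict(ensemble, Xp)
        r <- suppressWarnings(cor(p0, p1))
        if (!is.finite(r)) 1 else r
      }, numeric(1))
      mean(1 - rs)
    }, numeric(1))
  })
  clamp(imp, 0, 1)
}

#' Ensemble response curve for one variable
#'
#' Evaluation-strip curve: the focal variable is varied over its observed
#' range at `nPoints` while all other predictors are fixed at their medians
#' over the landscape; the ensemble prediction is returned per point.
#'
#' @param ensemble an [EnsembleModel-class].
#' @param pset the [PredictorSet-class] supplying observed ranges/medians.
#' @param variable focal predictor name.
#' @param nPoints number of evaluation points.
#' @return data.frame (value, suitability).
#' @export
responseCurves <- function(ensemble, pset, variable, nPoints = 50) {
  predNames <- setdiff(names(ensemble@evalData), "label")
  if (!variable %in% predNames)
    stop("unknown variable: ", variable)
  med <- vapply(predNames, function(nm) {
    v <- pset@layers[[nm]]@values
    median(v[is.finite(v)])
  }, numeric(1))
  fv <- pset@layers[[variable]]@values
  fv <- fv[is.finite(fv)]
  grid <- seq(min(fv), max(fv), length.out = nPoints)
  X <- matrix(rep(med, each = nPoints), nrow = nPoints,
              dimnames = list(NULL, predNames))
  X[, variable] <- grid
  data.frame(value = grid, suitability = ensemblePredict(ensemble, X))
}
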