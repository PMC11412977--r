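#' Default run configuration
#'
#' All stage parameters with their conventional defaults (cleaning year
#' 1945, 1-km thinning, minimum 5 records, |r| <= 0.7 and VIF < 5
#' screening, 3 x 10000 pseudo-absences, 100 replicates at 80/20,
#' TSS > 0.8 ensemble membership, status weights 1-4, CPF thresholds
#' 1 km2 and rank 0.95). `cpaTopFraction` has no conventional default and
#' must be set by the user. `demoConfig()` is a scaled-down profile (small
#' grid, 2 learners, few replicates) that completes in well under a minute.
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @return Named list of configuration blocks.
#' @export
defaultConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    landscape = list(shape = c(100, 100), cellSize = 1000,
                     forestFraction = 0.12, nFragments = 30,
                     autocorrRange = 5),
    taxa = list(),
    qc = list(minYear = 1945, maxPrecisionM = 1000, countRange = c(1, 99),
              thinDistM = 1000, minN = 5),
    screen = list(largeFragKm2 = 1, windowCells = 5, sampleCells = 10000,
                  rMax = 0.7, vifMax = 5),
    sdm = list(nPa = 10000, nSets = 3, paMinDistM = 1000,
               roster = c("glm", "gbm", "cta", "ann"), nReplicates = 100,
               trainFrac = 0.8, prevalence = 0.5, tssMin = 0.8),
    zonation = list(cpaTopFraction = NA_real_, useCondition = TRUE,
                    useProtectedMask = TRUE),
    corridors = list(minAreaKm2 = 1, minMeanRank = 0.95, allPairs = FALSE))
}

#' @rdname defaultConfig
#' @export
demoConfig <- function(seed = 1) {
  cfg <- defaultConfig(seed)
  cfg$landscape <- list(shape = c(40, 40), cellSize = 1000,
                        forestFraction = 0.2, nFragments = 12,
                        autocorrRange = 3)
  cfg$taxa <- list(
    list(name = "taxon_cr", coefs = c(treeCover = 2, percOldForest = 1),
         nPresences = 60, status = "CR"),
    list(name = "taxon_en", coefs = c(elevation = 2.5),
         nPresences = 50, status = "EN"),
    list(name = "taxon_vu", coefs = c(treeCover = 1.5, tempRange = -1),
         nPresences = 40, status = "VU"))
  cfg$screen$sampleCells <- 1500
  cfg$sdm <- list(nPa = 300, nSets = 2, paMinDistM = 1000,
                  roster = c("glm", "cta"), nReplicates = 3,
                  trainFrac = 0.8, prevalence = 0.5, tssMin = 0.2)
  cfg$zonation$cpaTopFraction <- 0.2
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [defaultConfig()]. Unknown keys are
#'   rejected, and every parameter is range-checked at load.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultConfig(cfg$seed %||% 1)
  merged <- modifyBlocks(base, cfg)
  checkConfig(merged)
  merged
}

modifyBlocks <- function(base, cfg) {
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(cfg)) {
    if (nm %in% c("taxa", "seed")) { base[[nm]] <- cfg[[nm]]; next }
    blk <- cfg[[nm]]
    badk <- setdiff(names(blk), names(base[[nm]]))
    if (length(badk))
      stop("unknown config key(s) in ", nm, ": ", paste(badk, collapse = ", "))
    base[[nm]][names(blk)] <- blk
  }
  base
}

#' Validate a run configuration
#'
#' @param cfg configuration list as from [defaultConfig()].
#' @return Invisibly TRUE; errors on the first invalid parameter.
#' @export
checkConfig <- function(cfg) {
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid config: ", what)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  with(cfg$landscape, {
    chk(length(shape) == 2 && all(shape >= 20), "landscape$shape (>= 20x20)")
    chk(cellSize > 0, "landscape$cellSize")
    chk(forestFraction > 0 && forestFraction < 1, "landscape$forestFraction")
    chk(nFragments >= 1, "landscape$nFragments")
  })
  chk(length(cfg$taxa) >= 1, "taxa (need at least one)")
  for (t in cfg$taxa) {
    chk(!is.null(t$name) && !is.null(t$coefs) && !is.null(t$nPresences),
        "taxa entries need name, coefs, nPresences")
    chk((t$status %||% "DD") %in% names(statusWeights()), "taxa status")
  }
  with(cfg$qc, {
    chk(maxPrecisionM > 0, "qc$maxPrecisionM")
    chk(length(countRange) == 2 && countRange[1] <= countRange[2],
        "qc$countRange")
    chk(thinDistM >= 0, "qc$thinDistM")
    chk(minN >= 1, "qc$minN")
  })
  with(cfg$screen, {
    chk(rMax > 0 && rMax <= 1, "screen$rMax")
    chk(vifMax > 1, "screen$vifMax")
    chk(sampleCells > 10, "screen$sampleCells")
  })
  with(cfg$sdm, {
    chk(nPa > 0, "sdm$nPa")
    chk(nSets >= 1, "sdm$nSets")
    chk(nReplicates >= 1, "sdm$nReplicates")
    chk(trainFrac > 0 && trainFrac < 1, "sdm$trainFrac")
    chk(prevalence > 0 && prevalence < 1, "sdm$prevalence")
    chk(is.numeric(tssMin) && tssMin >= -1 && tssMin <= 1,
        "sdm$tssMin (within [-1, 1])")
  })
  chk(is.na(cfg$zonation$cpaTopFraction) ||
        (cfg$zonation$cpaTopFraction > 0 && cfg$zonation$cpaTopFraction <= 1),
      "zonation$cpaTopFraction")
  with(cfg$corridors, {
    chk(minAreaKm2 >= 0, "corridors$minAreaKm2")
    chk(minMeanRank >= 0 && minMeanRank <= 1, "corridors$minMeanRank")
  })
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes all stages in order — synthetic landscape and taxa generation,
#' occurrence cleaning and thinning, taxon screening, predictor derivation
#' and collinearity screening, pseudo-absence sampling, candidate fitting
#' and TSS-weighted ensembles, area and diversity summaries, core-area
#' zonation ranking with condition and protected-area mask, CPF extraction
#' and corridor planning — and writes every artifact plus a machine-readable
#' manifest to `outDir`. The run is fully deterministic for a given config:
#' stage seeds derive from the global seed.
#'
#' @param config configuration list ([defaultConfig()], [demoConfig()], or
#'   [readRunConfig()]).
#' @param outDir output directory (created; pass NULL to skip writing).
#' @return Invisibly, a list with every stage result.
#' @export
runPipeline <- function(config, outDir = NULL) {
  checkConfig(config)
  if (is.na(config$zonation$cpaTopFraction))
    stop("config$zonation$cpaTopFraction is required (no conventional default)")
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outDir))
        writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                   file.path(outDir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ls <- config$landscape
  landscape <- stage("generate", makeLandscape(
    seed, shape = ls$shape, cellSize = ls$cellSize,
    forestFraction = ls$forestFraction, nFragments = ls$nFragments,
    autocorrRange = ls$autocorrRange))
  taxa <- stage("generate", lapply(seq_along(config$taxa), function(i) {
    t <- config$taxa[[i]]
    makeVirtualTaxon(landscape, list(coefs = unlist(t$coefs)),
                     nPresences = t$nPresences, status = t$status %||% "DD",
                     seed = seed + 1000L + i, name = t$name,
                     dirty = t$dirty)
  }))
  log$taxaGenerated <- length(taxa)

  qc <- config$qc
  studyArea <- likeRaster(landscape@landcover, 1)
  occsets <- stage("qc", lapply(taxa, function(t) {
    s <- filterRecords(t@occurrences, studyArea, landscape@landcover,
                       minYear = qc$minYear, maxPrecisionM = qc$maxPrecisionM,
                       countRange = qc$countRange, taxon = t@name)
    thinSpatial(s, minDistM = qc$thinDistM)
  }))
  screened <- stage("qc", screenTaxa(occsets, minN = qc$minN))
  keptTaxa <- taxa[match(vapply(screened$included, function(s) s@taxon,
                                character(1)),
                         vapply(taxa, function(t) t@name, character(1)))]
  log$taxaScreened <- length(screened$included)
  if (!length(screened$included))
    stage("qc", stop("no taxon passed occurrence screening"))

  sc <- config$screen
  pset <- stage("screen", derivePredictors(landscape,
                                           largeFragKm2 = sc$largeFragKm2,
                                           windowCells = sc$windowCells))
  pset <- stage("screen", pearsonPrune(pset, sampleCells = sc$sampleCells,
                                       rMax = sc$rMax, seed = seed + 2000L))
  pset <- stage("screen", vifPrune(pset, sampleCells = sc$sampleCells,
                                   vifMax = sc$vifMax, seed = seed + 2000L))
  log$predictorsRetained <- length(pset@retained)

  sd <- config$sdm
  paSets <- stage("sdm", suppressWarnings(samplePseudoAbsences(
    landscape, n = sd$nPa, minDistM = sd$paMinDistM, nSets = sd$nSets,
    seed = seed + 3000L)))
  ensembles <- list(); evals <- list(); importances <- list()
  for (i in seq_along(screened$included)) {
    occ <- screened$included[[i]]
    cands <- stage("sdm", fitCandidates(
      occ, pset, paSets, roster = sd$roster, nReplicates = sd$nReplicates,
      trainFrac = sd$trainFrac, prevalence = sd$prevalence,
      seed = seed + 4000L + i))
    evals[[occ@taxon]] <- candidateEvals(cands)
    ens <- stage("sdm", buildEnsemble(cands, pset, tssMin = sd$tssMin))
    ensembles[[occ@taxon]] <- ens
    importances[[occ@taxon]] <- variableImportance(ens, nPerm = 3,
                                                   seed = seed + 5000L + i)
  }
  log$ensembles <- length(ensembles)

  statuses <- vapply(keptTaxa, function(t) t@status, character(1))
  areas <- stage("summaries", do.call(rbind, lapply(seq_along(ensembles),
    function(i) suitableAreas(ensembles[[i]]@binary, landscape@landcover,
                              landscape@protected,
                              taxon = names(ensembles)[i],
                              status = statuses[i]))))
  alpha <- stage("summaries",
                 alphaDiversity(lapply(ensembles, function(e) e@binary)))

  zo <- config$zonation
  feats <- stage("prioritize", featureStack(ensembles, statuses = statuses))
  if (isTRUE(zo$useCondition))
    feats <- stage("prioritize", applyCondition(feats, landscape@ghm))
  mask <- if (isTRUE(zo$useProtectedMask))
    likeRaster(landscape@protected, landscape@protected@values + 1) else NULL
  rank <- stage("prioritize", cazRank(feats, mask))
  cpa <- stage("prioritize", extractCpa(rank, zo$cpaTopFraction))

  co <- config$corridors
  frags <- stage("corridors", labelFragments(forestMask(landscape)))
  cpfs <- stage("corridors", extractCpfs(rank, frags,
                                         minAreaKm2 = co$minAreaKm2,
                                         minMeanRank = co$minMeanRank))
  log$nCpfs <- nrow(cpfs)
  landR <- stage("corridors", landscapeResistance(landscape))
  taxR <- stage("corridors", taxonResistance(unname(ensembles)))
  resist <- stage("corridors", finalResistance(landR, taxR))
  corridors <- if (nrow(cpfs) >= 2)
    stage("corridors", planCorridors(cpfs, resist, allPairs = co$allPairs))
  else emptyCorridors()
  log$nCorridors <- nrow(corridors)

  result <- list(config = config, landscape = landscape, taxa = taxa,
                 occsets = occsets, screened = screened, predictors = pset,
                 paSets = paSets, evals = evals, ensembles = ensembles,
                 importances = importances, areas = areas, alpha = alpha,
                 rank = rank, cpa = cpa, cpfs = cpfs,
                 resistance = resist, corridors = corridors, log = log)
  if (!is.null(outDir)) writeRunArtifacts(result, outDir)
  invisible(result)
}

writeRunArtifacts <- function(res, outDir) {
  w <- function(df, name) write.csv(df, file.path(outDir, name),
                                    row.names = FALSE)
  for (s in res$occsets)
    writeOccurrences(s, file.path(outDir, paste0("occ_", s@taxon, ".csv")))
  w(screeningReport(res$predictors), "predictor_screening.csv")
  w(do.call(rbind, Map(function(e, nm) cbind(taxon = nm, e),
                       res$evals, names(res$evals))), "candidate_evals.csv")
  imp <- do.call(rbind, Map(function(v, nm)
    data.frame(taxon = nm, variable = names(v), importance = unname(v)),
    res$importances, names(res$importances)))
  w(imp, "variable_importance.csv")
  w(res$areas, "suitable_areas.csv")
  w(res$rank@curves, "performance_curves.csv")
  w(res$cpfs, "cpfs.csv")
  w(res$corridors, "corridors.csv")
  for (nm in names(res$ensembles))
    writeRaster(res$ensembles[[nm]]@suitability,
                file.path(outDir, paste0("suitability_", nm, ".asc")))
  writeRaster(res$alpha, file.path(outDir, "alpha_diversity.asc"))
  writeRaster(res$rank@rank, file.path(outDir, "priority_rank.asc"))
  writeRaster(res$cpa, file.path(outDir, "cpa.asc"))
  writeRaster(res$resistance@final, file.path(outDir, "resistance.asc"))
  manifest <- list(
    config = res$config,
    counts = res$log,
    records = lapply(res$occsets, function(s)
      list(taxon = s@taxon, kept = nrow(s@records), removed = nrow(s@audit))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
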