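#' Filter occurrence records through the cleaning cascade
#'
#' Applies the record-level cleaning rules in a fixed order, so each removed
#' record carries exactly one (first-triggered) reason code:
#' `no_coords` (missing coordinates), `outside_area` (off grid or outside
#' the study-area mask), `nonvegetated` (land cover water or non-vegetated),
#' `precision` (coordinate precision coarser than `maxPrecisionM`),
#' `count_range` (count below `countRange[1]` or above `countRange[2]`),
#' `year` (collected before `minYear`), `exclusion_zone` (within one cell of
#' a user-supplied exclusion point), `outlier` (geographic distance outlier,
#' see Details). All boundary comparisons are strict: year 1944 is removed
#' and 1945 kept; count 99 kept and 100 removed; precision 1000 m kept.
#'
#' @details The distance-outlier rule flags records whose median distance to
#' all other same-taxon survivors exceeds five times the taxon's median of
#' those medians; it needs at least three surviving records to apply. The
#' `exclusion_points` mechanism generically replaces gazetteer-based tests
#' (political centroids, institutions) that require external reference data.
#'
#' @param records data.frame with columns x, y, year, count, precision_m
#'   (a `taxon` column is carried through if present).
#' @param studyArea boolean [GridRaster-class] of the analyzable area.
#' @param landcover categorical [GridRaster-class] (codes of
#'   [landcoverCodes()]).
#' @param exclusionPoints optional data.frame (x, y) of exclusion points.
#' @param minYear records strictly before this year are removed.
#' @param maxPrecisionM records with precision strictly above this are removed.
#' @param countRange inclusive \[lo, hi\] kept range of individual counts.
#' @param taxon taxon name for the resulting set.
#' @return An [OccurrenceSet-class].
#' @export
filterRecords <- function(records, studyArea, landcover,
                          exclusionPoints = NULL, minYear = 1945,
                          maxPrecisionM = 1000, countRange = c(1, 99),
                          taxon = NULL) {
  need <- c("x", "y", "year", "count", "precision_m")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing required column(s): ", paste(miss, collapse = ", "))
  assertCompatible(studyArea, landcover)
  taxon <- taxon %||%
    (if ("taxon" %in% names(records) && nrow(records)) records$taxon[1] else "unknown")
  records$.rowid <- seq_len(max(nrow(records), 0L))
  reason <- rep(NA_character_, nrow(records))
  alive <- function() is.na(reason)
  flag <- function(idx, code) {
    idx[is.na(idx)] <- FALSE
    idx <- idx & alive()
    reason[idx] <<- code
  }

  flag(is.na(records$x) | is.na(records$y), "no_coords")

  cell <- rep(NA_integer_, nrow(records))
  ok <- alive()
  cell[ok] <- cellFromXY(studyArea, records$x[ok], records$y[ok])
  inArea <- !is.na(cell) & !is.na(studyArea@values[cell]) &
    studyArea@values[cell] != 0
  flag(alive() & !inArea, "outside_area")

  codes <- landcoverCodes()
  lcv <- rep(NA_real_, nrow(records))
  lcv[!is.na(cell)] <- landcover@values[cell[!is.na(cell)]]
  flag(alive() & lcv %in% c(codes[["water"]], codes[["nonveg"]]), "nonvegetated")

  flag(alive() & records$precision_m > maxPrecisionM, "precision")
  flag(alive() & (records$count < countRange[1] | records$count > countRange[2]),
       "count_range")
  flag(alive() & records$year < minYear, "year")

  if (!is.null(exclusionPoints) && nrow(exclusionPoints)) {
    exCell <- cellFromXY(studyArea, exclusionPoints$x, exclusionPoints$y)
    exRC <- cellRowCol(studyArea, exCell[!is.na(exCell)])
    if (nrow(exRC)) {
      rc <- cellRowCol(studyArea, cell)
      near <- rep(FALSE, nrow(records))
      okc <- !is.na(cell)
      if (any(okc)) {
        cheb <- outer(rc$row[okc], exRC$row, function(a, b) abs(a - b))
        cheb <- pmax(cheb, outer(rc$col[okc], exRC$col, function(a, b) abs(a - b)))
        near[okc] <- apply(cheb <= 1, 1, any)
      }
      flag(alive() & near, "exclusion_zone")
    }
  }

  surv <- which(alive())
  if (length(surv) >= 3) {
    d <- as.matrix(dist(records[surv, c("x", "y")]))
    diag(d) <- NA
    med <- apply(d, 1, median, na.rm = TRUE)
    thr <- 5 * median(med)
    if (is.finite(thr) && thr > 0)
      flag(seq_len(nrow(records)) %in% surv[med > thr], "outlier")
  }

  kept <- records[alive(), , drop = FALSE]
  audit <- records[!alive(), , drop = FALSE]
  audit$reason <- reason[!alive()]
  rownames(kept) <- rownames(audit) <- NULL
  new("OccurrenceSet", taxon = as.character(taxon), records = kept,
      audit = audit)
}

#' Spatially thin occurrence records
#'
#' Exact spatial duplicates collapse to one record first (reason
#' `duplicate`), then records are thinned greedily: sorted by year
#' descending (ties by stable input order), each record is kept only if it
#' lies at least `minDistM` from every record already kept (reason
#' `thinned` otherwise). Two records exactly `minDistM` apart are therefore
#' both kept, and the most recent record always wins a conflict. The
#' operation is idempotent.
#'
#' @param occset an [OccurrenceSet-class].
#' @param minDistM minimum pairwise distance in meters.
#' @return An [OccurrenceSet-class] with the audit extended.
#' @export
thinSpatial <- function(occset, minDistM = 1000) {
  rec <- occset@records
  if (!nrow(rec)) return(occset)
  reason <- rep(NA_character_, nrow(rec))

  dupKey <- paste(rec$x, rec$y)
  for (k in unique(dupKey[duplicated(dupKey)])) {
    idx <- which(dupKey == k)
    win <- idx[order(-rec$year[idx], idx)][1L]
    reason[setdiff(idx, win)] <- "duplicate"
  }

  cand <- which(is.na(reason))
  ord <- cand[order(-rec$year[cand], cand)]
  keptIdx <- integer()
  for (i in ord) {
    if (length(keptIdx)) {
      dd <- sqrt((rec$x[keptIdx] - rec$x[i])^2 + (rec$y[keptIdx] - rec$y[i])^2)
      if (any(dd < minDistM)) { reason[i] <- "thinned"; next }
    }
    keptIdx <- c(keptIdx, i)
  }
  kept <- rec[sort(keptIdx), , drop = FALSE]
  removed <- rec[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  audit <- rbind(occset@audit, removed)
  rownames(kept) <- rownames(audit) <- NULL
  new("OccurrenceSet", taxon = occset@taxon, records = kept, audit = audit)
}

#' Screen taxa by minimum occurrence count
#'
#' Taxa with at least `minN` kept records (after thinning) are included;
#' the boundary is inclusive, so exactly `minN` records pass.
#'
#' @param occsets list of [OccurrenceSet-class].
#' @param minN minimum number of kept records.
#' @return list(included = ..., excluded = ...), both lists of
#'   [OccurrenceSet-class].
#' @export
screenTaxa <- function(occsets, minN = 5) {
  n <- vapply(occsets, function(s) nrow(s@records), integer(1))
  list(included = occsets[n >= minN], excluded = occsets[n < minN])
}

#' @describeIn filterRecords accessors for kept records and the audit trail.
#' @param x an OccurrenceSet.
#' @export
keptRecords <- function(x) x@records

#' @rdname filterRecords
#' @export
auditTrail <- function(x) x@audit

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet '%s'  %d kept, %d removed\n", object@taxon,
              nrow(object@records), nrow(object@audit)))
  if (nrow(object@audit)) {
    tb <- table(object@audit$reason)
    cat("  removals:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
})

#' Write an occurrence set and its audit to CSV
#'
#' @param occset an [OccurrenceSet-class].
#' @param path CSV path for the kept records; the audit goes to a sidecar
#'   `*_audit.csv`.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occset, path) {
  write.csv(occset@records, path, row.names = FALSE)
  write.csv(occset@audit, sub("\\.csv$", "_audit.csv", path),
            row.names = FALSE)
  invisible(path)
}
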