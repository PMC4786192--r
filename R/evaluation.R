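## Scoring a PredictionSet against contact maps: confusion counts, the
## report metrics, random-baseline correction, range calibration, cutoff
## scans and characteristic-distance peak extraction.

#' Confusion counts of a prediction set against a contact map
#'
#' Standard semantics over the full pair universe of n(n-1)/2 unordered
#' pairs: TP = predicted and in contact, FP = predicted but not in
#' contact, FN = in contact but not predicted, TN = the rest.  The four
#' counts always sum to the universe size.
#'
#' @param pred a [PredictionSet-class]
#' @param cm a [ContactMap-class]
#' @return named integer vector c(tp, fp, fn, tn) with attribute
#'   \code{"universe"}
#' @export
confusionCounts <- function(pred, cm) {
  pp <- predictionPairs(pred)
  n <- cm@n
  if (nrow(pp) > 0L) {
    bad <- unique(c(pp[pp[, 1L] > n | pp[, 1L] < 1L, 1L],
                    pp[pp[, 2L] > n | pp[, 2L] < 1L, 2L]))
    if (length(bad))
      stop("prediction indices outside structure residues 1..", n, ": ",
           paste(sort(bad), collapse = ", "))
  }
  ctc <- contactPairs(cm)
  predIdx <- if (nrow(pp)) pairIndex(pp[, 1L], pp[, 2L], n) else numeric()
  ctcIdx <- if (nrow(ctc)) pairIndex(ctc[, 1L], ctc[, 2L], n) else numeric()
  tp <- sum(predIdx %in% ctcIdx)
  fp <- length(predIdx) - tp
  fn <- length(ctcIdx) - tp
  universe <- universeSize(cm)
  counts <- c(tp = tp, fp = fp, fn = fn,
              tn = as.integer(universe - tp - fp - fn))
  attr(counts, "universe") <- universe
  counts
}

countsUniverse <- function(counts) {
  attr(counts, "universe") %||% sum(counts[c("tp", "fp", "fn", "tn")])
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).  When any
#' factor of the denominator is zero the value is taken as 0 (degenerate
#' prediction or contact set); this convention is reported via a message.
#'
#' @param counts named vector with tp, fp, fn, tn (see [confusionCounts()])
#' @return value in [-1, 1]
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]]); tn <- as.numeric(counts[["tn"]])
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(fac == 0)) {
    message("MCC denominator has a zero factor; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(fac))
}

#' Report accuracy, (TN - TP) / total
#'
#' The accuracy variant used in the benchmark report tables:
#' (TN - TP) / (TP + FP + FN + TN).  Because true negatives dominate
#' sparse contact problems it behaves almost like the standard accuracy
#' minus twice the TP rate; the standard (TP + TN) / total is available
#' as [accuracyStd()] and both are carried through every scan.
#'
#' @param counts named vector with tp, fp, fn, tn
#' @return dimensionless value
#' @export
accuracyReport <- function(counts) {
  (as.numeric(counts[["tn"]]) - as.numeric(counts[["tp"]])) /
    countsUniverse(counts)
}

#' Standard accuracy, (TP + TN) / total
#' @param counts named vector with tp, fp, fn, tn
#' @return value in [0, 1]
#' @export
accuracyStd <- function(counts) {
  (as.numeric(counts[["tp"]]) + as.numeric(counts[["tn"]])) /
    countsUniverse(counts)
}

#' Precision, TP / (TP + FP)
#'
#' Undefined when nothing is predicted (TP + FP = 0); reported as 0 with
#' attribute \code{"undefined" = TRUE}.
#'
#' @param counts named vector with tp, fp, fn, tn
#' @return value in [0, 1]
#' @export
precisionScore <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  if (tp + fp == 0) return(structure(0, undefined = TRUE))
  tp / (tp + fp)
}

#' Sensitivity (recall), TP / (TP + FN)
#'
#' Undefined when there are no contacts (TP + FN = 0); reported as 0 with
#' attribute \code{"undefined" = TRUE}.
#'
#' @param counts named vector with tp, fp, fn, tn
#' @return value in [0, 1]
#' @export
sensitivityScore <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fn <- as.numeric(counts[["fn"]])
  if (tp + fn == 0) return(structure(0, undefined = TRUE))
  tp / (tp + fn)
}

allMetrics <- function(counts) {
  c(mcc = mcc(counts),
    accy = accuracyReport(counts),
    accy_std = accuracyStd(counts),
    prec = as.numeric(precisionScore(counts)),
    sensy = as.numeric(sensitivityScore(counts)))
}

#' Mean metrics of equally sized random prediction sets
#'
#' Draws \code{nReps} prediction sets of \code{k} distinct pairs uniformly
#' without replacement from the pair universe, scores each against the
#' contact map, and returns the per-metric means.  Subtracting these means
#' from a predictor's metrics removes the chance-level signal
#' (RND correction).
#'
#' @param cm a [ContactMap-class]
#' @param k number of pairs per random set (usually the evaluated
#'   predictor's pair count)
#' @param nReps number of random sets (default 100)
#' @param seed integer seed; mandatory for reproducibility
#' @return named numeric vector of metric means (mcc, accy, accy_std,
#'   prec, sensy) with attributes \code{"sd"} (per-metric standard
#'   deviation across repetitions, from which the Monte-Carlo standard
#'   error of each mean is sd/sqrt(nReps)) and \code{"meta"} =
#'   list(nReps, seed, k)
#' @export
randomBaseline <- function(cm, k, nReps = 100L, seed) {
  universe <- universeSize(cm)
  if (k < 0 || k > universe)
    stop("k must be in 0..", universe)
  if (missing(seed))
    stop("seed is mandatory for the random baseline")
  ctc <- contactPairs(cm)
  ctcIdx <- if (nrow(ctc)) pairIndex(ctc[, 1L], ctc[, 2L], cm@n) else numeric()
  nc <- length(ctcIdx)
  reps <- withSeed(seed, {
    vapply(seq_len(nReps), function(r) {
      tp <- if (k == 0) 0L else {
        draw <- sample.int(universe, k)
        sum(draw %in% ctcIdx)
      }
      counts <- c(tp = tp, fp = k - tp, fn = nc - tp,
                  tn = as.integer(universe - k - nc + tp))
      attr(counts, "universe") <- universe
      suppressMessages(allMetrics(counts))
    }, numeric(5L))
  })
  out <- rowMeans(reps)
  attr(out, "sd") <- apply(reps, 1L, stats::sd)
  attr(out, "meta") <- list(nReps = nReps, seed = seed, k = k)
  out
}

#' RND-corrected metric: observed minus random-baseline mean
#' @param value observed metric value
#' @param baseline mean of the same metric over random prediction sets
#' @return corrected value
#' @export
correctedMetric <- function(value, baseline) {
  as.numeric(value) - as.numeric(baseline)
}

scanRecord <- function(cutoff, counts, rnd = NULL) {
  m <- suppressMessages(allMetrics(counts))
  rec <- data.frame(cutoff = cutoff,
                    tp = counts[["tp"]], fp = counts[["fp"]],
                    fn = counts[["fn"]], tn = counts[["tn"]],
                    mcc = m[["mcc"]], accy = m[["accy"]],
                    accy_std = m[["accy_std"]], prec = m[["prec"]],
                    sensy = m[["sensy"]])
  if (!is.null(rnd)) {
    rec$mcc_rnd <- rnd[["mcc"]]
    rec$mcc_corr <- correctedMetric(m[["mcc"]], rnd[["mcc"]])
    rec$prec_corr <- correctedMetric(m[["prec"]], rnd[["prec"]])
    rec$sensy_corr <- correctedMetric(m[["sensy"]], rnd[["sensy"]])
  }
  rec
}

#' Metric scan of one prediction set across the cutoff ladder
#'
#' Holds the prediction set fixed and evaluates it against the contact map
#' at every ladder cutoff, optionally with a random-baseline correction
#' whose set size matches the predictor's pair count.
#'
#' @param pred a [PredictionSet-class]
#' @param dm distance matrix of the target structure
#' @param cutoffs increasing cutoff ladder
#'   (default [contactLadderCutoffs()])
#' @param rnd NULL for no correction, or list(nReps =, seed =); each
#'   cutoff uses seed + its ladder rank so repetitions are independent yet
#'   reproducible
#' @return a [CutoffScan-class]
#' @export
metricScan <- function(pred, dm, cutoffs = contactLadderCutoffs(),
                       rnd = NULL) {
  if (length(cutoffs) == 0L || any(diff(cutoffs) <= 0))
    stop("cutoffs must be a non-empty increasing vector")
  k <- nrow(predictionPairs(pred))
  recs <- lapply(seq_along(cutoffs), function(ci) {
    cm <- contactMap(dm, cutoffs[ci])
    counts <- confusionCounts(pred, cm)
    base <- if (is.null(rnd)) NULL
            else randomBaseline(cm, k, nReps = rnd$nReps %||% 100L,
                                seed = rnd$seed + ci)
    scanRecord(cutoffs[ci], counts, base)
  })
  meta <- if (is.null(rnd)) list()
          else list(nReps = rnd$nReps %||% 100L, seed = rnd$seed, k = k)
  new("CutoffScan", method = methodLabel(pred),
      records = do.call(rbind, recs), rndMeta = meta)
}

#' Build a CutoffScan from externally tabulated confusion counts
#'
#' Recomputes every metric from tp/fp/fn/tn columns, e.g. from a published
#' benchmark table, so peak extraction and metric checks run on printed
#' counts exactly as they do on counts the package derives itself.
#'
#' @param method predictor label
#' @param counts data.frame with columns cutoff, tp, fp, fn, tn (cutoffs
#'   increasing)
#' @return a [CutoffScan-class]
#' @export
scanFromCounts <- function(method, counts) {
  need <- c("cutoff", "tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  counts <- counts[order(counts$cutoff), , drop = FALSE]
  recs <- lapply(seq_len(nrow(counts)), function(r) {
    cc <- c(tp = counts$tp[r], fp = counts$fp[r],
            fn = counts$fn[r], tn = counts$tn[r])
    scanRecord(counts$cutoff[r], cc)
  })
  new("CutoffScan", method = method, records = do.call(rbind, recs),
      rndMeta = list())
}

#' Calibrate the score band of a range predictor
#'
#' Scans a grid of band centers: for each center the range predictor is
#' built and its MCC evaluated at each calibration cutoff (defaults 6 and
#' 10 A).  Returns the per-cutoff optima, whether they agree, and the
#' number of selected positions and proposed pairs ("hits") per center.
#'
#' @param scores per-position score vector
#' @param dm distance matrix
#' @param centers grid of band centers
#' @param halfWidth band half-width (default 0.05)
#' @param cutoffs calibration cutoffs (default c(6, 10))
#' @return list with \code{table} (center x cutoff MCC plus hit counts),
#'   \code{bestPerCutoff} (named vector of optimal centers),
#'   \code{agree} (logical), \code{best} (optimal center at the first
#'   calibration cutoff, the operating point)
#' @export
calibrateRange <- function(scores, dm, centers, halfWidth = 0.05,
                           cutoffs = c(6, 10)) {
  if (length(centers) == 0L)
    stop("centers grid must be non-empty")
  cms <- lapply(cutoffs, function(ct) contactMap(dm, ct))
  rows <- lapply(centers, function(ce) {
    pred <- suppressMessages(rangePredict(scores, ce, halfWidth))
    hits <- nrow(predictionPairs(pred))
    mccs <- vapply(cms, function(cm)
      suppressMessages(mcc(confusionCounts(pred, cm))), numeric(1L))
    c(center = ce, n_selected = length(selectPositionsQuiet(scores, ce,
                                                            halfWidth)),
      hits = hits, stats::setNames(mccs, sprintf("mcc_%g", cutoffs)))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  if (all(tab$hits == 0))
    stop("every center produced an empty selection; widen the grid or band")
  best <- vapply(sprintf("mcc_%g", cutoffs), function(cl) {
    tab$center[which.max(tab[[cl]])]
  }, numeric(1L))
  names(best) <- sprintf("%g", cutoffs)
  list(table = tab, bestPerCutoff = best,
       agree = length(unique(best)) == 1L, best = best[[1L]])
}

selectPositionsQuiet <- function(scores, center, halfWidth)
  suppressMessages(selectPositions(scores, center, halfWidth))

#' Characteristic contact distance(s) of a metric profile
#'
#' The primary peak is the ladder cutoff maximizing MCC (ties resolved to
#' the smaller cutoff).  Secondary peaks are interior local maxima of the
#' profile reaching at least \code{secondaryFrac} of the primary MCC,
#' excluding the primary itself.  The profile is flagged erratic when the
#' primary MCC falls below \code{erraticFloor} or the primary sits on a
#' ladder boundary (the true optimum may lie outside the scanned range).
#'
#' @param scan a [CutoffScan-class]
#' @param erraticFloor minimum primary MCC for a trustworthy profile
#'   (default 0.10)
#' @param secondaryFrac fraction of the primary MCC a secondary peak must
#'   reach (default 0.5)
#' @return a [PeakSummary-class]
#' @export
findPeaks <- function(scan, erraticFloor = 0.10, secondaryFrac = 0.5) {
  rec <- scanTable(scan)
  v <- rec$mcc
  nl <- length(v)
  pi <- which.max(v)          # which.max takes the first (smaller cutoff) tie
  primary <- rec$cutoff[pi]
  primaryMcc <- v[pi]
  secondary <- numeric()
  if (nl >= 3L) {
    for (i in 2:(nl - 1L)) {
      if (i == pi) next
      localMax <- v[i] >= v[i - 1L] && v[i] >= v[i + 1L] &&
        (v[i] > v[i - 1L] || v[i] > v[i + 1L])
      if (localMax && v[i] >= secondaryFrac * primaryMcc)
        secondary <- c(secondary, rec$cutoff[i])
    }
  }
  erratic <- primaryMcc < erraticFloor || pi == 1L || pi == nl
  new("PeakSummary", method = methodLabel(scan), primary = primary,
      primaryMcc = primaryMcc, secondary = secondary, erratic = erratic)
}

#' Write a metric scan as a report-style TSV
#'
#' Columns mirror the benchmark report layout (method, cutoff, TP, FP,
#' FN, TN, MCC, ACCY, PREC, SENSY and corrected columns when present),
#' with MCC rounded to 4 decimals and the other metrics to 3.  A comment
#' header records the provenance passed in.
#'
#' @param scan a [CutoffScan-class]
#' @param path output file
#' @param provenance named character vector written as "# key: value"
#'   header lines
#' @return invisibly, the path
#' @export
writeMetricScan <- function(scan, path, provenance = character()) {
  rec <- scanTable(scan)
  out <- data.frame(method = methodLabel(scan), cutoff = rec$cutoff,
                    tp = rec$tp, fp = rec$fp, fn = rec$fn, tn = rec$tn,
                    mcc = sprintf("%.4f", rec$mcc),
                    accy = sprintf("%.3f", rec$accy),
                    prec = sprintf("%.3f", rec$prec),
                    sensy = sprintf("%.3f", rec$sensy))
  if (!is.null(rec$mcc_corr))
    out$mcc_corr <- sprintf("%.4f", rec$mcc_corr)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
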