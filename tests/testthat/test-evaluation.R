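toyMap <- function(n = 20L, cutoff = 8, seed = 3L) {
  set.seed(seed)
  co <- data.frame(resno = seq_len(n), x = runif(n, 0, 18),
                   y = runif(n, 0, 18), z = runif(n, 0, 18))
  list(dm = distanceMatrix(co), cm = contactMap(distanceMatrix(co), cutoff))
}

test_that("confusion counts match exhaustive enumeration and conserve the universe", {
  t <- toyMap()
  # perfect predictor
  perfect <- ContactLadder:::newPredictionSet("P", contactPairs(t$cm), "t")
  cc <- confusionCounts(perfect, t$cm)
  expect_equal(cc[["fp"]], 0L); expect_equal(cc[["fn"]], 0L)
  expect_equal(cc[["tp"]], nContacts(t$cm))
  # empty predictor
  none <- pairsFromSelection(integer(0))
  cc0 <- confusionCounts(none, t$cm)
  expect_equal(cc0[["tp"]] + cc0[["fp"]], 0L)
  expect_equal(cc0[["fn"]], nContacts(t$cm))
  # random predictors vs brute-force oracle over all 190 pairs
  for (s in 1:5) {
    pred <- randomPrediction(20L, 25L, seed = s)
    cc <- confusionCounts(pred, t$cm)
    expect_equal(cc[c("tp", "fp", "fn", "tn")], bruteForceConfusion(pred, t$cm))
    expect_equal(sum(cc), 190)
  }
  bad <- ContactLadder:::newPredictionSet("B", cbind(1L, 99L), "t")
  expect_error(confusionCounts(bad, t$cm), "99")
})

test_that("metric formulas reproduce published benchmark rows", {
  cc <- function(tp, fp, fn, tn) {
    out <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    attr(out, "universe") <- tp + fp + fn + tn
    out
  }
  expect_equal(round(mcc(cc(102, 487, 109, 6805)), 4), 0.2561)
  expect_equal(round(mcc(cc(146, 1123, 130, 6104)), 4), 0.1876)
  expect_equal(mcc(cc(10, 0, 0, 50)), 1)
  expect_equal(round(accuracyReport(cc(102, 487, 109, 6805)), 3), 0.893)
  expect_equal(round(accuracyReport(cc(7, 54, 938, 6504)), 3), 0.866)
  expect_equal(accuracyReport(cc(5, 1, 2, 5)), 0)   # tp = tn
  expect_equal(accuracyStd(cc(102, 487, 109, 6805)), (102 + 6805) / 7503)
  expect_equal(round(precisionScore(cc(120, 501, 66, 6816)), 3), 0.193)
  expect_equal(round(sensitivityScore(cc(120, 501, 66, 6816)), 3), 0.645)
  expect_equal(round(sensitivityScore(cc(7, 61, 23, 7412)), 3), 0.233)
  expect_equal(as.numeric(precisionScore(cc(0, 61, 88, 7354))), 0)
  # undefined cases flagged, reported as 0
  pu <- precisionScore(cc(0, 0, 10, 90))
  expect_equal(as.numeric(pu), 0); expect_true(attr(pu, "undefined"))
  su <- sensitivityScore(cc(0, 10, 0, 90))
  expect_equal(as.numeric(su), 0); expect_true(attr(su, "undefined"))
  # zero-denominator convention
  expect_message(z <- mcc(cc(0, 0, 10, 90)), "zero factor")
  expect_equal(z, 0)
})

test_that("random baseline obeys degenerate cases and the hypergeometric mean", {
  t <- toyMap()
  u <- universeSize(t$cm); nc <- nContacts(t$cm)
  b0 <- randomBaseline(t$cm, k = 0L, nReps = 10L, seed = 1L)
  expect_equal(b0[["mcc"]], 0)
  bAll <- randomBaseline(t$cm, k = as.integer(u), nReps = 5L, seed = 1L)
  expect_equal(bAll[["sensy"]], 1)
  expect_error(randomBaseline(t$cm, k = as.integer(u) + 1L, nReps = 2L,
                              seed = 1L), "k must be")
  expect_error(randomBaseline(t$cm, k = 5L, nReps = 10L), "seed")
  # E(tp) = k * |contacts| / universe  => E(sensy) = k / universe
  b <- randomBaseline(t$cm, k = 40L, nReps = 500L, seed = 2L)
  se <- attr(b, "sd")[["sensy"]] / sqrt(500)
  expect_lt(abs(b[["sensy"]] - 40 / u), 4 * se)
  # reproducibility
  expect_equal(as.numeric(randomBaseline(t$cm, 30L, 50L, seed = 9L)),
               as.numeric(randomBaseline(t$cm, 30L, 50L, seed = 9L)))
  expect_equal(correctedMetric(0.30, 0.05), 0.25)
  expect_equal(correctedMetric(0.30, 0), 0.30)
})

test_that("metric scan equals independent per-cutoff recomputation", {
  sp <- defaultSynth()
  dm <- distanceMatrix(sp@coords)
  pred <- randomPrediction(nrow(dm), 200L, seed = 4L)
  scan <- metricScan(pred, dm)
  st <- scanTable(scan)
  expect_equal(st$cutoff, contactLadderCutoffs())
  for (r in seq_len(nrow(st))) {   # no-caching oracle
    cc <- confusionCounts(pred, contactMap(dm, st$cutoff[r]))
    expect_equal(st$tp[r], cc[["tp"]])
    expect_equal(st$mcc[r], suppressMessages(mcc(cc)))
    expect_equal(sum(cc), universeSize(contactMap(dm, st$cutoff[r])))
  }
  expect_true(all(diff(st$tp + st$fn) >= 0))  # nested maps
  # empty predictor scans to all-zero MCC
  st0 <- scanTable(metricScan(pairsFromSelection(integer(0)), dm))
  expect_true(all(st0$mcc == 0))
  expect_error(metricScan(pred, dm, cutoffs = c(6, 4)), "increasing")
})

test_that("perfect predictor peaks exactly at its construction cutoff", {
  t <- toyMap(cutoff = 8)
  perfect <- ContactLadder:::newPredictionSet("P", contactPairs(t$cm), "t")
  scan <- metricScan(perfect, t$dm)
  st <- scanTable(scan)
  expect_equal(st$mcc[st$cutoff == 8], 1)
  expect_equal(primaryPeak(findPeaks(scan)), 8)
})

test_that("scan with RND correction reproduces deterministically and centers random predictors at 0", {
  t <- toyMap()
  pred <- randomPrediction(20L, 30L, seed = 6L)
  s1 <- metricScan(pred, t$dm, cutoffs = c(6, 8, 10),
                   rnd = list(nReps = 200L, seed = 11L))
  s2 <- metricScan(pred, t$dm, cutoffs = c(6, 8, 10),
                   rnd = list(nReps = 200L, seed = 11L))
  expect_equal(scanTable(s1), scanTable(s2))
  # a random predictor's corrected MCC is within Monte-Carlo noise of 0
  expect_true(all(abs(scanTable(s1)$mcc_corr) < 0.2))
})

test_that("range calibration recovers a planted optimum", {
  sp <- defaultSynth()
  dm <- distanceMatrix(sp@coords)
  n <- nrow(dm)
  # plant scores: contacts live among positions scored ~0.30
  core <- which(sp@burial == "core")
  sc <- rep(0.8, n); sc[core] <- 0.30
  cal <- calibrateRange(sc, dm, centers = seq(0.1, 0.9, by = 0.1))
  expect_equal(unname(cal$bestPerCutoff[["6"]]), 0.3)
  expect_equal(unname(cal$bestPerCutoff[["10"]]), 0.3)
  expect_true(cal$agree)
  expect_equal(cal$best, 0.3)
  expect_named(cal$table, c("center", "n_selected", "hits", "mcc_6", "mcc_10"))
  # single-center grid returns that center
  one <- calibrateRange(sc, dm, centers = 0.5, halfWidth = 0.25)
  expect_equal(one$best, 0.5)
  expect_error(calibrateRange(sc, dm, centers = c(10, 20)), "empty")
})

test_that("peak extraction follows the tie, secondary and erratic rules", {
  mkscan <- function(mccs, cutoffs = seq_along(mccs)) {
    rec <- data.frame(cutoff = cutoffs, tp = 1L, fp = 1L, fn = 1L, tn = 1L,
                      mcc = mccs, accy = 0, accy_std = 0, prec = 0, sensy = 0)
    new("CutoffScan", method = "T", records = rec, rndMeta = list())
  }
  pk <- findPeaks(mkscan(c(0.1, 0.5, 0.2, 0.4, 0.1)))
  expect_equal(primaryPeak(pk), 2)
  expect_equal(secondaryPeaks(pk), 4)   # interior local max >= 50% of primary
  expect_false(isErratic(pk))
  # tie resolves to the smaller cutoff
  expect_equal(primaryPeak(findPeaks(mkscan(c(0.1, 0.5, 0.5, 0.2, 0.1)))), 2)
  # weak secondary (< 50% of primary) excluded
  expect_length(secondaryPeaks(findPeaks(mkscan(c(0.1, 0.6, 0.1, 0.2, 0.1)))), 0L)
  # monotone profile: boundary peak -> erratic
  expect_true(isErratic(findPeaks(mkscan(c(0.1, 0.2, 0.3, 0.4, 0.5)))))
  # weak primary -> erratic
  expect_true(isErratic(findPeaks(mkscan(c(0.01, 0.05, 0.02, 0.03, 0.01)))))
})

test_that("report writer mirrors the benchmark table layout", {
  b <- benchmarkCounts1a4v()
  scan <- scanFromCounts("KOL", b[b$method == "KOL", ])
  f <- tempfile(fileext = ".tsv")
  writeMetricScan(scan, f, provenance = c(target = "1a4v"))
  lines <- readLines(f)
  expect_match(lines[1L], "# target: 1a4v")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 9L)
  expect_equal(tab$mcc[tab$cutoff == 10], 0.2561)
  expect_equal(tab$accy[tab$cutoff == 10], 0.893)
})
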