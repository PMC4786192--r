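## Cross-method comparison: assemble per-method metric profiles over
## (protein, cutoff) observations and run a PCA of the methods plus the
## cutoff itself as variables.

#' Assemble a profile matrix from per-method cutoff scans
#'
#' Rows are (protein, cutoff) observations; columns are one metric per
#' method plus the cutoff as an additional variable, so the PCA can place
#' each method relative to the distance scale.  All scans must share the
#' same cutoff ladder.  Observations with a missing cell are dropped with
#' a warning.
#'
#' @param scans nested list: \code{scans[[protein]][[method]]} is a
#'   [CutoffScan-class]; all proteins must carry the same methods
#' @param metric which column of the scan records to use ("mcc_corr" when
#'   the scans were RND-corrected, otherwise "mcc")
#' @return numeric matrix with columns = methods + "cutoff", rownames
#'   "protein:cutoff"; attribute \code{"metric"} records the choice
#' @export
assembleProfiles <- function(scans, metric = c("mcc_corr", "mcc")) {
  metric <- match.arg(metric)
  proteins <- names(scans)
  methods <- names(scans[[1L]])
  ladder <- scanTable(scans[[1L]][[1L]])$cutoff
  rows <- list()
  for (p in proteins) {
    if (!identical(sort(names(scans[[p]])), sort(methods)))
      stop("protein '", p, "' does not carry the same methods")
    vals <- sapply(methods, function(m) {
      rec <- scanTable(scans[[p]][[m]])
      if (!identical(rec$cutoff, ladder))
        stop("cutoff ladder mismatch for protein '", p, "', method '",
             m, "'")
      col <- rec[[metric]]
      if (is.null(col))
        stop("scan for '", m, "' has no '", metric,
             "' column (was it RND-corrected?)")
      col
    })
    block <- cbind(vals, cutoff = ladder)
    rownames(block) <- paste0(p, ":", sprintf("%g", ladder))
    rows[[p]] <- block
  }
  m <- do.call(rbind, rows)
  bad <- !stats::complete.cases(m)
  if (any(bad)) {
    warning(sum(bad), " observation(s) with missing cells dropped: ",
            paste(rownames(m)[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  attr(m, "metric") <- metric
  m
}

#' PCA of the method profile matrix
#'
#' Correlation-mode PCA (variables centered and unit-scaled) by singular
#' value decomposition via \code{stats::prcomp}.  Zero-variance columns
#' are dropped with a warning.  Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so results are
#' fully deterministic.
#'
#' @param m profile matrix from [assembleProfiles()] (or any numeric
#'   matrix, observations x variables)
#' @param nComponents number of components to keep (default: all)
#' @param scale unit-scale the variables (correlation PCA, the default);
#'   set FALSE for covariance PCA
#' @return list with \code{loadings} (variables x components),
#'   \code{scores} (observations x components), \code{varExplained}
#'   (fractions, summing to 1 over all components of the full
#'   decomposition), \code{sdev}
#' @export
pcaProfiles <- function(m, nComponents = NULL, scale = TRUE) {
  m <- as.matrix(m)
  v <- apply(m, 2L, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[v == 0], collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  varExplained <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents %||% ncol(pc$rotation), ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| of each component is positive
  for (cj in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, cj])), cj])
    if (s < 0) {
      load[, cj] <- -load[, cj]
      scores[, cj] <- -scores[, cj]
    }
  }
  list(loadings = load, scores = scores,
       varExplained = varExplained[seq_len(k)],
       varExplainedAll = varExplained, sdev = pc$sdev)
}

#' Angle between two variables' loading vectors (degrees)
#'
#' Measures, in the plane (or space) of the kept components, how two
#' variables co-load: ~0 degrees = aligned, ~90 = orthogonal, ~180 =
#' antiparallel.  Used to read the PCA geometry quantitatively (e.g.
#' conservation-driven methods near-antiparallel to the cutoff variable,
#' likelihood-matrix methods near-orthogonal to it).
#'
#' @param pca result of [pcaProfiles()]
#' @param a,b variable names (rows of the loading matrix)
#' @param components which components to use (default first two)
#' @return angle in degrees, in [0, 180]
#' @export
loadingAngle <- function(pca, a, b, components = 1:2) {
  va <- pca$loadings[a, components]
  vb <- pca$loadings[b, components]
  ct <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Write PCA outputs (loadings, scores, explained variance) as TSVs
#'
#' @param pca result of [pcaProfiles()]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the three file paths
#' @export
writePcaResult <- function(pca, dir, prefix = "pca") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("loadings", "scores", "variance"),
                                 ".tsv"))
  utils::write.table(round(pca$loadings, 6), paths[1L], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(round(pca$scores, 6), paths[2L], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(
    data.frame(component = seq_along(pca$varExplainedAll),
               var_explained = round(pca$varExplainedAll, 6)),
    paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
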