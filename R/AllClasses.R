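#' @import methods
NULL

#' ContactMap: residue pairs in spatial contact at one distance cutoff
#'
#' Holds the set of unordered residue pairs (i < j) whose CA atoms lie
#' within \code{cutoff} angstroms of one another, together with the number
#' of residues, from which the pair universe n(n-1)/2 follows.  No
#' sequence-separation filter is applied: adjacent residues are legitimate
#' pairs, so TP+FP+FN+TN always equals n(n-1)/2 downstream.
#'
#' @slot cutoff distance cutoff in angstroms (contact test is d <= cutoff)
#' @slot contacts integer matrix with two columns (i, j), i < j; zero rows
#'   allowed
#' @slot n number of residues in the structure
#'
#' @seealso [contactMap()], [universeSize()], [contactPairs()]
#' @exportClass ContactMap
setClass("ContactMap",
  slots = c(cutoff = "numeric", contacts = "matrix", n = "integer"))

setValidity("ContactMap", function(object) {
  msg <- character()
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    msg <- c(msg, "cutoff must be a single positive number")
  if (length(object@n) != 1L || object@n < 1L)
    msg <- c(msg, "n must be a single positive integer")
  cm <- object@contacts
  if (ncol(cm) != 2L)
    msg <- c(msg, "contacts must have two columns (i, j)")
  if (nrow(cm) > 0L) {
    if (any(cm[, 1L] >= cm[, 2L]))
      msg <- c(msg, "contact pairs must satisfy i < j")
    if (any(cm < 1L) || any(cm > object@n))
      msg <- c(msg, "contact indices out of 1..n")
    if (anyDuplicated(paste(cm[, 1L], cm[, 2L])))
      msg <- c(msg, "duplicate contact pairs")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionSet: candidate contacting residue pairs from one method
#'
#' @slot method label for the predictor (e.g. "CMA", "KOL", "VRN", "P2P",
#'   "SVB", or any other label)
#' @slot pairs integer matrix with two columns (i, j), i < j, de-duplicated
#' @slot provenance free-text record of how the set was produced (score
#'   range, file read, threshold, ...)
#'
#' @seealso [pairsFromSelection()], [svbPredict()],
#'   [readExternalPredictions()]
#' @exportClass PredictionSet
setClass("PredictionSet",
  slots = c(method = "character", pairs = "matrix", provenance = "character"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  if (length(object@method) != 1L)
    msg <- c(msg, "method must be a single label")
  p <- object@pairs
  if (ncol(p) != 2L)
    msg <- c(msg, "pairs must have two columns (i, j)")
  if (nrow(p) > 0L) {
    if (any(p[, 1L] >= p[, 2L]))
      msg <- c(msg, "pairs must satisfy i < j")
    if (any(p < 1L))
      msg <- c(msg, "pair indices must be >= 1")
    if (anyDuplicated(paste(p[, 1L], p[, 2L])))
      msg <- c(msg, "duplicate pairs")
  }
  if (length(msg)) msg else TRUE
})

#' CutoffScan: confusion-matrix metrics across the distance-cutoff ladder
#'
#' One row per cutoff with the confusion counts (tp, fp, fn, tn), the four
#' report metrics (mcc, accy, accy_std, prec, sensy) and, when a random
#' baseline was requested, the baseline means and corrected values
#' (columns suffixed \code{_rnd} and \code{_corr}).
#'
#' @slot method predictor label
#' @slot records data.frame, one row per cutoff, cutoffs strictly increasing
#' @slot rndMeta list recording the random-baseline configuration
#'   (nReps, seed) or empty when no correction was computed
#'
#' @seealso [metricScan()], [findPeaks()], [scanFromCounts()]
#' @exportClass CutoffScan
setClass("CutoffScan",
  slots = c(method = "character", records = "data.frame", rndMeta = "list"))

setValidity("CutoffScan", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("cutoff", "mcc")
  if (!all(need %in% names(rec)))
    msg <- c(msg, "records must contain at least 'cutoff' and 'mcc' columns")
  else if (nrow(rec) > 1L && any(diff(rec$cutoff) <= 0))
    msg <- c(msg, "cutoffs must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' PeakSummary: characteristic contact distance(s) of a predictor
#'
#' The primary peak is the cutoff at which the MCC profile attains its
#' maximum (ties resolved to the smaller cutoff); secondary peaks are
#' interior local maxima reaching at least a configurable fraction of the
#' primary MCC.  The erratic flag mirrors profiles whose maximum is weak or
#' sits on a ladder boundary.
#'
#' @slot method predictor label
#' @slot primary primary peak cutoff (angstroms)
#' @slot primaryMcc MCC at the primary peak
#' @slot secondary secondary peak cutoffs (possibly empty)
#' @slot erratic logical flag
#'
#' @seealso [findPeaks()]
#' @exportClass PeakSummary
setClass("PeakSummary",
  slots = c(method = "character", primary = "numeric", primaryMcc = "numeric",
            secondary = "numeric", erratic = "logical"))

#' SyntheticProtein: coupled structure/alignment fixture with known truth
#'
#' @slot coords data.frame with columns resno, x, y, z (CA positions, one
#'   per residue)
#' @slot burial character vector, "core"/"surface" per residue
#' @slot contacts ContactMap at the generator's contact radius (the ground
#'   truth)
#' @slot aln Biostrings::AAStringSet, alignment of depth nSequences with
#'   one column per residue
#' @slot config the GeneratorConfig list used
#'
#' @seealso [generateSyntheticProtein()], [generatorConfig()]
#' @exportClass SyntheticProtein
setClass("SyntheticProtein",
  slots = c(coords = "data.frame", burial = "character",
            contacts = "ContactMap", aln = "ANY", config = "list"))

setValidity("SyntheticProtein", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (length(object@burial) != n)
    msg <- c(msg, "burial must have one class per residue")
  if (!all(object@burial %in% c("core", "surface")))
    msg <- c(msg, "burial classes must be 'core' or 'surface'")
  if (length(msg)) msg else TRUE
})

## ---- generics and accessors -------------------------------------------

#' @describeIn ContactMap number of contacting pairs
#' @param object a ContactMap
#' @export
setGeneric("nContacts", function(object) standardGeneric("nContacts"))
setMethod("nContacts", "ContactMap", function(object) nrow(object@contacts))

#' Pair universe size n(n-1)/2
#' @param object a ContactMap
#' @export
setGeneric("universeSize", function(object) standardGeneric("universeSize"))
setMethod("universeSize", "ContactMap",
  function(object) as.numeric(object@n) * (object@n - 1) / 2)

#' Contact pairs as a two-column integer matrix (i < j)
#' @param object a ContactMap
#' @export
setGeneric("contactPairs", function(object) standardGeneric("contactPairs"))
setMethod("contactPairs", "ContactMap", function(object) object@contacts)

#' Distance cutoff (angstroms) of a ContactMap
#' @param object a ContactMap
#' @export
setGeneric("cutoffValue", function(object) standardGeneric("cutoffValue"))
setMethod("cutoffValue", "ContactMap", function(object) object@cutoff)

#' Predicted pairs as a two-column integer matrix (i < j)
#' @param object a PredictionSet
#' @export
setGeneric("predictionPairs",
  function(object) standardGeneric("predictionPairs"))
setMethod("predictionPairs", "PredictionSet", function(object) object@pairs)

#' Predictor label of an object
#' @param object a PredictionSet, CutoffScan or PeakSummary
#' @export
setGeneric("methodLabel", function(object) standardGeneric("methodLabel"))
setMethod("methodLabel", "PredictionSet", function(object) object@method)
setMethod("methodLabel", "CutoffScan", function(object) object@method)
setMethod("methodLabel", "PeakSummary", function(object) object@method)

#' Per-cutoff metric table of a CutoffScan
#' @param object a CutoffScan
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))
setMethod("scanTable", "CutoffScan", function(object) object@records)

#' Primary characteristic contact distance
#' @param object a PeakSummary
#' @export
setGeneric("primaryPeak", function(object) standardGeneric("primaryPeak"))
setMethod("primaryPeak", "PeakSummary", function(object) object@primary)

#' Secondary peak cutoffs
#' @param object a PeakSummary
#' @export
setGeneric("secondaryPeaks",
  function(object) standardGeneric("secondaryPeaks"))
setMethod("secondaryPeaks", "PeakSummary", function(object) object@secondary)

#' Erratic-profile flag
#' @param object a PeakSummary
#' @export
setGeneric("isErratic", function(object) standardGeneric("isErratic"))
setMethod("isErratic", "PeakSummary", function(object) object@erratic)

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: %d residues, cutoff %.1f A, %d/%d pairs in contact\n",
              object@n, object@cutoff, nrow(object@contacts),
              universeSize(object)))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet [%s]: %d pairs\n  provenance: %s\n",
              object@method, nrow(object@pairs), object@provenance))
})

setMethod("show", "CutoffScan", function(object) {
  cat(sprintf("CutoffScan [%s]: %d cutoffs (%.1f..%.1f A)%s\n",
              object@method, nrow(object@records),
              min(object@records$cutoff), max(object@records$cutoff),
              if (length(object@rndMeta)) ", RND-corrected" else ""))
  print(utils::head(object@records, 4L))
  if (nrow(object@records) > 4L) cat("  ...\n")
})

setMethod("show", "PeakSummary", function(object) {
  cat(sprintf("PeakSummary [%s]: primary %.1f A (MCC %.4f)%s%s\n",
              object@method, object@primary, object@primaryMcc,
              if (length(object@secondary))
                paste0(", secondary ",
                       paste(sprintf("%.1f", object@secondary),
                             collapse = " ")) else "",
              if (object@erratic) " [erratic]" else ""))
})

setMethod("show", "SyntheticProtein", function(object) {
  cat(sprintf(
    "SyntheticProtein: %d residues (%d core), depth-%d alignment, contact radius %.1f A\n",
    nrow(object@coords), sum(object@burial == "core"),
    length(object@aln), object@config$contactRadius))
})
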