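#' Published benchmark confusion counts for alpha-lactalbumin (1a4v)
#'
#' Confusion counts (TP, FP, FN, TN) for five contact predictors (SVB,
#' P2P, KOL, VRN, CMA) evaluated against CA-CA contact maps of the
#' 123-residue alpha-lactalbumin domain (PDB 1a4v) at nine distance
#' cutoffs (4-20 A), together with the metric values printed in the
#' original benchmark report (columns suffixed \code{_ref}).  Every row's
#' counts sum to C(123, 2) = 7503, the full pair universe.  Shipped as a
#' plain-text fixture so the package's metric and peak machinery can be
#' validated against published numbers without any downloads.
#'
#' @return data.frame with columns method, cutoff, tp, fp, fn, tn,
#'   mcc_ref, accy_ref, prec_ref, sensy_ref, mcc_corr_ref
#' @examples
#' b <- benchmarkCounts1a4v()
#' subset(b, method == "KOL" & cutoff == 10)
#' @export
benchmarkCounts1a4v <- function() {
  path <- system.file("extdata", "benchmark_1a4v_counts.tsv",
                      package = "ContactLadder", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
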