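# shared fixture builders; everything is generated in code at test time

twenty <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

writeFastaLines <- function(seqs, path, names = sprintf("s%d", seq_along(seqs))) {
  writeLines(as.vector(rbind(paste0(">", names), seqs)), path)
  path
}

# minimal fixed-column PDB ATOM writer for reader tests
pdbAtomLine <- function(eleno, resno, x, y, z, chain = "A", altloc = " ",
                        occ = 1.00, resid = "ALA", elety = " CA ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          eleno, elety, altloc, resid, chain, resno, " ", x, y, z, occ, 0.0)
}

writeToyPdb <- function(lines, path) {
  writeLines(c(lines, "END"), path)
  path
}

# the default-condition synthetic protein, generated once per test run
defaultSynth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateSyntheticProtein(generatorConfig(seed = 42L))
    cache
  }
})

# k distinct random pairs over 1..n as a PredictionSet
randomPrediction <- function(n, k, seed, method = "RANDOM") {
  set.seed(seed)
  all <- t(utils::combn(n, 2L))
  idx <- sample.int(nrow(all), k)
  p <- all[idx, , drop = FALSE]
  ContactLadder:::newPredictionSet(method, p, "random fixture")
}

# brute-force confusion oracle: enumerate every unordered pair
bruteForceConfusion <- function(pred, cm) {
  n <- cm@n
  predKey <- paste(predictionPairs(pred)[, 1L], predictionPairs(pred)[, 2L])
  ctcKey <- paste(contactPairs(cm)[, 1L], contactPairs(cm)[, 2L])
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    key <- paste(i, j)
    p <- key %in% predKey
    c <- key %in% ctcKey
    if (p && c) tp <- tp + 1L else if (p) fp <- fp + 1L
    else if (c) fn <- fn + 1L else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
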