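test_that("readAlignment validates alignment structure", {
  f <- tempfile(fileext = ".fasta")
  writeFastaLines(c("ACD", "ACE"), f)
  aln <- readAlignment(f)
  expect_s4_class(aln, "AAStringSet")
  expect_length(aln, 2L)
  expect_equal(unique(Biostrings::width(aln)), 3L)
  expect_equal(names(aln), c("s1", "s2"))

  writeFastaLines("ACD", f)
  expect_error(readAlignment(f), ">=2 sequences")

  writeFastaLines(c("ACD", "ACDE"), f, names = c("ok", "long"))
  expect_error(readAlignment(f), "long")

  writeLines(character(), f)
  expect_error(readAlignment(f))
  expect_error(readAlignment(tempfile()), "not found")
})

test_that("column profiles count only standard residues", {
  m <- matrix(c("A", "A", "A", "A",
                "A", "A", "-", "-",
                "A", "C", "D", "E",
                "X", "-", ".", "B"), nrow = 4L)
  p1 <- columnProfile(m, 1L)
  expect_equal(p1$counts, c(A = 4L))
  expect_equal(p1$nUngapped, 4L)
  p2 <- columnProfile(m, 2L)
  expect_equal(p2$counts, c(A = 2L))
  expect_equal(p2$nUngapped, 2L)
  p3 <- columnProfile(m, 3L)
  expect_equal(sort(names(p3$counts)), c("A", "C", "D", "E"))
  expect_true(all(p3$counts == 1L))
  p4 <- columnProfile(m, 4L)   # gaps, X and ambiguity codes all excluded
  expect_equal(p4$nUngapped, 0L)
  expect_error(columnProfile(m, 5L), "out of range")
  expect_error(columnProfile(m, 0L), "out of range")
})

test_that("entropy and variability match hand-computed values", {
  p <- function(col) columnProfile(matrix(col, ncol = 1L), 1L)
  expect_equal(shannonEntropy(p(rep("A", 4L))), 0)
  expect_equal(shannonEntropy(p(c("A", "A", "C", "C"))), 1)
  expect_equal(shannonEntropy(p(twenty)), log2(20))
  expect_true(is.na(shannonEntropy(p(rep("-", 3L)))))

  expect_equal(variability(p(rep("A", 4L))), 1)
  expect_equal(variability(p(c("A", "A", "C", "C"))), 2)
  expect_equal(variability(p(twenty)), 20)
  expect_equal(variability(p(twenty), normalize = TRUE), 1)
  expect_true(is.na(variability(p(rep("-", 3L)))))
})

test_that("entropy bound log2(min(20, n)) holds on random columns", {
  set.seed(31)
  for (r in 1:20) {
    depth <- sample(2:40, 1L)
    col <- sample(twenty, depth, replace = TRUE)
    h <- shannonEntropy(columnProfile(matrix(col, ncol = 1L), 1L))
    expect_gte(h, 0)
    expect_lte(h, log2(min(20, depth)) + 1e-12)
  }
})

test_that("ENT and VAR are depth-duplication invariant and zero iff constant", {
  set.seed(7)
  m <- matrix(sample(c(twenty, "-"), 30L * 8L, replace = TRUE), nrow = 30L)
  m2 <- rbind(m, m)
  for (pos in 1:8) {
    pa <- columnProfile(m, pos); pb <- columnProfile(m2, pos)
    expect_equal(shannonEntropy(pa), shannonEntropy(pb))
    expect_equal(variability(pa), variability(pb))
    if (!is.na(shannonEntropy(pa)))
      expect_equal(shannonEntropy(pa) == 0, variability(pa) == 1)
  }
})

test_that("complexity score separates constant from mixed columns (frozen regression)", {
  constCol <- matrix("A", nrow = 500L, ncol = 1L)
  set.seed(2024)
  mixedCol <- matrix(sample(twenty, 500L, replace = TRUE), ncol = 1L)
  kConst <- kolmogorovScore(constCol, 1L)
  kMixed <- kolmogorovScore(mixedCol, 1L)
  # frozen values for the default gzip compressor
  expect_equal(kConst, 0.02739726, tolerance = 1e-6)
  expect_equal(kMixed, 0.59686890, tolerance = 1e-6)
  expect_lt(kConst, kMixed)
  expect_gte(kConst, 0); expect_lte(kMixed, 1)
  # monotonicity holds at depth 200 too
  expect_lt(kolmogorovScore(matrix("A", 200L, 1L), 1L),
            kolmogorovScore(matrix(sample(twenty, 200L, TRUE), ncol = 1L), 1L))
})

test_that("complexity score is stable under column permutation (documented tolerance)", {
  set.seed(11)
  col <- sample(rep(c("A", "C", "D", "E", "L", "K"),
                    times = c(80, 50, 30, 20, 15, 5)))
  ks <- vapply(1:20, function(i) {
    set.seed(100 + i)
    kolmogorovScore(matrix(sample(col), ncol = 1L), 1L)
  }, numeric(1L))
  # compressors are order-sensitive; empirical max spread is ~0.033
  expect_lt(max(ks) - min(ks), 0.05)
})

test_that("columnScores flags gappy columns and records the compressor", {
  m <- cbind(rep("A", 10L),
             c(rep("A", 4L), rep("-", 6L)),   # 40% ungapped -> missing
             c(rep("C", 5L), rep("-", 5L)))   # exactly 50% -> kept
  sc <- columnScores(m)
  expect_equal(nrow(sc), 3L)
  expect_equal(attr(sc, "compressor"), "gzip")
  expect_false(anyNA(sc[1L, c("var", "ent", "kol")]))
  expect_true(all(is.na(sc[2L, c("var", "ent", "kol")])))
  expect_equal(sc$ent[3L], 0)
  expect_equal(sc$n_ungapped, c(10L, 4L, 5L))

  f <- tempfile(fileext = ".tsv")
  writeColumnScores(sc, f)
  expect_match(readLines(f, n = 1L), "compressor: gzip")
  back <- utils::read.delim(f, comment.char = "#")
  expect_equal(back$position, 1:3)
})

test_that("synthetic core columns score lower than surface columns", {
  sp <- defaultSynth()
  sc <- columnScores(sp@aln)
  core <- sp@burial == "core"
  for (col in c("ent", "var")) {
    w <- stats::wilcox.test(sc[[col]][core], sc[[col]][!core],
                            alternative = "less", exact = FALSE)
    expect_lt(w$p.value, 1e-6)
  }
  expect_lt(median(sc$kol[core]), median(sc$kol[!core]))
})
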