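test_that("generator config enforces its invariants", {
  expect_s3_class(generatorConfig(), "GeneratorConfig")
  expect_error(generatorConfig(nResidues = 5), ">= 10")
  expect_error(generatorConfig(nSequences = 5), ">= 10")
  expect_error(generatorConfig(coreRate = 0.5, surfaceRate = 0.4), "coreRate")
  expect_error(generatorConfig(conservationCoupling = 1.2), "Coupling")
  expect_error(generatorConfig(contactRadius = -1), "positive")
})

test_that("generated chains respect bond length, self-avoidance and compactness", {
  cfg <- generatorConfig(nResidues = 10L, seed = 3L)
  co <- generateChain(cfg)
  expect_equal(nrow(co), 10L)
  xyz <- as.matrix(co[, c("x", "y", "z")])
  consec <- sqrt(rowSums((xyz[-1L, ] - xyz[-10L, ])^2))
  expect_true(all(abs(consec - 3.8) < 0.2))
  sp <- defaultSynth()
  xyz <- as.matrix(sp@coords[, c("x", "y", "z")])
  n <- nrow(xyz)
  consec <- sqrt(rowSums((xyz[-1L, ] - xyz[-n, ])^2))
  expect_true(all(abs(consec - 3.8) < 0.2))
  dm <- distanceMatrix(sp@coords)
  expect_gte(min(dm[abs(row(dm) - col(dm)) > 1L & upper.tri(dm)]), 3.0)
  # collapsed: radius of gyration below that of an extended chain
  rg <- function(m) sqrt(mean(rowSums(sweep(m, 2L, colMeans(m))^2)))
  extended <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  expect_lt(rg(xyz), rg(extended))
  # deterministic from seed
  expect_equal(generateChain(generatorConfig(seed = 3L)),
               generateChain(generatorConfig(seed = 3L)))
})

test_that("burial classification matches a brute-force neighbour count", {
  # far-apart collinear points: no contacts, everything is surface
  far <- data.frame(resno = 1:3, x = c(0, 50, 100), y = 0, z = 0)
  expect_equal(classifyBurial(far, 8), rep("surface", 3L))
  # dense cluster plus an outlier: the outlier is surface
  set.seed(8)
  clu <- data.frame(resno = 1:11,
                    x = c(rnorm(10, sd = 3), 90),
                    y = c(rnorm(10, sd = 3), 0), z = 0)
  expect_equal(classifyBurial(clu, 8)[11L], "surface")
  # independent double-loop oracle on the synthetic protein
  sp <- defaultSynth()
  r <- sp@config$contactRadius
  co <- sp@coords
  n <- nrow(co)
  counts <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- sqrt(sum((co[i, c("x", "y", "z")] - co[j, c("x", "y", "z")])^2))
    if (d <= r) counts[i] <- counts[i] + 1L
  }
  nCore <- ceiling(n / 3)
  expected <- rep("surface", n)
  expected[order(-counts, seq_len(n))[seq_len(nCore)]] <- "core"
  expected[counts == 0L] <- "surface"
  expect_equal(sp@burial, expected)
  expect_equal(sum(sp@burial == "core"), nCore)
})

test_that("alignment conservation tracks burial as configured", {
  burial <- rep(c("core", "surface"), each = 20L)
  # coreRate 0 and full coupling: core columns perfectly conserved
  cfg <- generatorConfig(nResidues = 40L, nSequences = 60L,
                         coreRate = 0, surfaceRate = 0.4, seed = 5L)
  msa <- generateMsa(burial, cfg)
  expect_length(msa$aln, 60L)
  sc <- columnScores(msa$aln)
  expect_true(all(sc$ent[burial == "core"] == 0))
  expect_gt(median(sc$ent[burial == "surface"]), 1)
  # consensus equals the ancestral sequence on conserved columns
  m <- as.matrix(msa$aln)
  expect_true(all(m[, burial == "core"][1L, ] ==
                  rep(msa$ancestral[burial == "core"], each = 1L)))
  # zero coupling: no core/surface entropy difference
  cfg0 <- generatorConfig(nResidues = 40L, nSequences = 60L,
                          conservationCoupling = 0, seed = 5L)
  sc0 <- columnScores(generateMsa(burial, cfg0)$aln)
  w <- stats::wilcox.test(sc0$ent[burial == "core"],
                          sc0$ent[burial == "surface"], exact = FALSE)
  expect_gt(w$p.value, 0.01)
  # default conditions: conserved core, variable surface
  sp <- defaultSynth()
  scd <- columnScores(sp@aln)
  expect_lt(median(scd$ent[sp@burial == "core"]),
            median(scd$ent[sp@burial == "surface"]))
})

test_that("synthetic fixtures round-trip through the real readers", {
  sp <- generateSyntheticProtein(
    generatorConfig(nResidues = 30L, nSequences = 20L, seed = 12L))
  fa <- tempfile(fileext = ".fasta")
  pdb <- tempfile(fileext = ".pdb")
  writeSyntheticProtein(sp, fa, pdb)
  aln <- readAlignment(fa)
  expect_length(aln, 20L)
  expect_equal(unique(Biostrings::width(aln)), 30L)
  co <- readCaCoordinates(pdb, "A")
  expect_equal(nrow(co), 30L)
  expect_equal(co$x, sp@coords$x, tolerance = 1e-3)  # PDB stores 3 decimals
  expect_equal(bio3d::aa321(attr(co, "resid")), sp@config$ancestral)
})

test_that("the whole synthetic protein is deterministic from its seed", {
  a <- generateSyntheticProtein(generatorConfig(nResidues = 20L,
                                                nSequences = 15L, seed = 9L))
  b <- generateSyntheticProtein(generatorConfig(nResidues = 20L,
                                                nSequences = 15L, seed = 9L))
  expect_equal(a@coords, b@coords)
  expect_equal(as.character(a@aln), as.character(b@aln))
  expect_equal(a@burial, b@burial)
  expect_equal(contactPairs(a@contacts), contactPairs(b@contacts))
})
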