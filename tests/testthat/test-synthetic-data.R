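# Synthetic genome, library, screening and hit-table generators.

test_that("invalid genome specs are rejected naming the field", {
  expect_error(genomeSpec(centromereOverlapLen = 2e5,
                          armLengths = c(S = 1e5, L = 1e5)),
               "centromereOverlapLen")
  expect_error(genomeSpec(distalEnrichment = 0.5), "distalEnrichment")
  expect_error(genomeSpec(gc = 1.2), "gc")
  expect_error(genomeSpec(interiorIsland = data.frame(
    chrom = "9H", start = 1, end = 10, extraGenes = 5)), "interiorIsland")
})

test_that("gene placement is uniform when distal enrichment is 1", {
  g <- simulateGenome(genomeSpec(
    nChromosomes = 1, armLengths = c(S = 2e5, L = 2e5),
    centromereOverlapLen = 2e4, geneCount = 2000, distalEnrichment = 1,
    interiorIsland = NULL, repeatFamilies = 0, seed = 11))
  genes <- geneTable(g)
  len <- g@truth$chromLen[["1H"]]
  bins <- cut(genes$start, breaks = seq(0, len, length.out = 11))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("distal enrichment biases genes toward telomeres", {
  g <- simulateGenome(genomeSpec(
    nChromosomes = 1, armLengths = c(S = 3e5, L = 3e5),
    centromereOverlapLen = 2e4, geneCount = 2000, distalEnrichment = 4,
    interiorIsland = NULL, repeatFamilies = 0, seed = 12))
  genes <- geneTable(g)
  len <- g@truth$chromLen[["1H"]]
  cen <- g@truth$cenCenter[["1H"]]
  distal <- sum(genes$start < 0.1 * len | genes$start > 0.9 * len)
  central <- sum(abs(genes$start - cen) < 0.1 * len)
  expect_gt(distal, 2 * central)
})

test_that("an interior island is several-fold denser than its flanks", {
  g <- simulateGenome(genomeSpec(seed = 13))
  isl <- genomeSpec()@interiorIsland
  genes <- geneTable(g)
  g2 <- genes[genes$chrom == isl$chrom, ]
  w <- isl$end - isl$start
  inIsland <- sum(g2$start >= isl$start & g2$start <= isl$end)
  flankMean <- mean(c(
    sum(g2$start >= isl$start - w & g2$start < isl$start),
    sum(g2$start > isl$end & g2$start <= isl$end + w)))
  expect_gte(inIsland, 3 * flankMean)
})

test_that("simulation is deterministic given (spec, seed)", {
  s <- smallGenomeSpec()
  g1 <- simulateGenome(s); g2 <- simulateGenome(s)
  expect_identical(as.character(armTargets(g1)), as.character(armTargets(g2)))
  expect_identical(geneTable(g1), geneTable(g2))
  l1 <- simulateBacLibrary(g1, 20, 3e4, 3e3, nodeSplit = 3, seed = 5)
  l2 <- simulateBacLibrary(g2, 20, 3e4, 3e3, nodeSplit = 3, seed = 5)
  expect_identical(as.character(l1@nodes), as.character(l2@nodes))
  m1 <- simulateProbeScreening(g1, l1, nPools = 6, seed = 3)
  m2 <- simulateProbeScreening(g2, l2, nPools = 6, seed = 3)
  expect_identical(m1, m2)
  h1 <- simulateHitTable(l1, g1, noise = 0.2, seed = 9)
  h2 <- simulateHitTable(l2, g2, noise = 0.2, seed = 9)
  expect_identical(h1, h2)
})

test_that("arm targets share exactly the centromeric overlap", {
  g <- smallGenome()
  O <- g@spec@centromereOverlapLen
  for (ch in c("1H", "2H")) {
    s <- as.character(armTargets(g)[[paste0(ch, "S")]])
    l <- as.character(armTargets(g)[[paste0(ch, "L")]])
    expect_identical(substr(s, nchar(s) - O + 1, nchar(s)),
                     substr(l, 1, O))
  }
})

test_that("the genetic map is weakly monotone and spans totalCm", {
  g <- smallGenome()
  m <- mapTable(g)
  for (ch in unique(m$chrom)) {
    cm <- m$cM[m$chrom == ch]
    expect_false(is.unsorted(cm))
    expect_equal(max(cm), g@spec@totalCm)
  }
})

test_that("gene counts are conserved per chromosome", {
  g <- simulateGenome(genomeSpec(seed = 21))
  spec <- genomeSpec()
  genes <- geneTable(g)
  for (ch in c("1H", "3H"))
    expect_equal(sum(genes$chrom == ch), spec@geneCount)
  isl <- spec@interiorIsland
  expect_equal(sum(genes$chrom == "2H"),
               spec@geneCount + sum(isl$extraGenes))
})

test_that("library inserts honour nodeSplit and size contracts", {
  g <- smallGenome()
  lib1 <- simulateBacLibrary(g, 15, 3e4, 0, nodeSplit = 1, seed = 2)
  tr <- bacTruth(lib1)
  for (i in seq_len(nrow(tr))) {
    nd <- bacNodes(lib1, tr$bac_id[i])
    expect_length(nd, 1L)
    expect_equal(Biostrings::width(nd), tr$end[i] - tr$start[i] + 1)
    # node equals the insert verbatim
    chrom <- as.character(g@chromosomes[[tr$chrom[i]]])
    expect_identical(as.character(nd[[1]]),
                     substr(chrom, tr$start[i], tr$end[i]))
  }
  expect_equal(length(simulateBacLibrary(g, 0, 3e4)), 0L)
  expect_error(simulateBacLibrary(g, 5, insertMean = 1e9), "chromosome")
  libS <- simulateBacLibrary(g, 25, 3e4, 3e3, nodeSplit = 4, seed = 8)
  expect_true(all(Biostrings::width(libS@nodes) >= 200))
})

test_that("simulated coverage recovers the configured depth", {
  g <- simulateGenome(genomeSpec(
    nChromosomes = 1, armLengths = c(S = 5e5, L = 5e5),
    centromereOverlapLen = 5e4, geneCount = 10, interiorIsland = NULL,
    repeatFamilies = 0, seed = 31))
  genomeBp <- sum(g@truth$chromLen)
  lib <- simulateBacLibrary(g, 100, 5e4, 2e3, nodeSplit = 1, seed = 32)
  cov <- sum(Biostrings::width(lib@nodes)) / genomeBp
  expect_gt(cov, 4.5); expect_lt(cov, 5.5)
})

test_that("probe screening matches truth at the noise-free corners", {
  g <- smallGenome()
  lib <- simulateBacLibrary(g, 40, 3e4, 3e3, nodeSplit = 2, seed = 4)
  m1 <- simulateProbeScreening(g, lib, nPools = 8, detectProb = 1,
                               fpRate = 0, seed = 5)
  detected <- colnames(m1)[colSums(m1) > 0]
  expect_setequal(detected, attr(m1, "geneBearing"))
  m0 <- simulateProbeScreening(g, lib, nPools = 8, detectProb = 0,
                               fpRate = 0, seed = 5)
  expect_true(all(m0 == 0))
  expect_error(simulateProbeScreening(g, lib, nPools = 0), "nPools")
  expect_error(simulateProbeScreening(g, lib, nPools = 3, detectProb = 2),
               "probabilities")
})

test_that("per-pool detection counts match the binomial expectation", {
  g <- smallGenome()
  lib <- simulateBacLibrary(g, 60, 3e4, 3e3, nodeSplit = 2, seed = 6)
  p <- 0.6
  m <- simulateProbeScreening(g, lib, nPools = 5, detectProb = p,
                              fpRate = 0, seed = 77)
  # reconstruct the per-pool signal counts from truth
  poolOf <- attr(m, "poolOfGene")
  ov <- lib@geneOverlaps
  for (pool in seq_len(nrow(m))) {
    genesInPool <- names(poolOf)[poolOf == pool]
    nSignal <- length(unique(ov$bac_id[ov$gene_id %in% genesInPool]))
    got <- sum(m[pool, ])
    sd3 <- 3 * sqrt(nSignal * p * (1 - p))
    expect_lte(abs(got - nSignal * p), max(sd3, 3))
  }
})

test_that("noise-free hit tables reflect true origins exactly", {
  g <- smallGenome()
  lib <- simulateBacLibrary(g, 30, 3e4, 3e3, nodeSplit = 2, seed = 14)
  h <- simulateHitTable(lib, g, noise = 0, seed = 15)
  tr <- bacTruth(lib)
  orth <- setNames(paste0("Os", 1:2), c("1H", "2H"))
  trueChrom <- setNames(orth[tr$chrom], tr$bac_id)
  expect_true(all(h$subject_chrom == trueChrom[h$query]))
  # per-BAC record counts equal true overlap counts
  ovn <- table(lib@geneOverlaps$bac_id)
  hn <- table(h$query)
  expect_equal(as.vector(hn[names(ovn)]), as.vector(ovn))
  # sorted by query then e-value
  expect_false(is.unsorted(h$query))
  for (q in unique(h$query))
    expect_false(is.unsorted(h$evalue[h$query == q]))
  expect_true(all(h$evalue <= 1e-20))
})
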