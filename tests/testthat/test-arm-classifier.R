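# Discriminative k-mer index construction and BAC classification.

test_that("index equals the brute-force dictionary on small targets", {
  set.seed(41)
  # 2HS/2HL share a synthetic centromere segment; 3HS is a third target
  # that also carries a segment shared three ways (must be discarded).
  shared2 <- rdna(3000)
  shared3 <- rdna(500)
  t <- Biostrings::DNAStringSet(c(
    `2HS` = paste0(rdna(8000), shared2, shared3),
    `2HL` = paste0(shared2, rdna(8000), shared3),
    `3HS` = paste0(rdna(8000), shared3)))
  cfg <- classifierConfig(k = 19, minKmerCount = 1)
  idx <- buildKmerIndex(t, cfg)
  oracle <- bruteForceIndex(t, k = 19, minCount = 1)
  got <- setNames(idx@label, idx@kmer)
  expect_setequal(names(got), names(oracle))
  expect_identical(got[order(names(got))], oracle[order(names(oracle))])
  # centromeric label present, three-way-shared k-mers absent
  expect_true("2HC" %in% idx@label)
  expect_false(any(idx@label == "3HC"))
})

test_that("min k-mer count is applied within each target", {
  # a k-mer occurring once in target A and twice in target B
  dup <- rdna(19, seed = 42)
  t <- Biostrings::DNAStringSet(c(
    A = paste0(rdna(2000), dup),
    B = paste0(rdna(2000), dup, rdna(50), dup)))
  idx1 <- buildKmerIndex(t, classifierConfig(k = 19, minKmerCount = 2))
  oracle <- bruteForceIndex(t, 19, minCount = 2)
  got <- setNames(idx1@label, idx1@kmer)
  expect_identical(got[order(names(got))], oracle[order(names(oracle))])
  # with the rarity filter, 'dup' survives only in B, hence is single-target
  can <- min(dup, chartr("ACGT", "TGCA",
                         paste(rev(strsplit(dup, "")[[1]]), collapse = "")))
  expect_identical(unname(got[can]), "B")
})

test_that("index construction validates its inputs", {
  t <- Biostrings::DNAStringSet(c(A = rdna(100, 1)))
  expect_error(buildKmerIndex(t), ">= 2 targets")
  t2 <- Biostrings::DNAStringSet(c(A = rdna(100, 2), B = ""))
  expect_error(buildKmerIndex(t2), "empty target")
  tl <- list(A = Biostrings::DNAStringSet(rdna(100, 3)),
             A2 = Biostrings::DNAStringSet(rdna(100, 4)))
  names(tl) <- c("A", "A")
  expect_error(buildKmerIndex(tl), "unique names")
})

test_that("ambiguous bases break k-mer enumeration", {
  t <- Biostrings::DNAStringSet(c(A = paste0(rdna(60, 5), "N", rdna(60, 6)),
                                  B = rdna(80, 8)))
  idx <- buildKmerIndex(t, classifierConfig(k = 19, minKmerCount = 1))
  expect_false(any(grepl("N", idx@kmer)))
  # windows on each side of the N are still indexed: 42 + 42 from A
  expect_equal(sum(idx@label == "A"), 84L)
})

test_that("classification is exact on verbatim target slices", {
  g <- smallGenome()
  cfg <- classifierConfig(minKmerCount = 1)
  idx <- buildKmerIndex(armTargets(g), cfg)
  # unique region of 2HL (past the overlap)
  l <- as.character(armTargets(g)[["2HL"]])
  slice <- substr(l, 5e4, 6e4)
  a <- classifyBac(idx, Biostrings::DNAStringSet(c(`q|node1` = slice)), cfg)
  expect_identical(a$label, "2HL")
  expect_equal(a$confidence, 1)
  # a slice wholly inside the centromeric overlap gets the C label
  cen <- substr(l, 1000, 9000)
  ac <- classifyBac(idx, Biostrings::DNAStringSet(c(`q|node1` = cen)), cfg)
  expect_identical(ac$label, "2HC")
})

test_that("zero indexed k-mers give UNASSIGNED with confidence 0", {
  t <- Biostrings::DNAStringSet(c(A = rdna(3000, 51), B = rdna(3000, 52)))
  cfg <- classifierConfig(minKmerCount = 1)
  idx <- buildKmerIndex(t, cfg)
  a <- classifyBac(idx, Biostrings::DNAStringSet(c(q = rdna(500, 53))), cfg)
  expect_identical(a$label, "UNASSIGNED")
  expect_equal(a$confidence, 0)
  expect_equal(a$total_hits, 0L)
})

test_that("confidence exactly 0.75 is not accepted (strict > rule)", {
  t <- Biostrings::DNAStringSet(c(A = rdna(5000, 61), B = rdna(5000, 62)))
  cfg <- classifierConfig(minKmerCount = 1)
  idx <- buildKmerIndex(t, cfg)
  # 30 k-mer occurrences from A (k+29 bp slice), 10 from B (k+9 bp slice)
  bac <- Biostrings::DNAStringSet(c(
    `q|node1` = substr(as.character(t[["A"]]), 101, 101 + 19 + 29 - 1),
    `q|node2` = substr(as.character(t[["B"]]), 201, 201 + 19 + 9 - 1)))
  a <- classifyBac(idx, bac, cfg)
  expect_equal(a$h1, 30L)
  expect_equal(a$h2, 10L)
  expect_equal(a$confidence, 0.75)
  expect_identical(a$label, "UNASSIGNED")
  # one more top-label k-mer pushes it over the threshold
  bac2 <- Biostrings::DNAStringSet(c(
    `q|node1` = substr(as.character(t[["A"]]), 101, 101 + 19 + 30 - 1),
    `q|node2` = substr(as.character(t[["B"]]), 201, 201 + 19 + 9 - 1)))
  a2 <- classifyBac(idx, bac2, cfg)
  expect_gt(a2$confidence, 0.75)
  expect_identical(a2$label, "A")
})

test_that("ties for the top label are left unassigned", {
  t <- Biostrings::DNAStringSet(c(A = rdna(5000, 63), B = rdna(5000, 64)))
  cfg <- classifierConfig(minKmerCount = 1)
  idx <- buildKmerIndex(t, cfg)
  bac <- Biostrings::DNAStringSet(c(
    `q|node1` = substr(as.character(t[["A"]]), 1, 19 + 4),
    `q|node2` = substr(as.character(t[["B"]]), 1, 19 + 4)))
  a <- classifyBac(idx, bac, cfg)
  expect_equal(a$h1, a$h2)
  expect_identical(a$label, "UNASSIGNED")
})

test_that("assignments are invariant to node order and monotone in evidence", {
  g <- smallGenome()
  cfg <- classifierConfig(minKmerCount = 1)
  idx <- buildKmerIndex(armTargets(g), cfg)
  s <- as.character(armTargets(g)[["1HS"]])
  l <- as.character(armTargets(g)[["2HL"]])
  nodes <- c(`q|node1` = substr(s, 1e4, 2e4), `q|node2` = substr(l, 1e5, 1.02e5),
             `q|node3` = substr(s, 3e4, 3.5e4))
  a1 <- classifyBac(idx, Biostrings::DNAStringSet(nodes), cfg)
  a2 <- classifyBac(idx, Biostrings::DNAStringSet(nodes[c(3, 1, 2)]), cfg)
  expect_equal(a1$label, a2$label)
  expect_equal(a1$confidence, a2$confidence)
  expect_equal(a1$h1, a2$h1)
  # appending more 1HS-only sequence never decreases the 1HS hit count
  more <- c(nodes, `q|node4` = substr(s, 5e4, 5.3e4))
  a3 <- classifyBac(idx, Biostrings::DNAStringSet(more), cfg)
  expect_gte(a3$h1, a1$h1)
})

test_that("k or canonicalization mismatch between index and config errors", {
  t <- Biostrings::DNAStringSet(c(A = rdna(1000, 71), B = rdna(1000, 72)))
  idx <- buildKmerIndex(t, classifierConfig(k = 15, minKmerCount = 1))
  expect_error(classifyBac(idx, Biostrings::DNAStringSet(c(q = rdna(100))),
                           classifierConfig(k = 19)), "mismatch")
  expect_error(
    classifyBac(idx, Biostrings::DNAStringSet(c(q = rdna(100))),
                classifierConfig(k = 15, canonical = FALSE)),
    "mismatch")
})

test_that("library classification summarises counts and rates", {
  g <- smallGenome()
  cfg <- classifierConfig(minKmerCount = 1)
  idx <- buildKmerIndex(armTargets(g), cfg)
  lib <- simulateBacLibrary(g, 25, 3e4, 3e3, nodeSplit = 2, seed = 9)
  asn <- classifyLibrary(idx, lib, cfg)
  expect_equal(nrow(asn), 25L)
  s <- attr(asn, "summary")
  expect_equal(sum(s$perLabel), 25L)
  expect_equal(s$assigned + sum(asn$label == "UNASSIGNED"), 25L)
  # empty library: 0-of-0 reported as rate 0
  empty <- lib[character(0)]
  asn0 <- classifyLibrary(idx, empty, cfg)
  expect_equal(nrow(asn0), 0L)
  expect_equal(attr(asn0, "summary")$rate_pct, 0)
})

test_that("index serialization round-trips and rejects foreign files", {
  t <- Biostrings::DNAStringSet(c(A = rdna(2000, 81), B = rdna(2000, 82)))
  idx <- buildKmerIndex(t, classifierConfig(minKmerCount = 1))
  f <- tempfile(fileext = ".tsv")
  writeKmerIndex(idx, f)
  idx2 <- readKmerIndex(f)
  expect_equal(idx@k, idx2@k)
  expect_identical(sort(idx@kmer), sort(idx2@kmer))
  expect_identical(idx@targets, idx2@targets)
  bad <- tempfile()
  writeLines(c("not", "an index"), bad)
  expect_error(readKmerIndex(bad), "not a BACography k-mer index")
})
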