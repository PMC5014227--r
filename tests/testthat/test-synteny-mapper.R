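# Plurality voting, contig voting, anchor joining and inversion detection.

test_that("single-hit and multi-hit voting follow the plurality rule", {
  h1 <- data.frame(query = "b1", subject_chrom = "Os1",
                   subject_pos = 5e6, evalue = 1e-30)
  v1 <- voteBacs(h1)
  expect_identical(v1$chrom, "Os1")
  expect_equal(v1$position, 5e6)
  expect_identical(v1$status, "placed")

  h2 <- data.frame(query = "b2",
                   subject_chrom = c(rep("Os2", 3), "Os7"),
                   subject_pos = c(1e6, 2e6, 6e6, 9e6), evalue = 1e-30)
  v2 <- voteBacs(h2)
  expect_identical(v2$chrom, "Os2")
  expect_equal(v2$position, 3e6)  # mean of 1, 2, 6 Mb
  expect_equal(v2$n_hits, 4L)
})

test_that("vote ties and e-value filtering are handled", {
  h <- data.frame(query = "b1",
                  subject_chrom = c("Os1", "Os1", "Os1", "Os5", "Os5", "Os5"),
                  subject_pos = 1:6, evalue = 1e-30)
  v <- voteBacs(h)
  expect_identical(v$status, "tied")
  expect_true(is.na(v$chrom))
  # hits above the cutoff do not vote
  h2 <- data.frame(query = "b1", subject_chrom = c("Os1", "Os2", "Os2"),
                   subject_pos = c(1, 2, 3),
                   evalue = c(1e-30, 1e-10, 1e-12))
  v2 <- voteBacs(h2)
  expect_identical(v2$chrom, "Os1")
  # all hits filtered -> no row survives filtering at all
  h3 <- data.frame(query = "b1", subject_chrom = "Os1", subject_pos = 1,
                   evalue = 1e-5)
  expect_equal(nrow(voteBacs(h3)), 0L)
})

test_that("voting is hit-order invariant and monotone on the winner", {
  h <- data.frame(query = "b1",
                  subject_chrom = c("Os3", "Os3", "Os8"),
                  subject_pos = c(10, 20, 99), evalue = 1e-30)
  v1 <- voteBacs(h)
  v2 <- voteBacs(h[c(3, 1, 2), ])
  expect_equal(v1$chrom, v2$chrom)
  expect_equal(v1$position, v2$position)
  # adding a hit on the winning chromosome never unseats it
  h3 <- rbind(h, data.frame(query = "b1", subject_chrom = "Os3",
                            subject_pos = 50, evalue = 1e-25))
  expect_identical(voteBacs(h3)$chrom, "Os3")
})

test_that("contig votes aggregate member placements", {
  votes <- data.frame(
    bac_id = c("b1", "b2", "b3", "b4"),
    chrom = c("Os3", "Os3", "Os8", "Os3"),
    position = c(10, 20, 99, 30),
    status = "placed", n_hits = 1L, top_votes = 1L)
  mem <- data.frame(bac_id = c("b1", "b2", "b4", "b3"),
                    contig_id = c("c1", "c1", "c1", "c1"))
  cv <- voteContigs(votes, mem)
  expect_identical(cv$chrom, "Os3")
  expect_equal(cv$position, 20)  # mean of 10, 20, 30
  # single member: contig vote equals member vote
  cv1 <- voteContigs(votes[3, ], data.frame(bac_id = "b3",
                                            contig_id = "cX"))
  expect_identical(cv1$chrom, "Os8")
  expect_equal(cv1$position, 99)
  # no placed members
  unpl <- data.frame(bac_id = "b9", chrom = NA, position = NA,
                     status = "no_hits", n_hits = 0L, top_votes = 0L)
  cv0 <- voteContigs(unpl, data.frame(bac_id = "b9", contig_id = "c9"))
  expect_identical(cv0$status, "no_hits")
})

test_that("anchor joining chains markers through BACs with orthology filter", {
  mapA <- data.frame(marker = c("m1", "m2", "m3"),
                     group = c("1D", "1D", "5D"), cM = c(10, 20, 5))
  links <- data.frame(marker = c("m1", "m2", "m3"),
                      bac_id = c("bacX", "bacY", "bacZ"))
  mapB <- data.frame(bac_id = c("bacX", "bacY", "bacZ"),
                     group = c("1H", "5H", "5H"), cM = c(12, 99, 7))
  orth <- data.frame(group_a = c("1D", "5D"), group_b = c("1H", "5H"))
  j <- anchorJoin(mapA, links, mapB, orth)
  # m1 chain is orthologous (1D-1H); m2 lands on 5H (dropped); m3 kept
  expect_equal(nrow(j), 2L)
  expect_setequal(j$marker, c("m1", "m3"))
  expect_equal(j$cM_b[j$marker == "m1"], 12)
  # duplicate marker in map A errors
  expect_error(anchorJoin(rbind(mapA, mapA[1, ]), links, mapB, orth),
               "two groups")
})

test_that("anchor join size matches a hand-computed 20-marker join", {
  set.seed(55)
  n <- 20
  mapA <- data.frame(marker = sprintf("m%02d", 1:n), group = "2D",
                     cM = sort(runif(n, 0, 100)))
  links <- data.frame(marker = sprintf("m%02d", 1:n),
                      bac_id = sprintf("bac%02d", 1:n))
  # only 15 of the BACs are anchored on map B; 3 of those on a
  # non-orthologous group
  mapB <- data.frame(bac_id = sprintf("bac%02d", 1:15),
                     group = c(rep("2H", 12), rep("7H", 3)),
                     cM = runif(15, 0, 120))
  orth <- data.frame(group_a = "2D", group_b = "2H")
  j <- anchorJoin(mapA, links, mapB, orth)
  expect_equal(nrow(j), 12L)
  # restricting the orthology table never grows the join
  j0 <- anchorJoin(mapA, links, mapB,
                   data.frame(group_a = character(0),
                              group_b = character(0)))
  expect_equal(nrow(j0), 0L)
})

test_that("inversion detection flags a reversed block and only that", {
  set.seed(66)
  n <- 60
  cma <- sort(runif(n, 0, 100))
  cmb <- cma + rnorm(n, 0, 0.01)
  pairs <- data.frame(cM_a = cma, cM_b = cmb)
  expect_equal(nrow(detectInversions(pairs, windowSize = 8)), 0L)
  # reverse a 15-pair block in the middle
  block <- 25:39
  inv <- pairs
  inv$cM_b[block] <- rev(inv$cM_b[block])
  res <- detectInversions(inv, windowSize = 8)
  expect_equal(nrow(res), 1L)
  expect_lte(res$start_cM_a, cma[min(block) + 1])
  expect_gte(res$end_cM_a, cma[max(block) - 1])
  # global orientation flip turns the whole map negative
  flip <- pairs
  flip$cM_b <- -flip$cM_b
  resF <- detectInversions(flip, windowSize = 8)
  expect_equal(nrow(resF), 1L)
  expect_equal(resF$n_pairs, n)
  # fewer pairs than the window warns and returns nothing
  expect_warning(short <- detectInversions(pairs[1:4, ], windowSize = 8),
                 "fewer pairs")
  expect_equal(nrow(short), 0L)
})

test_that("synteny voting recovers true placements on clean hit tables", {
  g <- smallGenome()
  lib <- simulateBacLibrary(g, 80, 3e4, 3e3, nodeSplit = 2, seed = 23)
  h <- simulateHitTable(lib, g, noise = 0, seed = 24)
  v <- voteBacs(h)
  placed <- v[v$status == "placed", ]
  tr <- bacTruth(lib)
  orth <- setNames(paste0("Os", 1:2), c("1H", "2H"))
  trueChrom <- setNames(unname(orth[tr$chrom]), tr$bac_id)
  expect_true(all(placed$chrom == trueChrom[placed$bac_id]))
  # voted positions track true midpoints
  mid <- setNames((tr$start + tr$end) / 2, tr$bac_id)
  for (ch in unique(placed$chrom)) {
    p <- placed[placed$chrom == ch, ]
    if (nrow(p) >= 5)
      expect_gte(cor(p$position, mid[p$bac_id], method = "spearman"), 0.99)
  }
})
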