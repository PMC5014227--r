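# Shared fixtures, memoised so the expensive default-conditions run is
# simulated once per test session.
.fx <- new.env()

# Full pipeline under the reference study conditions (fixed seed).
defaultRun <- function() {
  if (is.null(.fx$run))
    .fx$run <- runPipeline(pipelineConfig(seed = 1),
                           outdir = file.path(tempdir(), "bacography-run"))
  .fx$run
}

# A small two-chromosome genome for cheap module tests.
smallGenomeSpec <- function(...) {
  args <- list(nChromosomes = 2, armLengths = c(S = 1e5, L = 1.5e5),
               centromereOverlapLen = 2e4, geneCount = 30,
               interiorIsland = NULL, repeatFamilies = 0, repeatCopies = 0,
               mapSuppressionWidth = 5e4, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(genomeSpec, args)
}

smallGenome <- function() {
  if (is.null(.fx$small)) .fx$small <- simulateGenome(smallGenomeSpec())
  .fx$small
}

# Brute-force discriminative k-mer dictionary: enumerate every k-mer of
# every target and apply the filtering rules literally. Independent oracle
# for buildKmerIndex.
bruteForceIndex <- function(targets, k, minCount = 1, canonical = TRUE) {
  labs <- unique(names(targets))
  kms <- lapply(labs, function(lb) {
    v <- unlist(lapply(as.character(targets[names(targets) == lb]),
                       function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      out <- character(0)
      for (i in seq_len(n - k + 1)) {
        w <- substr(s, i, i + k - 1)
        if (grepl("[^ACGT]", w)) next
        if (canonical) {
          rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]),
                                             collapse = ""))
          w <- min(w, rc)
        }
        out <- c(out, w)
      }
      out
    }))
    tab <- table(v)
    names(tab)[tab >= minCount]
  })
  names(kms) <- labs
  allk <- unique(unlist(kms))
  res <- character(0)
  for (w in allk) {
    inT <- labs[vapply(labs, function(lb) w %in% kms[[lb]], TRUE)]
    if (length(inT) == 1L) {
      res[w] <- inT
    } else if (length(inT) == 2L) {
      stems <- sub("[SL]$", "", inT)
      if (all(grepl("[SL]$", inT)) && stems[1] == stems[2] &&
          substring(inT[1], nchar(inT[1])) != substring(inT[2], nchar(inT[2])))
        res[w] <- paste0(stems[1], "C")
    }
  }
  res
}

# Random DNA helper for tests.
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
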