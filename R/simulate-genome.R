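#' @include AllClasses.R
NULL

#' Simulate a multi-chromosome genome with arm targets and ground truth
#'
#' Builds, per chromosome, a full sequence from which the short-arm (S) and
#' long-arm (L) flow-sorted target sequences are cut so that the two arm
#' targets share exactly the configured centromeric overlap segment and
#' nothing else (apart from inserted repeat-family copies, which recur
#' genome-wide). Genes are placed by thinning a uniform proposal against a
#' piecewise-linear density that rises from the centromere to the telomeres
#' by \code{distalEnrichment}; interior islands add a uniform block of extra
#' genes. The genetic map is the cumulative integral of a bathtub-shaped
#' recombination intensity with a low pericentromeric plateau of width
#' \code{mapSuppressionWidth}, scaled to \code{totalCm} per chromosome.
#'
#' @param spec a \code{\linkS4class{GenomeSpec}}.
#' @return A \code{\linkS4class{SimGenome}}.
#' @examples
#' g <- simulateGenome(genomeSpec(nChromosomes = 1, geneCount = 20,
#'                                interiorIsland = NULL))
#' g
#' @export
simulateGenome <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    nC <- spec@nChromosomes
    chromNames <- paste0(seq_len(nC), "H")
    S <- spec@armLengths[, "S"]
    L <- spec@armLengths[, "L"]
    O <- spec@centromereOverlapLen
    chromLen <- S + L - O

    chroms <- randomDna(chromLen, spec@gc)

    # shared repeat families: identical units copied across chromosomes
    repTruth <- NULL
    if (spec@repeatFamilies > 0L && spec@repeatCopies > 0L) {
      units <- randomDna(rep(spec@repeatLength, spec@repeatFamilies), spec@gc)
      ins <- list()
      for (f in seq_len(spec@repeatFamilies)) {
        for (cp in seq_len(spec@repeatCopies)) {
          ci <- sample.int(nC, 1, prob = chromLen)
          pos <- sample.int(chromLen[ci] - spec@repeatLength, 1)
          substr(chroms[ci], pos, pos + spec@repeatLength - 1) <- units[f]
          ins[[length(ins) + 1L]] <- data.frame(
            family = f, chrom = chromNames[ci], start = pos,
            end = pos + spec@repeatLength - 1)
        }
      }
      repTruth <- do.call(rbind, ins)
    }

    # centromere center on the full chromosome coordinate system
    cenCenter <- S - O / 2

    genes <- list()
    for (ci in seq_len(nC)) {
      n <- spec@geneCount
      if (n > 0L) {
        pos <- placeGenes(n, chromLen[ci], cenCenter[ci],
                          spec@distalEnrichment, spec@geneLength)
      } else pos <- numeric(0)
      island <- rep(FALSE, length(pos))
      isl <- spec@interiorIsland
      if (!is.null(isl)) {
        isl <- isl[isl$chrom == chromNames[ci], , drop = FALSE]
        for (r in seq_len(nrow(isl))) {
          extra <- round(runif(isl$extraGenes[r],
                               isl$start[r],
                               max(isl$start[r], isl$end[r] - spec@geneLength)))
          pos <- c(pos, extra)
          island <- c(island, rep(TRUE, length(extra)))
        }
      }
      if (length(pos)) {
        o <- order(pos)
        pos <- pos[o]; island <- island[o]
        genes[[ci]] <- data.frame(
          gene_id = sprintf("G%s_%04d", chromNames[ci], seq_along(pos)),
          chrom = chromNames[ci],
          start = pos, end = pmin(pos + spec@geneLength - 1, chromLen[ci]),
          class = ifelse(runif(length(pos)) < spec@hcFraction, "HC", "LC"),
          island = island)
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), class = character(0),
                 island = logical(0))
    rownames(genes) <- NULL

    map <- do.call(rbind, lapply(seq_len(nC), function(ci) {
      geneticMapSamples(chromNames[ci], chromLen[ci], cenCenter[ci],
                        spec@mapSuppressionWidth, spec@totalCm)
    }))

    arms <- character(2 * nC)
    armNames <- character(2 * nC)
    for (ci in seq_len(nC)) {
      arms[2 * ci - 1] <- substr(chroms[ci], 1, S[ci])
      arms[2 * ci] <- substr(chroms[ci], S[ci] - O + 1, chromLen[ci])
      armNames[2 * ci - 1] <- paste0(chromNames[ci], "S")
      armNames[2 * ci] <- paste0(chromNames[ci], "L")
    }

    armSet <- DNAStringSet(setNames(arms, armNames))
    chromSet <- DNAStringSet(setNames(chroms, chromNames))

    new("SimGenome", spec = spec, arms = armSet, chromosomes = chromSet,
        genes = genes, map = map,
        truth = list(chromLen = setNames(chromLen, chromNames),
                     armS = setNames(S, chromNames),
                     armL = setNames(L, chromNames),
                     overlap = O,
                     cenCenter = setNames(cenCenter, chromNames),
                     repeats = repTruth))
  })
}

# Gene placement by thinning: density 1 at the centromere rising linearly to
# `enrich` at each chromosome end.
placeGenes <- function(n, chromLen, cenCenter, enrich, geneLen) {
  maxStart <- chromLen - geneLen
  dens <- function(x) {
    d <- abs(x - cenCenter) / pmax(cenCenter - 1, chromLen - cenCenter)
    1 + (enrich - 1) * pmin(d, 1)
  }
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    prop <- runif(m, 1, maxStart)
    keep <- runif(m) < dens(prop + geneLen / 2) / enrich
    out <- c(out, prop[keep])
  }
  round(out[seq_len(n)])
}

# Bathtub recombination intensity integrated to a cumulative cM curve.
geneticMapSamples <- function(chrom, chromLen, cenCenter, suppressWidth,
                              totalCm, gridStep = 1e4) {
  bp <- unique(c(seq(1, chromLen, by = gridStep), chromLen))
  half <- suppressWidth / 2
  lo <- 0.05
  lambda <- vapply(bp, function(x) {
    d <- abs(x - cenCenter)
    if (d <= half) return(lo)
    edge <- if (x < cenCenter) cenCenter - 1 else chromLen - cenCenter
    if (edge <= half) return(1)
    lo + (1 - lo) * (d - half) / (edge - half)
  }, numeric(1))
  # trapezoidal cumulative integral
  dx <- diff(bp)
  inc <- dx * (head(lambda, -1) + tail(lambda, -1)) / 2
  cum <- c(0, cumsum(inc))
  data.frame(chrom = chrom, bp = bp, cM = totalCm * cum / cum[length(cum)])
}
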