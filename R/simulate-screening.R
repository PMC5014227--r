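#' @include simulate-library.R
NULL

#' Simulate probe-pool screening of a BAC library
#'
#' Emulates hybridization screening with pools of gene-derived probes:
#' genes are partitioned uniformly at random among \code{nPools} pools; a
#' pool gives a true signal for a clone when at least one of its genes
#' overlaps the clone's insert, and that signal is observed with probability
#' \code{detectProb}. Independently, every (pool, clone) cell can light up
#' as a false positive with probability \code{fpRate}.
#'
#' @param genome a \code{\linkS4class{SimGenome}}.
#' @param library a \code{\linkS4class{BacLibrary}} simulated from it.
#' @param nPools number of probe pools (>= 1).
#' @param detectProb probability that a pool containing one of a clone's
#'   genes detects the clone.
#' @param fpRate per-clone-per-pool false-positive probability.
#' @param seed integer seed.
#' @return A binary integer matrix (pools x clones) with pool row names and
#'   clone column names. Attributes: \code{geneBearing} (character vector of
#'   truly gene-bearing clone ids) and \code{poolOfGene} (named integer
#'   vector, the pool each gene was assigned to).
#' @export
simulateProbeScreening <- function(genome, library, nPools, detectProb = 1,
                                   fpRate = 0, seed = 1) {
  stopifnot(is(genome, "SimGenome"), is(library, "BacLibrary"))
  if (nPools < 1) stop("'nPools' must be >= 1", call. = FALSE)
  if (detectProb < 0 || detectProb > 1 || fpRate < 0 || fpRate > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  clones <- bacIds(library)
  genes <- genome@genes
  ov <- library@geneOverlaps

  withSeed(seed, {
    poolOf <- setNames(sample.int(nPools, nrow(genes), replace = TRUE),
                       genes$gene_id)
    mat <- matrix(0L, nrow = nPools, ncol = length(clones),
                  dimnames = list(sprintf("pool%02d", seq_len(nPools)),
                                  clones))
    if (nrow(ov)) {
      sig <- unique(data.frame(pool = poolOf[ov$gene_id], clone = ov$bac_id))
      det <- runif(nrow(sig)) < detectProb
      sig <- sig[det, , drop = FALSE]
      mat[cbind(sig$pool, match(sig$clone, clones))] <- 1L
    }
    if (fpRate > 0) {
      fp <- matrix(runif(length(mat)) < fpRate, nrow = nPools)
      mat[fp] <- 1L
    }
    attr(mat, "geneBearing") <- unique(ov$bac_id)
    attr(mat, "poolOfGene") <- poolOf
    mat
  })
}

#' Simulate a cross-species tabular hit table
#'
#' Stands in for translated-alignment output against an orthologous
#' reference: every true gene-clone overlap yields one hit record whose
#' subject chromosome is the ortholog of the clone's chromosome of origin
#' (collinear layout, \code{Os1} for \code{1H} and so on) and whose subject
#' position is the gene midpoint. Off-target noise adds, per clone, a
#' Poisson(\code{noise} x true hits) number of records with uniformly random
#' subject chromosome and position. All e-values are at or below 1e-20 so
#' the records survive the standard cutoff.
#'
#' @param library a \code{\linkS4class{BacLibrary}} with simulation truth.
#' @param genome the \code{\linkS4class{SimGenome}} it came from.
#' @param noise expected off-target hits per true hit (>= 0).
#' @param seed integer seed.
#' @param orthologPrefix prefix for subject chromosome names.
#' @return data.frame sorted by \code{query} then \code{evalue}:
#'   \code{query} (BAC id), \code{subject} (gene id), \code{subject_chrom},
#'   \code{subject_pos}, \code{evalue}, \code{true_hit}.
#' @export
simulateHitTable <- function(library, genome, noise = 0, seed = 1,
                             orthologPrefix = "Os") {
  stopifnot(is(library, "BacLibrary"), is(genome, "SimGenome"))
  if (noise < 0) stop("'noise' must be >= 0", call. = FALSE)
  ov <- library@geneOverlaps
  genes <- genome@genes
  chromNames <- names(genome@truth$chromLen)
  orth <- setNames(paste0(orthologPrefix, seq_along(chromNames)), chromNames)

  withSeed(seed, {
    mid <- setNames((genes$start + genes$end) / 2, genes$gene_id)
    gchrom <- setNames(genes$chrom, genes$gene_id)
    true <- data.frame(
      query = ov$bac_id,
      subject = ov$gene_id,
      subject_chrom = unname(orth[gchrom[ov$gene_id]]),
      subject_pos = unname(mid[ov$gene_id]),
      evalue = 10^-runif(nrow(ov), 30, 80),
      true_hit = TRUE)
    off <- NULL
    if (noise > 0 && nrow(true)) {
      nPer <- rpois(length(unique(true$query)),
                    noise * table(true$query)[unique(true$query)])
      tot <- sum(nPer)
      if (tot > 0) {
        offChrom <- sample(unname(orth), tot, replace = TRUE)
        off <- data.frame(
          query = rep(unique(true$query), nPer),
          subject = sprintf("OFF%05d", seq_len(tot)),
          subject_chrom = offChrom,
          subject_pos = runif(tot, 1, max(genome@truth$chromLen)),
          evalue = 10^-runif(tot, 20, 30),
          true_hit = FALSE)
      }
    }
    hits <- rbind(true, off)
    hits <- hits[order(hits$query, hits$evalue), , drop = FALSE]
    rownames(hits) <- NULL
    hits
  })
}
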