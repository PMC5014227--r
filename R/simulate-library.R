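#' @include simulate-genome.R
NULL

#' Simulate a BAC clone library from a genome
#'
#' Each clone insert is drawn from one chromosome with probability
#' proportional to chromosome length, with a normal insert size and a
#' uniform start. The insert is cut into nodes (assembler contigs): the
#' number of nodes is 1 plus a Poisson draw with mean \code{nodeSplit - 1},
#' breakpoints are uniform, and a small internal deletion (0-50 bp) is
#' applied at each junction to mimic assembly gaps. Nodes shorter than
#' \code{minNodeLen} are discarded, mirroring the minimum node size used
#' when analysing real BAC assemblies.
#'
#' Truth records each clone's chromosome and insert interval plus its true
#' arm-of-origin label: \code{<chrom>S} / \code{<chrom>L} for inserts wholly
#' within one arm's unique region, \code{<chrom>C} for inserts wholly within
#' the centromeric overlap, and \code{<chrom>*} for inserts spanning region
#' boundaries (ambiguous). True gene-clone overlaps are recorded with their
#' overlap size in bp.
#'
#' @param genome a \code{\linkS4class{SimGenome}}.
#' @param nClones number of clones (0 allowed).
#' @param insertMean,insertSd insert size distribution in bp.
#' @param nodeSplit mean number of nodes per clone (>= 1); 1 means every
#'   clone is a single node equal to its insert.
#' @param seed integer seed.
#' @param minNodeLen nodes shorter than this are dropped (default 200 bp).
#' @return A \code{\linkS4class{BacLibrary}}.
#' @examples
#' g <- simulateGenome(genomeSpec(nChromosomes = 1, geneCount = 20,
#'                                interiorIsland = NULL))
#' lib <- simulateBacLibrary(g, nClones = 5, insertMean = 5e4,
#'                           insertSd = 5e3, nodeSplit = 3, seed = 1)
#' lib
#' @export
simulateBacLibrary <- function(genome, nClones, insertMean, insertSd = 0,
                               nodeSplit = 1, seed = 1, minNodeLen = 200) {
  stopifnot(is(genome, "SimGenome"))
  if (nClones < 0) stop("'nClones' must be >= 0", call. = FALSE)
  if (insertMean <= 0) stop("'insertMean' must be > 0", call. = FALSE)
  chromLen <- genome@truth$chromLen
  if (insertMean > min(chromLen))
    stop("'insertMean' exceeds the shortest chromosome (",
         min(chromLen), " bp)", call. = FALSE)
  if (nClones == 0)
    return(bacLibrary(DNAStringSet(), bac = character(0)))

  withSeed(seed, {
    chromNames <- names(chromLen)
    S <- genome@truth$armS
    O <- genome@truth$overlap

    ci <- sample.int(length(chromLen), nClones, replace = TRUE,
                     prob = chromLen)
    len <- round(rnorm(nClones, insertMean, insertSd))
    len <- pmax(pmin(len, chromLen[ci] - 1), max(minNodeLen, insertMean / 2))
    start <- floor(runif(nClones, 1, chromLen[ci] - len + 1))
    end <- start + len - 1

    bacId <- sprintf("BAC%04d", seq_len(nClones))
    label <- trueArmLabel(chromNames[ci], start, end, S[ci], O)

    nodeSeqs <- vector("list", nClones)
    for (i in seq_len(nClones)) {
      insert <- substr(as.character(genome@chromosomes[[ci[i]]]),
                       start[i], end[i])
      nodeSeqs[[i]] <- splitInsert(insert, nodeSplit, minNodeLen)
    }
    nPer <- lengths(nodeSeqs)
    nodes <- unlist(nodeSeqs, use.names = FALSE)
    bacOf <- rep(bacId, nPer)
    nodeNames <- unlist(lapply(nPer, function(k) {
      sprintf("node%d", seq_len(k))
    }), use.names = FALSE)
    nodeSet <- DNAStringSet(setNames(nodes, paste0(bacOf, "|", nodeNames)))

    truth <- data.frame(bac_id = bacId, chrom = chromNames[ci],
                        start = start, end = end, label = label)
    ov <- trueGeneOverlaps(genome@genes, truth)
    bacLibrary(nodeSet, bac = bacOf, truth = truth, geneOverlaps = ov)
  })
}

# True arm-of-origin label from an insert interval; '*' marks ambiguity.
trueArmLabel <- function(chrom, start, end, S, O) {
  label <- paste0(chrom, "*")
  label[end <= S - O] <- paste0(chrom, "S")[end <= S - O]
  label[start > S] <- paste0(chrom, "L")[start > S]
  inC <- start > S - O & end <= S
  label[inC] <- paste0(chrom, "C")[inC]
  label
}

# Cut an insert into nodes with small junction deletions; drop short nodes.
splitInsert <- function(insert, nodeSplit, minNodeLen) {
  len <- nchar(insert)
  nNodes <- if (nodeSplit <= 1) 1L else 1L + rpois(1, nodeSplit - 1)
  if (nNodes == 1L) return(insert)
  cuts <- sort(sample.int(len - 1L, min(nNodes - 1L, len - 1L)))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  gaps <- sample(0:50, length(starts), replace = TRUE)
  gaps[1L] <- 0L
  starts <- pmin(starts + gaps, ends)
  out <- substring(insert, starts, ends)
  out <- out[nchar(out) >= minNodeLen]
  if (!length(out)) out <- substring(insert, 1, len)  # degenerate fallback
  out
}

# Overlap in bp between each clone interval and each gene on its chromosome.
trueGeneOverlaps <- function(genes, truth) {
  if (!nrow(genes) || !nrow(truth))
    return(data.frame(bac_id = character(0), gene_id = character(0),
                      overlap_bp = numeric(0)))
  out <- lapply(seq_len(nrow(truth)), function(i) {
    g <- genes[genes$chrom == truth$chrom[i], , drop = FALSE]
    ov <- pmin(g$end, truth$end[i]) - pmax(g$start, truth$start[i]) + 1
    keep <- ov > 0
    if (!any(keep)) return(NULL)
    data.frame(bac_id = truth$bac_id[i], gene_id = g$gene_id[keep],
               overlap_bp = ov[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(bac_id = character(0), gene_id = character(0),
                      overlap_bp = numeric(0))
  rownames(out) <- NULL
  out
}
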