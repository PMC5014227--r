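#' @include BACography-package.R
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

# ---- GenomeSpec ------------------------------------------------------------

#' Specification of a synthetic multi-chromosome genome
#'
#' Describes the genome the synthetic-data generator emulates: chromosomes
#' made of a short (S) and a long (L) arm whose flow-sorted target sequences
#' share a centromeric overlap zone, telomere-biased gene density with an
#' optional interior gene-dense island, shared repeat families, and a weakly
#' monotone genetic map with pericentromeric recombination suppression.
#'
#' The prototype values are the package's reference study conditions: three
#' 1.28-Mb chromosomes (600-kb S arm, 800-kb L arm, 120-kb centromeric
#' overlap), 120 genes per chromosome with a four-fold distal enrichment, a
#' gene-dense island planted in the recombination-suppressed interior of
#' chromosome 2H, four shared repeat families, a 300-kb centromeric cM
#' plateau, 150 cM per chromosome and GC content 0.445.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot armLengths numeric matrix (nChromosomes x 2, columns \code{S},
#'   \code{L}) of arm lengths in bp.
#' @slot centromereOverlapLen bp of sequence shared by the two arm targets
#'   of each chromosome.
#' @slot geneCount genes per chromosome (before island extras).
#' @slot geneLength gene model length in bp.
#' @slot hcFraction fraction of genes labelled high-confidence (HC).
#' @slot distalEnrichment ratio (>= 1) of telomeric to pericentromeric gene
#'   density.
#' @slot interiorIsland \code{NULL} or a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{extraGenes}.
#' @slot repeatFamilies number of shared repeat families.
#' @slot repeatLength repeat unit length in bp.
#' @slot repeatCopies genome-wide copies per family.
#' @slot mapSuppressionWidth bp width of the pericentromeric low-cM plateau.
#' @slot totalCm genetic length per chromosome in cM.
#' @slot gc genome GC content in (0, 1).
#' @slot seed integer seed; all stochastic draws flow from it.
#' @seealso \code{\link{genomeSpec}}, \code{\link{simulateGenome}}
#' @export
setClass("GenomeSpec", representation(
  nChromosomes = "integer",
  armLengths = "matrix",
  centromereOverlapLen = "numeric",
  geneCount = "integer",
  geneLength = "numeric",
  hcFraction = "numeric",
  distalEnrichment = "numeric",
  interiorIsland = "data.frameOrNULL",
  repeatFamilies = "integer",
  repeatLength = "numeric",
  repeatCopies = "integer",
  mapSuppressionWidth = "numeric",
  totalCm = "numeric",
  gc = "numeric",
  seed = "integer"
))

setValidity("GenomeSpec", function(object) {
  msg <- character(0)
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  if (object@nChromosomes < 1L) msg <- c(msg, bad("nChromosomes", "must be >= 1"))
  if (!identical(colnames(object@armLengths), c("S", "L")))
    msg <- c(msg, bad("armLengths", "needs columns S and L"))
  if (nrow(object@armLengths) != object@nChromosomes)
    msg <- c(msg, bad("armLengths", "one row per chromosome required"))
  if (any(object@armLengths <= 0)) msg <- c(msg, bad("armLengths", "must be > 0"))
  if (object@centromereOverlapLen <= 0)
    msg <- c(msg, bad("centromereOverlapLen", "must be > 0"))
  if (object@centromereOverlapLen >= min(object@armLengths))
    msg <- c(msg, bad("centromereOverlapLen", "must be < min arm length"))
  if (object@geneCount < 0L) msg <- c(msg, bad("geneCount", "must be >= 0"))
  if (object@geneLength <= 0) msg <- c(msg, bad("geneLength", "must be > 0"))
  if (object@hcFraction < 0 || object@hcFraction > 1)
    msg <- c(msg, bad("hcFraction", "must be in [0, 1]"))
  if (object@distalEnrichment < 1)
    msg <- c(msg, bad("distalEnrichment", "must be >= 1"))
  if (!is.null(object@interiorIsland)) {
    need <- c("chrom", "start", "end", "extraGenes")
    if (!all(need %in% names(object@interiorIsland)))
      msg <- c(msg, bad("interiorIsland",
                        paste("needs columns", paste(need, collapse = ", "))))
    else if (any(object@interiorIsland$end <= object@interiorIsland$start))
      msg <- c(msg, bad("interiorIsland", "end must exceed start"))
  }
  if (object@repeatFamilies < 0L) msg <- c(msg, bad("repeatFamilies", "must be >= 0"))
  if (object@repeatLength <= 0) msg <- c(msg, bad("repeatLength", "must be > 0"))
  if (object@mapSuppressionWidth < 0)
    msg <- c(msg, bad("mapSuppressionWidth", "must be >= 0"))
  if (object@totalCm <= 0) msg <- c(msg, bad("totalCm", "must be > 0"))
  if (object@gc <= 0 || object@gc >= 1) msg <- c(msg, bad("gc", "must be in (0, 1)"))
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' All arguments default to the package's reference study conditions (see
#' \code{\linkS4class{GenomeSpec}}).
#'
#' @param nChromosomes number of chromosomes.
#' @param armLengths length-2 vector \code{c(S =, L =)} applied to every
#'   chromosome, or an nChromosomes x 2 matrix.
#' @param centromereOverlapLen bp shared by the two arm targets.
#' @param geneCount genes per chromosome.
#' @param geneLength gene length in bp.
#' @param hcFraction fraction of genes labelled HC.
#' @param distalEnrichment telomere/centromere gene-density ratio, >= 1.
#' @param interiorIsland \code{NULL} or data.frame(chrom, start, end,
#'   extraGenes).
#' @param repeatFamilies,repeatLength,repeatCopies shared repeat families:
#'   how many, unit length, genome-wide copies per family.
#' @param mapSuppressionWidth bp of pericentromeric cM plateau.
#' @param totalCm genetic length per chromosome (cM).
#' @param gc GC content.
#' @param seed integer seed.
#' @return A validated \code{GenomeSpec}.
#' @examples
#' spec <- genomeSpec(nChromosomes = 2, geneCount = 50)
#' @export
genomeSpec <- function(nChromosomes = 3,
                       armLengths = c(S = 6e5, L = 8e5),
                       centromereOverlapLen = 1.2e5,
                       geneCount = 120,
                       geneLength = 1500,
                       hcFraction = 0.6,
                       distalEnrichment = 4,
                       interiorIsland = data.frame(
                         chrom = "2H", start = 4e5, end = 6e5,
                         extraGenes = 60),
                       repeatFamilies = 4,
                       repeatLength = 2000,
                       repeatCopies = 8,
                       mapSuppressionWidth = 3e5,
                       totalCm = 150,
                       gc = 0.445,
                       seed = 42) {
  if (is.null(dim(armLengths))) {
    if (length(armLengths) != 2L)
      stop("invalid 'armLengths': give c(S =, L =) or a matrix", call. = FALSE)
    armLengths <- matrix(rep(as.numeric(armLengths), each = nChromosomes),
                         ncol = 2, dimnames = list(NULL, c("S", "L")))
  } else {
    armLengths <- as.matrix(armLengths)
    colnames(armLengths) <- c("S", "L")
  }
  if (!is.null(interiorIsland)) {
    ok <- interiorIsland$chrom %in% paste0(seq_len(nChromosomes), "H")
    if (!all(ok))
      stop("invalid 'interiorIsland': unknown chromosome ",
           paste(interiorIsland$chrom[!ok], collapse = ", "), call. = FALSE)
  }
  new("GenomeSpec",
      nChromosomes = as.integer(nChromosomes),
      armLengths = armLengths,
      centromereOverlapLen = as.numeric(centromereOverlapLen),
      geneCount = as.integer(geneCount),
      geneLength = as.numeric(geneLength),
      hcFraction = as.numeric(hcFraction),
      distalEnrichment = as.numeric(distalEnrichment),
      interiorIsland = interiorIsland,
      repeatFamilies = as.integer(repeatFamilies),
      repeatLength = as.numeric(repeatLength),
      repeatCopies = as.integer(repeatCopies),
      mapSuppressionWidth = as.numeric(mapSuppressionWidth),
      totalCm = as.numeric(totalCm),
      gc = as.numeric(gc),
      seed = as.integer(seed))
}

# ---- SimGenome -------------------------------------------------------------

#' A simulated genome with ground truth
#'
#' Holds the per-arm target sequences, full chromosome sequences, gene
#' coordinates, genetic-map samples and the simulation truth needed for
#' recovery tests.
#'
#' @slot spec the \code{\linkS4class{GenomeSpec}} that produced it.
#' @slot arms \code{DNAStringSet} of flow-sorted arm target sequences,
#'   named e.g. \code{1HS}, \code{1HL}.
#' @slot chromosomes \code{DNAStringSet} of full chromosome sequences
#'   (arms joined through the shared centromeric overlap).
#' @slot genes data.frame: \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{class} (HC/LC), \code{island} (logical). 1-based
#'   closed coordinates.
#' @slot map data.frame of genetic-map samples: \code{chrom}, \code{bp},
#'   \code{cM}; weakly monotone in bp within each chromosome.
#' @slot truth list of ground-truth helpers (chromosome lengths, centromere
#'   centers, repeat insert coordinates).
#' @export
setClass("SimGenome", representation(
  spec = "GenomeSpec",
  arms = "DNAStringSet",
  chromosomes = "DNAStringSet",
  genes = "data.frame",
  map = "data.frame",
  truth = "list"
))

setValidity("SimGenome", function(object) {
  msg <- character(0)
  for (ch in unique(object@map$chrom)) {
    cm <- object@map$cM[object@map$chrom == ch]
    if (is.unsorted(cm)) msg <- c(msg, sprintf("map not monotone on %s", ch))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimGenome", function(object) {
  cat(sprintf("SimGenome: %d chromosome(s), %d arm target(s), %d gene(s)\n",
              object@spec@nChromosomes, length(object@arms),
              nrow(object@genes)))
  cat(sprintf("  chromosome length(s): %s bp\n",
              paste(width(object@chromosomes), collapse = ", ")))
})

#' @describeIn SimGenome arm target sequences.
#' @param x,object a \code{SimGenome}.
#' @export
armTargets <- function(x) x@arms

#' @describeIn SimGenome gene coordinate table.
#' @export
geneTable <- function(x) x@genes

#' @describeIn SimGenome genetic-map sample table.
#' @export
mapTable <- function(x) x@map

#' Interpolated genetic position
#'
#' Linear interpolation of the simulated genetic map.
#' @param genome a \code{SimGenome}.
#' @param chrom chromosome name.
#' @param bp physical positions.
#' @return cM values at \code{bp}.
#' @export
cmAt <- function(genome, chrom, bp) {
  m <- genome@map[genome@map$chrom == chrom, ]
  if (!nrow(m)) stop("unknown chromosome: ", chrom, call. = FALSE)
  approx(m$bp, m$cM, xout = bp, rule = 2)$y
}

# ---- BacLibrary ------------------------------------------------------------

#' A simulated or loaded BAC library
#'
#' A set of BAC clone assemblies, each a collection of node sequences
#' (assembler contigs). Nodes are stored as one \code{DNAStringSet}; the
#' parallel \code{bac} vector maps each node to its clone. When simulated,
#' \code{truth} records each clone's true origin.
#'
#' @slot nodes \code{DNAStringSet}; names are \code{<bac_id>|node<i>}.
#' @slot bac character vector parallel to \code{nodes}: owning BAC id.
#' @slot truth data.frame (possibly 0-row): \code{bac_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{label} (true arm-of-origin label; a
#'   trailing \code{*} marks clones spanning arm boundaries ambiguously).
#' @slot geneOverlaps data.frame (possibly 0-row): true gene-clone overlaps
#'   with \code{bac_id}, \code{gene_id}, \code{overlap_bp}.
#' @export
setClass("BacLibrary", representation(
  nodes = "DNAStringSet",
  bac = "character",
  truth = "data.frame",
  geneOverlaps = "data.frame"
))

setValidity("BacLibrary", function(object) {
  if (length(object@nodes) != length(object@bac))
    "'bac' must be parallel to 'nodes'" else TRUE
})

setMethod("show", "BacLibrary", function(object) {
  cat(sprintf("BacLibrary: %d BAC(s), %d node(s), %.1f Mb assembled\n",
              length(unique(object@bac)), length(object@nodes),
              sum(width(object@nodes)) / 1e6))
})

setMethod("length", "BacLibrary", function(x) length(unique(x@bac)))

#' @describeIn BacLibrary unique BAC identifiers.
#' @param x a \code{BacLibrary}.
#' @export
bacIds <- function(x) unique(x@bac)

#' @describeIn BacLibrary node sequences of one BAC (a \code{DNAStringSet}).
#' @param id a BAC identifier.
#' @export
bacNodes <- function(x, id) x@nodes[x@bac == id]

#' @describeIn BacLibrary simulation truth table.
#' @export
bacTruth <- function(x) x@truth

#' @describeIn BacLibrary named list of node-length vectors per BAC.
#' @export
nodeLengths <- function(x) split(setNames(width(x@nodes), names(x@nodes)), x@bac)

#' Subset a BacLibrary by BAC id
#' @param x a \code{BacLibrary}.
#' @param i character vector of BAC ids.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BacLibrary", function(x, i, j, ..., drop = FALSE) {
  keep <- x@bac %in% i
  new("BacLibrary", nodes = x@nodes[keep], bac = x@bac[keep],
      truth = x@truth[x@truth$bac_id %in% i, , drop = FALSE],
      geneOverlaps = x@geneOverlaps[x@geneOverlaps$bac_id %in% i, ,
                                    drop = FALSE])
})

#' Assemble a BacLibrary from sequences
#'
#' @param nodes \code{DNAStringSet} of node sequences; names must be
#'   \code{<bac_id>|<node_id>} unless \code{bac} is given.
#' @param bac optional character vector assigning each node to a BAC.
#' @param truth,geneOverlaps optional simulation-truth tables.
#' @return A \code{BacLibrary}.
#' @export
bacLibrary <- function(nodes, bac = NULL, truth = NULL, geneOverlaps = NULL) {
  if (is.null(bac)) {
    if (is.null(names(nodes)) || !all(grepl("|", names(nodes), fixed = TRUE)))
      stop("node names must be '<bac_id>|<node_id>' when 'bac' is missing",
           call. = FALSE)
    bac <- sub("\\|.*$", "", names(nodes))
  }
  emptyTruth <- data.frame(bac_id = character(0), chrom = character(0),
                           start = numeric(0), end = numeric(0),
                           label = character(0))
  emptyOv <- data.frame(bac_id = character(0), gene_id = character(0),
                        overlap_bp = numeric(0))
  new("BacLibrary", nodes = nodes, bac = as.character(bac),
      truth = if (is.null(truth)) emptyTruth else truth,
      geneOverlaps = if (is.null(geneOverlaps)) emptyOv else geneOverlaps)
}
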