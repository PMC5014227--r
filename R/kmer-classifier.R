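#' @include AllClasses.R utils.R
NULL

# ---- configuration ---------------------------------------------------------

#' Classifier configuration
#'
#' Parameters of the discriminative k-mer classifier. The defaults follow
#' standard practice for assigning BAC assemblies to flow-sorted chromosome
#' arms: 19-mers, within-target k-mers seen only once discarded as likely
#' sequencing artefacts, canonical (strand-free) k-mers, and a strict
#' confidence acceptance of > 0.75.
#'
#' @slot k k-mer length (0 < k <= 31).
#' @slot minKmerCount minimum within-target occurrence count to keep a
#'   k-mer (>= 1).
#' @slot confidenceThreshold minimum accepted confidence, exclusive.
#' @slot canonical strand-canonicalize k-mers?
#' @slot countMode \code{"occurrences"} counts k-mer hits with multiplicity
#'   in the query; \code{"distinct"} counts each distinct k-mer once.
#' @export
setClass("ClassifierConfig", representation(
  k = "integer",
  minKmerCount = "integer",
  confidenceThreshold = "numeric",
  canonical = "logical",
  countMode = "character"
))

setValidity("ClassifierConfig", function(object) {
  msg <- character(0)
  if (object@k < 1L || object@k > 31L) msg <- c(msg, "'k' must be in 1..31")
  if (object@minKmerCount < 1L) msg <- c(msg, "'minKmerCount' must be >= 1")
  if (object@confidenceThreshold < 0 || object@confidenceThreshold >= 1)
    msg <- c(msg, "'confidenceThreshold' must be in [0, 1)")
  if (!object@countMode %in% c("occurrences", "distinct"))
    msg <- c(msg, "'countMode' must be 'occurrences' or 'distinct'")
  if (length(msg)) msg else TRUE
})

#' @rdname ClassifierConfig-class
#' @param k,minKmerCount,confidenceThreshold,canonical,countMode see slots.
#' @return a validated \code{ClassifierConfig}.
#' @examples
#' classifierConfig()
#' @export
classifierConfig <- function(k = 19, minKmerCount = 2,
                             confidenceThreshold = 0.75, canonical = TRUE,
                             countMode = c("occurrences", "distinct")) {
  new("ClassifierConfig", k = as.integer(k),
      minKmerCount = as.integer(minKmerCount),
      confidenceThreshold = as.numeric(confidenceThreshold),
      canonical = as.logical(canonical),
      countMode = match.arg(countMode))
}

# ---- KmerIndex -------------------------------------------------------------

#' Discriminative k-mer index
#'
#' Maps each retained k-mer to exactly one target label. Labels are the arm
#' or whole-chromosome target names plus centromeric pseudo-labels
#' (\code{<chrom>C}) for k-mers shared by exactly the S and L arm targets
#' of one chromosome.
#'
#' @slot k k-mer length.
#' @slot canonical whether k-mers are strand-canonicalized.
#' @slot kmer character vector of retained k-mers.
#' @slot label character vector parallel to \code{kmer}: the single target
#'   each k-mer is discriminative for.
#' @slot targets the input target labels.
#' @export
setClass("KmerIndex", representation(
  k = "integer",
  canonical = "logical",
  kmer = "character",
  label = "character",
  targets = "character"
))

setValidity("KmerIndex", function(object) {
  msg <- character(0)
  if (length(object@kmer) != length(object@label))
    msg <- c(msg, "'kmer' and 'label' must be parallel")
  if (anyDuplicated(object@kmer))
    msg <- c(msg, "a k-mer maps to two labels")
  cen <- setdiff(unique(object@label), object@targets)
  for (cl in cen) {
    stem <- sub("C$", "", cl)
    if (!grepl("C$", cl) ||
        !all(paste0(stem, c("S", "L")) %in% object@targets))
      msg <- c(msg, sprintf(
        "centromeric label '%s' lacks matching S/L arm targets", cl))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerIndex", function(object) {
  cat(sprintf("KmerIndex: k=%d, canonical=%s, %d discriminative k-mer(s)\n",
              object@k, object@canonical, length(object@kmer)))
  if (length(object@kmer)) {
    tab <- table(object@label)
    cat("  per-label counts:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' @describeIn KmerIndex number of discriminative k-mers per label.
#' @param object a \code{KmerIndex}.
#' @export
indexLabelCounts <- function(object) {
  tab <- table(object@label)
  setNames(as.integer(tab), names(tab))
}

# Do two labels form the S/L arm pair of one chromosome?
armPairChrom <- function(a, b) {
  sa <- sub("[SL]$", "", a); sb <- sub("[SL]$", "", b)
  ok <- grepl("[SL]$", a) & grepl("[SL]$", b) & sa == sb &
    substring(a, nchar(a)) != substring(b, nchar(b))
  ifelse(ok, sa, NA_character_)
}

#' Build a discriminative k-mer index from target sequences
#'
#' Enumerates the k-mers of every target (a target may comprise several
#' sequences, e.g. a labelled multi-FASTA), discards within-target k-mers
#' whose total count is below \code{minKmerCount}, then keeps a k-mer only
#' if it occurs in exactly one target (indexed under that target's label)
#' or in exactly the S and L arm targets of one chromosome and nowhere else
#' (indexed under the chromosome's centromeric label \code{<chrom>C}).
#' All other multi-target k-mers are discarded.
#'
#' @param targets a named \code{DNAStringSet} (duplicate names pool
#'   sequences into one target) or a named list of \code{DNAStringSet}.
#' @param config a \code{\linkS4class{ClassifierConfig}}.
#' @return A \code{\linkS4class{KmerIndex}}.
#' @examples
#' t <- Biostrings::DNAStringSet(c(
#'   A = paste(rep("ACGTT", 20), collapse = ""),
#'   B = paste(rep("GGATC", 20), collapse = "")))
#' buildKmerIndex(t, classifierConfig(k = 7, minKmerCount = 1))
#' @export
buildKmerIndex <- function(targets, config = classifierConfig()) {
  validObject(config)
  if (is.list(targets)) {
    labs <- names(targets)
    if (is.null(labs) || anyDuplicated(labs))
      stop("list targets need unique names", call. = FALSE)
    seqsOf <- lapply(targets, as.character)
  } else {
    labs <- unique(names(targets))
    if (is.null(labs)) stop("targets must be named", call. = FALSE)
    seqsOf <- lapply(labs, function(lb)
      as.character(targets[names(targets) == lb]))
    names(seqsOf) <- labs
  }
  if (length(labs) < 2L) stop("need >= 2 targets", call. = FALSE)
  if (any(!nzchar(unlist(seqsOf))) || any(lengths(seqsOf) == 0L))
    stop("empty target sequence set", call. = FALSE)

  perTarget <- lapply(seqsOf, function(ss) {
    km <- kmersOfSequences(ss, config@k, config@canonical)
    if (config@minKmerCount > 1L) {
      tt <- table(km)
      names(tt)[tt >= config@minKmerCount]
    } else unique(km)
  })

  allk <- unlist(perTarget, use.names = FALSE)
  alll <- rep(labs, lengths(perTarget))
  o <- order(allk, method = "radix")
  allk <- allk[o]; alll <- alll[o]
  r <- rle(allk)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  one <- r$lengths == 1L
  keepK <- r$values[one]
  keepL <- alll[starts[one]]

  two <- which(r$lengths == 2L)
  if (length(two)) {
    l1 <- alll[starts[two]]; l2 <- alll[starts[two] + 1L]
    stem <- armPairChrom(l1, l2)
    cen <- !is.na(stem)
    keepK <- c(keepK, r$values[two][cen])
    keepL <- c(keepL, paste0(stem[cen], "C"))
  }

  new("KmerIndex", k = config@k, canonical = config@canonical,
      kmer = keepK, label = keepL, targets = labs)
}

# ---- classification --------------------------------------------------------

UNASSIGNED <- "UNASSIGNED"

#' Classify one BAC assembly against a k-mer index
#'
#' Counts, per label, the BAC's k-mers found in the index (with
#' multiplicity under \code{countMode = "occurrences"}). With h1 the best
#' label's count and h2 the runner-up, the confidence is h1 / (h1 + h2)
#' (1 when h2 = 0, 0 when there are no hits). The top label is returned
#' only if the confidence strictly exceeds the threshold and h1 >= 1; ties
#' for the top count yield \code{UNASSIGNED}.
#'
#' @param index a \code{\linkS4class{KmerIndex}}.
#' @param bac a \code{DNAStringSet} of node sequences, a character vector,
#'   or a \code{\linkS4class{BacLibrary}} with a single BAC.
#' @param config a \code{\linkS4class{ClassifierConfig}}; its \code{k} and
#'   \code{canonical} must match the index.
#' @return A one-row data.frame: \code{bac_id}, \code{label},
#'   \code{confidence}, \code{h1}, \code{h2}, \code{total_hits}, with the
#'   full per-label count vector as attribute \code{"hits"}.
#' @export
classifyBac <- function(index, bac, config = classifierConfig()) {
  stopifnot(is(index, "KmerIndex"))
  if (config@k != index@k)
    stop("k mismatch between index (", index@k, ") and config (",
         config@k, ")", call. = FALSE)
  if (config@canonical != index@canonical)
    stop("canonicalization mismatch between index and config", call. = FALSE)
  bacId <- "query"
  if (is(bac, "BacLibrary")) {
    ids <- bacIds(bac)
    if (length(ids) != 1L)
      stop("use classifyLibrary() for multi-BAC input", call. = FALSE)
    bacId <- ids
    bac <- bacNodes(bac, ids)
  }
  km <- kmersOfSequences(bac, index@k, index@canonical)
  if (config@countMode == "distinct") km <- unique(km)
  labs <- sort(unique(index@label))
  hitlab <- index@label[match(km, index@kmer)]
  hits <- table(factor(hitlab[!is.na(hitlab)], levels = labs))
  hits <- setNames(as.integer(hits), labs)
  assignmentFromHits(bacId, hits, config@confidenceThreshold)
}

# Turn a per-label hit-count vector into an Assignment row.
assignmentFromHits <- function(bacId, hits, threshold) {
  h1 <- if (length(hits)) max(hits) else 0L
  top <- names(hits)[hits == h1]
  h2 <- if (length(hits) > 1L) max(hits[-which.max(hits)]) else 0L
  conf <- if (h1 == 0L) 0 else h1 / (h1 + h2)
  label <- if (h1 >= 1L && length(top) == 1L && conf > threshold)
    top else UNASSIGNED
  out <- data.frame(bac_id = bacId, label = label, confidence = conf,
                    h1 = h1, h2 = h2, total_hits = sum(hits))
  attr(out, "hits") <- hits
  out
}

#' Classify a whole BAC library
#'
#' @param index a \code{\linkS4class{KmerIndex}}.
#' @param library a \code{\linkS4class{BacLibrary}}.
#' @param config a \code{\linkS4class{ClassifierConfig}}.
#' @param chunkSize BACs looked up per \code{match()} call; a larger chunk
#'   amortizes the hash build over more queries at higher peak memory.
#' @return data.frame with one row per BAC (columns as
#'   \code{\link{classifyBac}}); attribute \code{"summary"} holds per-label
#'   counts and the assignment rate as a percentage with one decimal
#'   (0 for an empty library).
#' @export
classifyLibrary <- function(index, library, config = classifierConfig(),
                            chunkSize = 50L) {
  stopifnot(is(library, "BacLibrary"))
  if (config@k != index@k)
    stop("k mismatch between index (", index@k, ") and config (",
         config@k, ")", call. = FALSE)
  if (config@canonical != index@canonical)
    stop("canonicalization mismatch between index and config", call. = FALSE)
  ids <- bacIds(library)
  labs <- sort(unique(index@label))
  rows <- vector("list", length(ids))
  if (length(ids)) {
    chunks <- split(seq_along(ids), ceiling(seq_along(ids) / chunkSize))
    for (ck in chunks) {
      kms <- lapply(ids[ck], function(id) {
        km <- kmersOfSequences(bacNodes(library, id), index@k,
                               index@canonical)
        if (config@countMode == "distinct") unique(km) else km
      })
      grp <- rep(seq_along(ck), lengths(kms))
      lab <- index@label[match(unlist(kms, use.names = FALSE), index@kmer)]
      ok <- !is.na(lab)
      tab <- table(factor(grp[ok], levels = seq_along(ck)),
                   factor(lab[ok], levels = labs))
      for (j in seq_along(ck))
        rows[[ck[j]]] <- assignmentFromHits(
          ids[ck[j]], setNames(as.integer(tab[j, ]), labs),
          config@confidenceThreshold)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bac_id = character(0), label = character(0),
               confidence = numeric(0), h1 = integer(0), h2 = integer(0),
               total_hits = integer(0))
  out$bac_id <- ids[seq_len(nrow(out))]
  n <- nrow(out)
  assigned <- sum(out$label != UNASSIGNED)
  attr(out, "summary") <- list(
    n = n,
    assigned = assigned,
    rate_pct = if (n) pct1(assigned / n) else 0,
    perLabel = table(out$label))
  out
}

# ---- index serialization ---------------------------------------------------

.INDEX_MAGIC <- "#BACographyKmerIndex\tv1"

#' Write / read a k-mer index
#'
#' Plain-text TSV with an explicit magic string and version so corrupted or
#' foreign files are rejected on read.
#'
#' @param index a \code{\linkS4class{KmerIndex}}.
#' @param path file path.
#' @return \code{writeKmerIndex}: \code{path} invisibly;
#'   \code{readKmerIndex}: the \code{KmerIndex}.
#' @export
writeKmerIndex <- function(index, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(.INDEX_MAGIC, con)
  writeLines(sprintf("#k=%d\tcanonical=%s\ttargets=%s", index@k,
                     index@canonical,
                     paste(index@targets, collapse = ",")), con)
  write.table(data.frame(kmer = index@kmer, label = index@label), con,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeKmerIndex
#' @export
readKmerIndex <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L || head2[1L] != .INDEX_MAGIC)
    stop("not a BACography k-mer index: ", path, call. = FALSE)
  meta <- strsplit(sub("^#", "", head2[2L]), "\t")[[1L]]
  kv <- strsplit(meta, "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- read.delim(path, skip = 2L, header = FALSE,
                   col.names = c("kmer", "label"),
                   stringsAsFactors = FALSE)
  new("KmerIndex", k = as.integer(vals[["k"]]),
      canonical = as.logical(vals[["canonical"]]),
      kmer = df$kmer, label = df$label,
      targets = strsplit(vals[["targets"]], ",")[[1L]])
}
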