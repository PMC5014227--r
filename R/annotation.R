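#' @include AllClasses.R utils.R
NULL

#' Annotation configuration
#'
#' Filters applied to tabular alignment hits between BAC assembly nodes and
#' predicted gene models: nodes below a minimum length are ignored, weak
#' alignments are dropped by e-value, and gene models hitting many distinct
#' BACs (mostly transposable-element related) are excluded from counts.
#'
#' @param minNodeLen minimum node length in bp (default 200).
#' @param evalueCutoff maximum e-value retained (default 1e-20).
#' @param frequentBacThreshold gene models hitting at least this many
#'   distinct BACs are excluded (default 10).
#' @return a list of class \code{"AnnotationConfig"}.
#' @export
annotationConfig <- function(minNodeLen = 200, evalueCutoff = 1e-20,
                             frequentBacThreshold = 10) {
  if (minNodeLen < 1) stop("'minNodeLen' must be >= 1", call. = FALSE)
  if (evalueCutoff <= 0) stop("'evalueCutoff' must be > 0", call. = FALSE)
  if (frequentBacThreshold < 2)
    stop("'frequentBacThreshold' must be >= 2", call. = FALSE)
  structure(list(minNodeLen = minNodeLen, evalueCutoff = evalueCutoff,
                 frequentBacThreshold = frequentBacThreshold),
            class = "AnnotationConfig")
}

# Derive the owning BAC from node ids of the form "<bac>|<node>".
nodeToBac <- function(nodeIds) sub("\\|.*$", "", nodeIds)

#' Filter raw alignment hits by node length and e-value
#'
#' @param hits data.frame in 12-column tabular alignment format with at
#'   least \code{qseqid} (node id), \code{sseqid} (gene model id) and
#'   \code{evalue}; optional \code{sstart}, \code{send}.
#' @param nodeLen named numeric vector: length of every known node.
#' @param config an \code{\link{annotationConfig}}.
#' @param classOf optional named character vector mapping gene model id to
#'   confidence class (\code{HC}/\code{LC}); unknown models default to HC.
#' @return data.frame of retained hits, sorted by (bac_id, gene_model_id,
#'   evalue): \code{bac_id}, \code{gene_model_id}, \code{class},
#'   \code{node_id}, \code{evalue}, \code{sstart}, \code{send}.
#' @export
filterHits <- function(hits, nodeLen, config = annotationConfig(),
                       classOf = NULL) {
  need <- c("qseqid", "sseqid", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits need columns ", paste(need, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(hits$qseqid), names(nodeLen))
  if (length(unknown))
    stop("hits reference unknown node(s): ",
         paste(head(unknown, 10), collapse = ", "), call. = FALSE)
  keep <- nodeLen[hits$qseqid] >= config$minNodeLen &
    hits$evalue <= config$evalueCutoff
  h <- hits[keep, , drop = FALSE]
  cls <- if (is.null(classOf)) rep("HC", nrow(h)) else {
    cc <- unname(classOf[h$sseqid])
    cc[is.na(cc)] <- "HC"
    cc
  }
  out <- data.frame(bac_id = nodeToBac(h$qseqid),
                    gene_model_id = h$sseqid,
                    class = cls,
                    node_id = h$qseqid,
                    evalue = h$evalue,
                    sstart = if ("sstart" %in% names(h)) h$sstart else NA,
                    send = if ("send" %in% names(h)) h$send else NA)
  out <- out[order(out$bac_id, out$gene_model_id, out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude gene models hitting many distinct BACs
#'
#' A model is excluded when its distinct-BAC count reaches
#' \code{frequentBacThreshold}; all its hits are removed.
#'
#' @param hits filtered hits from \code{\link{filterHits}}.
#' @param config an \code{\link{annotationConfig}}.
#' @return list with \code{excluded} (character vector of model ids) and
#'   \code{retained} (the surviving hits).
#' @export
flagFrequentModels <- function(hits, config = annotationConfig()) {
  if (!nrow(hits))
    return(list(excluded = character(0), retained = hits))
  nBac <- tapply(hits$bac_id, hits$gene_model_id,
                 function(x) length(unique(x)))
  excluded <- names(nBac)[nBac >= config$frequentBacThreshold]
  list(excluded = excluded,
       retained = hits[!hits$gene_model_id %in% excluded, , drop = FALSE])
}

#' Count distinct gene models per BAC, per label and genome-wide
#'
#' A model aligning to several nodes of one BAC counts once for that BAC.
#' Per-label uniqueness is computed within the label; overall uniqueness
#' across all BACs (so the per-label counts can sum to more than the
#' overall count when models are shared between arms).
#'
#' @param hits retained hits (post \code{\link{flagFrequentModels}}).
#' @param assignments data.frame with \code{bac_id} and \code{label}
#'   covering every BAC of the library (including unassigned ones), e.g.
#'   from \code{\link{classifyLibrary}}.
#' @return list with \code{perBac} (bac_id, label, n_hc, n_lc),
#'   \code{perLabel} (label, n_bacs, unique_hc, unique_lc) and
#'   \code{summary} (unique model counts overall, BACs with 0 / >= 1
#'   models, mean HC models per BAC).
#' @export
countGenes <- function(hits, assignments) {
  if (!all(hits$bac_id %in% assignments$bac_id))
    stop("hits reference BACs absent from 'assignments'", call. = FALSE)
  pairs <- unique(hits[, c("bac_id", "gene_model_id", "class")])
  cnt <- function(ids, cls, bacs) {
    vapply(bacs, function(b)
      length(unique(ids[pairs$bac_id == b & pairs$class == cls])), 0L)
  }
  bacs <- assignments$bac_id
  perBac <- data.frame(
    bac_id = bacs,
    label = assignments$label,
    n_hc = cnt(pairs$gene_model_id, "HC", bacs),
    n_lc = cnt(pairs$gene_model_id, "LC", bacs))
  labOf <- setNames(assignments$label, assignments$bac_id)
  pairs$label <- unname(labOf[pairs$bac_id])
  perLabel <- do.call(rbind, lapply(sort(unique(perBac$label)), function(lb) {
    p <- pairs[pairs$label == lb, , drop = FALSE]
    data.frame(label = lb,
               n_bacs = sum(perBac$label == lb),
               unique_hc = length(unique(p$gene_model_id[p$class == "HC"])),
               unique_lc = length(unique(p$gene_model_id[p$class == "LC"])))
  }))
  list(perBac = perBac,
       perLabel = perLabel,
       summary = list(
         unique_hc = length(unique(pairs$gene_model_id[pairs$class == "HC"])),
         unique_lc = length(unique(pairs$gene_model_id[pairs$class == "LC"])),
         bacs_with_genes = sum(perBac$n_hc + perBac$n_lc > 0),
         bacs_without_genes = sum(perBac$n_hc + perBac$n_lc == 0),
         mean_hc_per_bac = mean(perBac$n_hc)))
}

#' GC content of an assembly
#'
#' (G+C)/(A+C+G+T) over all nodes; ambiguous letters are excluded from both
#' numerator and denominator. An assembly with no unambiguous bases has
#' undefined GC content, reported as \code{NA}.
#'
#' @param x a \code{DNAStringSet}, character vector of sequences, or a
#'   \code{\linkS4class{BacLibrary}} (one value per BAC).
#' @return numeric fraction in [0, 1], or a named vector for a library.
#' @examples
#' gcContent("ACGTN")  # 0.5
#' @export
gcContent <- function(x) {
  if (is(x, "BacLibrary")) {
    ids <- bacIds(x)
    return(setNames(vapply(ids, function(id) gcContent(bacNodes(x, id)),
                           numeric(1)), ids))
  }
  if (is.character(x)) x <- DNAStringSet(toupper(x))
  f <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f["G"] + f["C"]) / tot)
}

# ---- built-in matcher ------------------------------------------------------

#' Built-in exact-seed gene matcher
#'
#' A deterministic stand-in for an external aligner, sufficient for
#' synthetic sequence: non-overlapping seeds of length \code{seedLen} are
#' taken along each gene model (both strands) and located exactly in the
#' assembly nodes; each seed hit anchors an ungapped alignment of the whole
#' gene against the node, truncated at node boundaries. Alignments with
#' identity >= \code{minIdentity} over an aligned span of at least
#' \code{minSpan} bp are emitted as 12-column tabular hits with a
#' pseudo-e-value of 1e-30.
#'
#' @param nodes a \code{DNAStringSet} of assembly nodes (or a
#'   \code{\linkS4class{BacLibrary}}).
#' @param genes a named \code{DNAStringSet} of gene model sequences.
#' @param seedLen exact seed length (default 31).
#' @param minIdentity minimum identity fraction (default 0.9).
#' @param minSpan minimum aligned span in bp (default 200).
#' @return data.frame in tabular alignment format: \code{qseqid},
#'   \code{sseqid}, \code{pident}, \code{length}, \code{mismatch},
#'   \code{gapopen}, \code{qstart}, \code{qend}, \code{sstart},
#'   \code{send}, \code{evalue}, \code{bitscore}.
#' @export
matchGenesBuiltin <- function(nodes, genes, seedLen = 31, minIdentity = 0.9,
                              minSpan = 200) {
  if (is(nodes, "BacLibrary")) nodes <- nodes@nodes
  stopifnot(is(nodes, "DNAStringSet"), is(genes, "DNAStringSet"))
  if (is.null(names(nodes)) || is.null(names(genes)))
    stop("nodes and genes must be named", call. = FALSE)
  empty <- data.frame(qseqid = character(0), sseqid = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), gapopen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      evalue = numeric(0), bitscore = numeric(0))
  genes <- genes[width(genes) >= seedLen]
  if (!length(genes) || !length(nodes)) return(empty)

  # concatenate nodes with N spacers so seeds cannot bridge nodes
  spacer <- paste(rep("N", seedLen + 9), collapse = "")
  nodeChar <- as.character(nodes)
  cat1 <- DNAString(paste(nodeChar, collapse = spacer))
  offs <- cumsum(c(1, nchar(nodeChar) + nchar(spacer)))
  nodeStart <- offs[seq_along(nodeChar)]
  nodeEnd <- nodeStart + nchar(nodeChar) - 1

  seedRows <- list()
  for (strand in c("+", "-")) {
    gs <- if (strand == "+") genes else reverseComplement(genes)
    for (gi in seq_along(gs)) {
      gseq <- gs[[gi]]
      sOff <- seq(1, length(gseq) - seedLen + 1, by = seedLen)
      seedRows[[length(seedRows) + 1L]] <- data.frame(
        gene = names(gs)[gi], strand = strand, offset = sOff,
        seed = as.character(Biostrings::extractAt(
          gseq, IRanges(sOff, sOff + seedLen - 1))))
    }
  }
  seeds <- do.call(rbind, seedRows)
  pd <- Biostrings::PDict(DNAStringSet(seeds$seed))
  m <- Biostrings::matchPDict(pd, cat1)
  hits <- data.frame(
    pat = rep(seq_along(m), lengths(m)),
    pos = unlist(lapply(m, start), use.names = FALSE))
  if (!nrow(hits)) return(empty)
  hits$gene <- seeds$gene[hits$pat]
  hits$strand <- seeds$strand[hits$pat]
  hits$offset <- seeds$offset[hits$pat]
  ni <- findInterval(hits$pos, nodeStart)
  hits$node <- ni
  hits$nodePos <- hits$pos - nodeStart[ni] + 1
  hits$implied <- hits$nodePos - (hits$offset - 1)
  cand <- unique(hits[, c("gene", "strand", "node", "implied")])

  gCharF <- as.character(genes)
  gCharR <- as.character(reverseComplement(genes))
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand$gene[i]
    gseq <- if (cand$strand[i] == "+") gCharF[[g]] else gCharR[[g]]
    glen <- nchar(gseq)
    nlen <- nchar(nodeChar[cand$node[i]])
    qs <- max(1L, cand$implied[i])
    qe <- min(nlen, cand$implied[i] + glen - 1L)
    span <- qe - qs + 1L
    if (span < minSpan) next
    gs <- qs - cand$implied[i] + 1L
    ge <- gs + span - 1L
    a <- utf8ToInt(substr(nodeChar[cand$node[i]], qs, qe))
    b <- utf8ToInt(substr(gseq, gs, ge))
    ident <- sum(a == b) / span
    if (ident < minIdentity) next
    # subject coordinates on the forward gene strand
    if (cand$strand[i] == "+") {
      ss <- gs; se <- ge
    } else {
      ss <- glen - gs + 1L; se <- glen - ge + 1L
    }
    out[[i]] <- data.frame(
      qseqid = names(nodes)[cand$node[i]], sseqid = g,
      pident = round(100 * ident, 2), length = span,
      mismatch = as.integer(round(span * (1 - ident))), gapopen = 0L,
      qstart = qs, qend = qe, sstart = ss, send = se,
      evalue = 1e-30, bitscore = 2 * span)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$qseqid, out$sseqid, out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
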