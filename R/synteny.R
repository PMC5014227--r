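#' @include utils.R
NULL

#' Plurality-vote placement of BACs on a reference genome
#'
#' For each BAC, alignment hits passing the e-value cutoff are tallied per
#' subject chromosome; the chromosome with the plurality of matches wins
#' and the BAC's position is the arithmetic mean of the matched subject
#' coordinates on that chromosome. A tie for the plurality leaves the BAC
#' unplaced (\code{status = "tied"}); no surviving hits give
#' \code{status = "no_hits"}.
#'
#' @param hits data.frame with columns \code{query} (BAC id),
#'   \code{subject_chrom}, \code{subject_pos}, \code{evalue}.
#' @param evalueCutoff maximum e-value tallied (default 1e-20).
#' @return data.frame with one row per BAC: \code{bac_id}, \code{chrom}
#'   (NA unless placed), \code{position}, \code{status}, \code{n_hits},
#'   \code{top_votes}; attribute \code{"votes"} is a list of per-chromosome
#'   vote tables.
#' @examples
#' h <- data.frame(query = "b1", subject_chrom = "Os2",
#'                 subject_pos = c(1, 2, 6) * 1e6, evalue = 1e-30)
#' voteBacs(h)  # placed on Os2 at 3 Mb
#' @export
voteBacs <- function(hits, evalueCutoff = 1e-20) {
  need <- c("query", "subject_chrom", "subject_pos", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits need columns ", paste(need, collapse = ", "), call. = FALSE)
  hits <- hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  ids <- unique(hits$query)
  votesList <- list()
  rows <- lapply(ids, function(id) {
    h <- hits[hits$query == id, , drop = FALSE]
    if (!nrow(h))
      return(data.frame(bac_id = id, chrom = NA_character_,
                        position = NA_real_, status = "no_hits",
                        n_hits = 0L, top_votes = 0L))
    v <- table(h$subject_chrom)
    votesList[[id]] <<- v
    top <- names(v)[v == max(v)]
    if (length(top) > 1L)
      return(data.frame(bac_id = id, chrom = NA_character_,
                        position = NA_real_, status = "tied",
                        n_hits = nrow(h), top_votes = as.integer(max(v))))
    data.frame(bac_id = id, chrom = top,
               position = mean(h$subject_pos[h$subject_chrom == top]),
               status = "placed", n_hits = nrow(h),
               top_votes = as.integer(max(v)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bac_id = character(0), chrom = character(0),
               position = numeric(0), status = character(0),
               n_hits = integer(0), top_votes = integer(0))
  rownames(out) <- NULL
  attr(out, "votes") <- votesList
  out
}

#' Contig-level plurality vote
#'
#' Each member BAC already placed by \code{\link{voteBacs}} casts one vote
#' for its chromosome; the contig takes the plurality chromosome and the
#' mean of its members' positions on that chromosome.
#'
#' @param votes data.frame from \code{\link{voteBacs}}.
#' @param membership data.frame with \code{bac_id} and \code{contig_id}.
#' @return data.frame per contig: \code{contig_id}, \code{chrom},
#'   \code{position}, \code{status}, \code{n_members}, \code{n_placed}.
#' @export
voteContigs <- function(votes, membership) {
  if (!all(c("bac_id", "contig_id") %in% names(membership)))
    stop("membership needs columns bac_id, contig_id", call. = FALSE)
  v <- merge(membership, votes, by = "bac_id", all.x = TRUE)
  rows <- lapply(split(v, v$contig_id), function(m) {
    placed <- m[!is.na(m$status) & m$status == "placed", , drop = FALSE]
    base <- data.frame(contig_id = m$contig_id[1L], chrom = NA_character_,
                       position = NA_real_, status = "no_hits",
                       n_members = nrow(m), n_placed = nrow(placed))
    if (!nrow(placed)) return(base)
    tab <- table(placed$chrom)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) { base$status <- "tied"; return(base) }
    base$chrom <- top
    base$position <- mean(placed$position[placed$chrom == top])
    base$status <- "placed"
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join two genetic maps through shared markers and BACs
#'
#' Cross-relates two species' linkage maps via sequenced BACs: markers
#' anchored on map A are linked to BACs by sequence matches, and those BACs
#' carry positions on map B. Pairs whose linkage groups are not orthologous
#' per the supplied table are dropped; duplicate (marker, BAC) chains
#' collapse to one pair.
#'
#' @param markersToMapA data.frame: \code{marker}, \code{group}, \code{cM}.
#' @param markersToBacs data.frame: \code{marker}, \code{bac_id}.
#' @param bacsToMapB data.frame: \code{bac_id}, \code{group}, \code{cM}.
#' @param orthology data.frame of accepted group pairs: \code{group_a},
#'   \code{group_b}.
#' @return data.frame of anchor pairs: \code{marker}, \code{bac_id},
#'   \code{group_a}, \code{cM_a}, \code{group_b}, \code{cM_b}.
#' @export
anchorJoin <- function(markersToMapA, markersToBacs, bacsToMapB, orthology) {
  if (anyDuplicated(markersToMapA$marker)) {
    dup <- unique(markersToMapA$marker[duplicated(markersToMapA$marker)])
    stop("marker(s) mapped to two groups in map A: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(bacsToMapB$bac_id)) {
    dup <- unique(bacsToMapB$bac_id[duplicated(bacsToMapB$bac_id)])
    stop("BAC(s) mapped to two groups in map B: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  j <- merge(markersToMapA, markersToBacs, by = "marker")
  j <- merge(j, bacsToMapB, by = "bac_id", suffixes = c("_a", "_b"))
  ok <- paste(j$group_a, j$group_b) %in%
    paste(orthology$group_a, orthology$group_b)
  j <- j[ok, c("marker", "bac_id", "group_a", "cM_a", "group_b", "cM_b")]
  j <- unique(j)
  j <- j[order(j$group_a, j$cM_a, j$marker), , drop = FALSE]
  rownames(j) <- NULL
  j
}

#' Detect inversions between two maps from anchor pairs
#'
#' Slides a window of \code{windowSize} consecutive anchor pairs (sorted by
#' map-A position) and computes the Kendall rank correlation between the
#' two maps' positions. Maximal runs of at least \code{minRun} consecutive
#' windows with negative correlation are merged and reported with their
#' map-A extent. The windowed-correlation rule is a heuristic: reported
#' intervals depend on \code{windowSize} and local anchor density and
#' should be inspected on a dotplot.
#'
#' @param pairs data.frame with \code{cM_a} and \code{cM_b} (one orthology
#'   group pair).
#' @param windowSize consecutive pairs per window (default 10).
#' @param minRun minimum run of negative windows (default 2).
#' @return data.frame: \code{start_cM_a}, \code{end_cM_a}, \code{n_pairs},
#'   \code{mean_tau}. Empty (with a warning) when there are fewer pairs
#'   than \code{windowSize}.
#' @export
detectInversions <- function(pairs, windowSize = 10, minRun = 2) {
  empty <- data.frame(start_cM_a = numeric(0), end_cM_a = numeric(0),
                      n_pairs = integer(0), mean_tau = numeric(0))
  n <- nrow(pairs)
  if (n < windowSize) {
    warning("fewer pairs (", n, ") than windowSize (", windowSize, ")")
    return(empty)
  }
  pairs <- pairs[order(pairs$cM_a), , drop = FALSE]
  nw <- n - windowSize + 1L
  tau <- vapply(seq_len(nw), function(i) {
    idx <- i:(i + windowSize - 1L)
    suppressWarnings(cor(pairs$cM_a[idx], pairs$cM_b[idx],
                         method = "kendall"))
  }, numeric(1))
  neg <- !is.na(tau) & tau < 0
  if (!any(neg)) return(empty)
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= minRun)
  if (!length(runs)) return(empty)
  # pair-index intervals covered by each qualifying run; merge overlaps
  iv <- IRanges(starts[runs], ends[runs] + windowSize - 1L)
  iv <- reduce(iv)
  out <- data.frame(
    start_cM_a = pairs$cM_a[start(iv)],
    end_cM_a = pairs$cM_a[pmin(end(iv), n)],
    n_pairs = width(iv),
    mean_tau = vapply(seq_along(iv), function(j) {
      wins <- max(1L, start(iv)[j]):min(nw, end(iv)[j] - windowSize + 1L)
      mean(tau[wins], na.rm = TRUE)
    }, numeric(1)))
  rownames(out) <- NULL
  out
}
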