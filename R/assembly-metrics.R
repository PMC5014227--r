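#' @include AllClasses.R annotation.R
NULL

#' N50 and L50 of a set of node lengths
#'
#' With lengths sorted in decreasing order and T their total: L50 is the
#' smallest number of nodes whose lengths sum to \emph{more than} T/2, and
#' N50 is the length of the last node in the smallest prefix whose sum is
#' \emph{at least} T/2. The asymmetric readings (\code{>=} for N50,
#' \code{>} for L50) follow the definitions customarily attached to BAC
#' assembly summary tables; \code{mode = "conventional"} uses \code{>=}
#' for both.
#'
#' @param lengths numeric vector of positive node lengths.
#' @param mode \code{"classic"} (default; asymmetric readings) or
#'   \code{"conventional"}.
#' @return list with \code{n50} and \code{l50}.
#' @examples
#' n50l50(c(50, 50))          # n50 = 50, l50 = 2
#' n50l50(c(9, 8, 7, 6, 5))   # n50 = 7, l50 = 3
#' @export
n50l50 <- function(lengths, mode = c("classic", "conventional")) {
  mode <- match.arg(mode)
  if (!length(lengths)) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  cums <- cumsum(s)
  half <- sum(s) / 2
  i50 <- which(cums >= half)[1L]
  l50 <- if (mode == "classic") which(cums > half)[1L] else i50
  list(n50 = s[i50], l50 = as.integer(l50))
}

#' Per-BAC assembly statistics
#'
#' @param library a \code{\linkS4class{BacLibrary}}.
#' @param minNodeLen nodes shorter than this are ignored (default 200 bp).
#' @return data.frame: \code{bac_id}, \code{n_nodes}, \code{total_len},
#'   \code{n50}, \code{l50}, \code{gc}.
#' @export
bacStats <- function(library, minNodeLen = 200) {
  stopifnot(is(library, "BacLibrary"))
  ids <- bacIds(library)
  rows <- lapply(ids, function(id) {
    nd <- bacNodes(library, id)
    nd <- nd[width(nd) >= minNodeLen]
    if (!length(nd))
      return(data.frame(bac_id = id, n_nodes = 0L, total_len = 0,
                        n50 = NA_real_, l50 = NA_integer_, gc = NA_real_))
    nl <- n50l50(width(nd))
    data.frame(bac_id = id, n_nodes = length(nd),
               total_len = sum(width(nd)), n50 = nl$n50, l50 = nl$l50,
               gc = gcContent(nd))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-BAC statistics into a per-label summary table
#'
#' One row per assignment label plus an \code{All} row recomputed from the
#' pooled BAC set (not from group means). Group averages are unweighted
#' means over member BACs; values are not rounded (round at rendering).
#'
#' @param stats per-BAC statistics from \code{\link{bacStats}}.
#' @param assignments data.frame with \code{bac_id} and \code{label} for
#'   every BAC in \code{stats}.
#' @param geneCounts optional result of \code{\link{countGenes}}; adds
#'   per-label unique HC/LC model counts.
#' @return data.frame: \code{label}, \code{n_bacs}, \code{avg_nodes},
#'   \code{total_len}, \code{avg_len}, \code{avg_n50}, \code{avg_l50}
#'   (+ \code{unique_hc}, \code{unique_lc} when gene counts are supplied).
#' @export
aggregateTable <- function(stats, assignments, geneCounts = NULL) {
  missing <- setdiff(stats$bac_id, assignments$bac_id)
  if (length(missing))
    stop("BAC(s) without assignment: ", paste(head(missing, 5),
                                              collapse = ", "),
         call. = FALSE)
  labOf <- setNames(assignments$label, assignments$bac_id)
  stats$label <- unname(labOf[stats$bac_id])
  oneRow <- function(s, label) {
    data.frame(label = label, n_bacs = nrow(s),
               avg_nodes = mean(s$n_nodes),
               total_len = sum(s$total_len),
               avg_len = mean(s$total_len),
               avg_n50 = mean(s$n50, na.rm = TRUE),
               avg_l50 = mean(s$l50, na.rm = TRUE))
  }
  labs <- sort(unique(stats$label))
  out <- do.call(rbind, lapply(labs, function(lb)
    oneRow(stats[stats$label == lb, , drop = FALSE], lb)))
  out <- rbind(out, oneRow(stats, "All"))
  if (!is.null(geneCounts)) {
    pl <- geneCounts$perLabel
    out$unique_hc <- c(pl$unique_hc[match(labs, pl$label)],
                       geneCounts$summary$unique_hc)
    out$unique_lc <- c(pl$unique_lc[match(labs, pl$label)],
                       geneCounts$summary$unique_lc)
  }
  rownames(out) <- NULL
  out
}

#' Mutual exact-match coverage of two assemblies
#'
#' Coverage of assembly A by assembly B is the fraction of A's bases lying
#' in exact matches of at least \code{minMatch} bp to B (both strands),
#' merged over overlaps. Computed by marking every \code{minMatch}-length
#' window of A that occurs verbatim in B; this is a lower bound on
#' alignment-based coverage.
#'
#' @param a,b \code{DNAStringSet}s of node sequences (or character
#'   vectors).
#' @param minMatch minimum exact match length in bp (default 100).
#' @return list with \code{covA} and \code{covB}, percentages in [0, 100].
#' @export
pairwiseCoverage <- function(a, b, minMatch = 100) {
  toSet <- function(x) if (is.character(x)) DNAStringSet(toupper(x)) else x
  a <- toSet(a); b <- toSet(b)
  if (!length(a) || !sum(width(a)) || !length(b) || !sum(width(b)))
    stop("empty assembly", call. = FALSE)
  oneWay <- function(q, s) {
    sk <- unique(c(kmersOfSequences(s, minMatch, canonical = FALSE),
                   kmersOfSequences(reverseComplement(s), minMatch,
                                    canonical = FALSE)))
    tot <- sum(width(q))
    cov <- 0
    for (i in seq_along(q)) {
      qs <- as.character(q[[i]])
      n <- nchar(qs)
      if (n < minMatch) next
      starts <- seq_len(n - minMatch + 1L)
      win <- substring(qs, starts, starts + minMatch - 1L)
      hit <- starts[win %in% sk]
      if (length(hit)) {
        iv <- reduce(IRanges(hit, hit + minMatch - 1L))
        cov <- cov + sum(width(iv))
      }
    }
    100 * cov / tot
  }
  list(covA = oneWay(a, b), covB = oneWay(b, a))
}

#' Remove discordant assembly pairs
#'
#' A pair of independent assemblies of the same clone is discordant when
#' \emph{both} directional coverages fall strictly below the threshold
#' (attributable to rearray errors or cross-contamination rather than
#' assembly quality). \code{direction = "either"} removes a pair when any
#' one direction falls below the threshold.
#'
#' @param coverage data.frame with \code{covA} and \code{covB} columns
#'   (one row per pair; extra columns are carried through).
#' @param threshold percentage threshold (default 33).
#' @param direction \code{"both"} (default) or \code{"either"}.
#' @return list with \code{kept} and \code{removed} data.frames.
#' @export
filterDiscordantPairs <- function(coverage, threshold = 33,
                                  direction = c("both", "either")) {
  direction <- match.arg(direction)
  low <- if (direction == "both")
    coverage$covA < threshold & coverage$covB < threshold
  else coverage$covA < threshold | coverage$covB < threshold
  list(kept = coverage[!low, , drop = FALSE],
       removed = coverage[low, , drop = FALSE])
}
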