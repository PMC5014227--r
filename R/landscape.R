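#' @include utils.R
NULL

#' Landscape configuration
#'
#' Sliding-window parameters for chromosome landscapes. Defaults match the
#' scale used for a full Triticeae chromosome (40-Mb windows advanced in
#' 2.5-Mb steps); scale them down for smaller (e.g. synthetic) genomes.
#'
#' @param window window width in bp (default 4e7).
#' @param step step between window starts in bp (default 2.5e6; must be
#'   <= window).
#' @param gdQuantile upper quantile of gene density defining "gene-dense"
#'   (default 0.75).
#' @param rfQuantile lower quantile of recombination frequency defining
#'   "suppressed recombination" (default 0.25).
#' @param minBacsPerWindow windows with fewer BACs report missing gene
#'   density / recombination frequency (default 5).
#' @return list of class \code{"LandscapeConfig"}.
#' @export
landscapeConfig <- function(window = 4e7, step = 2.5e6, gdQuantile = 0.75,
                            rfQuantile = 0.25, minBacsPerWindow = 5) {
  if (step > window) stop("'step' must be <= 'window'", call. = FALSE)
  if (gdQuantile <= 0 || gdQuantile >= 1 || rfQuantile <= 0 || rfQuantile >= 1)
    stop("quantiles must be in (0, 1)", call. = FALSE)
  structure(list(window = window, step = step, gdQuantile = gdQuantile,
                 rfQuantile = rfQuantile,
                 minBacsPerWindow = minBacsPerWindow),
            class = "LandscapeConfig")
}

# Split semicolon-joined model ids into a list column if necessary.
modelIdList <- function(x) {
  if (is.list(x)) return(x)
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}

#' Sliding-window landscape statistics
#'
#' Windows advance by \code{step} from position 1 of each chromosome; a BAC
#' belongs to every window containing its anchor coordinate (point
#' membership). Per window: the BAC count; the proportions of BACs with 0,
#' exactly 1 and >= 3 HC gene models; the gene density GD = number of
#' distinct HC models among the window's BACs divided by the BAC count; and
#' the recombination frequency RF = (cM span of the window's BACs) /
#' (their bp span in Mb). Windows with fewer than
#' \code{minBacsPerWindow} BACs report \code{NA} for GD and RF.
#'
#' @param anchored data.frame with columns \code{bac_id}, \code{chrom},
#'   \code{bp}, \code{cM} and \code{model_ids} (list column or
#'   semicolon-joined string of HC model ids; post frequent-model
#'   exclusion).
#' @param config a \code{\link{landscapeConfig}}.
#' @param chromLen optional named vector of chromosome lengths; defaults to
#'   the maximum anchored bp per chromosome.
#' @return data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{center}, \code{partial}, \code{n_bacs}, \code{p0}, \code{p1},
#'   \code{p3plus}, \code{gd}, \code{rf}.
#' @export
windowStats <- function(anchored, config = landscapeConfig(),
                        chromLen = NULL) {
  need <- c("bac_id", "chrom", "bp", "cM", "model_ids")
  if (!all(need %in% names(anchored)))
    stop("anchored needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  anchored$model_ids <- modelIdList(anchored$model_ids)
  out <- list()
  for (ch in unique(anchored$chrom)) {
    a <- anchored[anchored$chrom == ch, , drop = FALSE]
    a <- a[order(a$bp), , drop = FALSE]
    if (is.unsorted(a$cM))
      stop("genetic map not monotone in bp on chromosome ", ch,
           call. = FALSE)
    len <- if (!is.null(chromLen)) chromLen[[ch]] else max(a$bp)
    starts <- seq(1, len, by = config$step)
    nHc <- lengths(a$model_ids)
    for (s in starts) {
      e <- s + config$window - 1
      inW <- a$bp >= s & a$bp <= e
      n <- sum(inW)
      gd <- rf <- NA_real_
      p0 <- p1 <- p3 <- NA_real_
      if (n > 0) {
        p0 <- mean(nHc[inW] == 0)
        p1 <- mean(nHc[inW] == 1)
        p3 <- mean(nHc[inW] >= 3)
      }
      if (n >= config$minBacsPerWindow) {
        gd <- length(unique(unlist(a$model_ids[inW]))) / n
        spanMb <- (max(a$bp[inW]) - min(a$bp[inW])) / 1e6
        rf <- if (spanMb > 0)
          (max(a$cM[inW]) - min(a$cM[inW])) / spanMb else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = min(e, len),
        center = s + (config$window - 1) / 2, partial = e > len,
        n_bacs = n, p0 = p0, p1 = p1, p3plus = p3, gd = gd, rf = rf)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect gene-dense, recombination-suppressed regions
#'
#' Thresholds are genome-wide quantiles over windows with non-missing
#' statistics: a window qualifies when its gene density reaches the upper
#' \code{gdQuantile} and its recombination frequency is at or below the
#' lower \code{rfQuantile}. Qualifying windows are merged per chromosome
#' when overlapping or adjacent.
#'
#' @param stats windows from \code{\link{windowStats}}.
#' @param config a \code{\link{landscapeConfig}}.
#' @param minWindows regions supported by fewer qualifying windows are
#'   dropped (default 2; overlapping windows make genuine regions span
#'   many windows, so single-window flickers are noise).
#' @return data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{mean_gd}, \code{mean_rf}, \code{n_windows}. Empty with a warning
#'   when every window is missing; empty when the profiles are degenerate
#'   (all equal).
#' @export
detectDeviantRegions <- function(stats, config = landscapeConfig(),
                                 minWindows = 2L) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_gd = numeric(0),
                      mean_rf = numeric(0), n_windows = integer(0))
  ok <- !is.na(stats$gd) & !is.na(stats$rf)
  if (!any(ok)) {
    warning("all windows missing gd/rf; no regions detectable")
    return(empty)
  }
  gd <- stats$gd[ok]; rf <- stats$rf[ok]
  if (length(unique(gd)) == 1L && length(unique(rf)) == 1L) return(empty)
  thrGd <- quantile(gd, config$gdQuantile, names = FALSE)
  thrRf <- quantile(rf, config$rfQuantile, names = FALSE)
  qual <- ok & stats$gd >= thrGd & stats$rf <= thrRf
  if (!any(qual)) return(empty)
  q <- stats[qual, , drop = FALSE]
  out <- list()
  for (ch in unique(q$chrom)) {
    w <- q[q$chrom == ch, , drop = FALSE]
    iv <- reduce(IRanges(as.integer(w$start), as.integer(w$end)),
                 min.gapwidth = 2L)
    hit <- findOverlaps(IRanges(as.integer(w$start), as.integer(w$end)), iv)
    for (j in seq_along(iv)) {
      members <- queryHits(hit)[subjectHits(hit) == j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start(iv)[j], end = end(iv)[j],
        mean_gd = mean(w$gd[members]), mean_rf = mean(w$rf[members]),
        n_windows = length(members))
    }
  }
  out <- do.call(rbind, out)
  out <- out[out$n_windows >= minWindows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window BAC counts
#'
#' The BAC-density track: how many anchored BACs fall in each sliding
#' window. An interior BAC contributes to \code{window/step} windows
#' (fewer at chromosome edges).
#'
#' @param anchored data.frame with \code{chrom} and \code{bp}.
#' @param config a \code{\link{landscapeConfig}}.
#' @param chromLen optional named vector of chromosome lengths.
#' @return data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{center}, \code{partial}, \code{n_bacs}.
#' @export
bacDensityTrack <- function(anchored, config = landscapeConfig(),
                            chromLen = NULL) {
  out <- list()
  chroms <- if (!is.null(chromLen)) names(chromLen) else
    unique(anchored$chrom)
  for (ch in chroms) {
    bp <- anchored$bp[anchored$chrom == ch]
    len <- if (!is.null(chromLen)) chromLen[[ch]] else
      if (length(bp)) max(bp) else config$window
    starts <- seq(1, len, by = config$step)
    ends <- starts + config$window - 1
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = starts, end = pmin(ends, len),
      center = starts + (config$window - 1) / 2, partial = ends > len,
      n_bacs = vapply(seq_along(starts), function(i)
        sum(bp >= starts[i] & bp <= ends[i]), 0L))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
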