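#' @include utils.R
NULL

# Validate a pools x clones detection matrix.
checkDetectionMatrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L || ncol(mat) < 1L)
    stop("detection matrix must have >= 1 pool and >= 1 clone",
         call. = FALSE)
  if (!all(mat %in% c(0, 1)))
    stop("detection matrix entries must be 0/1", call. = FALSE)
  if (!is.null(rownames(mat)) && anyDuplicated(rownames(mat)))
    stop("duplicate pool ids", call. = FALSE)
  if (!is.null(colnames(mat)) && anyDuplicated(colnames(mat)))
    stop("duplicate clone ids", call. = FALSE)
  invisible(mat)
}

#' Permutation accumulation curve of unique clones
#'
#' The screening order of probe pools is shuffled \code{nPermutations}
#' times; after each shuffle the cumulative number of distinct positive
#' clones is recorded as a function of the number of pools applied. The
#' mean and standard deviation over shuffles form the accumulation
#' (rarefaction) curve. With \code{method = "exhaustive"} every ordering of
#' the pools is enumerated instead (factorially many; intended for small
#' pool counts, and used as the exact oracle for the Monte-Carlo mode).
#'
#' @param mat binary pools x clones detection matrix.
#' @param nPermutations number of random orderings (default 10000).
#' @param seed integer seed for the Monte-Carlo mode.
#' @param method \code{"montecarlo"} (default) or \code{"exhaustive"}.
#' @return data.frame of class \code{"AccumulationCurve"}: \code{x} (pools
#'   applied), \code{mean_unique}, \code{sd_unique}; attributes
#'   \code{n_permutations}, \code{seed}, \code{total_unique}.
#' @export
accumulationCurve <- function(mat, nPermutations = 10000, seed = 1,
                              method = c("montecarlo", "exhaustive")) {
  checkDetectionMatrix(mat)
  method <- match.arg(method)
  D <- mat > 0
  P <- nrow(D)
  perms <- if (method == "exhaustive") {
    if (P > 8L)
      stop("exhaustive enumeration limited to 8 pools", call. = FALSE)
    allOrderings(P)
  } else NULL

  run <- function(ordGen, nPerm) {
    s <- numeric(P); ss <- numeric(P)
    for (p in seq_len(nPerm)) {
      ord <- ordGen(p)
      seen <- logical(ncol(D))
      cnt <- numeric(P)
      for (x in seq_len(P)) {
        seen <- seen | D[ord[x], ]
        cnt[x] <- sum(seen)
      }
      s <- s + cnt
      ss <- ss + cnt^2
    }
    m <- s / nPerm
    v <- pmax(0, ss / nPerm - m^2) * nPerm / max(1, nPerm - 1)
    list(mean = m, sd = sqrt(v))
  }

  res <- if (method == "exhaustive") {
    run(function(p) perms[p, ], nrow(perms))
  } else {
    withSeed(seed, run(function(p) sample.int(P), nPermutations))
  }
  out <- data.frame(x = seq_len(P), mean_unique = res$mean,
                    sd_unique = res$sd)
  class(out) <- c("AccumulationCurve", "data.frame")
  attr(out, "n_permutations") <-
    if (method == "exhaustive") factorial(P) else nPermutations
  attr(out, "seed") <- seed
  attr(out, "total_unique") <- sum(colSums(D) > 0)
  out
}

# All orderings of 1..n as rows of a matrix (n! x n).
allOrderings <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allOrderings(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Fit a saturation asymptote to an accumulation curve
#'
#' Least-squares fit of the mean curve to a saturating model:
#' \code{negexp}, y = A (1 - exp(-b x)), or \code{hyperbolic},
#' y = A x / (B + x). A is reported as the estimated asymptotic number of
#' unique clones. Because probes detect multi-gene clones more readily than
#' single-gene clones, the asymptote is expected to underestimate the true
#' clone count; estimates always carry the model name.
#'
#' @param curve an \code{\link{accumulationCurve}} result (or any
#'   data.frame with \code{x} and \code{mean_unique}).
#' @param model \code{"negexp"} (default) or \code{"hyperbolic"}.
#' @param weighted weight residuals by 1/sd_unique where positive?
#' @return list of class \code{"SaturationEstimate"}: \code{asymptote},
#'   \code{model}, \code{coefficients}, \code{residual_sd},
#'   \code{observed_unique}.
#' @export
fitAsymptote <- function(curve, model = c("negexp", "hyperbolic"),
                         weighted = FALSE) {
  model <- match.arg(model)
  if (nrow(curve) < 3L) stop("curve length must be >= 3", call. = FALSE)
  d <- data.frame(x = curve$x, y = curve$mean_unique)
  w <- rep(1, nrow(d))
  if (weighted && "sd_unique" %in% names(curve)) {
    sdu <- curve$sd_unique
    w <- ifelse(sdu > 0, 1 / sdu^2, max(1 / pmax(sdu, 1e-9)^2))
  }
  ymax <- max(d$y)
  fit <- tryCatch({
    if (model == "negexp") {
      A0 <- ymax * 1.05 + 1e-9
      b0 <- max(0.01, -log(max(1e-9, 1 - min(0.95, d$y[1L] / A0))))
      minpack.lm::nlsLM(y ~ A * (1 - exp(-b * x)), data = d, weights = w,
                        start = list(A = A0, b = b0),
                        lower = c(A = 0, b = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      A0 <- ymax * 1.5 + 1e-9
      B0 <- max(0.5, d$x[which.min(abs(d$y - ymax / 2))])
      minpack.lm::nlsLM(y ~ A * x / (B + x), data = d, weights = w,
                        start = list(A = A0, B = B0),
                        lower = c(A = 0, B = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop("asymptote fit did not converge (", model, "): ",
         conditionMessage(e), call. = FALSE)
  })
  est <- coef(fit)
  structure(list(asymptote = unname(est["A"]),
                 model = model,
                 coefficients = est,
                 residual_sd = sd(resid(fit)),
                 observed_unique = ymax),
            class = "SaturationEstimate")
}

#' @export
print.SaturationEstimate <- function(x, ...) {
  cat(sprintf("SaturationEstimate (%s): asymptote = %.1f clones\n",
              x$model, x$asymptote))
  cat(sprintf("  observed unique = %.1f, residual sd = %.2f\n",
              x$observed_unique, x$residual_sd))
  invisible(x)
}

#' Write / read a detection matrix as TSV
#'
#' First column is the pool id, remaining columns are clone ids with 0/1
#' entries.
#' @param mat binary pools x clones matrix.
#' @param path file path.
#' @return \code{writeDetectionMatrix}: \code{path} invisibly;
#'   \code{readDetectionMatrix}: the integer matrix.
#' @export
writeDetectionMatrix <- function(mat, path) {
  checkDetectionMatrix(mat)
  df <- data.frame(pool = rownames(mat), mat, check.names = FALSE)
  writeTsv(df, path)
}

#' @rdname writeDetectionMatrix
#' @export
readDetectionMatrix <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  checkDetectionMatrix(m)
  m
}
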