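# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that stochastic operations are
#' reproducible without disturbing the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage seed from a master seed, kept within 32-bit range.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) * 101L + as.integer(offset)) %% 2147483647L
}

#' Enumerate the k-mers of one sequence
#'
#' Returns every k-mer occurrence in order. Windows containing a non-ACGT
#' letter are skipped (ambiguous bases break enumeration). With
#' \code{canonical = TRUE} each k-mer is replaced by the lexicographic
#' minimum of itself and its reverse complement, so the result is
#' orientation-free.
#' @noRd
kmersOfSequence <- function(s, k, canonical = TRUE) {
  s <- toupper(as.character(s))
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  bad <- gregexpr("[^ACGT]", s)[[1L]]
  if (bad[1L] != -1L) {
    badcum <- cumsum(tabulate(as.integer(bad), nbins = n))
    nbad <- badcum[starts + k - 1L] - c(0L, badcum)[starts]
    starts <- starts[nbad == 0L]
    if (!length(starts)) return(character(0))
  }
  fwd <- substring(s, starts, starts + k - 1L)
  if (!canonical) return(fwd)
  rs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rc <- substring(rs, n - (starts + k - 1L) + 1L, n - starts + 1L)
  pmin(fwd, rc)
}

# k-mers of a set of sequences (character vector or DNAStringSet), pooled.
kmersOfSequences <- function(x, k, canonical = TRUE) {
  if (is(x, "XStringSet")) x <- as.character(x)
  unlist(lapply(unname(x), kmersOfSequence, k = k, canonical = canonical),
         use.names = FALSE)
}

# Random DNA of a given length and GC content (vector of lengths allowed).
randomDna <- function(n, gc = 0.445) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(n, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# ---- TSV helpers -----------------------------------------------------------

configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Write a data frame as TSV with a provenance comment line
#'
#' Every table the package emits starts with a header row preceded by a
#' comment line recording the package version and a hash of the
#' configuration that produced it.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param config optional list; hashed into the comment line.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else configHash(config)
  writeLines(sprintf("# BACography %s config=%s", .PKG_VERSION(), hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{\link{writeTsv}} (or any commented TSV)
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Fraction-style percentages rendered to one decimal, as in summary tables.
pct1 <- function(x) round(100 * x, 1)
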