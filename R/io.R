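#' @include utils.R
NULL

#' Read a FASTA file
#'
#' Wraps \code{Biostrings::readDNAStringSet} with stricter validation:
#' record order is preserved, sequence is uppercased, multi-line records
#' are accepted, records with empty sequence are rejected, and a malformed
#' header (sequence data before the first \code{>}) is reported with its
#' line number.
#'
#' @param path FASTA file path.
#' @return a named \code{DNAStringSet}.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonEmpty[1L]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA header at line ", first, " of ", path,
         call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  if (any(width(x) == 0L)) {
    bad <- names(x)[width(x) == 0L]
    stop("record(s) with empty sequence: ", paste(head(bad, 5),
                                                  collapse = ", "),
         call. = FALSE)
  }
  DNAStringSet(toupper(x))
}

#' Write sequences as FASTA
#'
#' @param x a named \code{DNAStringSet} or character vector.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
writeFastaFile <- function(x, path, width = 70) {
  if (is.character(x)) x <- DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a BAC library to FASTA (+ truth TSV)
#'
#' @param library a \code{\linkS4class{BacLibrary}}.
#' @param fastaPath output FASTA of node sequences.
#' @param truthPath optional TSV for the simulation truth table.
#' @return \code{fastaPath}, invisibly.
#' @export
writeBacLibrary <- function(library, fastaPath, truthPath = NULL) {
  writeFastaFile(library@nodes, fastaPath)
  if (!is.null(truthPath) && nrow(library@truth))
    writeTsv(library@truth, truthPath)
  invisible(fastaPath)
}

#' Read a BAC library from FASTA
#'
#' Node names must be \code{<bac_id>|<node_id>}.
#' @param fastaPath FASTA of node sequences.
#' @param truthPath optional truth TSV written by
#'   \code{\link{writeBacLibrary}}.
#' @return a \code{\linkS4class{BacLibrary}}.
#' @export
readBacLibrary <- function(fastaPath, truthPath = NULL) {
  nodes <- readFastaFile(fastaPath)
  truth <- if (!is.null(truthPath)) readTsv(truthPath) else NULL
  bacLibrary(nodes, truth = truth)
}
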