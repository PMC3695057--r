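# Internal helpers: RNG scoping, sequence alphabet handling, TSV/FASTA I/O.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the prior
#' RNG state so generators behave as pure functions of (config, seed) without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed, or NULL to use the current stream as-is
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

#' Canonicalize nucleotide sequences to the DNA alphabet
#'
#' Uppercases and maps U to T. RNA input (mature miRNAs) is accepted
#' everywhere; internally all sequences live in the DNA T-alphabet.
#'
#' @param x character vector of sequences
#' @param allow_n allow ambiguous N bases
#' @return character vector over {A,C,G,T[,N]}
#' @export
as_dna <- function(x, allow_n = TRUE) {
  nm <- names(x)
  x <- chartr("u", "t", toupper(as.character(x)))
  names(x) <- nm
  x <- chartr("U", "T", x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  x
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences
#' @return character vector of reverse complements
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## round-to-nearest with ties rounded up (documented convention for
## fraction * n gene counts)
round_half_up <- function(x) floor(x + 0.5)

#' Read a FASTA file into a named character vector
#'
#' Sequences are canonicalized to the DNA alphabet (U -> T) on read.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- as_dna(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param x named character vector
#' @param path output file
#' @param width line wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  ss <- Biostrings::DNAStringSet(as_dna(x))
  names(ss) <- names(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row; the first column holds feature identifiers.
#'
#' @param path TSV file
#' @return numeric matrix with feature rownames
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs an ID column plus >=1 sample column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature IDs in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param mat matrix with rownames
#' @param path output file
#' @param id_col name for the identifier column
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Write a plain data.frame as TSV (no rownames).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

## Read a two-column sample->value TSV (e.g. group labels, library sizes)
## into a named vector keyed by the first column.
read_keyed_tsv <- function(path, mode = "character") {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("expected two columns in ", path)
  v <- df[[2L]]
  if (mode == "numeric") v <- as.numeric(v) else v <- as.character(v)
  names(v) <- as.character(df[[1L]])
  v
}
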