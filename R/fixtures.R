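#' Generate random sequences from a letter composition
#'
#' Draws `count` iid sequences of `length` letters from `comp`, the workhorse
#' behind every simulated standard in the package. Deterministic under
#' `seed`.
#'
#' @param comp Named probability vector over the alphabet (sums to 1 within
#'   1e-12).
#' @param length Sequence length, >= 1.
#' @param count Number of sequences, >= 1.
#' @param seed Integer RNG seed.
#' @param prefix Name prefix for the records.
#' @return Named character vector of sequences (names are record ids).
#' @examples
#' generate_random_sequences(c(A = 0.5, B = 0.5), length = 10, count = 2,
#'                           seed = 1)
#' @export
generate_random_sequences <- function(comp, length, count, seed,
                                      prefix = "seq") {
  stopifnot(length >= 1, count >= 1)
  if (abs(sum(comp) - 1) > 1e-12) {
    stop(sprintf("composition sums to %.15g, not 1", sum(comp)))
  }
  if (any(comp < 0)) stop("composition has negative entries")
  letters <- names(comp)
  if (is.null(letters)) stop("composition must be named by letters")
  set.seed(seed)
  seqs <- vapply(seq_len(count), function(i) {
    paste(sample(letters, length, replace = TRUE, prob = comp),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("%s_%d", prefix, seq_len(count)))
}

#' Write / read sequences as FASTA
#'
#' Minimal plain-text FASTA io for the fixture generator and the CLI; lines
#' are wrapped at 60 characters on output.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return The reader returns a named character vector; the writer returns
#'   `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(unname(seqs), names_)
}
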