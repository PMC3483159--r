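encode_sequence <- function(seq, alphabet, what) {
  letters <- if (length(seq) == 1) strsplit(seq, "")[[1]] else
    as.character(seq)
  if (!length(letters)) stop(what, " is empty")
  code <- match(letters, alphabet) - 1L
  if (anyNA(code)) {
    pos <- which(is.na(code))[1]
    stop(sprintf("unknown letter '%s' at position %d of %s",
                 letters[pos], pos, what))
  }
  code
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman dynamic programming in three states (Gotoh) with a full
#' traceback, under gap cost `gap_open + g * gap_extend` for a gap of length
#' `g`. Traceback ties prefer a match/mismatch step over a gap in J over a
#' gap in I, and among equal-scoring end cells the smallest `end_i + end_j`,
#' then the smallest `end_i`, so the reported path is deterministic.
#'
#' The path is reported as steps from the alignment start, with the running
#' (cumulative) local score after each step; this is what
#' [extract_crossings()] scans to realize the required-length variates
#' `L_I(y)`, `L_J(y)`.
#'
#' @param seq_i,seq_j Sequences: single strings or character vectors of
#'   letters from the system's alphabet.
#' @param sys A [scoring_system()].
#' @return An object of class `sw_alignment`: a list with `score`,
#'   1-based inclusive `start_i`, `start_j`, `end_i`, `end_j`, `path`
#'   (character vector in `"match"`, `"gap_j"` (consumes I), `"gap_i"`
#'   (consumes J)), and `cumulative_scores`. A score of 0 has an empty path.
#' @examples
#' sys <- toy_scoring_system()
#' smith_waterman("ABAB", "ABAB", sys)$score
#' @export
smith_waterman <- function(seq_i, seq_j, sys) {
  ei <- encode_sequence(seq_i, sys$alphabet, "seq_i")
  ej <- encode_sequence(seq_j, sys$alphabet, "seq_j")
  raw <- sw_align_cpp(ei, ej, sys$matrix, sys$gap_open, sys$gap_extend)
  path <- c("match", "gap_j", "gap_i")[raw$path]
  res <- list(score = raw$score,
              start_i = raw$start_i, start_j = raw$start_j,
              end_i = raw$end_i, end_j = raw$end_j,
              path = path,
              cumulative_scores = cumsum(raw$step_scores))
  class(res) <- "sw_alignment"
  res
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %d", x$score))
  if (length(x$path)) {
    cat(sprintf(", I[%d..%d] x J[%d..%d], %d steps (%d gap)",
                x$start_i, x$end_i, x$start_j, x$end_j,
                length(x$path), sum(x$path != "match")))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.sw_alignment <- function(x, ...) {
  tibble::tibble(step = seq_along(x$path), kind = x$path,
                 cumulative_score = x$cumulative_scores)
}

#' Required-length samples at score thresholds
#'
#' Walks an optimal alignment path and, for each threshold `y` in `y_grid`
#' not exceeding the alignment score, records how many letters of I and of J
#' the path consumed up to the first step whose cumulative score reaches at
#' least `y`. These `(y, L_I, L_J)` triples realize (on the optimal path) the
#' random required lengths whose means, variances and covariance drive the
#' finite-size corrections.
#'
#' The first step to reach a new maximum is always a match/mismatch step
#' (gaps only decrease the score); this is asserted, not assumed.
#'
#' @param result An [smith_waterman()] alignment.
#' @param y_grid Increasing positive integer thresholds.
#' @return A tibble with columns `y`, `l_i`, `l_j`, one row per threshold
#'   `<= result$score`; zero rows for an empty path.
#' @examples
#' sys <- toy_scoring_system()
#' aln <- smith_waterman("ABBA", "ABBA", sys)
#' extract_crossings(aln, c(2, 4))
#' @export
extract_crossings <- function(result, y_grid) {
  stopifnot(is.numeric(y_grid), !is.unsorted(y_grid, strictly = TRUE))
  if (!length(result$path)) {
    return(tibble::tibble(y = integer(0), l_i = integer(0), l_j = integer(0)))
  }
  cum <- result$cumulative_scores
  # running maximum: first step where cum >= y, for increasing y
  run_max <- cummax(cum)
  cons_i <- cumsum(result$path != "gap_i")
  cons_j <- cumsum(result$path != "gap_j")
  ys <- y_grid[y_grid <= result$score & y_grid >= 1]
  idx <- findInterval(ys - 1L, run_max) + 1L  # first index with run_max >= y
  stopifnot(all(result$path[idx] == "match"))
  tibble::tibble(y = as.integer(ys),
                 l_i = as.integer(cons_i[idx]),
                 l_j = as.integer(cons_j[idx]))
}
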