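#' Construct a scoring system
#'
#' A scoring system bundles everything the score statistics depend on: an
#' ordered alphabet, an integer substitution matrix `s(A, B)`, affine gap
#' penalties, and background letter compositions for the two sequences being
#' compared. A gap of length `g` costs `gap_open + g * gap_extend`, so the
#' BLAST notation "11 + g" means `gap_open = 11`, `gap_extend = 1`.
#'
#' Asymmetric matrices and unequal compositions are supported throughout:
#' the required-length variates of the two sequences then have different
#' distributions, and all downstream moments keep separate I and J parts.
#'
#' @param matrix Integer substitution matrix with identical row and column
#'   dimnames giving the alphabet in order (e.g. from [read_score_matrix()]).
#' @param gap_open Non-negative integer gap opening penalty.
#' @param gap_extend Positive integer gap extension penalty.
#' @param comp_i,comp_j Background composition of sequence I (J): a
#'   probability vector over the alphabet, recycled from `comp_i` when
#'   `comp_j` is missing. Defaults to uniform over the matrix alphabet
#'   (dropping a `*` sentinel column if present).
#' @return An object of class `scoring_system`.
#' @seealso [validate_scoring_system()], [read_score_matrix()],
#'   [robinson_frequencies()]
#' @examples
#' sys <- toy_scoring_system()
#' sys
#' @export
scoring_system <- function(matrix, gap_open, gap_extend,
                           comp_i = NULL, comp_j = comp_i) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix))) {
    stop("`matrix` must have identical row and column letter names")
  }
  if (any(matrix != round(matrix))) stop("substitution scores must be integers")
  storage.mode(matrix) <- "integer"
  alphabet <- rownames(matrix)
  stat_alphabet <- setdiff(alphabet, "*")
  if (is.null(comp_i)) {
    comp_i <- stats::setNames(rep(1 / length(stat_alphabet),
                                  length(stat_alphabet)), stat_alphabet)
  }
  comp_i <- check_composition(comp_i, stat_alphabet, "comp_i")
  comp_j <- if (is.null(comp_j)) comp_i else
    check_composition(comp_j, stat_alphabet, "comp_j")
  if (gap_open < 0) stop("`gap_open` must be non-negative")
  if (gap_extend <= 0) stop("`gap_extend` must be positive")
  structure(
    list(alphabet = alphabet, matrix = matrix,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         comp_i = comp_i, comp_j = comp_j),
    class = "scoring_system"
  )
}

check_composition <- function(comp, alphabet, what) {
  if (is.null(names(comp))) {
    if (length(comp) != length(alphabet)) {
      stop(sprintf("`%s` has %d entries for a %d-letter alphabet",
                   what, length(comp), length(alphabet)))
    }
    names(comp) <- alphabet
  }
  if (!all(names(comp) %in% alphabet)) {
    stop(sprintf("`%s` names letters outside the alphabet: %s", what,
                 paste(setdiff(names(comp), alphabet), collapse = ", ")))
  }
  full <- stats::setNames(numeric(length(alphabet)), alphabet)
  full[names(comp)] <- comp
  if (any(full < 0)) stop(sprintf("`%s` has negative entries", what))
  if (abs(sum(full) - 1) > 1e-12) {
    stop(sprintf("`%s` sums to %.15g, not 1", what, sum(full)))
  }
  full
}

#' @export
print.scoring_system <- function(x, ...) {
  cat(sprintf("<scoring_system> %d-letter alphabet [%s%s]\n",
              length(x$alphabet), paste(utils::head(x$alphabet, 8), collapse = ""),
              if (length(x$alphabet) > 8) "..." else ""))
  cat(sprintf("  gap penalty: %d + %d g;  score range [%d, %d]\n",
              x$gap_open, x$gap_extend, min(x$matrix), max(x$matrix)))
  es <- expected_pair_score(x)
  cat(sprintf("  expected pair score: %.4f\n", es))
  invisible(x)
}

# Expected score of one aligned letter pair under the background compositions,
# restricted to letters with positive composition mass.
expected_pair_score <- function(sys) {
  a <- names(sys$comp_i)
  as.numeric(sys$comp_i %*% sys$matrix[a, a, drop = FALSE] %*% sys$comp_j)
}

#' Read an NCBI-format score matrix file
#'
#' Parses the whitespace-delimited text format used to distribute matrices
#' such as BLOSUM62: `#` comment lines, a header row of letters, then one
#' row per letter starting with its label. Asymmetric matrices are accepted
#' and preserved. A `*` column, if present, is kept in the matrix but is
#' ignored by all statistical computations.
#'
#' @param path Path to the matrix file.
#' @return A list with elements `alphabet` (letters in file order) and
#'   `matrix` (integer matrix with letter dimnames).
#' @examples
#' blosum62 <- read_score_matrix(
#'   system.file("extdata", "BLOSUM62", package = "fscstats"))
#' blosum62$matrix["W", "W"]
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) < 2) stop("matrix file has no header and data rows: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (anyDuplicated(header)) {
    stop(sprintf("duplicate letter '%s' in header (line %d)",
                 header[duplicated(header)][1], line_no[1]))
  }
  p <- length(header)
  rows <- lines[-1]
  if (length(rows) != p) {
    stop(sprintf("expected %d data rows for %d header letters, found %d",
                 p, p, length(rows)))
  }
  mat <- matrix(NA_integer_, p, p, dimnames = list(header, header))
  for (r in seq_along(rows)) {
    fields <- strsplit(trimws(rows[[r]]), "\\s+")[[1]]
    lab <- fields[1]
    vals <- fields[-1]
    if (!lab %in% header) {
      stop(sprintf("row label '%s' (line %d) not in header", lab, line_no[r + 1]))
    }
    if (length(vals) != p) {
      stop(sprintf("row '%s' (line %d) has %d cells, expected %d",
                   lab, line_no[r + 1], length(vals), p))
    }
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) | num != round(num))
    if (length(bad)) {
      stop(sprintf("non-integer score '%s' in row '%s' (line %d, column %d)",
                   vals[bad[1]], lab, line_no[r + 1], bad[1]))
    }
    mat[lab, ] <- as.integer(num)
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate row labels in matrix file")
  list(alphabet = header, matrix = mat)
}

#' Write a score matrix in NCBI text format
#'
#' Inverse of [read_score_matrix()]; integer matrices round-trip exactly.
#'
#' @param matrix Integer matrix with letter dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(matrix, path) {
  letters <- colnames(matrix)
  width <- max(nchar(as.character(matrix)), nchar(letters)) + 1
  fmt <- function(x) formatC(x, width = width)
  lines <- c(paste0(" ", paste(fmt(letters), collapse = "")),
             vapply(rownames(matrix), function(r) {
               paste0(r, paste(fmt(matrix[r, ]), collapse = ""))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a scoring system for the Gumbel (logarithmic) regime
#'
#' The Gumbel tail of local alignment scores exists only when the expected
#' pair score is negative and some letter pair with positive composition mass
#' scores positively. This reports every violated requirement rather than
#' stopping at the first.
#'
#' @param sys A [scoring_system()].
#' @return A tibble with columns `check`, `ok`, `detail`; zero violated rows
#'   means the system is usable. The `valid` attribute gives the overall
#'   verdict, also available via [is_valid_system()].
#' @examples
#' validate_scoring_system(toy_scoring_system())
#' @export
validate_scoring_system <- function(sys) {
  a <- names(sys$comp_i)
  checks <- list()
  add <- function(check, ok, detail) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, ok = ok, detail = detail)
  }
  sq <- nrow(sys$matrix) == ncol(sys$matrix) &&
    identical(rownames(sys$matrix), colnames(sys$matrix))
  add("square_matrix", sq, "one row/column per alphabet letter")
  for (nm in c("comp_i", "comp_j")) {
    comp <- sys[[nm]]
    add(paste0(nm, "_simplex"),
        all(comp >= 0) && abs(sum(comp) - 1) <= 1e-12,
        sprintf("sums to %.15g", sum(comp)))
  }
  es <- expected_pair_score(sys)
  add("negative_expected_score", es < 0,
      sprintf("expected pair score = %.6g (must be < 0)", es))
  mass <- outer(sys$comp_i, sys$comp_j)
  pos <- any(mass > 0 & sys$matrix[a, a] > 0)
  add("positive_score_possible", pos,
      "some letter pair with positive mass must score > 0")
  out <- dplyr::bind_rows(checks)
  attr(out, "valid") <- all(out$ok)
  out
}

#' @rdname validate_scoring_system
#' @export
is_valid_system <- function(sys) {
  isTRUE(attr(validate_scoring_system(sys), "valid"))
}

#' Built-in standard amino-acid background composition
#'
#' The Robinson and Robinson amino-acid frequencies used as the default
#' protein background in BLAST, normalized to sum exactly to 1.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @examples
#' robinson_frequencies()[c("A", "W")]
#' @export
robinson_frequencies <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f / sum(f)
}

#' Two-letter toy scoring system
#'
#' Uniform composition over letters A/B with match score `match` and
#' mismatch score `mismatch`. The default (+1/-2) has a closed-form ungapped
#' scale parameter, lambda = ln((1 + sqrt(5)) / 2), which makes it a handy
#' ground truth for calibration code.
#'
#' @param match,mismatch Integer match and mismatch scores.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return A [scoring_system()].
#' @export
toy_scoring_system <- function(match = 1, mismatch = -2,
                               gap_open = 3, gap_extend = 1) {
  m <- matrix(as.integer(mismatch), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  diag(m) <- as.integer(match)
  scoring_system(m, gap_open = gap_open, gap_extend = gap_extend)
}

#' BLOSUM62 scoring system
#'
#' Convenience constructor reading the packaged BLOSUM62 matrix with the
#' standard "11 + g" protein gap penalties and a choice of background.
#'
#' @param gap_open,gap_extend Affine gap penalties (default 11 + g).
#' @param background `"robinson"` (default) for the standard amino-acid
#'   background or `"uniform"` for uniform over the 20 standard residues.
#' @return A [scoring_system()].
#' @export
blosum62_system <- function(gap_open = 11, gap_extend = 1,
                            background = c("robinson", "uniform")) {
  background <- match.arg(background)
  parsed <- read_score_matrix(
    system.file("extdata", "BLOSUM62", package = "fscstats"))
  aa20 <- names(robinson_frequencies())
  comp <- if (background == "robinson") robinson_frequencies() else
    stats::setNames(rep(1 / 20, 20), aa20)
  scoring_system(parsed$matrix, gap_open = gap_open, gap_extend = gap_extend,
                 comp_i = comp)
}

#' Serialize / deserialize a scoring system as JSON
#'
#' @param sys A [scoring_system()].
#' @param path File path.
#' @return `read_scoring_system_json()` returns a [scoring_system()];
#'   the writer returns `path` invisibly.
#' @export
write_scoring_system_json <- function(sys, path) {
  obj <- list(schema = "fscstats/scoring_system/1",
              alphabet = sys$alphabet,
              matrix = unname(apply(sys$matrix, 1, as.integer, simplify = FALSE)),
              gap_open = sys$gap_open, gap_extend = sys$gap_extend,
              comp_i = as.list(sys$comp_i), comp_j = as.list(sys$comp_j))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scoring_system_json
#' @export
read_scoring_system_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fscstats/scoring_system/1")) {
    stop("unrecognized scoring-system schema in ", path)
  }
  mat <- if (is.matrix(obj$matrix)) obj$matrix else do.call(rbind, obj$matrix)
  dimnames(mat) <- list(obj$alphabet, obj$alphabet)
  scoring_system(mat, gap_open = obj$gap_open, gap_extend = obj$gap_extend,
                 comp_i = unlist(obj$comp_i), comp_j = unlist(obj$comp_j))
}
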