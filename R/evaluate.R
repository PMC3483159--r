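#' Empirical survival function of optimal scores by direct simulation
#'
#' Simulates `R` iid sequence pairs from the system's compositions, aligns
#' each, and estimates `P(M > y)` on an integer score grid with binomial
#' standard errors. Direct simulation is valid down to tail probabilities of
#' about `10 / R`; rarer tails need rare-event machinery that is out of this
#' package's scope.
#'
#' @param sys A [scoring_system()].
#' @param m,n Sequence lengths.
#' @param R Number of replicate pairs, >= 1000.
#' @param seed Integer RNG seed.
#' @param y_max Top of the score grid; defaults to the largest observed
#'   maximum.
#' @return An object of class `empirical_survival`: a tibble with columns
#'   `y`, `survival`, `se`, and attributes `R`, `m`, `n`.
#' @export
simulate_survival <- function(sys, m, n, R, seed, y_max = NULL) {
  stopifnot(R >= 1000)
  maxima <- simulate_score_maxima(sys, m, n, R, seed)
  if (is.null(y_max)) y_max <- max(maxima)
  y <- 0:y_max
  surv <- vapply(y, function(t) mean(maxima > t), numeric(1))
  out <- tibble::tibble(y = y, survival = surv,
                        se = sqrt(surv * (1 - surv) / R))
  attr(out, "R") <- R
  attr(out, "m") <- m
  attr(out, "n") <- n
  class(out) <- c("empirical_survival", class(out))
  out
}

#' Simulate optimal local alignment score maxima
#'
#' @inheritParams simulate_survival
#' @return Integer vector of `R` optimal scores.
#' @export
simulate_score_maxima <- function(sys, m, n, R, seed) {
  a_i <- names(sys$comp_i)
  a_j <- names(sys$comp_j)
  set.seed(seed)
  simulate_maxima_cpp(R, m, n, sys$comp_i, sys$comp_j,
                      sys$matrix[a_i, a_j], sys$gap_open, sys$gap_extend)
}

#' Compare corrected p-values against the empirical standard
#'
#' For each score on the empirical grid with a positive survival estimate,
#' computes the model p-value under the old (mean-length) and new
#' (distributional) corrections and reports relative errors as
#' `log10(p_model / p_emp)` — the scale on which a perfect estimate sits on
#' the horizontal line 0. Rows where the empirical estimate has relative
#' standard error above 30% are flagged rather than dropped.
#'
#' @param emp An [simulate_survival()] result.
#' @param gumbel A [gumbel_params()] object.
#' @param fsc An [fsc_params()] object.
#' @param m,n Sequence lengths; default to those recorded in `emp`.
#' @return A tibble of class `fsc_comparison` with columns `y`, `p_emp`,
#'   `p_emp_se`, `p_uncorrected`, `p_old`, `p_new`, `log10_new`,
#'   `log10_old`, `noisy`.
#' @export
compare_corrections <- function(emp, gumbel, fsc,
                                m = attr(emp, "m"), n = attr(emp, "n")) {
  usable <- emp$survival > 0
  if (!any(usable)) stop("no grid points with positive empirical survival")
  tb <- emp[usable, ]
  p_old <- alignment_pvalue(tb$y, m, n, gumbel, fsc, method = "old")
  p_new <- alignment_pvalue(tb$y, m, n, gumbel, fsc, method = "new")
  p_unc <- alignment_pvalue(tb$y, m, n, gumbel, method = "uncorrected")
  out <- tibble::tibble(
    y = tb$y, p_emp = tb$survival, p_emp_se = tb$se,
    p_uncorrected = p_unc, p_old = p_old, p_new = p_new,
    log10_new = log10(p_new / tb$survival),
    log10_old = log10(p_old / tb$survival),
    noisy = tb$se / tb$survival > 0.3)
  class(out) <- c("fsc_comparison", class(out))
  out
}

#' Pooled ROC_n retrieval score
#'
#' Pools retrieval records across queries, drops censored records, orders by
#' expect value (ties pessimistically place false positives first), and
#' truncates at the `n_fp`-th false positive. With `t_i` the number of true
#' positives ranked strictly before the i-th false positive and `T` the
#' total true positives among the (uncensored) records,
#' `ROC_n = sum(t_i) / (n_fp * T)`.
#'
#' @param records Tibble/data frame with columns `query_id`, `subject_id`,
#'   `evalue`, `label` (values `"true_positive"`, `"false_positive"`,
#'   `"censored"`).
#' @param n_fp Truncation count of false positives.
#' @return An object of class `roc_result`: list with `score`, `n_fp`,
#'   `total_tp`, and `curve` (cumulative `(fp, tp)` tibble up to the
#'   truncation).
#' @examples
#' rec <- tibble::tibble(query_id = "q", subject_id = letters[1:4],
#'                       evalue = 1:4,
#'                       label = c("true_positive", "false_positive",
#'                                 "true_positive", "false_positive"))
#' roc_n(rec, 2)$score  # 0.75
#' @export
roc_n <- function(records, n_fp) {
  stopifnot(all(c("query_id", "subject_id", "evalue", "label") %in%
                  names(records)),
            all(records$label %in% c("true_positive", "false_positive",
                                     "censored")),
            all(records$evalue >= 0))
  rec <- dplyr::filter(records, .data$label != "censored")
  total_tp <- sum(rec$label == "true_positive")
  total_fp <- sum(rec$label == "false_positive")
  if (total_fp < n_fp) {
    stop(sprintf("only %d false positives among records; %d required",
                 total_fp, n_fp))
  }
  if (total_tp == 0) stop("no true positives among records")
  rec <- rec[order(rec$evalue, rec$label != "false_positive"), ]
  is_fp <- rec$label == "false_positive"
  cum_tp <- cumsum(!is_fp)
  fp_idx <- which(is_fp)[seq_len(n_fp)]
  t_i <- cum_tp[fp_idx] - 0L  # TPs strictly before the i-th FP
  curve <- tibble::tibble(fp = seq_len(n_fp), tp = t_i)
  structure(list(score = sum(t_i) / (n_fp * total_tp),
                 n_fp = n_fp, total_tp = total_tp, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> ROC_%d = %.5f (T = %d true positives)\n",
              x$n_fp, x$score, x$total_tp))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(score = x$score, n_fp = x$n_fp, total_tp = x$total_tp)
}

#' Query-level bootstrap standard error of ROC_n
#'
#' Resamples queries with replacement `B` times, recomputes the pooled ROC_n
#' on each resample, and reports the standard deviation. A resample holding
#' fewer than `n_fp` false positives is truncated at the false positives it
#' has.
#'
#' @inheritParams roc_n
#' @param B Number of bootstrap resamples, >= 100.
#' @param seed Integer RNG seed.
#' @return A list with `se`, `B`, and the vector of bootstrap `scores`.
#' @export
bootstrap_roc_se <- function(records, n_fp, B = 200, seed = 1) {
  stopifnot(B >= 100)
  queries <- unique(records$query_id)
  if (length(queries) < 2) {
    stop("bootstrap over queries needs at least 2 distinct queries")
  }
  by_query <- split(seq_len(nrow(records)), records$query_id)
  set.seed(seed)
  scores <- vapply(seq_len(B), function(b) {
    qs <- sample(queries, length(queries), replace = TRUE)
    rec <- records[unlist(by_query[qs], use.names = FALSE), ]
    n_avail <- sum(rec$label == "false_positive")
    if (n_avail == 0 || !any(rec$label == "true_positive")) return(NA_real_)
    roc_n(rec, min(n_fp, n_avail))$score
  }, numeric(1))
  list(se = stats::sd(scores, na.rm = TRUE), B = B, scores = scores)
}
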