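#' Gumbel parameters of the score tail
#'
#' The score tail model is `P(M > y) ~ 1 - exp(-k A exp(-lambda y))`, where
#' `A` is the (possibly finite-size corrected) search area. `lambda` is the
#' scale parameter per score unit; `k` the pre-factor.
#'
#' @param lambda Scale parameter, > 0.
#' @param k Pre-factor, > 0.
#' @return An object of class `gumbel_params`.
#' @export
gumbel_params <- function(lambda, k) {
  stopifnot(lambda > 0, k > 0)
  structure(list(lambda = lambda, k = k), class = "gumbel_params")
}

#' @export
print.gumbel_params <- function(x, ...) {
  cat(sprintf("<gumbel_params> lambda = %.6g, k = %.6g\n", x$lambda, x$k))
  invisible(x)
}

#' Finite-size correction parameters
#'
#' Holds the slopes of the linear length-moment models
#' `l(y) = a y + b`, `v(y) = alpha y + beta`, `c(y) = sigma y + tau`
#' together with the ungapped constants `a_u`, `alpha_u` and the length-1 gap
#' penalty `G = gap_open + gap_extend`. The intercepts are not free: they are
#' derived from the slopes by [intercepts_from_slopes()], reflecting that the
#' p-values are relatively insensitive to the intercepts and that a gapped
#' excursion behaves like an ungapped one displaced by about `2G` in score.
#'
#' @param a_i,a_j Mean-length slopes (letters per score unit), > 0.
#' @param alpha_i,alpha_j Variance slopes, >= 0.
#' @param sigma Covariance slope.
#' @param a_u,alpha_u Ungapped mean-length and variance slopes (see
#'   [ungapped_slopes()]).
#' @param G Penalty of a length-1 gap, > 0.
#' @return An object of class `fsc_params` with the slopes, constants, and
#'   derived intercepts `b_i`, `b_j`, `beta_i`, `beta_j`, `tau`.
#' @export
fsc_params <- function(a_i, a_j, alpha_i, alpha_j, sigma, a_u, alpha_u, G) {
  stopifnot(a_i > 0, a_j > 0, a_u > 0, alpha_i >= 0, alpha_j >= 0,
            alpha_u >= 0, G > 0)
  ic <- intercepts_from_slopes(a_i, a_j, alpha_i, alpha_j, sigma, a_u, alpha_u, G)
  structure(c(list(a_i = a_i, a_j = a_j, alpha_i = alpha_i, alpha_j = alpha_j,
                   sigma = sigma, a_u = a_u, alpha_u = alpha_u, G = G), ic),
            class = "fsc_params")
}

#' @export
print.fsc_params <- function(x, ...) {
  cat(sprintf(paste0("<fsc_params> l_I(y) = %.4g y + %.4g, l_J(y) = %.4g y + %.4g\n",
                     "  v_I(y) = %.4g y + %.4g, v_J(y) = %.4g y + %.4g, ",
                     "c(y) = %.4g y + %.4g\n",
                     "  ungapped a_u = %.4g, alpha_u = %.4g; G = %g\n"),
              x$a_i, x$b_i, x$a_j, x$b_j, x$alpha_i, x$beta_i,
              x$alpha_j, x$beta_j, x$sigma, x$tau, x$a_u, x$alpha_u, x$G))
  invisible(x)
}

#' Intercepts of the length-moment models from their slopes
#'
#' The intercepts of the linear models for the required-length moments are
#' tied to the slopes through the ungapped constants and the length-1 gap
#' penalty `G`:
#' `b = 2 G (a_u - a)`, `beta = 2 G (alpha_u - alpha)`,
#' `tau = 2 G alpha_u - sigma`.
#'
#' @inheritParams fsc_params
#' @return Named list with `b_i`, `b_j`, `beta_i`, `beta_j`, `tau`.
#' @examples
#' intercepts_from_slopes(1.5, 1.5, 2, 2, 1, a_u = 2, alpha_u = 3, G = 12)
#' @export
intercepts_from_slopes <- function(a_i, a_j, alpha_i, alpha_j, sigma,
                                   a_u, alpha_u, G) {
  stopifnot(G > 0)
  list(b_i = 2 * G * (a_u - a_i),
       b_j = 2 * G * (a_u - a_j),
       beta_i = 2 * G * (alpha_u - alpha_i),
       beta_j = 2 * G * (alpha_u - alpha_j),
       tau = 2 * G * alpha_u - sigma)
}

#' Evaluate the length-moment models at a score
#'
#' Means, variances and covariance of the required lengths `(L_I(y), L_J(y))`
#' under the linear models. The linear models are asymptotic in `y`; at small
#' scores they can produce a negative variance or a covariance exceeding the
#' correlation bound. Negative variances are floored at 0 and flagged; the
#' covariance magnitude is checked against `sqrt(v_i * v_j)` and flagged
#' (not altered) when it overshoots.
#'
#' @param fsc An [fsc_params()] object.
#' @param y Score(s), >= 0; vectorized.
#' @return A tibble with columns `y`, `l_i`, `l_j`, `v_i`, `v_j`, `c`,
#'   `floored` (a variance was raised to 0), `cov_overshoot`.
#' @export
length_moments <- function(fsc, y) {
  stopifnot(all(y >= 0))
  v_i_raw <- fsc$alpha_i * y + fsc$beta_i
  v_j_raw <- fsc$alpha_j * y + fsc$beta_j
  v_i <- pmax(v_i_raw, 0)
  v_j <- pmax(v_j_raw, 0)
  cc <- fsc$sigma * y + fsc$tau
  tibble::tibble(
    y = y,
    l_i = fsc$a_i * y + fsc$b_i,
    l_j = fsc$a_j * y + fsc$b_j,
    v_i = v_i, v_j = v_j, c = cc,
    floored = v_i_raw < 0 | v_j_raw < 0,
    cov_overshoot = abs(cc) > sqrt(v_i * v_j) + 1e-9)
}

#' Mean-length (old) finite-size corrected area
#'
#' The classical correction subtracts the mean required lengths from the
#' sequence lengths: area `= (m - l_I(y)) (n - l_J(y))`. When a factor goes
#' negative it is clamped to the ad hoc value 1 per length, reproducing the
#' legacy behaviour that can understate the significance of matches to short
#' sequences.
#'
#' @param m,n Sequence lengths.
#' @param moments A [length_moments()] tibble (or one row of it).
#' @return Numeric vector of corrected areas, one per row of `moments`.
#' @export
area_old <- function(m, n, moments) {
  pmax(m - moments$l_i, 1) * pmax(n - moments$l_j, 1)
}

#' Distributional (new) finite-size corrected area
#'
#' Approximates the expected positive-part area
#' `E[(m - L_I(y))^+ (n - L_J(y))^+]` under a bivariate-normal model of the
#' required lengths, with an independence approximation for the cross term.
#' Writing `m_Phi = (m - l_I) / sqrt(v_I)` and using, for standard normal X,
#' the partial-expectation identity `E[X; X <= a] = -phi(a)` (differentiate
#' the normal density: the integral of `x phi(x)` up to `a` is `-phi(a)`),
#' each margin contributes
#' `factor = (m - l_I) Phi(m_Phi) + sqrt(v_I) phi(m_Phi)`,
#' and the area is `factor_I * factor_J + c(y) Phi(m_Phi) Phi(n_Phi)`,
#' clamped below at 0 (the exact expectation is non-negative; only the
#' covariance term can push the approximation negative). A zero-variance
#' margin degenerates by continuity to `max(m - l, 0)` with `m_Phi = +-Inf`.
#'
#' @inheritParams area_old
#' @return A tibble with columns `y`, `m_phi`, `n_phi`, `factor_i`,
#'   `factor_j`, `area`, `clamped`.
#' @examples
#' fsc <- fsc_params(1.5, 1.5, 2, 2, 1, a_u = 2, alpha_u = 3, G = 4)
#' area_new(200, 200, length_moments(fsc, 25))
#' @export
area_new <- function(m, n, moments) {
  margin <- function(len, l, v) {
    excess <- len - l
    a <- ifelse(v > 0, excess / sqrt(v), ifelse(excess >= 0, Inf, -Inf))
    fac <- ifelse(v > 0,
                  excess * stats::pnorm(a) + sqrt(v) * stats::dnorm(a),
                  pmax(excess, 0))
    list(a = a, fac = fac)
  }
  mi <- margin(m, moments$l_i, moments$v_i)
  mj <- margin(n, moments$l_j, moments$v_j)
  raw <- mi$fac * mj$fac +
    moments$c * stats::pnorm(mi$a) * stats::pnorm(mj$a)
  tibble::tibble(y = moments$y,
                 m_phi = mi$a, n_phi = mj$a,
                 factor_i = mi$fac, factor_j = mj$fac,
                 area = pmax(raw, 0),
                 clamped = raw < 0)
}

#' Tail p-value of a local alignment score
#'
#' `P(M > y) = 1 - exp(-k A e^(-lambda y))` with the search area `A` equal to
#' `m n` (`"uncorrected"`), the mean-length corrected area (`"old"`), or the
#' distributional corrected area (`"new"`). Computed in log space: tiny
#' p-values are exact down to the double-precision floor.
#'
#' @param y Score(s), >= 0.
#' @param m,n Sequence lengths.
#' @param gumbel A [gumbel_params()] object.
#' @param fsc An [fsc_params()] object (required for corrected methods).
#' @param method One of `"new"`, `"old"`, `"uncorrected"`.
#' @return Numeric vector of p-values in `[0, 1]`; 0 exactly when the
#'   corrected area is 0.
#' @examples
#' gum <- gumbel_params(lambda = 0.3, k = 0.05)
#' alignment_pvalue(60, 250, 250, gum, method = "uncorrected")
#' @export
alignment_pvalue <- function(y, m, n, gumbel, fsc = NULL,
                             method = c("new", "old", "uncorrected")) {
  method <- match.arg(method)
  stopifnot(all(y >= 0), all(m >= 1), all(n >= 1))
  if (method != "uncorrected" && is.null(fsc)) {
    stop("`fsc` parameters are required for method '", method, "'")
  }
  A <- switch(method,
              uncorrected = as.numeric(m) * as.numeric(n),
              old = area_old(m, n, length_moments(fsc, y)),
              new = area_new(m, n, length_moments(fsc, y))$area)
  # rate = k * A * exp(-lambda y), kept in logs to survive lambda*y >> 700
  log_rate <- log(gumbel$k) + log(A) - gumbel$lambda * y
  p <- -expm1(-exp(log_rate))
  A <- rep_len(A, length(p))
  # below the exp() underflow floor, the rate itself is the exact limit
  tiny <- A > 0 & rep_len(log_rate, length(p)) < -700
  p[tiny] <- exp(rep_len(log_rate, length(p))[tiny])
  p[A == 0] <- 0
  p
}

#' Database expect value from a pairwise p-value
#'
#' Converts the pairwise tail probability to a Poisson rate `-ln(1 - p)` and
#' scales it by the ratio of the database length to the subject sequence
#' length, so that a database of many subject-sized sequences contributes
#' proportionally many chances of a spurious hit.
#'
#' @param p_pair Pairwise p-value(s) in `[0, 1]`.
#' @param subject_len Subject (target) sequence length, >= 1.
#' @param db_len Total database length in letters, >= `subject_len`.
#' @return Expect value(s), >= 0; `Inf` (with a warning) when `p_pair = 1`.
#' @examples
#' evalue(0.01, subject_len = 100, db_len = 1000)
#' @export
evalue <- function(p_pair, subject_len, db_len) {
  stopifnot(all(p_pair >= 0), all(p_pair <= 1),
            all(subject_len >= 1), all(db_len >= subject_len))
  if (any(p_pair == 1)) {
    warning("p_pair = 1 gives an infinite expect value")
  }
  (db_len / subject_len) * (-log1p(-p_pair))
}
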