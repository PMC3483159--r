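# Brute-force local alignment DP without the three-state affine
# decomposition: gap costs are enumerated over explicit gap lengths.
# O(mn(m+n)) -- only for small test instances.
brute_force_sw <- function(seq_i, seq_j, sys) {
  si <- strsplit(seq_i, "")[[1]]
  sj <- strsplit(seq_j, "")[[1]]
  go <- sys$gap_open
  ge <- sys$gap_extend
  m <- length(si)
  n <- length(sj)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      cand <- c(0, H[i - 1, j - 1] + sys$matrix[si[i - 1], sj[j - 1]])
      for (g in seq_len(i - 1)) cand <- c(cand, H[i - g, j] - go - g * ge)
      for (g in seq_len(j - 1)) cand <- c(cand, H[i, j - g] - go - g * ge)
      H[i, j] <- max(cand)
      best <- max(best, H[i, j])
    }
  }
  as.integer(best)
}

random_string <- function(letters, n) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Hand-built alignment object for crossing-extraction tests.
fake_alignment <- function(path, step_scores) {
  structure(list(score = max(c(0, cumsum(step_scores))),
                 start_i = 1, start_j = 1,
                 end_i = sum(path != "gap_i"), end_j = sum(path != "gap_j"),
                 path = path, cumulative_scores = cumsum(step_scores)),
            class = "sw_alignment")
}

# Crossing samples drawn directly from a stated linear moment model:
# (L_I, L_J) bivariate normal at each threshold, independently across
# thresholds.
synthetic_crossings <- function(y_grid, n_per_y,
                                a = 1.8, b = 5, alpha = 3, beta = 10,
                                sigma = 1.5, tau = 2) {
  purrr::map_dfr(y_grid, function(y) {
    l <- a * y + b
    v <- alpha * y + beta
    cv <- sigma * y + tau
    z1 <- stats::rnorm(n_per_y)
    z2 <- stats::rnorm(n_per_y)
    rho <- cv / v
    li <- l + sqrt(v) * z1
    lj <- l + sqrt(v) * (rho * z1 + sqrt(1 - rho^2) * z2)
    tibble::tibble(y = y, l_i = li, l_j = lj)
  })
}

# Single-seed slope-recovery check used by unit and acceptance tests:
# TRUE when every one of the five recovered slopes lies within `k` SEs of
# the generating value.
slopes_recovered <- function(seed, k = 2, y_grid = 10:30, n_per_y = 500) {
  set.seed(seed)
  cr <- synthetic_crossings(y_grid, n_per_y)
  fits <- fit_length_moment_slopes(cr)
  truth <- c(l_i = 1.8, l_j = 1.8, v_i = 3, v_j = 3, c = 1.5)
  all(abs(fits$slope - truth[fits$moment]) <= k * fits$slope_se)
}
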