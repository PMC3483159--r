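test_that("length moments are linear in the score with the derived intercepts", {
  fsc <- fsc_params(a_i = 1.5, a_j = 1.5, alpha_i = 2, alpha_j = 2,
                    sigma = 1, a_u = 2, alpha_u = 3, G = 4)
  # b_i = 2*4*(2 - 1.5) = 4, so l_i(10) = 1.5*10 + 4
  mo <- length_moments(fsc, 10)
  expect_equal(mo$l_i, 19)
  expect_equal(mo$v_i, 2 * 10 + 2 * 4 * (3 - 2))
  expect_equal(mo$c, 1 * 10 + (2 * 4 * 3 - 1))
})

test_that("negative raw variances are floored at zero and flagged", {
  # alpha = 2, beta forced to -30 via alpha_u: beta = 2G(alpha_u - alpha)
  fsc <- fsc_params(a_i = 1, a_j = 1, alpha_i = 2, alpha_j = 2, sigma = 0,
                    a_u = 1, alpha_u = 2 - 30 / 24, G = 12)
  expect_equal(fsc$beta_i, -30)
  mo <- length_moments(fsc, 10)  # raw v = 20 - 30 = -10
  expect_equal(mo$v_i, 0)
  expect_true(mo$floored)
  mo2 <- length_moments(fsc, 100)
  expect_false(mo2$floored)
})

test_that("intercepts follow the slope relations exactly", {
  ic <- intercepts_from_slopes(a_i = 1.5, a_j = 2, alpha_i = 1, alpha_j = 1,
                               sigma = 10, a_u = 2, alpha_u = 17.856, G = 12)
  expect_equal(ic$b_i, 2 * 12 * (2 - 1.5))
  expect_equal(ic$b_j, 0)          # a_j = a_u
  expect_equal(ic$tau, 2 * 12 * 17.856 - 10)  # 418.544
  expect_equal(ic$beta_i, 2 * 12 * (17.856 - 1))
})

test_that("mean-length area reproduces the legacy clamp", {
  mo <- tibble::tibble(y = 0, l_i = 50, l_j = 50, v_i = 0, v_j = 0, c = 0)
  expect_equal(area_old(200, 200, mo), 150 * 150)
  # clamp engaged on the short side
  mo2 <- tibble::tibble(y = 0, l_i = 120, l_j = 120, v_i = 0, v_j = 0, c = 0)
  expect_equal(area_old(100, 400, mo2), 1 * 280)
  # zero mean lengths leave the raw area untouched
  mo3 <- tibble::tibble(y = 0, l_i = 0, l_j = 0, v_i = 0, v_j = 0, c = 0)
  expect_equal(area_old(123, 77, mo3), 123 * 77)
})

test_that("distributional area: forced spot value and degenerate limits", {
  # m = l_i and v_i = 2*pi force factor_i = sqrt(2*pi) * phi(0) = 1
  mo <- tibble::tibble(y = 0, l_i = 100, l_j = 50, v_i = 2 * pi, v_j = 0,
                       c = 0)
  a <- area_new(100, 200, mo)
  expect_equal(a$factor_i, 1)
  expect_equal(a$m_phi, 0)

  # all variances zero: unclamped mean-length product, positive part
  mo2 <- tibble::tibble(y = 0, l_i = 60, l_j = 70, v_i = 0, v_j = 0, c = 0)
  expect_equal(area_new(200, 300, mo2)$area, 140 * 230)
  expect_equal(area_new(50, 300, mo2)$area, 0)   # m < l_i: 0, not the clamp
  expect_identical(area_new(50, 300, mo2)$m_phi, -Inf)
})

test_that("distributional area matches Monte-Carlo with independent margins", {
  set.seed(4)
  mo <- tibble::tibble(y = 0, l_i = 100, l_j = 100, v_i = 400, v_j = 400,
                       c = 0)
  a <- area_new(200, 300, mo)
  n_mc <- 2e5
  li <- rnorm(n_mc, 100, 20)
  lj <- rnorm(n_mc, 100, 20)
  prod <- pmax(200 - li, 0) * pmax(300 - lj, 0)
  expect_lt(abs(a$area - mean(prod)), 3 * sd(prod) / sqrt(n_mc))
})

test_that("covariance term can clamp the area at zero, flagged", {
  mo <- tibble::tibble(y = 0, l_i = 100, l_j = 100, v_i = 1, v_j = 1,
                       c = -1e6)
  a <- area_new(101, 101, mo)
  expect_equal(a$area, 0)
  expect_true(a$clamped)
})

test_that("new-correction area is continuous in m where the old one clamps", {
  fsc <- fsc_params(a_i = 1.5, a_j = 1.5, alpha_i = 25, alpha_j = 25,
                    sigma = 10, a_u = 1.8, alpha_u = 30, G = 12)
  mo <- length_moments(fsc, 40)   # l ~ 69
  ms <- seq(floor(mo$l_i) - 15, floor(mo$l_i) + 15, by = 0.25)
  areas_new <- vapply(ms, function(m) area_new(m, 200, mo)$area, numeric(1))
  areas_old <- vapply(ms, function(m) area_old(m, 200, mo), numeric(1))
  # old area is pinned at the clamp for every m below l_i
  expect_true(all(areas_old[ms < mo$l_i] == 1 * (200 - mo$l_j)))
  # new area stays positive with small, even increments (no jump)
  expect_true(all(areas_new > 0))
  steps <- diff(areas_new)
  expect_true(all(steps > 0))
  expect_lt(max(steps) / min(steps[steps > 0]), 10)
})

test_that("p-values hit forced values and the small-argument limit", {
  gum <- gumbel_params(lambda = 0.25, k = 0.1)
  # choose y so that k * m * n * exp(-lambda y) = ln 2  ->  p = 1/2
  m <- 100; n <- 200
  y <- (log(gum$k * m * n) - log(log(2))) / gum$lambda
  expect_equal(alignment_pvalue(y, m, n, gum, method = "uncorrected"), 0.5)

  # tiny rates: p equals the rate to relative 1e-7
  y2 <- (log(gum$k * m * n) + log(1e9)) / gum$lambda   # rate 1e-9
  p2 <- alignment_pvalue(y2, m, n, gum, method = "uncorrected")
  expect_equal(p2, 1e-9, tolerance = 1e-7)

  # extreme scores survive in log space instead of underflowing exp()
  y3 <- (log(gum$k * m * n) + 310 * log(10)) / gum$lambda
  p3 <- alignment_pvalue(y3, m, n, gum, method = "uncorrected")
  expect_gt(p3, 0)
  expect_lt(p3, 1e-300)
})

test_that("p-value is zero exactly when the corrected area is zero", {
  gum <- gumbel_params(lambda = 0.25, k = 0.1)
  fsc <- fsc_params(a_i = 2, a_j = 2, alpha_i = 0, alpha_j = 0, sigma = 0,
                    a_u = 2, alpha_u = 0, G = 4)
  # deterministic lengths l = 2y; at m = n = 30 and y = 20, m < l -> area 0
  expect_equal(alignment_pvalue(20, 30, 30, gum, fsc, method = "new"), 0)
  expect_gt(alignment_pvalue(10, 30, 30, gum, fsc, method = "new"), 0)
})

test_that("corrected rate k*A(y)*exp(-lambda y) decreases in y", {
  fsc <- fsc_params(a_i = 1.5, a_j = 1.6, alpha_i = 25, alpha_j = 28,
                    sigma = 20, a_u = 1.8, alpha_u = 30, G = 12)
  gum <- gumbel_params(lambda = 0.27, k = 0.05)
  y <- 10:60
  mo <- length_moments(fsc, y)
  for (A in list(area_old(150, 150, mo), area_new(150, 150, mo)$area)) {
    log_rate <- log(gum$k) + log(A) - gum$lambda * y
    expect_true(all(diff(log_rate) < 0))
    p <- -expm1(-exp(log_rate))
    expect_true(all(diff(p) <= 0))
  }
})

test_that("new area approaches m*n as y -> 0 with zero intercepts", {
  # a = a_u, alpha = alpha_u and sigma = 2*G*alpha_u zero every intercept
  fsc <- fsc_params(a_i = 1.8, a_j = 1.8, alpha_i = 30, alpha_j = 30,
                    sigma = 2 * 12 * 30, a_u = 1.8, alpha_u = 30, G = 12)
  expect_equal(fsc$b_i, 0)
  expect_equal(fsc$tau, 0)
  a0 <- area_new(200, 300, length_moments(fsc, 0))
  expect_equal(a0$area, 200 * 300)
  # and never exceeds m*n + |c|
  for (y in c(0, 10, 30, 80)) {
    mo <- length_moments(fsc, y)
    expect_lte(area_new(200, 300, mo)$area, 200 * 300 + abs(mo$c))
  }
})

test_that("expect values scale with database length via the Poisson rate", {
  expect_equal(evalue(0.01, 100, 1000), 10 * (-log(0.99)))
  expect_equal(evalue(0, 100, 1000), 0)
  # single-sequence database: E ~ p for small p
  expect_equal(evalue(1e-6, 100, 100), 1e-6, tolerance = 1e-5)
  expect_warning(e1 <- evalue(1, 100, 1000), "infinite")
  expect_identical(e1, Inf)
  expect_error(evalue(0.5, 100, 50))
})
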