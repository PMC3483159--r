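test_that("ungapped lambda has the golden-ratio closed form for the toy system", {
  # uniform 2-letter, +1/-2: with x = exp(lambda), the moment equation is
  # x^3 - 2x^2 + 1 = 0 whose relevant root is the golden ratio
  lam <- lambda_ungapped(toy_scoring_system())
  expect_equal(lam, log((1 + sqrt(5)) / 2), tolerance = 1e-12)
  x <- exp(lam)
  expect_lt(abs(x^3 - 2 * x^2 + 1), 1e-10)
})

test_that("lambda halves exactly when scores double", {
  lam1 <- lambda_ungapped(toy_scoring_system())
  lam2 <- lambda_ungapped(toy_scoring_system(match = 2, mismatch = -4))
  expect_equal(lam2, lam1 / 2, tolerance = 1e-10)
})

test_that("moment-equation residual at the root is below 1e-12", {
  for (sys in list(toy_scoring_system(), blosum62_system(),
                   blosum62_system(background = "uniform"))) {
    tm <- tilted_moments(sys)
    expect_lt(tm$residual, 1e-12)
  }
})

test_that("BLOSUM62 lambda matches an independent bisection oracle", {
  sys <- blosum62_system()
  aa <- names(sys$comp_i)
  mass <- as.vector(outer(sys$comp_i, sys$comp_j))
  s <- as.vector(sys$matrix[aa, aa])
  f <- function(lam) sum(mass * exp(lam * s)) - 1
  lo <- 1e-6; hi <- 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(lambda_ungapped(sys), (lo + hi) / 2, tolerance = 1e-10)
})

test_that("tilted moments and ungapped slopes match hand arithmetic", {
  tm <- tilted_moments(toy_scoring_system())
  phi <- (1 + sqrt(5)) / 2
  expect_equal(exp(tm$lambda_u) / 2, phi / 2, tolerance = 1e-10)  # tilted match prob
  mu <- 1 * phi / 2 + (-2) * (1 - phi / 2)
  expect_equal(tm$mu_star, mu, tolerance = 1e-10)
  us <- ungapped_slopes(tm)
  expect_equal(us$a_u, 1 / mu, tolerance = 1e-10)
  expect_equal(us$a_u, 2.341641, tolerance = 1e-6)
  # degenerate walk: zero step variance gives zero variance slope
  expect_equal(ungapped_slopes(list(mu_star = 2, sigma2_star = 0))$alpha_u, 0)
})

test_that("ungapped slope formula agrees with simulated tilted first passage", {
  tm <- tilted_moments(toy_scoring_system())
  us <- ungapped_slopes(tm)
  p_match <- exp(tm$lambda_u) / 2
  set.seed(2024)
  n_rep <- 4000
  y_targets <- c(10, 20, 30)
  lengths <- sapply(y_targets, function(y) {
    mean(replicate(n_rep, {
      s <- 0; n <- 0
      while (s < y) {
        s <- s + ifelse(runif(1) < p_match, 1, -2)
        n <- n + 1
      }
      n
    }))
  })
  slope <- stats::coef(stats::lm(lengths ~ y_targets))[2]
  expect_lt(abs(slope - us$a_u) / us$a_u, 0.03)
})

test_that("Gumbel ML fit recovers known parameters from exact draws", {
  set.seed(99)
  lambda <- 0.30; k <- 0.05; m <- n <- 1000
  u <- log(k * m * n) / lambda
  x <- u - log(-log(runif(2e4))) / lambda
  fit <- fit_gumbel(x, m, n)
  expect_lt(abs(fit$lambda - lambda) / lambda, 0.02)
  expect_lt(abs(fit$k - k) / k, 0.15)
  expect_lt(abs(fit$lambda - lambda), 3 * fit$lambda_se)
})

test_that("Gumbel fit is location-equivariant", {
  set.seed(17)
  x <- 30 - log(-log(runif(5000))) / 0.3
  f1 <- fit_gumbel(x, 100, 100)
  f2 <- fit_gumbel(x + 5, 100, 100)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-4)
  expect_equal(f2$k / f1$k, exp(f1$lambda * 5), tolerance = 0.02)
})

test_that("Gumbel fit is robust to a single extreme outlier", {
  set.seed(31)
  x <- 30 - log(-log(runif(2e4))) / 0.3
  x_out <- c(x, max(x) + 30)
  f1 <- fit_gumbel(x, 100, 100)
  f2 <- fit_gumbel(x_out, 100, 100)
  expect_lt(abs(f1$lambda - f2$lambda), f1$lambda_se)
})

test_that("degenerate scores are rejected", {
  expect_error(fit_gumbel(rep(5, 2000), 100, 100), "degenerate")
  expect_error(fit_gumbel(1:999, 100, 100), "at least 1000")
})

test_that("slope regression recovers a known linear moment model", {
  expect_true(slopes_recovered(seed = 1))
  # and the recovery is stable at a milder tolerance across several seeds
  ok3 <- vapply(2:6, slopes_recovered, logical(1), k = 3)
  expect_true(all(ok3))
})

test_that("slope regression reports sane uncertainties and errors", {
  set.seed(12)
  cr <- synthetic_crossings(10:30, 200)
  fits <- fit_length_moment_slopes(cr)
  expect_identical(fits$moment, c("l_i", "l_j", "v_i", "v_j", "c"))
  expect_true(all(fits$slope_se > 0))
  expect_identical(fits$n_points[1], 21L)
  expect_error(fit_length_moment_slopes(cr[cr$y == 10, ]),
               "fewer than 3 usable thresholds")
})

test_that("symmetric systems give matching I and J mean-length slopes", {
  sys <- toy_scoring_system()
  cfg <- calibration_config(n_sim = 200, R = 400, y_grid = 5:14, seed = 5)
  es <- estimate_slopes(sys, cfg)
  ai <- es$fits[es$fits$moment == "l_i", ]
  aj <- es$fits[es$fits$moment == "l_j", ]
  expect_lt(abs(ai$slope - aj$slope),
            2 * sqrt(ai$slope_se^2 + aj$slope_se^2))
  # variance estimates non-negative at every grid point; |corr| <= 1
  per_y <- dplyr::group_by(es$crossings, y)
  sm <- dplyr::summarise(per_y, v_i = stats::var(l_i), v_j = stats::var(l_j),
                         c = stats::cov(l_i, l_j))
  expect_true(all(sm$v_i >= 0 & sm$v_j >= 0))
  expect_true(all(abs(sm$c) <= sqrt(sm$v_i * sm$v_j) + 1e-9))
})

test_that("huge gap penalties drive the gapped slope to the ungapped one", {
  sys <- toy_scoring_system(gap_open = 1000, gap_extend = 1)
  us <- ungapped_slopes(tilted_moments(sys))
  # the grid top needs headroom below the typical score maximum, otherwise
  # conditioning on the optimum biases the crossing lengths short
  cfg <- calibration_config(n_sim = 2500, R = 300, y_grid = seq(4, 26, 2),
                            seed = 8)
  es <- estimate_slopes(sys, cfg)
  a_i <- es$fits$slope[es$fits$moment == "l_i"]
  expect_lt(abs(a_i - us$a_u) / us$a_u, 0.05)
})

test_that("slope estimation refuses grids the simulation cannot reach", {
  sys <- toy_scoring_system()
  cfg <- calibration_config(n_sim = 30, R = 100, y_grid = c(10, 25), seed = 3)
  expect_error(estimate_slopes(sys, cfg), "reached the top threshold")
})

test_that("calibration is deterministic and round-trips through JSON", {
  sys <- toy_scoring_system()
  cfg <- calibration_config(n_sim = 150, R = 150, y_grid = 4:10, seed = 42,
                            R_scores = 2000)
  cal1 <- calibrate(sys, cfg)
  cal2 <- calibrate(sys, cfg)
  expect_identical(glance(cal1), glance(cal2))

  f <- withr::local_tempfile()
  write_params_json(cal1, f)
  back <- read_params_json(f)
  y <- c(10, 15, 20)
  expect_equal(
    alignment_pvalue(y, 100, 100, back$gumbel, back$fsc, "new"),
    alignment_pvalue(y, 100, 100, cal1$gumbel, cal1$fsc, "new"),
    tolerance = 1e-12)
  expect_identical(back$provenance$seed, 42L)
})

test_that("different seeds move lambda by less than combined fit noise", {
  sys <- toy_scoring_system()
  cfgA <- calibration_config(n_sim = 150, R = 150, y_grid = 4:10, seed = 1,
                             R_scores = 4000)
  cfgB <- calibration_config(n_sim = 150, R = 150, y_grid = 4:10, seed = 2,
                             R_scores = 4000)
  fA <- calibrate(toy_scoring_system(), cfgA)$gumbel_fit
  fB <- calibrate(toy_scoring_system(), cfgB)$gumbel_fit
  expect_lt(abs(fA$lambda - fB$lambda),
            3 * sqrt(fA$lambda_se^2 + fB$lambda_se^2))
})
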