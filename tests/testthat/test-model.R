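test_that("step_spectrum places amplitudes on closed probe intervals", {
  one <- cnv_state(data.frame(s = 200, w = 50, a = 1.5), 1)
  f <- step_spectrum(one, 500)
  expect_equal(f[200:249], rep(1.5, 50))
  expect_equal(sum(f != 0), 50)

  expect_equal(step_spectrum(cnv_state(NULL, 1), 10), rep(0, 10))

  two <- cnv_state(data.frame(s = c(1, 4), w = c(2, 1), a = c(-1, 2)), 1)
  expect_equal(step_spectrum(two, 5), c(-1, -1, 0, 2, 0))

  expect_error(step_spectrum(one, 100), "past the end")
})

test_that("segment containers enforce their invariants", {
  expect_error(cnv_state(data.frame(s = 1, w = 0, a = 1), 1), "widths")
  expect_error(cnv_state(data.frame(s = c(1, 3), w = c(4, 2), a = c(1, 2)), 1),
               "non-overlapping")
  expect_error(cnv_state(NULL, -1), "positive")
  # canonical order: segments sorted by start
  st <- cnv_state(data.frame(s = c(50, 10), w = c(5, 5), a = c(1, 2)), 1)
  expect_equal(st$segments$s, c(10L, 50L))
  expect_equal(st$segments$e, c(14L, 54L))
})

test_that("log_likelihood matches the Gaussian closed form and a naive oracle", {
  # standard normal density at 0
  d1 <- gcn_signal(1, 0)
  expect_equal(log_likelihood(d1, cnv_state(NULL, 1)), -0.5 * log(2 * pi))

  # exact fit: only the normalisation term remains
  st <- cnv_state(data.frame(s = 3, w = 4, a = 2), sigma2 = 0.3)
  f <- step_spectrum(st, 10)
  expect_equal(log_likelihood(gcn_signal(1:10, f), st),
               -(10 / 2) * log(2 * pi * 0.3))

  # term-by-term hand evaluation
  d3 <- gcn_signal(1:3, c(1.0, 1.2, -0.3))
  st3 <- cnv_state(data.frame(s = 1, w = 2, a = 1.1), sigma2 = 0.04)
  expect_equal(log_likelihood(d3, st3),
               oracle_loglik(c(1.0, 1.2, -0.3), c(1.1, 1.1, 0), 0.04),
               tolerance = 1e-12)

  expect_error(log_likelihood(d3, cnv_state(data.frame(s = 1, w = 5, a = 1), 1)),
               "past the end")
})

test_that("prefix-sum residual evaluation agrees with naive summation", {
  set.seed(101)
  for (rep in 1:20) {
    m <- sample(20:200, 1)
    n <- sample(0:3, 1)
    segs <- NULL
    if (n > 0) {
      starts <- sort(sample(seq(1, m - 5, by = 5), n))
      segs <- data.frame(s = starts,
                         w = pmin(sample(1:5, n, replace = TRUE),
                                  diff(c(starts, m + 1))),
                         a = rnorm(n, 0, 2))
    }
    st <- cnv_state(segs, sigma2 = runif(1, 0.01, 2))
    x <- rnorm(m, 0, 1)
    d <- gcn_signal(1:m, x)
    expect_equal(log_likelihood(d, st),
                 oracle_loglik(x, oracle_spectrum(st$segments, m), st$sigma2),
                 tolerance = 1e-9)
  }
})

test_that("log_prior combines the documented densities and normalizes", {
  hp <- cnv_prior()
  m <- 10
  # N = 0: only the inverse-gamma term
  lp0 <- log_prior(cnv_state(NULL, 0.5), hp, m)
  expect_equal(lp0, log(1) - 0 - 2 * log(0.5) - 1 / 0.5) # alpha=beta=1 by hand

  # amplitude at its prior mean contributes -log(kappa * sqrt(2*pi))
  st <- cnv_state(data.frame(s = 2, w = 3, a = 0), 0.5)
  expect_equal(log_prior(st, hp, m) - lp0 + 2 * log(m),
               -log(hp$kappa * sqrt(2 * pi)))

  # normalization over the discrete (s, w) grid times the continuous factors
  total <- m^2 * (1 / m^2) *
    stats::integrate(function(a) dnorm(a, hp$tau, hp$kappa), -Inf, Inf)$value *
    stats::integrate(function(v) {
      vapply(v, function(vi) {
        exp(log_prior(cnv_state(NULL, vi), hp, m))
      }, numeric(1))
    }, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("informative windows zero the prior outside their support", {
  hp <- cnv_prior(informative_windows = data.frame(
    j = 1, s_lo = 100, s_hi = 150, w_lo = 10, w_hi = 60
  ))
  inside <- cnv_state(data.frame(s = 120, w = 30, a = 1), 1)
  outside <- cnv_state(data.frame(s = 99, w = 30, a = 1), 1)
  too_wide <- cnv_state(data.frame(s = 120, w = 61, a = 1), 1)
  expect_true(is.finite(log_prior(inside, hp, 500)))
  expect_identical(log_prior(outside, hp, 500), -Inf)
  expect_identical(log_prior(too_wide, hp, 500), -Inf)
  # uniform mass inside the window replaces the 1/M^2 factors
  expect_equal(
    log_prior(inside, hp, 500) - log_prior(inside, cnv_prior(), 500),
    2 * log(500) - log(51) - log(51)
  )
})

test_that("log_posterior is likelihood plus prior and peaks where it should", {
  set.seed(7)
  d <- simulate_gcn(cnv_state(data.frame(s = 5, w = 4, a = 1), 0.2), 20)
  hp <- cnv_prior()
  s1 <- cnv_state(data.frame(s = 5, w = 4, a = 1.0), 0.2)
  s2 <- cnv_state(data.frame(s = 9, w = 2, a = -0.4), 0.7)
  expect_equal(
    log_posterior(d, s1, hp) - log_posterior(d, s2, hp),
    (log_likelihood(d, s1) + log_prior(s1, hp, 20)) -
      (log_likelihood(d, s2) + log_prior(s2, hp, 20))
  )

  # with an exact fit, the posterior decreases in sigma2 above its mode
  f <- step_spectrum(s1, 20)
  dfit <- gcn_signal(1:20, f)
  grid <- seq(0.12, 2, by = 0.02) # mode is beta/(alpha + M/2 + 1) = 1/12
  vals <- vapply(grid, function(v) {
    log_posterior(dfit, cnv_state(s1$segments, v), hp)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("two-CNV posterior surface peaks at the generating starts", {
  p <- cnv_preset("two_cnv")
  d <- simulate_gcn(p$state, p$m, seed = 11)
  hp <- cnv_prior()
  grid <- seq(10, 660, by = 10)
  best <- c(NA, NA)
  best_val <- -Inf
  for (s1 in grid) {
    for (s2 in grid) {
      if (s2 < s1 + 20) next # keep segments ordered and non-overlapping
      st <- cnv_state(data.frame(s = c(s1, s2), w = c(20, 20), a = c(2, 2)),
                      p$state$sigma2)
      v <- log_posterior(d, st, hp)
      if (v > best_val) {
        best_val <- v
        best <- c(s1, s2)
      }
    }
  }
  expect_equal(best, c(100, 600))
})
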