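# A fixed toy problem small enough for exhaustive enumeration.
toy_m8 <- function() {
  x <- c(0.1, -0.2, 1.4, 1.6, 1.3, 0.2, -0.1, 0.3)
  list(
    data = gcn_signal(1:8, x),
    x = x,
    state = cnv_state(data.frame(s = 3, w = 3, a = 1.2), sigma2 = 0.2),
    prior = cnv_prior(w_min = 2, w_max = 4)
  )
}

test_that("amplitude conditional matches the printed conjugate formulas", {
  # w = 50 probes with mean exactly 1.5, sigma2 = 0.16, tau = 0, kappa = 100
  x <- numeric(100)
  x[21:70] <- 1.5
  d <- gcn_signal(1:100, x)
  st <- cnv_state(data.frame(s = 21, w = 50, a = 0), sigma2 = 0.16)
  cond <- amplitude_conditional(1, st, d, cnv_prior())

  prec <- 1 / 100^2 + 50 / 0.16
  expect_equal(cond$mean, ((50 / 0.16) / prec) * 1.5, tolerance = 1e-9)
  expect_equal(cond$var, 1 / prec, tolerance = 1e-9)
  expect_equal(cond$var, 3.199998976e-3, tolerance = 1e-7)

  # flat-prior limit kappa -> Inf: mean -> xbar, var -> sigma2 / w
  cflat <- amplitude_conditional(1, st, d, cnv_prior(kappa = 1e9))
  expect_equal(cflat$mean, 1.5, tolerance = 1e-6)
  expect_equal(cflat$var, 0.16 / 50, tolerance = 1e-6)

  # residuals are taken about the other segments' spectrum
  x2 <- x
  x2[1:10] <- x2[1:10] + 2
  st2 <- cnv_state(data.frame(s = c(1, 21), w = c(10, 50), a = c(2, 0)), 0.16)
  cond2 <- amplitude_conditional(2, st2, gcn_signal(1:100, x2), cnv_prior())
  expect_equal(cond2$mean, cond$mean, tolerance = 1e-9)
})

test_that("sigma2 conditional is InvGamma(alpha + M/2, beta + RSS/2)", {
  # residuals engineered so RSS = 80 with M = 500
  x <- rep(sqrt(80 / 500), 500)
  d <- gcn_signal(1:500, x)
  cond <- sigma2_conditional(cnv_state(NULL, 1), d, cnv_prior())
  expect_equal(cond$shape, 251, tolerance = 1e-12)
  expect_equal(cond$scale, 41, tolerance = 1e-9)

  # analytic mean scale/(shape - 1) = 41/250, checked against sampling
  set.seed(5)
  draws <- replicate(2e4, sample_sigma2(cnv_state(NULL, 1), d, cnv_prior()))
  an_mean <- 41 / 250
  an_sd <- sqrt(41^2 / (250^2 * 249))
  expect_equal(mean(draws), an_mean, tolerance = 4 * an_sd / sqrt(2e4) / an_mean)

  # no-data limit recovers the prior
  cond0 <- sigma2_conditional(cnv_state(NULL, 1), gcn_signal(1, 0), cnv_prior())
  expect_equal(cond0$scale, 1)
})

test_that("fixed-amplitude (s, w) conditional matches exhaustive enumeration", {
  toy <- toy_m8()
  cond <- position_width_conditional(1, toy$state, toy$data, toy$prior,
                                     collapse = FALSE)
  oracle <- oracle_sw_fixed_a(toy$x, a = 1.2, sigma2 = 0.2,
                              w_min = 2, w_max = 4)
  merged <- merge(as.data.frame(cond), oracle, by = c("s", "w"))
  expect_equal(nrow(merged), nrow(oracle)) # same candidate set
  expect_equal(exp(merged$log_weight), merged$prob, tolerance = 1e-9)
})

test_that("collapsed (s, w) conditional matches the quadrature oracle", {
  toy <- toy_m8()
  cond <- position_width_conditional(1, toy$state, toy$data, toy$prior,
                                     collapse = TRUE)
  oracle <- oracle_sw_marginal(toy$x, sigma2 = 0.2, tau = 0, kappa = 100,
                               w_min = 2, w_max = 4)
  merged <- merge(as.data.frame(cond), oracle, by = c("s", "w"))
  expect_equal(exp(merged$log_weight), merged$prob, tolerance = 1e-6)
})

test_that("the scan respects informative windows and flags empty candidate sets", {
  toy <- toy_m8()
  hp <- cnv_prior(w_min = 2, w_max = 4, informative_windows = data.frame(
    j = 1, s_lo = 3, s_hi = 5, w_lo = 2, w_hi = 3
  ))
  cond <- position_width_conditional(1, toy$state, toy$data, hp)
  expect_true(all(cond$s >= 3 & cond$s <= 5))
  expect_true(all(cond$w >= 2 & cond$w <= 3))

  # a window fully occupied by another segment leaves no candidates
  st2 <- cnv_state(data.frame(s = c(3, 7), w = c(3, 2), a = c(1, 1)), 0.2)
  hp2 <- cnv_prior(w_min = 2, w_max = 4, informative_windows = data.frame(
    j = 2, s_lo = 2, s_hi = 4, w_lo = 2, w_hi = 4
  ))
  expect_error(position_width_conditional(2, st2, toy$data, hp2),
               class = "stepcnv_config_error")
})

test_that("noise-free data makes the (s, w) conditional a point mass", {
  f <- numeric(40)
  f[11:25] <- 2
  d <- gcn_signal(1:40, f)
  st <- cnv_state(data.frame(s = 5, w = 3, a = 2), sigma2 = 1e-4)
  hp <- cnv_prior(w_min = 2, w_max = 30)
  set.seed(2)
  draws <- t(replicate(50, sample_position_width(1, st, d, hp, collapse = FALSE)))
  expect_true(all(draws[, "s"] == 11 & draws[, "w"] == 15))
})

test_that("repeated (s, w) draws follow the enumerated conditional (TV)", {
  toy <- toy_m8()
  cond <- position_width_conditional(1, toy$state, toy$data, toy$prior,
                                     collapse = FALSE)
  set.seed(31)
  draws <- t(replicate(2e4, sample_position_width(1, toy$state, toy$data,
                                                  toy$prior, collapse = FALSE)))
  exact <- data.frame(s = cond$s, w = cond$w, prob = exp(cond$log_weight))
  expect_lt(tv_distance(draws[, "s"], draws[, "w"], exact), 0.03)
})

test_that("the (s, w) + amplitude sweep targets the marginalised conditional", {
  # Frozen toy: sigma2 held fixed, alternate (s, w) and amplitude draws;
  # the stationary (s, w) frequencies must match the amplitude-marginalised
  # conditional computed by quadrature.
  toy <- toy_m8()
  exact <- oracle_sw_marginal(toy$x, sigma2 = 0.2, tau = 0, kappa = 100,
                              w_min = 2, w_max = 4)
  st <- toy$state
  n_sweeps <- 4e4
  s_seen <- integer(n_sweeps)
  w_seen <- integer(n_sweeps)
  set.seed(17)
  for (t in seq_len(n_sweeps)) {
    sw <- sample_position_width(1, st, toy$data, toy$prior, collapse = TRUE)
    st$segments$s[1] <- sw[["s"]]
    st$segments$w[1] <- sw[["w"]]
    st$segments$e[1] <- sw[["s"]] + sw[["w"]] - 1L
    st$segments$a[1] <- sample_amplitude(1, st, toy$data, toy$prior)
    s_seen[t] <- sw[["s"]]
    w_seen[t] <- sw[["w"]]
  }
  expect_lt(tv_distance(s_seen, w_seen, exact), 0.02)
})

test_that("chains are bit-reproducible given a seed", {
  d <- simulate_gcn(cnv_state(data.frame(s = 20, w = 10, a = 1.5), 0.1),
                    60, seed = 3)
  cfg <- sampler_config(n_iter = 40, burn_in = 10, seed = 99)
  f1 <- run_gibbs(d, 1, config = cfg)
  f2 <- run_gibbs(d, 1, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$iterations, f2$iterations)
  f3 <- run_gibbs(d, 1, config = sampler_config(n_iter = 40, burn_in = 10, seed = 100))
  expect_false(identical(f1$iterations, f3$iterations))
})

test_that("a null-model chain draws sigma2 from its fixed conditional", {
  set.seed(8)
  x <- rnorm(80, 0, 0.5)
  d <- gcn_signal(1:80, x)
  fit <- run_gibbs(d, 0, config = sampler_config(n_iter = 3000, burn_in = 0, seed = 12))
  shape <- 1 + 80 / 2
  scale <- 1 + sum(x^2) / 2
  an_mean <- scale / (shape - 1)
  an_var <- scale^2 / ((shape - 1)^2 * (shape - 2))
  expect_equal(mean(fit$iterations$sigma2), an_mean,
               tolerance = 4 * sqrt(an_var / 3000) / an_mean)
  expect_equal(nrow(fit$draws), 0)
})

test_that("posterior summaries: modes, means, and mean +/- 1.96 sd intervals", {
  d <- simulate_gcn(cnv_state(data.frame(s = 20, w = 10, a = 3), 0.01),
                    60, seed = 4)
  fit <- run_gibbs(d, 1, config = sampler_config(n_iter = 120, burn_in = 20, seed = 4))
  td <- tidy(fit)
  # high SNR: breakpoint draws are constant -> sd 0, degenerate interval
  srow <- td[td$term == "s_1", ]
  expect_equal(srow$estimate, 20)
  expect_equal(srow$std.error, 0)
  expect_equal(srow$conf.low, srow$conf.high)
  arow <- td[td$term == "a_1", ]
  expect_equal(arow$conf.high - arow$conf.low, 2 * 1.96 * arow$std.error)
  expect_true(arow$conf.low <= arow$estimate & arow$estimate <= arow$conf.high)
  expect_true(all(td$std.error >= 0))
  g <- glance(fit)
  expect_equal(g$n_draws, 100)
  expect_equal(g$seed, 4L)
  expect_error(tidy(run_gibbs(d, 0, config = sampler_config(n_iter = 5, burn_in = 4))),
               NA)
})

test_that("one-CNV recovery: credible intervals cover and modes hit the truth", {
  # At amplitude 1.5 and noise sd 0.4, each probe adjacent to a true
  # breakpoint shifts the posterior mode by one probe whenever its noise
  # crosses half the step height, i.e. with probability pnorm(-1.875) ~ 3%
  # per edge probe (4 such probes) -- so exact modal recovery is expected in
  # ~88% of replicates and recovery within one probe in ~99%.
  gen <- cnv_preset("one_cnv")
  n_rep <- 50
  covered <- logical(n_rep)
  exact_hit <- logical(n_rep)
  near_hit <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulate_gcn(gen$state, gen$m, seed = 6000 + r)
    fit <- run_gibbs(d, 1, config = sampler_config(n_iter = 250, burn_in = 50,
                                                   seed = 6000 + r))
    td <- tidy(fit)
    a1 <- td[td$term == "a_1", ]
    covered[r] <- a1$conf.low <= 1.5 && 1.5 <= a1$conf.high
    s_hat <- td$estimate[td$term == "s_1"]
    e_hat <- td$estimate[td$term == "e_1"]
    exact_hit[r] <- s_hat == 200 && e_hat == 249
    near_hit[r] <- abs(s_hat - 200) <= 1 && abs(e_hat - 249) <= 1
  }
  expect_gte(mean(covered), 0.85)
  expect_gte(mean(exact_hit), 0.7)
  expect_gte(mean(near_hit), 0.95)
})

test_that("one sweep on M = 500 with a wide scan finishes well under a second", {
  d <- simulate_gcn(cnv_state(data.frame(s = 200, w = 50, a = 1.5), 0.16),
                    500, seed = 1)
  hp <- cnv_prior(w_max = 200)
  cfg <- sampler_config(n_iter = 1, burn_in = 0, seed = 1)
  run_gibbs(d, 1, hp, cfg) # warm up
  elapsed <- system.time(run_gibbs(d, 1, hp, cfg))[["elapsed"]]
  expect_lt(elapsed, 1)
})

test_that("dispersed chains converge to overlapping summaries", {
  d <- simulate_gcn(cnv_preset("one_cnv")$state, 500, seed = 21)
  out <- gibbs_convergence(d, 1, config = sampler_config(
    n_iter = 150, burn_in = 50, seed = 300, n_chains = 3
  ))
  s_modes <- out$estimate[out$term == "s_1"]
  a_means <- out$estimate[out$term == "a_1"]
  expect_true(all(s_modes == 200))
  expect_lt(max(a_means) - min(a_means), 0.05)
})

test_that("per-probe inclusion frequencies reflect segment occupancy", {
  d <- simulate_gcn(cnv_state(data.frame(s = 20, w = 10, a = 3), 0.01),
                    60, seed = 9)
  fit <- run_gibbs(d, 1, config = sampler_config(n_iter = 100, burn_in = 20, seed = 9))
  incl <- inclusion_frequency(fit)
  expect_length(incl, 60)
  expect_true(all(incl >= 0 & incl <= 1))
  expect_true(all(incl[20:29] > 0.95))
  expect_true(all(incl[c(1:15, 35:60)] < 0.2))
})
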