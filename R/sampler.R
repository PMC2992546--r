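#' Sampler configuration
#'
#' @param n_iter Total Gibbs iterations T. Default 500, which is ample for
#'   this model: chains typically reach stationarity within a few dozen
#'   sweeps.
#' @param burn_in Initial iterations discarded before summarisation and
#'   evidence estimation. Default 100.
#' @param seed Integer RNG seed; recorded in all outputs. `NULL` leaves the
#'   RNG state untouched (runs are then not reproducible).
#' @param n_chains Number of chains for convergence checking (see
#'   [gibbs_convergence()]). Default 1.
#' @param init Optional explicit initial state (a [cnv_state()]).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 500L, burn_in = 100L, seed = NULL,
                           n_chains = 1L, init = NULL) {
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  if (burn_in >= n_iter) rlang::abort("`burn_in` must be smaller than `n_iter`.")
  if (burn_in < 0) rlang::abort("`burn_in` must be >= 0.")
  if (!is.null(init) && !inherits(init, "cnv_state")) {
    rlang::abort("`init` must be a `cnv_state`.")
  }
  structure(
    list(n_iter = n_iter, burn_in = burn_in,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         n_chains = as.integer(n_chains), init = init),
    class = "sampler_config"
  )
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Candidate grid and log-weights for the discrete (s, w) conditional of
# segment j. Residuals are taken about the spectrum of the *other* segments;
# windowed residual sums come from one prefix-sum pass and, per width, the
# weight is an affine/quadratic function of that sum, so the whole O(M * W)
# grid costs O(1) arithmetic per candidate — never a fresh O(M) summation.
# collapse = TRUE integrates the segment's amplitude out of the weight
# (conjugate normal prior, or a finite sum over discrete amplitude levels);
# collapse = FALSE conditions on the current amplitude a_j.
position_width_grid <- function(j, state, data, prior, collapse = TRUE) {
  x <- data$value
  m <- length(x)
  seg <- state$segments
  others <- seg[-j, , drop = FALSE]
  f_minus <- numeric(m)
  for (i in seq_len(nrow(others))) {
    f_minus[others$s[i]:others$e[i]] <- others$a[i]
  }
  r <- x - f_minus
  pre <- c(0, cumsum(r))

  s_lo <- 1L; s_hi <- m
  w_lo <- prior$w_min; w_hi <- effective_w_max(prior, m)
  win <- window_for(prior, j)
  if (!is.null(win)) {
    s_lo <- max(s_lo, as.integer(win$s_lo)); s_hi <- min(s_hi, as.integer(win$s_hi))
    w_lo <- max(w_lo, as.integer(win$w_lo)); w_hi <- min(w_hi, as.integer(win$w_hi))
  }
  if (s_lo > s_hi || w_lo > w_hi) {
    rlang::abort(sprintf("Empty (s, w) candidate set for segment %d.", j),
                 class = "stepcnv_config_error")
  }
  s_vals <- s_lo:s_hi
  w_vals <- w_lo:w_hi
  ns <- length(s_vals); nw <- length(w_vals)
  sigma2 <- state$sigma2
  logw <- matrix(-Inf, ns, nw)

  lev <- prior$amplitude_levels
  if (collapse && is.null(lev)) {
    # marginal over a ~ N(tau, kappa^2), a quadratic in the residual sum R:
    # log w = -log(kappa^2 lam)/2 - tau^2/(2 kappa^2) + (tau/kappa^2 + R/sigma2)^2 / (2 lam)
    lam <- 1 / prior$kappa^2 + w_vals / sigma2
    cw <- -0.5 * log(prior$kappa^2 * lam) - prior$tau^2 / (2 * prior$kappa^2)
    tt <- prior$tau / prior$kappa^2
  } else if (!collapse) {
    a_cur <- seg$a[j]
  }

  for (wi in seq_len(nw)) {
    w <- w_vals[wi]
    n_ok <- min(ns, m - w + 2L - s_lo) # need s + w - 1 <= m
    if (n_ok < 1L) next
    sv <- s_vals[seq_len(n_ok)]
    rsum <- pre[sv + w] - pre[sv]
    col <- if (!collapse) {
      (a_cur / sigma2) * rsum - w * a_cur^2 / (2 * sigma2)
    } else if (is.null(lev)) {
      z <- tt + rsum / sigma2
      cw[wi] + 0.5 * z * z / lam[wi]
    } else {
      parts <- lapply(seq_len(nrow(lev)), function(l) {
        log(lev$prob[l]) + (lev$a[l] / sigma2) * rsum -
          w * lev$a[l]^2 / (2 * sigma2)
      })
      mx <- Reduce(pmax, parts)
      mx + log(Reduce(`+`, lapply(parts, function(p) exp(p - mx))))
    }
    # exclude candidates overlapping the other segments:
    # [s, s + w - 1] hits [s2, e2] iff s in [s2 - w + 1, e2]
    for (i in seq_len(nrow(others))) {
      lo <- max(sv[1L], others$s[i] - w + 1L)
      hi <- min(sv[n_ok], others$e[i])
      if (lo <= hi) col[(lo - sv[1L] + 1L):(hi - sv[1L] + 1L)] <- -Inf
    }
    logw[seq_len(n_ok), wi] <- col
  }
  if (max(logw) == -Inf) {
    rlang::abort(sprintf(
      "Empty (s, w) candidate set for segment %d: informative window conflicts with other segments.", j
    ), class = "stepcnv_config_error")
  }
  list(s_vals = s_vals, w_vals = w_vals, logw = logw)
}

#' Discrete full conditional of a segment's (start, width)
#'
#' Enumerates every candidate start/width pair for segment `j` — all
#' `s` in `[1, M]` and `w` in `[w_min, min(w_max, M - s + 1)]`, excluding
#' pairs overlapping the other segments and pairs outside any informative
#' window — with its unnormalised log conditional weight. With
#' `collapse = TRUE` (the default used inside [run_gibbs()]) the segment's
#' amplitude is integrated out analytically; with `collapse = FALSE` the
#' weight conditions on the current amplitude `a_j`.
#'
#' @param j Segment index (into `state$segments`).
#' @param state Current [cnv_state()].
#' @param data GCN tibble.
#' @param prior A [cnv_prior()].
#' @param collapse Marginalise the amplitude analytically?
#' @return A tibble with columns `s`, `w`, `log_weight` (finite rows only),
#'   normalised so the weights' log-sum-exp is 0.
#' @export
position_width_conditional <- function(j, state, data, prior, collapse = TRUE) {
  data <- validate_gcn(data)
  g <- position_width_grid(j, state, data, prior, collapse)
  keep <- which(is.finite(g$logw))
  lw <- g$logw[keep] - logsumexp(g$logw[keep])
  ns <- length(g$s_vals)
  tibble::tibble(
    s = g$s_vals[(keep - 1L) %% ns + 1L],
    w = g$w_vals[(keep - 1L) %/% ns + 1L],
    log_weight = lw
  )
}

#' Gibbs updates: segment position/width, amplitude, and noise variance
#'
#' These are the three conditional draws cycled by [run_gibbs()]; they are
#' exported so the conditionals can be inspected and validated directly.
#'
#' `sample_position_width()` draws `(s_j, w_j)` from the discrete conditional
#' over all candidate pairs (probability proportional to the exponentiated
#' log posterior, normalised by log-sum-exp; the current pair is always a
#' candidate). `sample_amplitude()` draws `a_j` from its conjugate normal
#' conditional with mean
#' `[(1/kappa^2) tau + (w/sigma^2) xbar_j] / (1/kappa^2 + w/sigma^2)` and
#' variance `1 / (1/kappa^2 + w/sigma^2)` where `xbar_j` is the mean signal
#' inside segment `j` (residual about the other segments); under a discrete
#' amplitude prior it draws from the finite conditional instead.
#' `sample_sigma2()` draws from `InvGamma(alpha + M/2, beta + RSS/2)` with
#' RSS the residual sum of squares about the current fitted spectrum.
#'
#' @inheritParams position_width_conditional
#' @return `sample_position_width()`: integer vector `c(s, w)`;
#'   `sample_amplitude()` and `sample_sigma2()`: a single draw.
#' @seealso [amplitude_conditional()], [sigma2_conditional()] for the closed
#'   forms behind the conjugate draws.
#' @export
sample_position_width <- function(j, state, data, prior, collapse = TRUE) {
  g <- position_width_grid(j, state, data, prior, collapse)
  cs <- cumsum(exp(g$logw - max(g$logw)))
  u <- stats::runif(1L) * cs[length(cs)]
  idx <- sum(cs < u) + 1L
  ns <- length(g$s_vals)
  c(s = g$s_vals[(idx - 1L) %% ns + 1L],
    w = g$w_vals[(idx - 1L) %/% ns + 1L])
}

#' Closed-form conditional moments of a segment amplitude
#'
#' @inheritParams position_width_conditional
#' @return For the normal amplitude prior, a list with `mean` and `var`; for
#'   a discrete amplitude prior, a tibble with `a` and `prob`.
#' @export
amplitude_conditional <- function(j, state, data, prior) {
  seg <- state$segments
  others <- seg[-j, , drop = FALSE]
  idx <- seg$s[j]:seg$e[j]
  f_minus <- numeric(nrow(data))
  for (i in seq_len(nrow(others))) {
    f_minus[others$s[i]:others$e[i]] <- others$a[i]
  }
  r <- data$value[idx] - f_minus[idx]
  w <- seg$w[j]
  sigma2 <- state$sigma2
  if (is.null(prior$amplitude_levels)) {
    lam <- 1 / prior$kappa^2 + w / sigma2
    mu <- (prior$tau / prior$kappa^2 + sum(r) / sigma2) / lam
    list(mean = mu, var = 1 / lam)
  } else {
    lev <- prior$amplitude_levels
    lw <- log(lev$prob) - (w * lev$a^2 - 2 * lev$a * sum(r)) / (2 * sigma2)
    tibble::tibble(a = lev$a, prob = exp(lw - logsumexp(lw)))
  }
}

#' @rdname sample_position_width
#' @export
sample_amplitude <- function(j, state, data, prior) {
  cond <- amplitude_conditional(j, state, data, prior)
  if (is.data.frame(cond)) {
    cond$a[sample.int(nrow(cond), 1L, prob = cond$prob)]
  } else {
    stats::rnorm(1L, cond$mean, sqrt(cond$var))
  }
}

#' Closed-form conditional of the noise variance
#'
#' @inheritParams position_width_conditional
#' @return A list with inverse-gamma `shape` (`alpha + M/2`) and `scale`
#'   (`beta + RSS/2`), RSS taken about the current fitted spectrum.
#' @export
sigma2_conditional <- function(state, data, prior) {
  m <- nrow(data)
  rss <- rss_state(data$value, state)
  list(shape = prior$alpha + m / 2, scale = prior$beta + rss / 2)
}

#' @rdname sample_position_width
#' @export
sample_sigma2 <- function(state, data, prior) {
  cond <- sigma2_conditional(state, data, prior)
  1 / stats::rgamma(1L, shape = cond$shape, rate = cond$scale)
}

# Default initial state: random non-overlapping starts (inside any
# informative window), widths w_min, amplitudes 0, sigma2 = sample variance.
default_init <- function(data, n_cnv, prior) {
  m <- nrow(data)
  w0 <- prior$w_min
  if (n_cnv * w0 > m) {
    rlang::abort("Cannot place the requested number of segments in the signal.")
  }
  segments <- NULL
  if (n_cnv > 0) {
    for (try in 1:1000) {
      s <- integer(n_cnv)
      for (j in seq_len(n_cnv)) {
        win <- window_for(prior, j)
        lo <- if (is.null(win)) 1L else as.integer(win$s_lo)
        hi <- if (is.null(win)) m - w0 + 1L else min(as.integer(win$s_hi), m - w0 + 1L)
        s[j] <- sample(lo:hi, 1L)
      }
      o <- order(s)
      if (all(diff(s[o]) >= w0)) {
        segments <- tibble::tibble(s = s, w = rep(w0, n_cnv), a = 0)
        break
      }
    }
    if (is.null(segments)) {
      # deterministic fallback: evenly spaced placement
      s <- as.integer(round(seq(1, m - w0 + 1, length.out = n_cnv)))
      segments <- tibble::tibble(s = s, w = rep(w0, n_cnv), a = 0)
    }
  }
  s2 <- stats::var(data$value)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1
  cnv_state(segments, sigma2 = s2)
}

#' Fit the stepwise CNV model by Gibbs sampling
#'
#' Runs a systematic-sweep Gibbs sampler over the parameters of an `N`-segment
#' model: each iteration updates, for `j = 1..N`, the pair `(s_j, w_j)` from
#' its discrete conditional (amplitude marginalised analytically, so the scan
#' compares candidate placements on their integrated support rather than at
#' the current amplitude) and then `a_j` from its conjugate conditional;
#' finally `sigma2` is drawn from its inverse-gamma conditional. Segments are
#' re-sorted by start after each sweep (canonical labelling), and the data
#' log-likelihood and unnormalised log posterior of each draw are recorded.
#' For `n_cnv = 0` only `sigma2` is sampled. Runs are bit-reproducible given
#' `config$seed`.
#'
#' @param data A GCN tibble ([gcn_signal()] / [read_gcn_table()]).
#' @param n_cnv Fixed number of CNV segments N >= 0 (model selection over N
#'   is done by [select_n()]).
#' @param prior A [cnv_prior()].
#' @param config A [sampler_config()].
#' @param collapse Use the amplitude-marginalised (s, w) scan (default TRUE);
#'   `FALSE` conditions the scan on the current amplitude.
#' @return An object of class `cnv_chain`: a list with `draws` (tibble:
#'   `iteration`, `segment`, `s`, `w`, `e`, `a`), `iterations` (tibble:
#'   `iteration`, `sigma2`, `loglik`, `logpost`), the data, prior, config,
#'   `n_cnv` and `m`. Use [tidy()][tidy.cnv_chain] / [glance()] /
#'   [autoplot()][autoplot.cnv_chain] on it.
#' @examples
#' sim <- simulate_gcn(cnv_state(data.frame(s = 30, w = 12, a = 1.5), 0.16),
#'                     m = 100, seed = 1)
#' fit <- run_gibbs(sim, n_cnv = 1,
#'                  config = sampler_config(n_iter = 60, burn_in = 20, seed = 1))
#' tidy(fit)
#' @export
run_gibbs <- function(data, n_cnv, prior = cnv_prior(),
                      config = sampler_config(), collapse = TRUE) {
  data <- validate_gcn(data)
  m <- nrow(data)
  n_cnv <- as.integer(n_cnv)
  stopifnot(n_cnv >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)

  state <- if (is.null(config$init)) default_init(data, n_cnv, prior) else config$init
  check_state_bounds(state, m)
  if (n_segments(state) != n_cnv) {
    rlang::abort("`init` has a different number of segments than `n_cnv`.")
  }

  t_tot <- config$n_iter
  s_mat <- matrix(NA_integer_, t_tot, n_cnv)
  w_mat <- matrix(NA_integer_, t_tot, n_cnv)
  a_mat <- matrix(NA_real_, t_tot, n_cnv)
  sigma2_vec <- numeric(t_tot)
  loglik_vec <- numeric(t_tot)
  logpost_vec <- numeric(t_tot)

  for (t in seq_len(t_tot)) {
    for (j in seq_len(n_cnv)) {
      sw <- sample_position_width(j, state, data, prior, collapse = collapse)
      state$segments$s[j] <- sw[["s"]]
      state$segments$w[j] <- sw[["w"]]
      state$segments$e[j] <- sw[["s"]] + sw[["w"]] - 1L
      state$segments$a[j] <- sample_amplitude(j, state, data, prior)
    }
    if (n_cnv > 1) {
      state$segments <- state$segments[order(state$segments$s), , drop = FALSE]
    }
    state$sigma2 <- sample_sigma2(state, data, prior)

    if (n_cnv > 0) {
      s_mat[t, ] <- state$segments$s
      w_mat[t, ] <- state$segments$w
      a_mat[t, ] <- state$segments$a
    }
    sigma2_vec[t] <- state$sigma2
    loglik_vec[t] <- log_likelihood(data, state)
    logpost_vec[t] <- loglik_vec[t] + log_prior(state, prior, m)
  }

  draws <- if (n_cnv > 0) {
    tibble::tibble(
      iteration = rep(seq_len(t_tot), times = n_cnv),
      segment = rep(seq_len(n_cnv), each = t_tot),
      s = as.integer(s_mat), w = as.integer(w_mat),
      e = as.integer(s_mat + w_mat - 1L), a = as.double(a_mat)
    )
  } else {
    tibble::tibble(iteration = integer(), segment = integer(),
                   s = integer(), w = integer(), e = integer(), a = double())
  }

  structure(
    list(
      draws = draws,
      iterations = tibble::tibble(
        iteration = seq_len(t_tot), sigma2 = sigma2_vec,
        loglik = loglik_vec, logpost = logpost_vec
      ),
      data = data, prior = prior, config = config,
      n_cnv = n_cnv, m = m, final_state = state
    ),
    class = "cnv_chain"
  )
}

#' @export
print.cnv_chain <- function(x, ...) {
  cat(sprintf(
    "<cnv_chain> N = %d, M = %d, %d iterations (burn-in %d)%s\n",
    x$n_cnv, x$m, x$config$n_iter, x$config$burn_in,
    if (is.null(x$config$seed)) "" else sprintf(", seed %d", x$config$seed)
  ))
  print(tidy(x))
  invisible(x)
}

post_burnin <- function(chain) {
  keep <- chain$iterations$iteration > chain$config$burn_in
  if (!any(keep)) rlang::abort("No draws remain after burn-in.")
  list(
    draws = chain$draws[chain$draws$iteration > chain$config$burn_in, , drop = FALSE],
    iterations = chain$iterations[keep, , drop = FALSE]
  )
}

stat_mode <- function(v) {
  ux <- sort(unique(v))
  ux[which.max(tabulate(match(v, ux)))] # ties break toward the smaller value
}

#' Posterior summaries of a fitted chain
#'
#' Discards burn-in draws and summarises each parameter: posterior mode (ties
#' toward the smaller value) for the discrete start `s`, width `w` and end
#' `e`; posterior mean for amplitudes and the noise s.d. `sigma` (square root
#' of the sampled variance). Each summary carries the posterior standard
#' deviation and the 95% credible interval `mean +/- 1.96 sd`.
#'
#' @param x A `cnv_chain` from [run_gibbs()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `parameter`, `segment`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.cnv_chain <- function(x, ...) {
  kept <- post_burnin(x)
  rows <- list()
  d <- kept$draws
  for (j in seq_len(x$n_cnv)) {
    dj <- d[d$segment == j, , drop = FALSE]
    for (par in c("s", "w", "e")) {
      v <- dj[[par]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = paste0(par, "_", j), parameter = par, segment = j,
        estimate = as.double(stat_mode(v)), std.error = stats::sd(v),
        center = mean(v)
      )
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = paste0("a_", j), parameter = "a", segment = j,
      estimate = mean(dj$a), std.error = stats::sd(dj$a), center = mean(dj$a)
    )
  }
  sig <- sqrt(kept$iterations$sigma2)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    term = "sigma", parameter = "sigma", segment = NA_integer_,
    estimate = mean(sig), std.error = stats::sd(sig), center = mean(sig)
  )
  out <- dplyr::bind_rows(rows)
  out$conf.low <- out$center - 1.96 * out$std.error
  out$conf.high <- out$center + 1.96 * out$std.error
  out$center <- NULL
  out
}

#' One-row summary of a fitted chain
#'
#' @param x A `cnv_chain`.
#' @param ... Unused.
#' @return A tibble with the model size, posterior noise s.d., draw counts,
#'   maximum log-likelihood and the seed.
#' @export
glance.cnv_chain <- function(x, ...) {
  kept <- post_burnin(x)
  tibble::tibble(
    n_cnv = x$n_cnv,
    sigma_hat = mean(sqrt(kept$iterations$sigma2)),
    n_iter = x$config$n_iter,
    burn_in = x$config$burn_in,
    n_draws = nrow(kept$iterations),
    max_loglik = max(kept$iterations$loglik),
    seed = if (is.null(x$config$seed)) NA_integer_ else x$config$seed
  )
}

#' Per-probe posterior inclusion frequency
#'
#' The fraction of post-burn-in draws in which probe `k` lies inside any
#' segment — a per-probe CNV detection score in `[0, 1]`, used e.g. as the
#' ROC score in benchmark simulations.
#'
#' @param chain A `cnv_chain`.
#' @return A numeric vector of length M.
#' @export
inclusion_frequency <- function(chain) {
  kept <- post_burnin(chain)
  n_draws <- nrow(kept$iterations)
  delta <- numeric(chain$m + 1L)
  d <- kept$draws
  if (nrow(d)) {
    for (i in seq_len(nrow(d))) {
      delta[d$s[i]] <- delta[d$s[i]] + 1
      delta[d$e[i] + 1L] <- delta[d$e[i] + 1L] - 1
    }
  }
  cumsum(delta[seq_len(chain$m)]) / n_draws
}

#' Convergence check across dispersed chains
#'
#' Runs several chains from different random initialisations (seeds
#' `seed, seed + 1, ...`) and returns their tidied posterior summaries side
#' by side, for checking that dispersed starts converge to overlapping
#' summaries.
#'
#' @inheritParams run_gibbs
#' @return A tibble of [tidy.cnv_chain()] rows with a `chain` column.
#' @export
gibbs_convergence <- function(data, n_cnv, prior = cnv_prior(),
                              config = sampler_config(n_chains = 2L)) {
  base_seed <- if (is.null(config$seed)) 1L else config$seed
  purrr::map_dfr(seq_len(config$n_chains), function(k) {
    cfg <- config
    cfg$seed <- base_seed + k - 1L
    cfg$n_chains <- 1L
    fit <- run_gibbs(data, n_cnv, prior, cfg)
    dplyr::mutate(tidy(fit), chain = k, .before = 1)
  })
}
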