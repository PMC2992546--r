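#' Marginal-likelihood estimators from posterior log-likelihood draws
#'
#' `log_evidence_hm()` is the harmonic-mean estimator of the log marginal
#' likelihood `ln p(D | M)`: the reciprocal of the mean reciprocal likelihood
#' over K posterior draws, computed entirely in log space as
#' `-logsumexp(-loglik) + ln K`. It is consistent but can have infinite
#' variance across simulations.
#'
#' `log_evidence_stabilized()` is the defensive-mixture stabilisation of
#' Newton & Raftery (1994): the posterior sample is augmented with
#' `m = delta * K` pseudo-draws whose likelihood equals the current marginal
#' estimate, giving the fixed point
#' \deqn{\hat p = \frac{m\delta/(1-\delta) + \sum_i L_i / (\delta \hat p + (1-\delta) L_i)}
#'                    {m\delta/((1-\delta)\hat p) + \sum_i 1 / (\delta \hat p + (1-\delta) L_i)}}
#' which is solved by iteration from the harmonic-mean value, in log space.
#' It has finite variance and reduces to the harmonic mean as `delta -> 0`.
#'
#' @param loglik Numeric vector of per-draw data log-likelihoods (finite).
#' @param delta Mixing weight in (0, 1); default 0.01.
#' @param tol Relative convergence tolerance on the log estimate.
#' @param max_iter Maximum fixed-point iterations.
#' @return The estimated log marginal likelihood (scalar).
#' @references Newton, M.A. and Raftery, A.E. (1994) Approximate Bayesian
#'   inference with the weighted likelihood bootstrap. JRSS B 56, 3-48.
#' @export
log_evidence_hm <- function(loglik) {
  if (length(loglik) < 1) rlang::abort("Need at least one log-likelihood draw.")
  if (anyNA(loglik) || any(!is.finite(loglik))) {
    rlang::abort("Log-likelihood draws must be finite.")
  }
  -logsumexp(-loglik) + log(length(loglik))
}

#' @rdname log_evidence_hm
#' @export
log_evidence_stabilized <- function(loglik, delta = 0.01,
                                    tol = 1e-10, max_iter = 1000L) {
  if (length(loglik) < 1) rlang::abort("Need at least one log-likelihood draw.")
  if (!(delta > 0 && delta < 1)) rlang::abort("`delta` must be in (0, 1).")
  k <- length(loglik)
  m_pseudo <- delta * k
  log_c <- log(m_pseudo) + log(delta) - log1p(-delta) # log(m delta / (1 - delta))
  l <- log_evidence_hm(loglik)
  for (it in seq_len(max_iter)) {
    # log(delta * phat + (1 - delta) * L_i), elementwise
    log_mix <- pmax(log(delta) + l, log1p(-delta) + loglik) +
      log1p(exp(-abs((log(delta) + l) - (log1p(-delta) + loglik))))
    num <- logsumexp(c(log_c, logsumexp(loglik - log_mix)))
    den <- logsumexp(c(log_c - l, logsumexp(-log_mix)))
    l_new <- num - den
    if (abs(l_new - l) <= tol * max(1, abs(l_new))) return(l_new)
    l <- l_new
  }
  rlang::abort(sprintf(
    "Stabilized evidence estimator did not converge in %d iterations (last log value %.6g, last change %.3g).",
    max_iter, l, abs(l_new - l)
  ))
}

#' Evidence of a fitted model
#'
#' Estimates the log marginal likelihood of a fitted chain from its
#' post-burn-in log-likelihood draws.
#'
#' @param chain A `cnv_chain` from [run_gibbs()].
#' @param estimator `"stabilized"` (default) or `"harmonic"`.
#' @param delta Mixing weight for the stabilized estimator.
#' @return A one-row tibble: `n`, `log_evidence`, `estimator`, `delta`,
#'   `n_draws`.
#' @export
evidence <- function(chain, estimator = c("stabilized", "harmonic"),
                     delta = 0.01) {
  estimator <- match.arg(estimator)
  ll <- post_burnin(chain)$iterations$loglik
  le <- switch(estimator,
    stabilized = log_evidence_stabilized(ll, delta = delta),
    harmonic = log_evidence_hm(ll)
  )
  tibble::tibble(
    n = chain$n_cnv, log_evidence = le, estimator = estimator,
    delta = if (estimator == "stabilized") delta else NA_real_,
    n_draws = length(ll)
  )
}

#' Log Bayes factor between two fitted models
#'
#' Under equal model priors the log Bayes factor of model 1 against model 2
#' is the difference of their log marginal likelihoods.
#'
#' @param ev1,ev2 Evidence rows from [evidence()] (or bare log-evidence
#'   numbers) for two models fitted to the same data.
#' @return The log Bayes factor (scalar, nats).
#' @export
log_bayes_factor <- function(ev1, ev2) {
  le <- function(e) if (is.data.frame(e)) e$log_evidence[1] else as.double(e)
  le(ev1) - le(ev2)
}

#' Select the number of CNVs by Bayes factors
#'
#' Fits models with `N = 0, 1, ..., n_max` segments by Gibbs sampling,
#' estimates each model's log marginal likelihood with the stabilized
#' estimator on post-burn-in draws, and compares every model with the null
#' (N = 0) model through log Bayes factors.
#'
#' Because the evidence estimates come from posterior likelihood draws, the
#' difference between models that fit the data equally well (an extra segment
#' parked on noise, or one CNV split in two) sits at the estimator's
#' few-nat noise floor, while each genuine CNV contributes tens to hundreds
#' of nats. The selected model is therefore built up greedily: `N` is
#' accepted over `N - 1` only when the incremental log Bayes factor exceeds
#' `min_gain` (default 5 nats, the conventional "very strong evidence"
#' cutoff), and the scan stops once two consecutive increments fall short
#' (when `early_stop = TRUE`). `min_gain = 0` reduces to the plain argmax of
#' the log Bayes factor with ties toward smaller `N`.
#'
#' @inheritParams run_gibbs
#' @param n_max Largest model to consider (default `prior$n_max`).
#' @param delta Mixing weight for the stabilized evidence estimator.
#' @param min_gain Incremental log-Bayes-factor (nats) required to accept a
#'   larger model.
#' @param early_stop Stop the scan after two consecutive sub-threshold
#'   increments?
#' @param keep_chains Keep the fitted chains in the result (default TRUE;
#'   needed by downstream reporting).
#' @return An object of class `cnv_scan`: list with `best_n`, `results`
#'   (tibble: `n`, `log_evidence`, `log_bf_vs_null`, `selected`), and
#'   `chains` (list indexed by `as.character(n)`). Use [tidy()] /
#'   [glance()] / [autoplot()][autoplot.cnv_scan] on it.
#' @references Kass, R.E. and Raftery, A.E. (1995) Bayes factors. JASA 90,
#'   773-795.
#' @examples
#' sim <- simulate_gcn(cnv_state(data.frame(s = 30, w = 15, a = 2), 0.16),
#'                     m = 100, seed = 7)
#' scan <- select_n(sim, config = sampler_config(n_iter = 80, burn_in = 20, seed = 7),
#'                  n_max = 2)
#' scan$best_n
#' @export
select_n <- function(data, prior = cnv_prior(), config = sampler_config(),
                     n_max = prior$n_max, delta = 0.01, min_gain = 5,
                     early_stop = TRUE, keep_chains = TRUE) {
  data <- validate_gcn(data)
  stopifnot(n_max >= 1, min_gain >= 0)
  base_seed <- config$seed
  chains <- list()
  rows <- list()
  short <- 0L
  last_bf <- 0
  best_n <- 0L
  ev0 <- NULL
  for (n in 0:n_max) {
    cfg <- config
    if (!is.null(base_seed)) cfg$seed <- base_seed + n
    chain <- run_gibbs(data, n, prior, cfg)
    ev <- evidence(chain, "stabilized", delta = delta)
    if (n == 0) ev0 <- ev
    bf <- log_bayes_factor(ev, ev0)
    rows[[length(rows) + 1L]] <- dplyr::mutate(ev, log_bf_vs_null = bf)
    if (keep_chains) chains[[as.character(n)]] <- chain
    if (n >= 1) {
      gain <- bf - last_bf
      if (gain > min_gain && best_n == n - 1L) best_n <- n
      short <- if (gain <= min_gain) short + 1L else 0L
      if (early_stop && short >= 2L) break
    }
    last_bf <- bf
  }
  results <- dplyr::bind_rows(rows)
  if (min_gain == 0) {
    best_n <- results$n[which.max(results$log_bf_vs_null)] # ties -> smaller N
  }
  results$selected <- results$n == best_n
  structure(
    list(best_n = best_n, results = results,
         chains = if (keep_chains) chains else NULL,
         prior = prior, config = config, delta = delta, min_gain = min_gain),
    class = "cnv_scan"
  )
}

#' @export
print.cnv_scan <- function(x, ...) {
  cat(sprintf("<cnv_scan> best N = %d\n", x$best_n))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.cnv_scan <- function(x, ...) {
  x$results[, c("n", "log_evidence", "log_bf_vs_null", "selected")]
}

#' @export
glance.cnv_scan <- function(x, ...) {
  tibble::tibble(
    best_n = x$best_n,
    log_bf_best = max(x$results$log_bf_vs_null),
    n_models = nrow(x$results),
    delta = x$delta
  )
}

#' Write a model-scan report
#'
#' Writes the per-model comparison table (`n`, `log_evidence`,
#' `log_bf_vs_null`, `selected`) as TSV, or as JSON together with the
#' selected model, the evidence settings and the sampler seed.
#'
#' @param scan A `cnv_scan` from [select_n()].
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   TSV otherwise).
#' @return `path`, invisibly.
#' @export
write_model_scan <- function(scan, path) {
  res <- tidy(scan)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(
      best_n = scan$best_n,
      models = res,
      delta = scan$delta,
      min_gain = scan$min_gain,
      seed = if (is.null(scan$config$seed)) NA else scan$config$seed
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    readr::write_tsv(res, path, progress = FALSE)
  }
  invisible(path)
}

#' Best fitted chain of a model scan
#'
#' @param scan A `cnv_scan` from [select_n()] (run with `keep_chains = TRUE`).
#' @return The `cnv_chain` of the selected model.
#' @export
best_chain <- function(scan) {
  if (is.null(scan$chains)) rlang::abort("Scan was run with `keep_chains = FALSE`.")
  scan$chains[[as.character(scan$best_n)]]
}
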