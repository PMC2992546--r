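# Independent oracles used to validate the model arithmetic. These never call
# the package's own likelihood/scan code paths: spectra are built by direct
# assignment, likelihoods by stats::dnorm sums, conditionals by exhaustive
# enumeration, and amplitude marginals by numeric quadrature.

# Step spectrum by direct assignment from a segments data frame.
oracle_spectrum <- function(segments, m) {
  f <- numeric(m)
  for (i in seq_len(nrow(segments))) {
    f[segments$s[i]:(segments$s[i] + segments$w[i] - 1)] <- segments$a[i]
  }
  f
}

# Gaussian log-likelihood as a plain sum of normal log-densities.
oracle_loglik <- function(x, f, sigma2) {
  sum(stats::dnorm(x, mean = f, sd = sqrt(sigma2), log = TRUE))
}

# Exhaustive (s, w) conditional at a fixed amplitude: one naive O(M)
# likelihood evaluation per candidate pair.
oracle_sw_fixed_a <- function(x, a, sigma2, w_min, w_max,
                              others = data.frame(s = integer(), w = integer(),
                                                  a = double())) {
  m <- length(x)
  f_others <- oracle_spectrum(others, m)
  rows <- list()
  for (s in 1:m) {
    for (w in w_min:w_max) {
      e <- s + w - 1
      if (e > m) next
      if (nrow(others) &&
          any(s <= others$s + others$w - 1 & e >= others$s)) next
      f <- f_others
      f[s:e] <- a
      rows[[length(rows) + 1]] <-
        data.frame(s = s, w = w, loglik = oracle_loglik(x, f, sigma2))
    }
  }
  out <- do.call(rbind, rows)
  out$prob <- exp(out$loglik - max(out$loglik))
  out$prob <- out$prob / sum(out$prob)
  out
}

# Exhaustive (s, w) conditional with the amplitude integrated out by
# numeric quadrature against its N(tau, kappa^2) prior.
oracle_sw_marginal <- function(x, sigma2, tau, kappa, w_min, w_max) {
  m <- length(x)
  rows <- list()
  for (s in 1:m) {
    for (w in w_min:w_max) {
      e <- s + w - 1
      if (e > m) next
      ref <- oracle_loglik(x, numeric(m), sigma2) # scale factor, cancels
      integrand <- function(a) {
        vapply(a, function(ai) {
          f <- numeric(m)
          f[s:e] <- ai
          exp(oracle_loglik(x, f, sigma2) - ref) *
            stats::dnorm(ai, tau, kappa)
        }, numeric(1))
      }
      val <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value
      rows[[length(rows) + 1]] <- data.frame(s = s, w = w, weight = val)
    }
  }
  out <- do.call(rbind, rows)
  out$prob <- out$weight / sum(out$weight)
  out
}

# Total variation distance between an empirical (s, w) table and exact probs.
tv_distance <- function(emp_s, emp_w, exact) {
  key <- paste(exact$s, exact$w)
  emp <- table(paste(emp_s, emp_w)) / length(emp_s)
  p_emp <- as.numeric(emp[key])
  p_emp[is.na(p_emp)] <- 0
  extra <- sum(emp[!(names(emp) %in% key)])
  (sum(abs(p_emp - exact$prob)) + extra) / 2
}

# Closed-form log marginal likelihood of the null (flat-spectrum) model with
# an IG(alpha, beta) prior on the noise variance:
# p(D) = (2 pi)^(-M/2) * beta^alpha / Gamma(alpha)
#        * Gamma(alpha + M/2) / (beta + S/2)^(alpha + M/2),  S = sum(x^2).
oracle_null_log_marginal <- function(x, alpha = 1, beta = 1) {
  m <- length(x)
  s <- sum(x^2)
  -(m / 2) * log(2 * pi) + alpha * log(beta) - lgamma(alpha) +
    lgamma(alpha + m / 2) - (alpha + m / 2) * log(beta + s / 2)
}

# Naive ROC enumeration: for each threshold call score >= t positive.
oracle_roc <- function(scores, truth, thresholds) {
  do.call(rbind, lapply(thresholds, function(t) {
    call <- scores >= t
    data.frame(
      threshold = t,
      fpr = sum(call & !truth) / sum(!truth),
      tpr = sum(call & truth) / sum(truth)
    )
  }))
}
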