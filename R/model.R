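#' Model state: N step segments plus a noise variance
#'
#' The stepwise model describes the noiseless copy-number spectrum as a sum of
#' `N` rectangles ("segments"), each defined by a 1-based start probe index
#' `s`, a width in probes `w >= 1` and an amplitude `a` in signal units; the
#' observed signal is this spectrum plus iid Gaussian noise with variance
#' `sigma2`. Segments must be pairwise non-overlapping in probe index
#' (overlapping step levels are unidentifiable) and are kept sorted by `s`.
#'
#' @param segments A data frame with columns `s`, `w`, `a` (may have 0 rows),
#'   or `NULL` for the null (N = 0) model.
#' @param sigma2 Noise variance, > 0.
#'
#' @return An object of class `cnv_state`: a list with a `segments` tibble
#'   (sorted by `s`, with derived end column `e = s + w - 1`) and `sigma2`.
#' @examples
#' cnv_state(data.frame(s = 200, w = 50, a = 1.5), sigma2 = 0.4^2)
#' cnv_state(NULL, sigma2 = 1) # null model
#' @export
cnv_state <- function(segments = NULL, sigma2 = 1) {
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- tibble::tibble(s = integer(), w = integer(), a = double())
  }
  segments <- tibble::as_tibble(segments)[, c("s", "w", "a")]
  segments$s <- as.integer(segments$s)
  segments$w <- as.integer(segments$w)
  segments$a <- as.double(segments$a)
  if (any(segments$w < 1L)) rlang::abort("Segment widths must be >= 1 probe.")
  if (any(segments$s < 1L)) rlang::abort("Segment starts must be >= 1.")
  if (!is.numeric(sigma2) || length(sigma2) != 1 || is.na(sigma2) || sigma2 <= 0) {
    rlang::abort("`sigma2` must be a single positive number.")
  }
  segments <- segments[order(segments$s), , drop = FALSE]
  segments$e <- segments$s + segments$w - 1L
  if (nrow(segments) > 1 &&
      any(segments$s[-1] <= segments$e[-nrow(segments)])) {
    rlang::abort("Segments must be pairwise non-overlapping in probe index.")
  }
  structure(list(segments = segments, sigma2 = sigma2), class = "cnv_state")
}

#' @export
print.cnv_state <- function(x, ...) {
  cat(sprintf("<cnv_state> N = %d segment(s), sigma2 = %.6g\n",
              nrow(x$segments), x$sigma2))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

n_segments <- function(state) nrow(state$segments)

check_state_bounds <- function(state, m) {
  seg <- state$segments
  if (nrow(seg) && any(seg$e > m)) {
    rlang::abort(sprintf(
      "Segment runs past the end of the signal (e = %d > M = %d).",
      max(seg$e), m
    ))
  }
  invisible(state)
}

#' Prior settings for the stepwise CNV model
#'
#' Encodes the prior system of the model: uniform priors over segment start
#' and width (`1/M` each), a conjugate normal prior `N(tau, kappa^2)` on each
#' amplitude (or, for clean read-depth data, a finite discrete amplitude
#' support with multinomial masses), and an inverse-gamma `IG(alpha, beta)`
#' prior on the noise variance. `tau = 0`, `kappa = 100` make the amplitude
#' prior effectively flat around 0, and `alpha = beta = 1` is a weak variance
#' prior; parameter inference is insensitive to these for the data sizes the
#' model is used at.
#'
#' @param tau Amplitude prior mean (signal units). Default 0.
#' @param kappa Amplitude prior standard deviation, > 0. Default 100.
#' @param alpha,beta Inverse-gamma shape and scale for `sigma2`, > 0. Default 1, 1.
#' @param n_max Maximum number of CNVs considered during model selection.
#' @param w_min,w_max Width bounds (probes) for the discrete conditional scan.
#'   `w_min = 2` by default (a 1-probe step is indistinguishable from noise);
#'   `w_max = NULL` means `min(M, 500)` at fit time, bounding the O(M w) scan.
#' @param informative_windows Optional data frame with columns `j` (segment
#'   index), `s_lo`, `s_hi`, `w_lo`, `w_hi`: restricts segment `j`'s start to
#'   `[s_lo, s_hi]` and width to `[w_lo, w_hi]`, with uniform mass inside and
#'   zero prior mass (log prior `-Inf`) outside.
#' @param amplitude_levels Optional data frame with columns `a` (level, signal
#'   units) and `prob` (prior mass, normalized internally). When set, the
#'   discrete multinomial amplitude prior replaces the normal prior for all
#'   segments; see [discrete_amplitude_prior()].
#'
#' @return An object of class `cnv_prior` (a list of the settings above).
#' @examples
#' cnv_prior()
#' cnv_prior(amplitude_levels = discrete_amplitude_prior(20))
#' @export
cnv_prior <- function(tau = 0, kappa = 100, alpha = 1, beta = 1,
                      n_max = 5L, w_min = 2L, w_max = NULL,
                      informative_windows = NULL, amplitude_levels = NULL) {
  stopifnot(kappa > 0, alpha > 0, beta > 0, n_max >= 1, w_min >= 1)
  if (!is.null(w_max) && w_max < w_min) {
    rlang::abort("`w_max` must be >= `w_min`.")
  }
  if (!is.null(informative_windows)) {
    informative_windows <- tibble::as_tibble(informative_windows)
    need <- c("j", "s_lo", "s_hi", "w_lo", "w_hi")
    if (!all(need %in% names(informative_windows))) {
      rlang::abort("`informative_windows` needs columns j, s_lo, s_hi, w_lo, w_hi.")
    }
  }
  if (!is.null(amplitude_levels)) {
    amplitude_levels <- tibble::as_tibble(amplitude_levels)
    if (!all(c("a", "prob") %in% names(amplitude_levels))) {
      rlang::abort("`amplitude_levels` needs columns `a` and `prob`.")
    }
    if (any(amplitude_levels$prob <= 0)) {
      rlang::abort("Amplitude level prior masses must be positive.")
    }
    amplitude_levels$prob <- amplitude_levels$prob / sum(amplitude_levels$prob)
  }
  structure(
    list(
      tau = tau, kappa = kappa, alpha = alpha, beta = beta,
      n_max = as.integer(n_max), w_min = as.integer(w_min),
      w_max = if (is.null(w_max)) NULL else as.integer(w_max),
      informative_windows = informative_windows,
      amplitude_levels = amplitude_levels
    ),
    class = "cnv_prior"
  )
}

effective_w_max <- function(prior, m) {
  if (is.null(prior$w_max)) min(m, 500L) else min(prior$w_max, m)
}

# Informative start/width window for segment j, or NULL.
window_for <- function(prior, j) {
  iw <- prior$informative_windows
  if (is.null(iw)) return(NULL)
  row <- iw[iw$j == j, , drop = FALSE]
  if (nrow(row) == 0) NULL else as.list(row[1, ])
}

#' Evaluate the step spectrum of a model state
#'
#' The noiseless spectrum takes value `a_j` at probes `s_j .. s_j + w_j - 1`
#' (1-based, inclusive) and 0 outside all segments.
#'
#' @param state A [cnv_state()].
#' @param m Signal length M (number of probes).
#' @return A numeric vector of length `m`.
#' @examples
#' step_spectrum(cnv_state(data.frame(s = 4, w = 2, a = -1), 1), m = 6)
#' @export
step_spectrum <- function(state, m) {
  m <- as.integer(m)
  stopifnot(m >= 1)
  check_state_bounds(state, m)
  f <- numeric(m)
  seg <- state$segments
  for (i in seq_len(nrow(seg))) {
    f[seg$s[i]:seg$e[i]] <- seg$a[i]
  }
  f
}

# Residual sum of squares about the fitted spectrum, via per-segment prefix
# sums: RSS = sum(x^2) + sum_j (w_j a_j^2 - 2 a_j sum_{k in j} x_k).
# O(M + N) instead of O(M) per candidate inside the sampler's scans.
rss_state <- function(x, state) {
  seg <- state$segments
  rss <- sum(x * x)
  if (nrow(seg)) {
    cx <- c(0, cumsum(x))
    sums <- cx[seg$e + 1L] - cx[seg$s]
    rss <- rss + sum(seg$w * seg$a^2 - 2 * seg$a * sums)
  }
  rss
}

#' Gaussian log-likelihood of a GCN signal under a model state
#'
#' `log p(D | theta) = -psi^2/2 - (M/2) log(2 pi sigma^2)` with
#' `psi^2 = sum_k (x_k - f_k)^2 / sigma^2`, where `f` is the step spectrum.
#'
#' @inheritParams step_spectrum
#' @param data A GCN tibble ([gcn_signal()]).
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(data, state) {
  data <- validate_gcn(data)
  m <- nrow(data)
  check_state_bounds(state, m)
  if (state$sigma2 <= 0) rlang::abort("`sigma2` must be positive.")
  rss <- rss_state(data$value, state)
  -rss / (2 * state$sigma2) - (m / 2) * log(2 * pi * state$sigma2)
}

# Inverse-gamma log-density.
dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Log prior density of a model state
#'
#' Sums the log prior terms for a fixed number of segments N: `-N log(M^2)`
#' for the two uniform factors per segment (replaced by the informative-window
#' uniform masses where such windows are declared), the normal (or discrete
#' multinomial) log-density of each amplitude, and the inverse-gamma
#' log-density of the noise variance. The constant `p(N) = 1/N_max` is dropped
#' (N is fixed within a fit). States outside an informative window's support,
#' or amplitudes off the discrete support, return `-Inf`.
#'
#' @inheritParams step_spectrum
#' @param prior A [cnv_prior()].
#' @return The log prior density (scalar, possibly `-Inf`).
#' @export
log_prior <- function(state, prior, m) {
  seg <- state$segments
  lp <- dinvgamma_log(state$sigma2, prior$alpha, prior$beta)
  for (j in seq_len(nrow(seg))) {
    win <- window_for(prior, j)
    if (is.null(win)) {
      lp <- lp - 2 * log(m)
    } else {
      if (seg$s[j] < win$s_lo || seg$s[j] > win$s_hi ||
          seg$w[j] < win$w_lo || seg$w[j] > win$w_hi) {
        return(-Inf)
      }
      lp <- lp - log(win$s_hi - win$s_lo + 1) - log(win$w_hi - win$w_lo + 1)
    }
    if (is.null(prior$amplitude_levels)) {
      lp <- lp + stats::dnorm(seg$a[j], prior$tau, prior$kappa, log = TRUE)
    } else {
      hit <- which(abs(prior$amplitude_levels$a - seg$a[j]) < 1e-12)
      if (length(hit) == 0) return(-Inf)
      lp <- lp + log(prior$amplitude_levels$prob[hit[1]])
    }
  }
  lp
}

#' Unnormalized log posterior of a model state
#'
#' `log_likelihood(data, state) + log_prior(state, prior, M)`, i.e. the log
#' posterior up to the additive constant `-log p(D)`.
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return The unnormalized log posterior (scalar, possibly `-Inf`).
#' @export
log_posterior <- function(data, state, prior) {
  data <- validate_gcn(data)
  lp <- log_prior(state, prior, nrow(data))
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(data, state)
}
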