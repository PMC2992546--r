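#' Simulate a GCN signal from a known model state
#'
#' Generates `x_k = f_k + eps_k` with `eps_k ~ N(0, sigma2)` iid, where `f`
#' is the step spectrum of `state`; locations are the probe indices `1..m`.
#'
#' @param state The generating [cnv_state()] (segments plus noise variance).
#' @param m Number of probes M.
#' @param seed Optional RNG seed for reproducible data.
#' @param chrom Optional chromosome label for the output table.
#' @return A GCN tibble ([gcn_signal()]).
#' @examples
#' simulate_gcn(cnv_state(data.frame(s = 200, w = 50, a = 1.5), 0.4^2),
#'              m = 500, seed = 1)
#' @export
simulate_gcn <- function(state, m, seed = NULL, chrom = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- step_spectrum(state, m)
  gcn_signal(seq_len(m), f + stats::rnorm(m, 0, sqrt(state$sigma2)), chrom = chrom)
}

#' Named simulation presets
#'
#' Standard generating conditions used throughout the package's tests and
#' examples:
#' \describe{
#'   \item{`one_cnv`}{M = 500, one segment (s = 200, w = 50, a = 1.5),
#'     noise s.d. 0.4 — a single clear gain in moderately noisy array data.}
#'   \item{`four_cnv`}{M = 1000, segments (100, 30, 0.7), (200, 20, -0.3),
#'     (400, 80, 1.5), (600, 90, -0.6), noise s.d. 0.1 — mixed gains and
#'     losses of varying prominence, for model-selection exercises.}
#'   \item{`two_cnv`}{M = 700, segments (100, 20, 2) and (600, 20, 2),
#'     noise s.d. 0.4 — two widely separated high-amplitude gains whose
#'     posterior surface is strongly multimodal in (s1, s2).}
#' }
#'
#' @param name Preset name.
#' @return A list with the generating `state` (a [cnv_state()]) and `m`.
#' @export
cnv_preset <- function(name = c("one_cnv", "four_cnv", "two_cnv")) {
  name <- match.arg(name)
  switch(name,
    one_cnv = list(
      state = cnv_state(data.frame(s = 200, w = 50, a = 1.5), sigma2 = 0.4^2),
      m = 500L
    ),
    four_cnv = list(
      state = cnv_state(
        data.frame(s = c(100, 200, 400, 600), w = c(30, 20, 80, 90),
                   a = c(0.7, -0.3, 1.5, -0.6)),
        sigma2 = 0.1^2
      ),
      m = 1000L
    ),
    two_cnv = list(
      state = cnv_state(data.frame(s = c(100, 600), w = c(20, 20), a = c(2, 2)),
                        sigma2 = 0.4^2),
      m = 700L
    )
  )
}

#' Simulate a single-CNV benchmark signal at a given signal-to-noise ratio
#'
#' One centered CNV of `width` probes with amplitude `snr * sigma`
#' (`sigma = 1` canonical), plus per-probe truth labels for TPR/FPR scoring —
#' the layout of the classic aCGH segmentation benchmark's hardest setting
#' (width 40 probes, SNR 1).
#'
#' @param width CNV width in probes.
#' @param snr Signal-to-noise ratio a / sigma, > 0.
#' @param m Number of probes (default 100).
#' @param sigma Noise s.d. (default 1).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `location`, `value`, `truth` (logical
#'   per-probe CNV labels).
#' @export
simulate_single_block <- function(width = 40, snr = 1, m = 100, sigma = 1,
                                  seed = NULL) {
  stopifnot(snr > 0, width >= 1, width <= m)
  s <- as.integer(floor((m - width) / 2) + 1L)
  state <- cnv_state(data.frame(s = s, w = width, a = snr * sigma),
                     sigma2 = sigma^2)
  data <- simulate_gcn(state, m, seed = seed)
  data$truth <- seq_len(m) >= s & seq_len(m) <= s + width - 1L
  data
}

#' Per-probe ROC curve
#'
#' Computes (FPR, TPR) points as the detection threshold on a per-probe
#' score — e.g. the posterior inclusion frequency from
#' [inclusion_frequency()] — is varied. A probe is called positive when its
#' score is `>=` the threshold.
#'
#' @param scores Per-probe scores (higher = more CNV-like).
#' @param truth Logical per-probe truth labels; must contain at least one
#'   `TRUE` and one `FALSE`.
#' @param thresholds Optional threshold vector; defaults to all distinct
#'   score values plus `Inf`.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, sorted by
#'   ascending `fpr` (TPR is then monotone non-decreasing).
#' @export
roc_curve <- function(scores, truth, thresholds = NULL) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (!any(truth)) rlang::abort("TPR undefined: truth mask has no positives.")
  if (all(truth)) rlang::abort("FPR undefined: truth mask has no negatives.")
  if (is.null(thresholds)) thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sum(truth)
  neg <- sum(!truth)
  out <- purrr::map_dfr(thresholds, function(th) {
    call <- scores >= th
    tibble::tibble(
      threshold = th,
      fpr = sum(call & !truth) / neg,
      tpr = sum(call & truth) / pos
    )
  })
  dplyr::arrange(out, .data$fpr, .data$tpr)
}
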