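#' Plot a fitted chain
#'
#' `type = "fit"` overlays the data with the posterior step function (modal
#' breakpoints, posterior-mean amplitudes) and shaded amplitude credible
#' intervals; `type = "trace"` shows per-parameter traces over iterations;
#' `type = "posterior"` shows post-burn-in marginal histograms.
#'
#' @param object A `cnv_chain` from [run_gibbs()].
#' @param type One of `"fit"`, `"trace"`, `"posterior"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_chain <- function(object, type = c("fit", "trace", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "fit") {
    est <- tidy(object)
    segs <- purrr::map_dfr(seq_len(object$n_cnv), function(j) {
      pick <- function(par, col = "estimate") est[[col]][est$term == paste0(par, "_", j)]
      tibble::tibble(
        x_from = object$data$location[pick("s")],
        x_to = object$data$location[pick("e")],
        a = pick("a"),
        a_lo = pick("a", "conf.low"), a_hi = pick("a", "conf.high")
      )
    })
    p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$location, y = .data$value)) +
      ggplot2::geom_point(size = 0.4, alpha = 0.5) +
      ggplot2::labs(x = "location", y = "signal") +
      ggplot2::theme_minimal()
    if (nrow(segs)) {
      p <- p +
        ggplot2::geom_rect(
          data = segs,
          ggplot2::aes(xmin = .data$x_from, xmax = .data$x_to,
                       ymin = .data$a_lo, ymax = .data$a_hi),
          inherit.aes = FALSE, fill = "gold", alpha = 0.5
        ) +
        ggplot2::geom_segment(
          data = segs,
          ggplot2::aes(x = .data$x_from, xend = .data$x_to,
                       y = .data$a, yend = .data$a),
          inherit.aes = FALSE, linewidth = 0.8, colour = "black"
        )
    }
    return(p)
  }
  long <- chain_long(object)
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::theme_minimal()
  } else {
    long <- long[long$iteration > object$config$burn_in, , drop = FALSE]
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::theme_minimal()
  }
}

chain_long <- function(chain) {
  parts <- list(
    tibble::tibble(iteration = chain$iterations$iteration, term = "sigma",
                   value = sqrt(chain$iterations$sigma2))
  )
  d <- chain$draws
  if (nrow(d)) {
    for (par in c("s", "w", "a")) {
      parts[[length(parts) + 1L]] <- tibble::tibble(
        iteration = d$iteration,
        term = paste0(par, "_", d$segment),
        value = as.double(d[[par]])
      )
    }
  }
  dplyr::bind_rows(parts)
}

#' Plot a model-selection scan
#'
#' Log Bayes factor against the null model for each candidate number of
#' CNVs, the selected model highlighted.
#'
#' @param object A `cnv_scan` from [select_n()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_scan <- function(object, ...) {
  res <- tidy(object)
  ggplot2::ggplot(res, ggplot2::aes(x = factor(.data$n), y = .data$log_bf_vs_null,
                                    fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60")) +
    ggplot2::labs(x = "number of CNVs (N)", y = "ln Bayes factor vs null") +
    ggplot2::theme_minimal()
}

#' Plot a coverage-downsampling experiment
#'
#' Mean posterior standard deviation of the start and end breakpoints
#' (window units) against sequencing depth.
#'
#' @param object A `cnv_downsample` from [downsample_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_downsample <- function(object, ...) {
  res <- tidyr::pivot_longer(tidy(object), c("mean_sd_s", "mean_sd_e"),
                             names_to = "breakpoint", values_to = "sd")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$coverage, y = .data$sd,
                                    colour = .data$breakpoint)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "coverage (x)", y = "breakpoint s.d. (windows)") +
    ggplot2::theme_minimal()
}
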