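#' Plan chunked processing of a long signal
#'
#' MCMC cost grows quickly with signal length, so long chromosomes are
#' processed as chunks of consecutive features (default 1000), optionally
#' extended by an overlap on each side so CNVs straddling a boundary are seen
#' whole by at least one chunk. Chunk boundaries never cross chromosomes, and
#' at `overlap = 0` the chunk cores tile the features exactly once.
#'
#' @param data A GCN tibble.
#' @param chunk_size Chunk core size in features (default 1000).
#' @param overlap Extension in features on each side (default 0; a value
#'   around twice the maximum expected CNV width avoids boundary splitting).
#' @return A tibble with one row per chunk: `chunk_id`, `chrom`,
#'   `core_from`, `core_to`, `from`, `to` (all 1-based indices within the
#'   chromosome's sorted features).
#' @export
chunk_plan <- function(data, chunk_size = 1000L, overlap = 0L) {
  data <- validate_gcn(data)
  chroms <- if ("chrom" %in% names(data)) data$chrom else rep("chr1", nrow(data))
  purrr::imap_dfr(split(seq_len(nrow(data)), chroms)[unique(chroms)],
    function(idx, chrom) {
      m <- length(idx)
      starts <- seq(1L, m, by = chunk_size)
      tibble::tibble(
        chrom = chrom,
        core_from = starts,
        core_to = pmin(starts + chunk_size - 1L, m),
        from = pmax(starts - overlap, 1L),
        to = pmin(starts + chunk_size - 1L + overlap, m)
      )
    }) |>
    dplyr::mutate(chunk_id = dplyr::row_number(), .before = 1)
}

# Calls straddle chunk overlap zones -> deduplicate by reciprocal index
# overlap, keeping the higher-confidence (|amplitude|/sd) call.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Merge segment calls from overlapping chunks
#'
#' Within each chromosome, calls from different chunks with reciprocal probe
#' index overlap >= 50% are treated as duplicates of one underlying CNV; the
#' call with the larger posterior amplitude confidence `|estimate| / sd` is
#' kept (a zero sd counts as infinite confidence). Non-overlapping calls
#' pass through unchanged.
#'
#' @param calls A segment-call tibble as produced by [run_cnv_pipeline()]
#'   (columns `chrom`, `s_index`, `e_index`, `a_estimate`, `a_sd`, ...).
#' @param min_reciprocal Reciprocal overlap threshold (default 0.5).
#' @return The deduplicated call tibble.
#' @export
merge_chunk_calls <- function(calls, min_reciprocal = 0.5) {
  if (nrow(calls) < 2) return(calls)
  conf <- abs(calls$a_estimate) / ifelse(calls$a_sd > 0, calls$a_sd, .Machine$double.eps)
  keep <- rep(TRUE, nrow(calls))
  ord <- order(calls$chrom, calls$s_index)
  for (ii in seq_along(ord)[-1]) {
    i <- ord[ii]
    for (jj in seq_len(ii - 1)) {
      j <- ord[jj]
      if (!keep[j] || calls$chrom[i] != calls$chrom[j]) next
      ro <- reciprocal_overlap(calls$s_index[i], calls$e_index[i],
                               calls$s_index[j], calls$e_index[j])
      if (ro >= min_reciprocal) {
        if (conf[i] > conf[j]) keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
  }
  calls[keep, , drop = FALSE]
}

# Turn the best chain of one chunk into call rows with global indices and
# 0-based half-open genomic coordinates.
chunk_calls <- function(chain, data_slice, offset, chrom, chunk_id, config_hash) {
  if (chain$n_cnv == 0) return(NULL)
  est <- tidy(chain)
  locs <- data_slice$location
  purrr::map_dfr(seq_len(chain$n_cnv), function(j) {
    pick <- function(par, col = "estimate") est[[col]][est$term == paste0(par, "_", j)]
    s_idx <- pick("s"); e_idx <- pick("e")
    tibble::tibble(
      chrom = chrom,
      start = locs[s_idx] - 1, # 1-based bp -> 0-based half-open BED
      end = locs[e_idx],
      s_index = s_idx + offset, e_index = e_idx + offset,
      s_sd = pick("s", "std.error"), e_sd = pick("e", "std.error"),
      s_conf_low = pick("s", "conf.low") + offset,
      s_conf_high = pick("s", "conf.high") + offset,
      e_conf_low = pick("e", "conf.low") + offset,
      e_conf_high = pick("e", "conf.high") + offset,
      a_estimate = pick("a"), a_sd = pick("a", "std.error"),
      a_conf_low = pick("a", "conf.low"), a_conf_high = pick("a", "conf.high"),
      n_selected = chain$n_cnv,
      chunk_id = chunk_id,
      seed = if (is.null(chain$config$seed)) NA_integer_ else chain$config$seed,
      config_hash = config_hash
    )
  })
}

#' Run the full CNV-calling pipeline on a GCN table
#'
#' Sorts features by genomic location within each chromosome (duplicate
#' locations are an error), splits them into chunks per [chunk_plan()], runs
#' Bayes-factor model selection ([select_n()]) on every chunk, converts the
#' selected model's posterior summaries into segment calls with genomic
#' coordinates and credible intervals, and merges duplicate calls from
#' chunk-overlap zones.
#'
#' @param data A GCN tibble or a path to a GCN table ([read_gcn_table()]).
#' @param prior A [cnv_prior()].
#' @param config A [sampler_config()]; the seed is propagated (offset per
#'   chunk and per model) so reruns are identical.
#' @param chunk_size,overlap See [chunk_plan()].
#' @param n_max Largest per-chunk model (default `prior$n_max`).
#' @return An object of class `cnv_pipeline`: list with `calls` (segment-call
#'   tibble), `model_scan` (per-chunk model comparison table), `plan`,
#'   `seed`, and `config_hash`.
#' @export
run_cnv_pipeline <- function(data, prior = cnv_prior(),
                             config = sampler_config(),
                             chunk_size = 1000L, overlap = 0L,
                             n_max = prior$n_max) {
  if (is.character(data)) data <- read_gcn_table(data)
  data <- tibble::as_tibble(data)
  if (!"chrom" %in% names(data)) {
    data <- tibble::add_column(data, chrom = "chr1", .before = 1)
  }
  dup <- data[duplicated(data[, c("chrom", "location")]), ]
  if (nrow(dup)) {
    rlang::abort(c(
      "Duplicate feature locations cannot be ordered:",
      utils::capture.output(print(utils::head(dup, 5)))
    ))
  }
  data <- dplyr::arrange(data, .data$chrom, .data$location)
  data <- validate_gcn(data)
  plan <- chunk_plan(data, chunk_size, overlap)
  config_hash <- rlang::hash(list(prior = unclass(prior), config = unclass(config),
                                  chunk_size = chunk_size, overlap = overlap))
  calls <- list()
  scans <- list()
  for (i in seq_len(nrow(plan))) {
    rows <- which((if ("chrom" %in% names(data)) data$chrom else "chr1") == plan$chrom[i])
    slice_idx <- rows[plan$from[i]:plan$to[i]]
    slice <- data[slice_idx, , drop = FALSE]
    slice_gcn <- gcn_signal(seq_len(nrow(slice)), slice$value)
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- config$seed + 100L * i
    scan <- select_n(slice_gcn, prior, cfg, n_max = n_max)
    scans[[i]] <- dplyr::mutate(tidy(scan), chunk_id = i, .before = 1)
    calls[[i]] <- chunk_calls(best_chain(scan), slice, offset = plan$from[i] - 1L,
                              chrom = plan$chrom[i], chunk_id = i,
                              config_hash = config_hash)
  }
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls)) calls <- merge_chunk_calls(calls)
  structure(
    list(calls = calls, model_scan = dplyr::bind_rows(scans), plan = plan,
         seed = if (is.null(config$seed)) NA_integer_ else config$seed,
         config_hash = config_hash),
    class = "cnv_pipeline"
  )
}

#' @export
print.cnv_pipeline <- function(x, ...) {
  cat(sprintf("<cnv_pipeline> %d call(s) over %d chunk(s); seed %s, config %s\n",
              nrow(x$calls), nrow(x$plan), x$seed, x$config_hash))
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}

#' Writers for pipeline and chain outputs
#'
#' `write_calls_bed()` writes segment calls as BED (0-based half-open;
#' name `cnv_<i>`, score = amplitude estimate). `write_calls_tsv()` writes
#' the full call table, keeping 1-based inclusive probe indices alongside
#' the genomic coordinates. `write_chain_tsv()` writes the chain trace
#' (iteration, per-parameter columns, log-likelihood, log-posterior).
#' `write_summary_json()` writes a fit's point estimates, sds and credible
#' intervals plus seed and config hash as JSON.
#'
#' @param x A `cnv_pipeline` (calls writers) or `cnv_chain` (trace/summary
#'   writers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(x, path) {
  calls <- if (inherits(x, "cnv_pipeline")) x$calls else x
  bed <- tibble::tibble(
    chrom = calls$chrom,
    start = format(calls$start, scientific = FALSE, trim = TRUE),
    end = format(calls$end, scientific = FALSE, trim = TRUE),
    name = paste0("cnv_", seq_len(nrow(calls))),
    score = calls$a_estimate
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
write_calls_tsv <- function(x, path) {
  calls <- if (inherits(x, "cnv_pipeline")) x$calls else x
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
write_chain_tsv <- function(x, path) {
  wide <- x$iterations
  if (x$n_cnv > 0) {
    d <- tidyr::pivot_wider(
      x$draws[, c("iteration", "segment", "s", "w", "a")],
      names_from = "segment", values_from = c("s", "w", "a"),
      names_sep = "_"
    )
    wide <- dplyr::left_join(d, wide, by = "iteration")
  }
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
write_summary_json <- function(x, path) {
  est <- tidy(x)
  payload <- list(
    n_cnv = x$n_cnv,
    estimates = est,
    seed = if (is.null(x$config$seed)) NA else x$config$seed,
    config_hash = rlang::hash(list(prior = unclass(x$prior),
                                   config = unclass(x$config))),
    n_iter = x$config$n_iter,
    burn_in = x$config$burn_in
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
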