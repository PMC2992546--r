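#' Read mapped-read start positions
#'
#' Accepts either BED3 (`chrom`, `start`, `end`) or a two-column
#' (`chrom`, `start`) tab-delimited file; only the chromosome and the 0-based
#' read start are used downstream (reads are assigned to depth windows by
#' their start coordinate).
#'
#' @param path File path.
#' @return A tibble with columns `chrom`, `start`, sorted by chromosome and
#'   start.
#' @export
read_read_positions <- function(path) {
  reads <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           col_types = readr::cols(), progress = FALSE)
  if (ncol(reads) < 2) rlang::abort("Read-position input needs >= 2 columns.")
  out <- tibble::tibble(chrom = as.character(reads[[1]]),
                        start = as.double(reads[[2]]))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Count reads in non-overlapping windows
#'
#' Tiles `region` with consecutive `window_bp`-wide windows and assigns each
#' read to exactly one window by its start coordinate, so read totals are
#' conserved: the counts sum to the number of reads whose start lies in the
#' region.
#'
#' @param reads A data frame with columns `chrom` and `start` (0-based bp),
#'   one chromosome at a time.
#' @param window_bp Window size in bp (default 200).
#' @param region Length-2 numeric `c(start, end)`, 0-based half-open;
#'   defaults to `[0, ceiling(max(start) + 1 in windows))`.
#' @return A depth tibble with columns `chrom`, `window_start` (0-based bp)
#'   and `count`, plus a `window_bp` attribute.
#' @export
window_counts <- function(reads, window_bp = 200, region = NULL) {
  stopifnot(window_bp >= 1)
  reads <- tibble::as_tibble(reads)
  if (!all(c("chrom", "start") %in% names(reads))) {
    rlang::abort("`reads` needs `chrom` and `start` columns.")
  }
  if (length(unique(reads$chrom)) > 1) {
    rlang::abort("`window_counts()` processes one chromosome at a time.")
  }
  if (is.null(region)) {
    hi <- if (nrow(reads)) max(reads$start) + 1 else window_bp
    region <- c(0, ceiling(hi / window_bp) * window_bp)
  }
  if (region[2] <= region[1]) rlang::abort("Empty region.")
  n_win <- ceiling((region[2] - region[1]) / window_bp)
  keep <- reads$start >= region[1] & reads$start < region[2]
  idx <- floor((reads$start[keep] - region[1]) / window_bp) + 1L
  counts <- tabulate(idx, nbins = n_win)
  out <- tibble::tibble(
    chrom = if (nrow(reads)) reads$chrom[1] else "chr1",
    window_start = region[1] + (seq_len(n_win) - 1L) * window_bp,
    count = as.double(counts)
  )
  attr(out, "window_bp") <- window_bp
  out
}

#' Center a depth signal into a GCN signal
#'
#' Subtracts the global mean count, producing an array-like signal whose
#' baseline (normal copy number) sits at 0; the locations are the window
#' start coordinates. A homozygous deletion then appears as a step near
#' minus the mean count.
#'
#' @param depth A depth tibble from [window_counts()].
#' @return A GCN tibble ([gcn_signal()]).
#' @export
center_depth <- function(depth) {
  if (nrow(depth) < 1) rlang::abort("Need at least one window.")
  gcn_signal(depth$window_start, depth$count - mean(depth$count),
             chrom = depth$chrom)
}

#' Discrete amplitude prior for clean read-depth data
#'
#' In high-quality read-depth data the amplitude of a CNV takes one of a few
#' discrete values set by the copy-number change: with haploid mean depth
#' `c`, a heterozygous deletion shifts the centered count by `-c`, a
#' single-copy gain by `+c` and a two-copy gain by `+2c`. This prior places
#' multinomial mass on exactly that level set.
#'
#' @param c Haploid mean depth (counts per window), > 0.
#' @param prob Prior masses for the levels `(-c, c, 2c)`; default uniform.
#' @return A tibble with columns `a` and `prob`, for use as
#'   `cnv_prior(amplitude_levels = ...)`.
#' @export
discrete_amplitude_prior <- function(c, prob = c(1, 1, 1) / 3) {
  stopifnot(c > 0, length(prob) == 3, all(prob > 0))
  tibble::tibble(a = c(-c, c, 2 * c), prob = prob / sum(prob))
}

#' Simulate mapped-read start positions over a region with one deletion
#'
#' Reads start over the region at a rate set by `coverage` (total read count
#' ~ Poisson(coverage * region_bp / read_len)); reads whose start falls
#' inside `deletion` are retained with probability `copy_ratio`
#' (0 = homozygous deletion, 0.5 = heterozygous).
#'
#' With `dispersion = 0` the read rate is uniform, producing ideal Poisson
#' window counts. Real short-read depth is overdispersed by mappability and
#' GC structure; `dispersion > 0` emulates this by modulating the local read
#' rate with a fixed (per-genome) gamma multiplier of mean 1 and coefficient
#' of variation `dispersion` on `tile_bp` tiles, which makes window counts
#' negative-binomial-like while conserving the total read count.
#'
#' @param region_bp Region length in bp.
#' @param coverage Mean sequencing depth (x) outside the deletion.
#' @param read_len Read length in bp (default 50).
#' @param deletion Optional `c(start, end)` 0-based half-open deletion
#'   interval.
#' @param copy_ratio Retention probability inside the deletion (default 0).
#' @param dispersion Coefficient of variation of the local rate multiplier
#'   (default 0 = uniform rate).
#' @param tile_bp Tile size over which the rate multiplier is constant.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `chrom`, `start`, sorted.
#' @export
simulate_read_positions <- function(region_bp, coverage, read_len = 50,
                                    deletion = NULL, copy_ratio = 0,
                                    dispersion = 0, tile_bp = 200,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, coverage * region_bp / read_len)
  if (dispersion > 0) {
    n_tiles <- ceiling(region_bp / tile_bp)
    g <- stats::rgamma(n_tiles, shape = 1 / dispersion^2, rate = 1 / dispersion^2)
    tile <- sample.int(n_tiles, n, replace = TRUE, prob = g)
    starts <- floor((tile - 1) * tile_bp + stats::runif(n, 0, tile_bp))
    starts <- starts[starts < region_bp]
  } else {
    starts <- floor(stats::runif(n, 0, region_bp))
  }
  if (!is.null(deletion)) {
    inside <- starts >= deletion[1] & starts < deletion[2]
    drop <- inside & stats::runif(length(starts)) > copy_ratio
    starts <- starts[!drop]
  }
  tibble::tibble(chrom = "chr1", start = sort(starts))
}

#' Breakpoint uncertainty versus sequencing depth
#'
#' Emulates a coverage-titration experiment: for each depth fraction, mapped
#' reads are subsampled without replacement, the windowed and centered depth
#' signal is rebuilt, a one-CNV model is fitted by Gibbs sampling, and the
#' posterior standard deviations of the start and end breakpoints are
#' recorded in window-size units. Breakpoint uncertainty grows as coverage
#' falls, and detection eventually fails outright below roughly 1x.
#'
#' @param reads A tibble of read positions (`chrom`, `start`).
#' @param fractions Depth fractions in (0, 1] to subsample to.
#' @param window_bp Window size in bp (default 200).
#' @param read_len Read length in bp, used only to report coverage.
#' @param region Optional region `c(start, end)` passed to [window_counts()].
#' @param replicates Subsampling replicates per fraction (default 3).
#' @param truth Optional `c(start, end)` bp interval of the true CNV; when
#'   given, a detection rate (modal fitted segment achieving >= 50%
#'   reciprocal overlap with the truth) is reported.
#' @param prior,config Passed to [run_gibbs()] (N = 1).
#' @param seed RNG seed for the subsampling and the fits.
#' @return A `cnv_downsample` tibble: one row per `(fraction, replicate)`
#'   with `coverage`, `sd_s`, `sd_e` (window units) and `detected`, plus the
#'   per-fraction means via [tidy()].
#' @export
downsample_experiment <- function(reads, fractions, window_bp = 200,
                                  read_len = 50, region = NULL,
                                  replicates = 3, truth = NULL,
                                  prior = cnv_prior(), config = sampler_config(),
                                  seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  if (is.null(region)) {
    region <- c(0, ceiling((max(reads$start) + 1) / window_bp) * window_bp)
  }
  n_reads <- nrow(reads)
  region_bp <- region[2] - region[1]
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_keep <- max(1L, floor(f * n_reads))
    if (n_keep / (region_bp / window_bp) < 1) {
      rlang::warn(sprintf(
        "Fraction %.3g leaves < 1 read per window on average; estimates will be weak.", f
      ))
    }
    for (r in seq_len(replicates)) {
      set.seed(seed + 1000L * fi + r)
      sub <- reads[sort(sample.int(n_reads, n_keep)), , drop = FALSE]
      signal <- center_depth(window_counts(sub, window_bp, region))
      cfg <- config
      cfg$seed <- seed + 1000L * fi + r
      fit <- run_gibbs(signal, 1L, prior, cfg)
      est <- tidy(fit)
      sd_s <- est$std.error[est$term == "s_1"]
      sd_e <- est$std.error[est$term == "e_1"]
      detected <- NA
      if (!is.null(truth)) {
        s_hat <- est$estimate[est$term == "s_1"]
        e_hat <- est$estimate[est$term == "e_1"]
        # window index -> bp, half-open
        call_bp <- c(signal$location[s_hat], signal$location[e_hat] + window_bp)
        ov <- max(0, min(call_bp[2], truth[2]) - max(call_bp[1], truth[1]))
        detected <- ov >= 0.5 * (call_bp[2] - call_bp[1]) &&
          ov >= 0.5 * (truth[2] - truth[1])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fraction = f,
        coverage = n_keep * read_len / region_bp,
        replicate = r, sd_s = sd_s, sd_e = sd_e, detected = detected
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cnv_downsample", class(out))
  attr(out, "window_bp") <- window_bp
  out
}

#' @export
tidy.cnv_downsample <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$fraction),
    coverage = mean(.data$coverage),
    mean_sd_s = mean(.data$sd_s),
    mean_sd_e = mean(.data$sd_e),
    detection_rate = if (all(is.na(.data$detected))) NA_real_ else mean(.data$detected),
    .groups = "drop"
  )
}
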