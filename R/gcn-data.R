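#' Construct a genomic copy-number (GCN) signal table
#'
#' A GCN signal is the common tabular form of both array-CGH and read-depth
#' data: one row per probe or window, with a sorted genomic location and a
#' real-valued signal (a log2 intensity ratio, or a mean-centered read count).
#'
#' @param location Integer genomic coordinates (bp) or probe indices,
#'   strictly increasing within a chromosome.
#' @param value Finite numeric signal at each location.
#' @param chrom Optional chromosome label (length 1 or `length(location)`).
#'
#' @return A tibble with columns `chrom` (if given), `location`, `value`.
#' @examples
#' gcn_signal(1:5, c(0.1, -0.2, 1.4, 1.6, 0.0))
#' @export
gcn_signal <- function(location, value, chrom = NULL) {
  location <- as.double(location)
  value <- as.double(value)
  if (length(location) != length(value)) {
    rlang::abort("`location` and `value` must have the same length.")
  }
  out <- tibble::tibble(location = location, value = value)
  if (!is.null(chrom)) {
    out <- tibble::add_column(out, chrom = as.character(chrom), .before = 1)
  }
  validate_gcn(out)
}

#' @keywords internal
#' @noRd
validate_gcn <- function(data) {
  if (!is.data.frame(data)) {
    rlang::abort("A GCN signal must be a data frame.")
  }
  data <- tibble::as_tibble(data)
  if (!all(c("location", "value") %in% names(data))) {
    rlang::abort("A GCN signal needs `location` and `value` columns.")
  }
  if (nrow(data) < 1) {
    rlang::abort("A GCN signal needs at least one data point (M >= 1).")
  }
  if (anyNA(data$location) || anyNA(data$value) || !all(is.finite(data$value))) {
    rlang::abort("GCN locations and values must be finite and non-missing.")
  }
  split_by <- if ("chrom" %in% names(data)) data$chrom else rep(1L, nrow(data))
  ok <- tapply(data$location, split_by, function(g) all(diff(g) > 0))
  if (!all(unlist(ok))) {
    rlang::abort("GCN locations must be strictly increasing within a chromosome.")
  }
  data
}

#' Read and write GCN tables
#'
#' The on-disk GCN table is tab-delimited with columns `chrom`, `location`
#' (integer bp or probe index) and `value` (float); a header line is optional
#' on read and always written.
#'
#' @param path File path.
#' @param data A GCN tibble as returned by [gcn_signal()].
#' @return `read_gcn_table()` returns a validated GCN tibble;
#'   `write_gcn_table()` returns `data` invisibly.
#' @export
read_gcn_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("chrom|location|value|position", first, ignore.case = TRUE)
  cols <- readr::cols(
    chrom = readr::col_character(),
    location = readr::col_double(),
    value = readr::col_double()
  )
  data <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("chrom", "location", "value"),
    col_types = cols, progress = FALSE
  )
  names(data)[names(data) == "position"] <- "location"
  validate_gcn(data)
}

#' @rdname read_gcn_table
#' @export
write_gcn_table <- function(data, path) {
  data <- validate_gcn(data)
  if (!"chrom" %in% names(data)) {
    data <- tibble::add_column(data, chrom = "chr1", .before = 1)
  }
  readr::write_tsv(data[, c("chrom", "location", "value")], path, progress = FALSE)
  invisible(data)
}
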