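#' Read a long-format plate-reader table
#'
#' Parses the tidy kinetic-export dialect: comma-separated text with a
#' header and at least the columns `plate_id`, `well`, `time_h`, `od`
#' (extra columns are preserved as per-series metadata; a `blank` column,
#' when present, sets each series' baseline).  Rows may appear in any
#' order; one [od_series()] is returned per `(plate_id, well)` with times
#' sorted ascending.  Lines starting with `#` are stamp/comment lines and
#' are skipped.
#'
#' @param path Path to the delimited text file.
#' @return Named list of [od_series()] objects (`plate/well` names).
#' @export
read_plate_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  colClasses = "character", check.names = FALSE)
  required <- c("plate_id", "well", "time_h", "od")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_invalid("plate table schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(raw[[col]])))
    if (length(bad)) {
      stop_invalid("non-numeric `", col, "` at data row(s): ",
                   paste(head(bad, 5), collapse = ", "))
    }
    if (anyNA(v)) {
      stop_invalid("missing `", col, "` at data row(s): ",
                   paste(head(which(is.na(v)), 5), collapse = ", "))
    }
    v
  }
  time_h <- num("time_h"); od <- num("od")
  blank <- if ("blank" %in% names(raw)) num("blank") else NULL
  key <- paste(raw$plate_id, raw$well, sep = "/")
  if (anyDuplicated(paste(key, time_h))) {
    stop_invalid("duplicate (plate_id, well, time_h) rows in ", path)
  }
  extra <- setdiff(names(raw), c(required, "blank"))
  out <- lapply(split(seq_len(nrow(raw)), key), function(i) {
    o <- order(time_h[i]); i <- i[o]
    s <- od_series(times = time_h[i], od = od[i],
                   well_id = raw$well[i[1]], plate_id = raw$plate_id[i[1]],
                   blank = if (is.null(blank)) NULL else blank[i[1]])
    if (length(extra)) attr(s, "metadata") <- raw[i[1], extra, drop = FALSE]
    s
  })
  out[order(names(out))]
}

#' Write optical-density series as a long-format plate table
#'
#' Inverse of [read_plate_table()]: columns `plate_id`, `well`, `time_h`,
#' `od` (and `blank` when known), written with full double precision so a
#' write-read round trip is exact.
#'
#' @param series A single [od_series()] or a list of them.
#' @param path Output path.
#' @param stamp Optional character vector written as leading `#` comment
#'   lines (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(series, path, stamp = NULL) {
  if (inherits(series, "od_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    d <- data.frame(plate_id = s$plate_id %||% "plate1",
                    well = s$well_id, time_h = fmt_full(s$times),
                    od = fmt_full(s$od), stringsAsFactors = FALSE)
    if (!is.null(s$blank)) d$blank <- fmt_full(s$blank)
    d
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Full-precision decimal formatting (17 significant digits round-trips any
# double exactly).
#' @noRd
fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write a tidy records (or any tabular) result to delimited text
#'
#' Writes comma-separated text with a fixed, documented column order and an
#' optional leading `#` stamp line.  List columns (e.g. `well_rates`) are
#' dropped with a message; the tidy scalar columns are the stable contract.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param stamp Optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path, stamp = NULL) {
  is_list_col <- vapply(x, is.list, logical(1))
  if (any(is_list_col)) {
    message("dropping list column(s): ",
            paste(names(x)[is_list_col], collapse = ", "))
    x <- x[!is_list_col]
  }
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy records table written by [write_records()]
#'
#' @param path Path to the delimited text file.
#' @return Tibble.
#' @export
read_records <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             comment.char = "#"))
}

#' Convert a wide plate-reader matrix export to the long dialect
#'
#' Many microplate readers export one column per well and one row per
#' reading.  This reshapes such a table (a `time_h` column plus one column
#' per well) into the long `plate_id, well, time_h, od` layout consumed by
#' [read_plate_table()].
#'
#' @param wide Data frame with a `time_h` column; every other column is a
#'   well.
#' @param plate_id Plate label to attach.
#' @return Long-format tibble.
#' @export
wide_to_long_plate <- function(wide, plate_id = "plate1") {
  if (!"time_h" %in% names(wide)) stop_invalid("`wide` needs a `time_h` column")
  long <- tidyr::pivot_longer(tibble::as_tibble(wide), -"time_h",
                              names_to = "well", values_to = "od")
  tibble::tibble(plate_id = plate_id, well = long$well,
                 time_h = long$time_h, od = long$od)
}
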