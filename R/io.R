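#' Read a 6-parameter motion file
#'
#' Reads a whitespace- or tab-delimited text file with one row per frame and
#' six numeric columns. Default column order is
#' `dx dy dz phi theta psi` (translations mm, rotations radians); motion
#' dialects from other tools can be accommodated with `col_order`.
#'
#' @param path file path.
#' @param tr_seconds repetition time (s); supplied by the user, never inferred.
#' @param col_order character permutation of
#'   `c("dx","dy","dz","phi","theta","psi")` giving the on-disk column order.
#' @return a [motion_trace()].
#' @export
read_motion_trace <- function(path, tr_seconds,
                              col_order = c("dx", "dy", "dz", "phi", "theta", "psi")) {
  if (!file.exists(path)) stopf("motion file not found: %s", path)
  std <- c("dx", "dy", "dz", "phi", "theta", "psi")
  if (!setequal(col_order, std)) stopf("col_order must be a permutation of %s", paste(std, collapse = " "))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) stopf("motion file %s has %d data rows; need >= 2", path, length(lines))
  toks <- strsplit(trimws(lines), "[\t ]+")
  vals <- matrix(NA_real_, nrow = length(lines), ncol = 6)
  for (ln in seq_along(toks)) {
    tk <- toks[[ln]]
    if (length(tk) != 6)
      stopf("motion file %s line %d: expected 6 columns, found %d", path, ln, length(tk))
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stopf("motion file %s line %d: non-numeric token '%s' in column %d",
            path, ln, tk[bad], bad)
    }
    vals[ln, ] <- v
  }
  colnames(vals) <- col_order
  motion_trace(vals[, std, drop = FALSE], tr_seconds = tr_seconds)
}

#' Write a motion trace to a tab-delimited file
#' @param motion a [motion_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motion_trace <- function(motion, path) {
  write.table(format(motion$params, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ROI time-series TSV
#'
#' Expects a header row of ROI ids and a numeric body, frames x regions.
#' Column order is preserved.
#'
#' @param path file path.
#' @param tr_seconds repetition time (s).
#' @return a [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, tr_seconds = 3) {
  if (!file.exists(path)) stopf("time-series file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) < 2 || ncol(df) < 2) stopf("%s: need >= 2 frames and >= 2 ROIs", path)
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) || any(!nzchar(df[[j]]))) {
      bad <- which(is.na(v) | !nzchar(df[[j]]))[1]
      stopf("%s: missing or non-numeric value at data row %d, column %d ('%s')",
            path, bad, j, names(df)[j])
    }
    m[, j] <- v
  }
  roi_timeseries(m, roi_ids = names(df), tr_seconds = tr_seconds)
}

#' Write an ROI time-series TSV (header row of ROI ids, full precision)
#' @param ts a [roi_timeseries()] or plain matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  m <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  df <- as.data.frame(format(m, digits = 17, trim = TRUE, scientific = TRUE))
  names(df) <- colnames(m)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write any numeric table as TSV with a header
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a configuration file
#'
#' Accepts JSON (via jsonlite) or flat `key = value` text (one pair per line,
#' `#` comments allowed; values parsed as numeric where possible, comma lists
#' split). There is no YAML support in this environment.
#'
#' @param path config path ending in `.json` or anything else for flat-key.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("config line not 'key = value': %s", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Write a JSON report (auto-unboxed, full precision)
#' @param x list to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
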