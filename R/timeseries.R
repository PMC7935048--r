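#' Component time series for one subject
#'
#' Container for one subject's activity-domain data: a numeric matrix with one
#' row per time point (volume) and one column per component/network time
#' course, plus the sampling interval.
#'
#' @param values Numeric matrix, rows = time points, columns = components.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param component_ids Optional character vector of component labels; defaults
#'   to the column names of `values` or `"C1"`, `"C2"`, ...
#' @param subject_id Optional subject label.
#' @return An object of class `component_timeseries` with elements `values`,
#'   `tr_seconds`, `component_ids`, `subject_id`.
#' @export
component_timeseries <- function(values, tr_seconds, component_ids = NULL,
                                 subject_id = "subject") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (nrow(values) < 2) stop("need at least 2 time points, got ", nrow(values))
  if (anyNA(values)) stop("'values' contains missing values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("'tr_seconds' must be a single positive number")
  if (is.null(component_ids)) {
    component_ids <- colnames(values)
    if (is.null(component_ids)) component_ids <- paste0("C", seq_len(ncol(values)))
  }
  if (length(component_ids) != ncol(values))
    stop("length of 'component_ids' (", length(component_ids),
         ") does not match number of components (", ncol(values), ")")
  colnames(values) <- component_ids
  structure(
    list(values = unname(values), tr_seconds = as.numeric(tr_seconds),
         component_ids = as.character(component_ids),
         subject_id = as.character(subject_id)),
    class = "component_timeseries")
}

#' @export
print.component_timeseries <- function(x, ...) {
  cat("<component_timeseries> subject '", x$subject_id, "': ",
      nrow(x$values), " time points x ", ncol(x$values),
      " components, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' @export
dim.component_timeseries <- function(x) dim(x$values)

#' Sliding-window specification
#'
#' A symmetric rectangular window of `2 * half_width + 1` samples, used both to
#' estimate the per-sample windowed moments behind w(t) and as the implicit
#' low-pass kernel of sliding-window Pearson correlation.
#'
#' @param half_width Positive integer half width (Delta), in samples.
#' @return An object of class `window_spec` with `half_width` and
#'   `window_length = 2 * half_width + 1`.
#' @export
window_spec <- function(half_width) {
  if (length(half_width) != 1 || half_width < 1 || half_width != round(half_width))
    stop("'half_width' must be a single positive integer")
  half_width <- as.integer(half_width)
  structure(list(half_width = half_width,
                 window_length = 2L * half_width + 1L),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("<window_spec> half width ", x$half_width, " (window of ",
      x$window_length, " samples)\n", sep = "")
  invisible(x)
}

.check_window_fits <- function(win, n) {
  if (win$window_length > n)
    stop("window of ", win$window_length,
         " samples does not fit in series of length ", n)
}

#' Read a component time-series file
#'
#' Reads delimited text (TSV or CSV, auto-detected from the header line) with a
#' header row of component IDs and one row per time point.
#'
#' @param path File path.
#' @param tr_seconds Sampling interval in seconds.
#' @param expected_components Optional component count to enforce.
#' @param subject_id Subject label; defaults to the file name without extension.
#' @return A [component_timeseries()].
#' @export
read_timeseries <- function(path, tr_seconds, expected_components = NULL,
                            subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 1 || nrow(df) < 2)
    stop("file ", path, " must have a header row and at least 2 data rows")
  mat <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(trimws(df[[j]]) %in% c("NA", "NaN")))
    if (length(bad) > 0)
      stop("non-numeric value '", df[bad[1], j], "' at data row ", bad[1],
           ", column ", j, " ('", names(df)[j], "') of ", path)
    mat[, j] <- v
  }
  if (anyNA(mat)) stop("missing values in ", path)
  if (!is.null(expected_components) && ncol(mat) != expected_components)
    stop("expected ", expected_components, " components in ", path,
         " but found ", ncol(mat))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  component_timeseries(mat, tr_seconds, component_ids = names(df),
                       subject_id = subject_id)
}

#' Write a component time series to delimited text
#'
#' @param x A [component_timeseries()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_timeseries <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "component_timeseries"))
  # %.17g so the write-then-read round trip is value-exact
  mat <- matrix(sprintf("%.17g", x$values), nrow(x$values))
  colnames(mat) <- x$component_ids
  utils::write.table(mat, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
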