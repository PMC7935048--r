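# Activity domain -> connectivity domain transforms.
#
# All windowed quantities use the valid-support (truncation) policy: a
# trajectory sample at index t (1-based) corresponds to activity sample
# t + half_width; no padding of the activity series.

# centered moving sum over 2D+1 samples, valid support only (length n - 2D)
.moving_sum <- function(x, half_width) {
  L <- 2L * half_width + 1L
  s <- stats::filter(x, rep(1, L), method = "convolution", sides = 2)
  as.numeric(s[(half_width + 1):(length(x) - half_width)])
}

#' Windowed mean and standard deviation
#'
#' Per-sample moments of a series over a centered rectangular window of
#' `2 * half_width + 1` samples. The standard deviation is the population form
#' (divisor equal to the window length), so a constant window gives exactly 0.
#'
#' @param x Numeric series.
#' @param win A [window_spec()].
#' @return List of class `windowed_moments` with `mean`, `sd` (each of length
#'   `length(x) - 2 * half_width`), `valid_range` (1-based first/last activity
#'   sample with a full window) and `window`.
#' @export
windowed_moments <- function(x, win) {
  stopifnot(inherits(win, "window_spec"))
  x <- as.numeric(x)
  .check_window_fits(win, length(x))
  L <- win$window_length
  m <- .moving_sum(x, win$half_width) / L
  # population variance; clip tiny negative values from cancellation
  v <- .moving_sum(x^2, win$half_width) / L - m^2
  s <- sqrt(pmax(v, 0))
  structure(list(mean = m, sd = s,
                 valid_range = c(win$half_width + 1L,
                                 length(x) - win$half_width),
                 window = win),
            class = "windowed_moments")
}

# per-sample windowed z-scores for every component; sigma = 0 gives NA
.windowed_zscores <- function(values, win) {
  D <- win$half_width
  tt <- nrow(values)
  z <- matrix(NA_real_, tt - 2L * D, ncol(values))
  n_zero <- 0L
  for (j in seq_len(ncol(values))) {
    wm <- windowed_moments(values[, j], win)
    s <- wm$sd
    zero <- s == 0
    n_zero <- n_zero + sum(zero)
    s[zero] <- NA_real_
    z[, j] <- (values[(D + 1):(tt - D), j] - wm$mean) / s
  }
  if (n_zero > 0)
    warning(n_zero, " window(s) with zero variance; ",
            "emitting missing values at those samples")
  z
}

#' Pair product trajectory w(t)
#'
#' The raw connectivity-domain signal: for each component pair (i, j), the
#' product of the per-sample windowed z-scores of the two series. Its
#' rectangular moving average approximates sliding-window Pearson correlation,
#' and band-filtering it yields connectivity estimates in any frequency band.
#'
#' Zero-variance windows produce missing values with a warning; an all-constant
#' component yields all-missing trajectories for its pairs.
#'
#' @param x A [component_timeseries()].
#' @param win A [window_spec()].
#' @return Object of class `pair_product` with `values` (matrix, rows = valid
#'   time points, columns = pairs), `pair_index`, `window`, `time_offset`
#'   (= half width), `tr_seconds`, `subject_id`.
#' @export
pair_product_trajectory <- function(x, win) {
  stopifnot(inherits(x, "component_timeseries"), inherits(win, "window_spec"))
  if (ncol(x$values) < 2) stop("need at least 2 components")
  .check_window_fits(win, nrow(x$values))
  z <- .windowed_zscores(x$values, win)
  pr <- pair_index(ncol(x$values))
  w <- z[, pr[, 1], drop = FALSE] * z[, pr[, 2], drop = FALSE]
  structure(list(values = w, pair_index = pr, window = win,
                 time_offset = win$half_width, tr_seconds = x$tr_seconds,
                 component_ids = x$component_ids, subject_id = x$subject_id),
            class = "pair_product")
}

#' @export
print.pair_product <- function(x, ...) {
  cat("<pair_product> ", nrow(x$values), " time points x ", ncol(x$values),
      " pairs (window ", x$window$window_length, " samples)\n", sep = "")
  invisible(x)
}

#' Sliding-window Pearson correlation
#'
#' Exact sample Pearson correlation of every component pair over a centered
#' sliding window, so every value lies in [-1, 1]. Windows in which either
#' series has zero variance produce missing values with a warning.
#'
#' @inheritParams pair_product_trajectory
#' @return Object of class `swpc_trajectory` with `values` (time x pairs),
#'   `pair_index`, `window`, `time_offset`, `tr_seconds`, `method = "direct"`.
#' @export
swpc <- function(x, win) {
  stopifnot(inherits(x, "component_timeseries"), inherits(win, "window_spec"))
  if (ncol(x$values) < 2) stop("need at least 2 components")
  .check_window_fits(win, nrow(x$values))
  vals <- x$values
  L <- win$window_length
  D <- win$half_width
  # center globally first for numerical stability of the running sums
  vals <- sweep(vals, 2, colMeans(vals))
  s1 <- apply(vals, 2, .moving_sum, half_width = D)
  s2 <- apply(vals^2, 2, .moving_sum, half_width = D)
  pr <- pair_index(ncol(vals))
  r <- matrix(NA_real_, nrow(s1), nrow(pr))
  n_zero <- 0L
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    sxy <- .moving_sum(vals[, i] * vals[, j], D)
    vx <- pmax(L * s2[, i] - s1[, i]^2, 0)
    vy <- pmax(L * s2[, j] - s1[, j]^2, 0)
    den <- sqrt(vx * vy)
    zero <- den == 0
    n_zero <- n_zero + sum(zero)
    den[zero] <- NA_real_
    r[, k] <- pmin(pmax((L * sxy - s1[, i] * s1[, j]) / den, -1), 1)
  }
  if (n_zero > 0)
    warning(n_zero, " window(s) with zero variance; ",
            "emitting missing values at those samples")
  structure(list(values = r, pair_index = pr, window = win, time_offset = D,
                 tr_seconds = x$tr_seconds, method = "direct",
                 component_ids = x$component_ids, subject_id = x$subject_id),
            class = "swpc_trajectory")
}

#' SWPC through the convolution identity
#'
#' Rectangular-kernel moving average of the pair product trajectory w(t),
#' normalized by the window length so the output is on the correlation scale.
#' This is the form that exposes SWPC as a low-pass filter acting on w(t); it
#' approximates [swpc()] (windowed moments are estimated around each sample
#' rather than once per window) and equals it exactly when global moments are
#' substituted for windowed ones. The valid support shrinks by a further half
#' width at each edge.
#'
#' @param w A [pair_product_trajectory()].
#' @return An `swpc_trajectory` with `method = "convolution"`.
#' @export
swpc_via_convolution <- function(w) {
  stopifnot(inherits(w, "pair_product"))
  win <- w$window
  if (nrow(w$values) < win$window_length)
    stop("trajectory of ", nrow(w$values),
         " samples is shorter than the window (", win$window_length, ")")
  g <- apply(w$values, 2, .moving_sum, half_width = win$half_width) /
    win$window_length
  if (!is.matrix(g)) g <- matrix(g, nrow = 1)
  structure(list(values = g, pair_index = w$pair_index, window = win,
                 time_offset = 2L * win$half_width, tr_seconds = w$tr_seconds,
                 method = "convolution", component_ids = w$component_ids,
                 subject_id = w$subject_id),
            class = "swpc_trajectory")
}

#' @export
print.swpc_trajectory <- function(x, ...) {
  cat("<swpc_trajectory> (", x$method, ") ", nrow(x$values),
      " time points x ", ncol(x$values), " pairs\n", sep = "")
  invisible(x)
}

#' Static functional network connectivity
#'
#' Pearson correlation matrix over the full recording. Zero-variance components
#' give a missing row/column with a warning.
#'
#' @param x A [component_timeseries()].
#' @return Symmetric correlation matrix with unit diagonal, component IDs as
#'   dimnames.
#' @export
static_fnc <- function(x) {
  stopifnot(inherits(x, "component_timeseries"))
  if (nrow(x$values) < 3) stop("need at least 3 time points")
  sds <- apply(x$values, 2, stats::sd)
  m <- suppressWarnings(stats::cor(x$values))
  if (any(sds == 0)) {
    warning("zero-variance component(s): ",
            paste(x$component_ids[sds == 0], collapse = ", "),
            "; corresponding rows/columns are missing")
    m[sds == 0, ] <- NA_real_
    m[, sds == 0] <- NA_real_
  }
  diag(m) <- 1
  dimnames(m) <- list(x$component_ids, x$component_ids)
  m
}

#' Write a pairwise trajectory to delimited text
#'
#' One row per time point with a leading time column in seconds (relative to
#' the start of the activity series) and one column per pair named `"i_j"`.
#'
#' @param x A `pair_product` or `swpc_trajectory`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_trajectory <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, c("pair_product", "swpc_trajectory")))
  ids <- x$component_ids
  nm <- paste(ids[x$pair_index[, 1]], ids[x$pair_index[, 2]], sep = "_")
  tt <- (x$time_offset + seq_len(nrow(x$values)) - 1) * x$tr_seconds
  vals <- matrix(sprintf("%.17g", x$values), nrow(x$values))  # value-exact
  df <- data.frame(time_s = sprintf("%.17g", tt), vals, check.names = FALSE)
  names(df) <- c("time_s", nm)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
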