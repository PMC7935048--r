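# Zero-phase application of band filters to connectivity trajectories.

# single-pass SOS filtering with zero initial conditions (C-speed via
# stats::filter: FIR part as convolution, IIR part as recursion)
.sosfilt <- function(sos, gain, x) {
  y <- x
  for (k in seq_len(nrow(sos))) {
    b <- sos[k, 1:3]; a <- sos[k, 4:6]
    v <- stats::filter(c(0, 0, y), b, method = "convolution", sides = 1)
    v <- as.numeric(v[-(1:2)])
    if (any(a[2:3] != 0))
      v <- as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
    y <- v
  }
  y * gain
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies a band filter forwards then backwards so phase distortion cancels;
#' the effective magnitude response is the squared single-pass response. Edges
#' are handled by odd-reflection padding of `3 * max(filter_order, 8)` samples
#' at each end, discarded after filtering.
#'
#' @param x Numeric series (no missing values).
#' @param filt A [design_band_filter()] result.
#' @return Filtered series, same length as `x`.
#' @export
zero_phase_filter <- function(x, filt) {
  stopifnot(inherits(filt, "band_filter"))
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains missing values; drop or impute first")
  n <- length(x)
  pad <- 3L * max(filt$filter_order, 8L)
  if (n <= pad + 1)
    stop("series of length ", n, " is too short for zero-phase filtering; ",
         "need more than ", pad + 1, " samples")
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- .sosfilt(filt$sos, filt$gain, xp)
  y <- rev(.sosfilt(filt$sos, filt$gain, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Apply a filter bank to a pair product trajectory
#'
#' Produces the banded connectivity estimate: for every band n and component
#' pair, the zero-phase band-filtered w(t). Rows of w containing missing
#' values are dropped first (with a warning reporting the count).
#'
#' @param w A [pair_product_trajectory()].
#' @param bank A [build_filter_bank()] result.
#' @return Object of class `banded_connectivity` with `values` (array
#'   band x time x pair), `bank`, `window`, `pair_index`, `tr_seconds`,
#'   `subject_id`, `n_dropped` (rows removed for missing values).
#' @export
apply_filter_bank <- function(w, bank) {
  stopifnot(inherits(w, "pair_product"), inherits(bank, "filter_bank"))
  vals <- w$values
  drop <- rowSums(is.na(vals)) > 0
  if (any(drop)) {
    warning(sum(drop), " trajectory row(s) with missing values dropped ",
            "before filtering")
    vals <- vals[!drop, , drop = FALSE]
  }
  nb <- length(bank$filters)
  out <- array(NA_real_, c(nb, nrow(vals), ncol(vals)))
  for (b in seq_len(nb)) {
    f <- bank$filters[[b]]
    out[b, , ] <- apply(vals, 2, zero_phase_filter, filt = f)
  }
  structure(list(values = out, bank = bank, window = w$window,
                 pair_index = w$pair_index, tr_seconds = w$tr_seconds,
                 component_ids = w$component_ids, subject_id = w$subject_id,
                 n_dropped = sum(drop)),
            class = "banded_connectivity")
}

#' @export
print.banded_connectivity <- function(x, ...) {
  d <- dim(x$values)
  cat("<banded_connectivity> ", d[1], " bands x ", d[2], " time points x ",
      d[3], " pairs (subject '", x$subject_id, "')\n", sep = "")
  invisible(x)
}
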