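# Filter-bank design in the connectivity domain.
#
# Each band of the bank is a minimal-order IIR filter (Chebyshev type 2 by
# default) meeting a stopband-attenuation / passband-loss spec, stored and
# applied as a cascade of second-order sections for numerical stability.

#' Tile the spectrum into contiguous bands
#'
#' Splits `[0, sampling_hz / 2]` into `n_bands` contiguous equal-width bands.
#'
#' @param n_bands Number of bands (>= 1).
#' @param sampling_hz Sampling rate in Hz (= 1 / TR for fMRI trajectories).
#' @return Data frame with columns `band`, `f_lo`, `f_hi` in Hz.
#' @export
tile_spectrum <- function(n_bands, sampling_hz) {
  if (n_bands < 1 || n_bands != round(n_bands)) stop("'n_bands' must be a positive integer")
  if (sampling_hz <= 0) stop("'sampling_hz' must be positive")
  nyq <- sampling_hz / 2
  width <- nyq / n_bands
  data.frame(band = seq_len(n_bands),
             f_lo = (seq_len(n_bands) - 1) * width,
             f_hi = seq_len(n_bands) * width)
}

#' Filter bank design specification
#'
#' @param sampling_hz Sampling rate of the trajectories in Hz.
#' @param n_bands Number of bands tiling 0 to Nyquist (default 10).
#' @param family `"chebyshev2"` (default), `"butterworth"` or `"elliptic"`.
#' @param stopband_atten_db Minimum stopband attenuation in dB (default 30).
#' @param passband_ripple_db Maximum passband loss in dB (default 3).
#' @param transition_fraction Stopband edges are offset from each passband edge
#'   by this fraction of the band width (default 0.25), clipped to
#'   (0, Nyquist).
#' @return Object of class `filter_design_spec`.
#' @export
filter_design_spec <- function(sampling_hz, n_bands = 10L,
                               family = c("chebyshev2", "butterworth", "elliptic"),
                               stopband_atten_db = 30,
                               passband_ripple_db = 3,
                               transition_fraction = 0.25) {
  family <- match.arg(family)
  if (sampling_hz <= 0) stop("'sampling_hz' must be positive")
  if (n_bands < 1 || n_bands != round(n_bands)) stop("'n_bands' must be a positive integer")
  if (stopband_atten_db <= passband_ripple_db)
    stop("'stopband_atten_db' must exceed 'passband_ripple_db'")
  if (transition_fraction <= 0 || transition_fraction >= 0.5)
    stop("'transition_fraction' must be in (0, 0.5)")
  structure(list(sampling_hz = sampling_hz, n_bands = as.integer(n_bands),
                 family = family, stopband_atten_db = stopband_atten_db,
                 passband_ripple_db = passband_ripple_db,
                 transition_fraction = transition_fraction),
            class = "filter_design_spec")
}

# ---- Chebyshev order selection ------------------------------------------------

# Minimal order of a Chebyshev (type 1 or 2) digital filter meeting
# Rp dB passband loss at Wp and Rs dB attenuation at Ws (normalized, 1 =
# Nyquist), plus the prototype passband-edge factor nf used to place the
# design stopband edges so the passband spec is met as tightly as possible.
.cheb_order <- function(Wp, Ws, Rp, Rs) {
  warp <- function(W) tan(pi * W / 2)
  passb <- warp(Wp); stopb <- warp(Ws)
  dr <- sqrt((10^(0.1 * Rs) - 1) / (10^(0.1 * Rp) - 1))
  if (length(Wp) == 1) {
    sel <- if (Wp[1] < Ws[1]) stopb / passb else passb / stopb
  } else {
    sel <- min(abs((stopb^2 - passb[1] * passb[2]) /
                     (stopb * (passb[1] - passb[2]))))
  }
  if (sel <= 1) stop("degenerate transition band (stop edge inside passband)")
  n <- ceiling(acosh(dr) / acosh(sel))
  list(n = n, nf = 1 / cosh(acosh(dr) / n), passb = passb, stopb = stopb)
}

# Design stopband edges (warped domain) for a Chebyshev-2 filter of order n:
# geometric-centered, scaled by gamma >= 1 between the tight analytic placement
# (gamma = 1, passband spec met exactly under the ideal bilinear mapping) and
# the raw stopband edges.
.cheb2_design_edges <- function(passb, stopb, nf, gamma, type) {
  if (type == "low") {
    min(passb / nf * gamma, stopb)
  } else if (type == "high") {
    max(passb * nf / gamma, stopb)
  } else {
    s <- gamma / nf
    bw <- s * (passb[2] - passb[1])
    w_hi <- bw / 2 + sqrt(bw^2 / 4 + passb[1] * passb[2])
    w_hi <- min(w_hi, stopb[2])
    w_lo <- max(passb[1] * passb[2] / w_hi, stopb[1])
    c(w_lo, w_hi)
  }
}

.unwarp <- function(w) 2 / pi * atan(w)

# ---- second-order sections ----------------------------------------------------

# Zero-pole-gain -> second-order-section cascade. Poles closest to the unit
# circle are paired first, each with its nearest remaining zeros, which keeps
# intermediate section gains bounded.
.zpg_to_sos <- function(zero, pole, gain, tol = 1e-8) {
  split_cplx <- function(v) {
    list(cplx = v[Im(v) > tol],
         real = Re(v[abs(Im(v)) <= tol]))
  }
  zz <- split_cplx(zero); pp <- split_cplx(pole)
  pc <- pp$cplx[order(-Mod(pp$cplx))]
  prl <- pp$real[order(-abs(pp$real))]
  zc <- zz$cplx; zrl <- zz$real

  pair_poly <- function(r) c(1, -2 * Re(r), Mod(r)^2)     # conjugate pair
  real2_poly <- function(r1, r2) c(1, -(r1 + r2), r1 * r2)
  real1_poly <- function(r) c(1, -r, 0)

  grab_zeros <- function(ref) {
    # numerator coefficients nearest to the reference pole, consuming state
    if (length(zc) > 0) {
      j <- which.min(Mod(zc - ref))
      b <- pair_poly(zc[j]); zc <<- zc[-j]
      return(b)
    }
    if (length(zrl) >= 2) {
      j <- order(abs(zrl - Re(ref)))[1:2]
      b <- real2_poly(zrl[j[1]], zrl[j[2]]); zrl <<- zrl[-j]
      return(b)
    }
    if (length(zrl) == 1) {
      b <- real1_poly(zrl[1]); zrl <<- numeric(0)
      return(b)
    }
    c(1, 0, 0)
  }

  sos <- NULL
  for (p in pc)
    sos <- rbind(sos, c(grab_zeros(p), pair_poly(p)))
  while (length(prl) >= 2) {
    a <- real2_poly(prl[1], prl[2])
    b <- grab_zeros(complex(real = prl[1], imaginary = 0))
    prl <- prl[-(1:2)]
    sos <- rbind(sos, c(b, a))
  }
  if (length(prl) == 1) {
    b <- if (length(zrl) >= 1) { r <- zrl[1]; zrl <- zrl[-1]; real1_poly(r) } else c(1, 0, 0)
    sos <- rbind(sos, c(b, real1_poly(prl[1])))
  }
  if (length(zc) > 0 || length(zrl) > 0)   # excess zeros (FIR remainder)
    for (z1 in c(zc, zrl))
      sos <- rbind(sos, c(if (Im(z1) != 0) pair_poly(z1) else real1_poly(Re(z1)), 1, 0, 0))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  list(sos = sos, gain = Re(gain))
}

# complex response of an SOS cascade at normalized frequencies w (1 = Nyquist)
.sos_response <- function(sos, gain, w) {
  ew1 <- exp(-1i * pi * w); ew2 <- ew1^2
  h <- rep(complex(real = gain), length(w))
  for (k in seq_len(nrow(sos))) {
    h <- h * (sos[k, 1] + sos[k, 2] * ew1 + sos[k, 3] * ew2) /
      (sos[k, 4] + sos[k, 5] * ew1 + sos[k, 6] * ew2)
  }
  h
}

.sos_poles <- function(sos) {
  unlist(lapply(seq_len(nrow(sos)), function(k) {
    a <- sos[k, 4:6]
    if (a[3] == 0 && a[2] == 0) return(complex(0))
    polyroot(rev(a[a != 0 | seq_along(a) <= max(which(a != 0))]))
  }))
}

.arma_to_sos <- function(f) {
  z <- signal::as.Zpg(f)
  .zpg_to_sos(z$zero, z$pole, z$gain)
}

# ---- band filter design --------------------------------------------------------

.band_type <- function(f_lo, f_hi, nyq, eps = 1e-12) {
  if (f_lo <= eps) "low" else if (f_hi >= nyq - eps) "high" else "pass"
}

# realized passband loss (dB) of an SOS cascade over the passband grid
.passband_loss <- function(sosg, Wp, type, n_grid = 1024) {
  w <- switch(type,
              low  = seq(0, Wp, length.out = n_grid),
              high = seq(Wp, 1, length.out = n_grid),
              pass = seq(Wp[1], Wp[2], length.out = n_grid))
  max(-20 * log10(Mod(.sos_response(sosg$sos, sosg$gain, w))))
}

.design_cheby2 <- function(Wp, Ws_raw, Rp, Rs, type, max_extra_order = 6L) {
  # design against stop edges pulled 0.1% of the transition width toward the
  # passband, so the realized attenuation at the nominal edges clears the spec
  # strictly rather than equaling it to within roundoff
  Ws_t <- Ws_raw + 1e-3 * (rep(Wp, length.out = length(Ws_raw)) - Ws_raw)
  ord <- .cheb_order(Wp, Ws_t, Rp, Rs)
  for (n in ord$n:(ord$n + max_extra_order)) {
    nf <- 1 / cosh(acosh(sqrt((10^(0.1 * Rs) - 1) / (10^(0.1 * Rp) - 1))) / n)
    make <- function(gamma) {
      wd <- .cheb2_design_edges(ord$passb, ord$stopb, nf, gamma, type)
      f <- signal::cheby2(n, Rs, .unwarp(wd), type = type)
      .arma_to_sos(f)
    }
    gamma_max <- switch(type,
                        low  = ord$stopb / (ord$passb / nf),
                        high = ord$passb * nf / ord$stopb,
                        pass = {
                          bw_raw <- ord$stopb[2] - ord$stopb[1]
                          bw_raw / ((ord$passb[2] - ord$passb[1]) / nf)
                        })
    gamma_max <- max(gamma_max, 1)
    sosg <- make(1)
    if (.passband_loss(sosg, Wp, type) <= Rp) return(c(sosg, list(n = n)))
    lo <- 1; hi <- gamma_max
    sos_hi <- make(hi)
    if (.passband_loss(sos_hi, Wp, type) > Rp) next  # need more order
    for (it in 1:30) {                               # loss decreases in gamma
      mid <- (lo + hi) / 2
      sm <- make(mid)
      if (.passband_loss(sm, Wp, type) <= Rp) { hi <- mid; sos_hi <- sm } else lo <- mid
    }
    return(c(sos_hi, list(n = n)))
  }
  stop("could not meet the passband spec within ", max_extra_order,
       " extra orders")
}

.design_buttord_family <- function(Wp, Ws_raw, Rp, Rs, type, family) {
  ordfun <- if (family == "butterworth") signal::buttord else signal::ellipord
  o <- suppressWarnings(ordfun(Wp = Wp, Ws = Ws_raw, Rp = Rp, Rs = Rs))
  f <- if (family == "butterworth") signal::butter(o) else signal::ellip(o)
  c(.arma_to_sos(f), list(n = o$n))
}

#' Design one band filter
#'
#' Designs the minimal-order filter of the requested family whose passband is
#' the given band and whose stopband begins `transition_fraction` x band width
#' beyond each passband edge. Band 1 is built as a low-pass, the Nyquist band
#' as a high-pass, interior bands as band-pass. The realized single-pass
#' magnitude response is measured on a dense grid and must meet the spec,
#' and all poles must lie strictly inside the unit circle.
#'
#' @param edges Numeric length-2 vector `c(f_lo, f_hi)` in Hz.
#' @param spec A [filter_design_spec()].
#' @param band_index Band number stored in the result.
#' @param n_grid Grid size for realized-response measurement (>= 4096).
#' @return Object of class `band_filter`: `band_index`, `passband_edges`,
#'   `stopband_edges`, `filter_order` (number of poles), `design_order`,
#'   `sos` (second-order sections), `gain`, `family`, `sampling_hz`,
#'   `realized` (`min_stopband_atten_db`, `max_passband_loss_db`, `stable`).
#' @export
design_band_filter <- function(edges, spec, band_index = 1L, n_grid = 8192L) {
  stopifnot(inherits(spec, "filter_design_spec"), length(edges) == 2)
  nyq <- spec$sampling_hz / 2
  f_lo <- edges[1]; f_hi <- edges[2]
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq + 1e-12))
    stop("invalid band edges [", f_lo, ", ", f_hi, "] for Nyquist ", nyq)
  type <- .band_type(f_lo, f_hi, nyq)
  d <- spec$transition_fraction * (f_hi - f_lo)
  Rp <- spec$passband_ripple_db; Rs <- spec$stopband_atten_db
  Wp <- switch(type, low = f_hi / nyq, high = f_lo / nyq,
               pass = c(f_lo, f_hi) / nyq)
  Ws <- switch(type, low = (f_hi + d) / nyq, high = (f_lo - d) / nyq,
               pass = c(f_lo - d, f_hi + d) / nyq)
  if (any(Ws <= 0) || any(Ws >= 1))
    stop("transition band falls outside (0, Nyquist) for band [",
         f_lo, ", ", f_hi, "]")
  des <- if (spec$family == "chebyshev2")
    .design_cheby2(Wp, Ws, Rp, Rs, type)
  else
    .design_buttord_family(Wp, Ws, Rp, Rs, type, spec$family)

  # realized single-pass specs on a dense grid
  fgrid <- seq(0, nyq, length.out = n_grid)
  wnorm <- fgrid / nyq
  mag <- Mod(.sos_response(des$sos, des$gain, wnorm))
  in_pass <- fgrid >= f_lo & fgrid <= f_hi
  in_stop <- switch(type,
                    low  = fgrid >= f_hi + d,
                    high = fgrid <= f_lo - d,
                    pass = fgrid <= f_lo - d | fgrid >= f_hi + d)
  loss <- max(-20 * log10(mag[in_pass]))
  atten <- min(-20 * log10(pmax(mag[in_stop], .Machine$double.xmin)))
  poles <- .sos_poles(des$sos)
  stable <- length(poles) == 0 || max(Mod(poles)) < 1
  # 0.05 dB grace for grid/roundoff when a design edge sits exactly on the
  # raw stopband edge; the default full tiling meets both specs strictly
  if (!stable || loss > Rp + 0.05 || atten < Rs - 0.05)
    stop(sprintf(paste0("band %d [%g, %g] Hz failed design checks: ",
                        "passband loss %.3f dB (max %g), stopband attenuation ",
                        "%.3f dB (min %g), stable = %s"),
                 band_index, f_lo, f_hi, loss, Rp, atten, Rs, stable))
  structure(list(band_index = as.integer(band_index),
                 passband_edges = c(f_lo, f_hi),
                 stopband_edges = switch(type, low = c(NA_real_, f_hi + d),
                                         high = c(f_lo - d, NA_real_),
                                         pass = c(f_lo - d, f_hi + d)),
                 type = type,
                 filter_order = length(poles), design_order = des$n,
                 sos = des$sos, gain = des$gain, family = spec$family,
                 sampling_hz = spec$sampling_hz,
                 realized = list(min_stopband_atten_db = atten,
                                 max_passband_loss_db = loss,
                                 stable = stable)),
            class = "band_filter")
}

#' @export
print.band_filter <- function(x, ...) {
  cat(sprintf(paste0("<band_filter> band %d (%s) [%g, %g] Hz, order %d, ",
                     "stopband %.1f dB, passband loss %.2f dB\n"),
              x$band_index, x$type, x$passband_edges[1], x$passband_edges[2],
              x$filter_order, x$realized$min_stopband_atten_db,
              x$realized$max_passband_loss_db))
  invisible(x)
}

#' Build a filter bank
#'
#' Tiles the spectrum (or uses explicit edges) and designs every band,
#' validating contiguity, coverage and stability.
#'
#' @param spec A [filter_design_spec()].
#' @param edges Optional matrix/data frame of custom band edges (columns
#'   `f_lo`, `f_hi`); bands need not cover the whole spectrum in that case.
#' @return Object of class `filter_bank` with `spec` and `filters` (list of
#'   [design_band_filter()] results).
#' @export
build_filter_bank <- function(spec, edges = NULL) {
  stopifnot(inherits(spec, "filter_design_spec"))
  full_tiling <- is.null(edges)
  if (full_tiling) edges <- tile_spectrum(spec$n_bands, spec$sampling_hz)
  edges <- as.data.frame(edges)
  if (is.null(edges$f_lo)) names(edges)[1:2] <- c("f_lo", "f_hi")
  n <- nrow(edges)
  if (n > 1 && any(abs(edges$f_lo[-1] - edges$f_hi[-n]) > 1e-12))
    stop("band edges are not contiguous")
  filters <- lapply(seq_len(n), function(i)
    design_band_filter(c(edges$f_lo[i], edges$f_hi[i]), spec, band_index = i))
  if (full_tiling) {
    stopifnot(abs(edges$f_lo[1]) < 1e-12,
              abs(edges$f_hi[n] - spec$sampling_hz / 2) < 1e-12)
  }
  structure(list(spec = spec, filters = filters), class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", length(x$filters), " ", x$spec$family,
      " bands, fs = ", x$spec$sampling_hz, " Hz\n", sep = "")
  for (f in x$filters) print(f)
  invisible(x)
}

#' Magnitude response of a band filter
#'
#' @param filt A [design_band_filter()] result.
#' @param n Number of grid points over `[0, Nyquist]`.
#' @return Data frame with `freq_hz`, `magnitude` (single pass) and
#'   `magnitude_zero_phase` (forward-backward, i.e. squared).
#' @export
filter_response <- function(filt, n = 4096L) {
  stopifnot(inherits(filt, "band_filter"))
  nyq <- filt$sampling_hz / 2
  fgrid <- seq(0, nyq, length.out = n)
  mag <- Mod(.sos_response(filt$sos, filt$gain, fgrid / nyq))
  data.frame(freq_hz = fgrid, magnitude = mag, magnitude_zero_phase = mag^2)
}

# ---- JSON round trip -----------------------------------------------------------

#' Export a filter bank to JSON
#'
#' Writes spec, per-band edges, orders, second-order sections and realized
#' specs with full numeric precision (bit-exact round trip via
#' [bank_from_json()]).
#'
#' @param bank A [build_filter_bank()] result.
#' @param path Output path.
#' @export
bank_to_json <- function(bank, path) {
  stopifnot(inherits(bank, "filter_bank"))
  # coefficients are serialized as %.17g strings: IEEE doubles survive the
  # text round trip bit-exactly, which plain JSON number formatting does not
  # guarantee
  exact <- function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  obj <- list(
    spec = unclass(bank$spec),
    filters = lapply(bank$filters, function(f) {
      f$sos <- exact(as.vector(t(f$sos)))   # row-major flat vector
      f$gain <- exact(f$gain)
      f$passband_edges <- exact(f$passband_edges)
      f$stopband_edges <- exact(f$stopband_edges)
      unclass(f)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Import a filter bank from JSON
#'
#' @param path Path written by [bank_to_json()].
#' @return A `filter_bank`.
#' @export
bank_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  spec <- do.call(filter_design_spec,
                  lapply(obj$spec[c("sampling_hz", "n_bands", "family",
                                    "stopband_atten_db", "passband_ripple_db",
                                    "transition_fraction")], `[[`, 1))
  filters <- lapply(obj$filters, function(f) {
    sos <- matrix(num(f$sos), ncol = 6, byrow = TRUE)
    colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
    structure(list(band_index = as.integer(f$band_index),
                   passband_edges = num(f$passband_edges),
                   stopband_edges = num(f$stopband_edges),
                   type = f$type,
                   filter_order = as.integer(f$filter_order),
                   design_order = as.integer(f$design_order),
                   sos = sos, gain = as.numeric(f$gain), family = f$family,
                   sampling_hz = as.numeric(f$sampling_hz),
                   realized = list(
                     min_stopband_atten_db = as.numeric(f$realized$min_stopband_atten_db),
                     max_passband_loss_db = as.numeric(f$realized$max_passband_loss_db),
                     stable = as.logical(f$realized$stable))),
              class = "band_filter")
  })
  structure(list(spec = spec, filters = filters), class = "filter_bank")
}
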