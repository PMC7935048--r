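# Oscillating-covariance simulator: multivariate normal series whose pairwise
# correlation oscillates as rho_ij(t) = A_ij * cos(2*pi*f_corr*t), switching
# between connectivity states. Used to validate that band-filtered
# connectivity recovers states whose oscillation frequency falls outside the
# sliding-window passband.

#' Amplitude matrix built from component pairs
#'
#' Convenience constructor: a symmetric 6x6 (or n x n) amplitude matrix with
#' the given value on the listed pairs and zero elsewhere.
#'
#' @param pairs List of length-2 integer vectors.
#' @param amplitude Correlation amplitude on those pairs.
#' @param n_series Matrix size (default 6).
#' @return Symmetric matrix with zero diagonal.
#' @export
pair_amplitude_matrix <- function(pairs, amplitude = 0.9, n_series = 6L) {
  a <- matrix(0, n_series, n_series)
  for (p in pairs) {
    a[p[1], p[2]] <- amplitude
    a[p[2], p[1]] <- amplitude
  }
  a
}

#' Default toy amplitude matrices
#'
#' Two clearly distinct, positive-definite-valid oscillation patterns over six
#' series: state 1 couples the pairs (1,2), (3,4), (5,6) and state 2 the pairs
#' (1,4), (2,5), (3,6), both at amplitude 0.9. With unit-variance series the
#' instantaneous covariance I + cos(.)*A stays positive definite over the full
#' oscillation (max |eigenvalue| = 0.9 < 1), and the two vectorized patterns
#' correlate at only -0.25, so state recovery is unambiguous.
#'
#' @return List of two amplitude matrices.
#' @export
default_toy_amplitudes <- function() {
  list(pair_amplitude_matrix(list(c(1, 2), c(3, 4), c(5, 6))),
       pair_amplitude_matrix(list(c(1, 4), c(2, 5), c(3, 6))))
}

#' Specification of one toy connectivity state
#'
#' @param A Symmetric amplitude matrix, zero diagonal, entries in (-1, 1).
#' @param f_corr Connectivity oscillation frequency in cycles/sample.
#' @param duration State duration in samples.
#' @param pd_tol Minimum allowed eigenvalue of I + c*A over the oscillation
#'   (default 1e-6); specs below it are rejected, never repaired.
#' @return Object of class `toy_state_spec` (fields `A`, `f_corr`, `duration`,
#'   `eigen` — the cached eigendecomposition of `A`).
#' @export
toy_state_spec <- function(A, f_corr, duration = 10000L, pd_tol = 1e-6) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-12)
    stop("'A' must be a symmetric square matrix")
  if (any(diag(A) != 0)) stop("'A' must have zero diagonal (unit variances are fixed)")
  if (any(abs(A[upper.tri(A)]) >= 1)) stop("amplitude entries must lie in (-1, 1)")
  if (f_corr < 0 || f_corr > 0.5) stop("'f_corr' must be in [0, 0.5] cycles/sample")
  if (duration < 2) stop("'duration' must be at least 2 samples")
  e <- eigen(A, symmetric = TRUE)
  # min over all phases c in [-1, 1] of eigenvalues of I + c*A
  min_eig <- 1 - max(abs(e$values))
  if (min_eig < pd_tol)
    stop(sprintf(paste0("Sigma(t) is not positive definite over the ",
                        "oscillation: minimum eigenvalue %.3g at the extreme ",
                        "phase (|cos| = 1); largest |eigenvalue| of A is %.3g"),
                 min_eig, max(abs(e$values))))
  structure(list(A = A, f_corr = f_corr, duration = as.integer(duration),
                 eigen = e),
            class = "toy_state_spec")
}

#' Instantaneous covariance of a toy state
#'
#' @param spec A [toy_state_spec()].
#' @param t Sample index within the state (0-based).
#' @return The covariance matrix `I + cos(2*pi*f_corr*t) * A` (unit diagonal).
#' @export
instantaneous_covariance <- function(spec, t) {
  stopifnot(inherits(spec, "toy_state_spec"))
  if (t < 0 || t >= spec$duration)
    stop("t = ", t, " outside state duration [0, ", spec$duration - 1, "]")
  diag(nrow(spec$A)) + cos(2 * pi * spec$f_corr * t) * spec$A
}

#' Toy scenario: states plus analysis parameters
#'
#' @param states List of [toy_state_spec()] (default: the two
#'   [default_toy_amplitudes()] patterns at the given frequencies).
#' @param f_corr Length-2 frequencies used when `states` is NULL.
#' @param duration Per-state duration used when `states` is NULL.
#' @param seed Simulation seed.
#' @param window_samples Odd window length for w(t) and SWPC (default 11).
#' @param bank_edges Band edges (Hz = cycles/sample at TR 1) for the toy bank;
#'   default a low-pass `[0, 0.025]` plus a band-pass `[0.025, 0.09]`, which
#'   deliberately do not cover the whole spectrum.
#' @param k Number of clusters (default 4: each state oscillates between +A
#'   and -A).
#' @return Object of class `toy_scenario`.
#' @export
toy_scenario <- function(states = NULL, f_corr = c(0.01, 0.07),
                         duration = 10000L, seed = 1L,
                         window_samples = 11L,
                         bank_edges = rbind(c(0, 0.025), c(0.025, 0.09)),
                         k = 4L) {
  if (is.null(states)) {
    amps <- default_toy_amplitudes()
    if (length(f_corr) != length(amps))
      stop("need one frequency per default state")
    states <- mapply(toy_state_spec, amps, f_corr,
                     MoreArgs = list(duration = duration), SIMPLIFY = FALSE)
  }
  stopifnot(all(vapply(states, inherits, TRUE, "toy_state_spec")))
  if (window_samples %% 2 != 1 || window_samples < 3)
    stop("'window_samples' must be an odd integer >= 3")
  bank_edges <- as.matrix(bank_edges)
  structure(list(states = states, seed = as.integer(seed),
                 window_samples = as.integer(window_samples),
                 bank_edges = bank_edges, k = as.integer(k),
                 n_series = nrow(states[[1]]$A)),
            class = "toy_scenario")
}

#' Named toy scenario presets
#'
#' Six scenarios crossing connectivity-frequency placement with window choice.
#' The toy bank is a low-pass band `[0, 0.025]` and a band-pass band
#' `[0.025, 0.09]` (cycles/sample); the SWPC main lobe extends to about
#' 1/window. Scenarios A-C use an 11-sample window (main lobe ~0.09, covering
#' both bands); D-F use a 31-sample window (main lobe ~0.03, covering only the
#' low band).
#'
#' * A: state frequencies 0.01 and 0.07 (one per band)
#' * B: 0.005 and 0.02 (both in the low band)
#' * C: 0.04 and 0.07 (both in the high band)
#' * D, E, F: same frequencies as A, B, C with the 31-sample window
#'
#' @param name One of `"A"`..`"F"`.
#' @param duration Per-state duration in samples (default 10000).
#' @param seed Simulation seed.
#' @return A [toy_scenario()].
#' @export
toy_scenario_preset <- function(name = c("A", "B", "C", "D", "E", "F"),
                                duration = 10000L, seed = 1L) {
  name <- match.arg(name)
  freqs <- switch(name,
                  A = , D = c(0.01, 0.07),
                  B = , E = c(0.005, 0.02),
                  C = , F = c(0.04, 0.07))
  win <- if (name %in% c("A", "B", "C")) 11L else 31L
  toy_scenario(f_corr = freqs, duration = duration, seed = seed,
               window_samples = win)
}

#' Simulate a toy scenario
#'
#' Each sample is an independent draw from N(0, Sigma(t)) with
#' `Sigma(t) = I + cos(2*pi*f_corr*t) * A` for the active state (states are
#' concatenated in order). Sampling uses the symmetric square root of
#' `Sigma(t)` via the eigendecomposition of `A`, vectorized over time.
#'
#' @param scenario A [toy_scenario()].
#' @return A [component_timeseries()] with TR = 1 s (frequencies are
#'   cycles/sample).
#' @export
simulate_toy <- function(scenario) {
  stopifnot(inherits(scenario, "toy_scenario"))
  set.seed(scenario$seed)
  blocks <- lapply(scenario$states, function(st) {
    v <- st$eigen$vectors
    lam <- st$eigen$values
    cvec <- cos(2 * pi * st$f_corr * (0:(st$duration - 1)))
    z <- matrix(stats::rnorm(st$duration * nrow(st$A)), st$duration)
    # Sigma(t)^(1/2) = V diag(sqrt(1 + c_t * lambda)) V'
    (z %*% v * sqrt(pmax(1 + outer(cvec, lam), 0))) %*% t(v)
  })
  component_timeseries(do.call(rbind, blocks), tr_seconds = 1,
                       subject_id = "toy")
}

#' Ground-truth centroid patterns of a toy scenario
#'
#' Each state's connectivity oscillates between +A and -A, so a two-state
#' scenario has four reference patterns: +A1, -A1, +A2, -A2 (vectorized in
#' [pair_index()] order).
#'
#' @param scenario A [toy_scenario()].
#' @return Matrix (2 x number of states) x P of reference centroids.
#' @export
ground_truth_centroids <- function(scenario) {
  stopifnot(inherits(scenario, "toy_scenario"))
  refs <- do.call(rbind, lapply(scenario$states, function(st) {
    v <- vectorize_fnc(st$A)
    rbind(v, -v)
  }))
  rownames(refs) <- unlist(lapply(seq_along(scenario$states), function(i)
    paste0(c("+A", "-A"), i)))
  refs
}

# filter bank for the toy analysis (custom, possibly partial tiling)
.toy_bank <- function(scenario) {
  spec <- filter_design_spec(sampling_hz = 1,
                             n_bands = nrow(scenario$bank_edges))
  build_filter_bank(spec, edges = scenario$bank_edges)
}

#' Run a toy scenario through FBC and/or SWPC
#'
#' Simulates the scenario, computes the pair product trajectory w(t), runs the
#' requested estimators (band-filtered connectivity and/or direct
#' sliding-window Pearson correlation), clusters each result into `k` states,
#' and matches the estimated centroids to the ground-truth patterns.
#'
#' @param scenario A [toy_scenario()].
#' @param methods Character subset of `c("fbc", "swpc")`.
#' @param replicates k-means restarts (default 30).
#' @return List of class `toy_report`: per method, matched correlations,
#'   assignment, centroid mean and (within-cluster) sd maps; for FBC also the
#'   per-band fraction of each band's observations spent in each matched
#'   cluster (`band_fractions`, references x bands).
#' @export
run_toy_scenario <- function(scenario, methods = c("fbc", "swpc"),
                             replicates = 30L) {
  stopifnot(inherits(scenario, "toy_scenario"))
  methods <- match.arg(methods, several.ok = TRUE)
  x <- simulate_toy(scenario)
  win <- window_spec((scenario$window_samples - 1) / 2)
  w <- pair_product_trajectory(x, win)
  refs <- ground_truth_centroids(scenario)
  out <- list(scenario = scenario)

  summarize <- function(model, values_by_row) {
    m <- match_states(model$centroids, refs)
    sd_maps <- lapply(seq_len(model$k), function(c) {
      rows <- values_by_row[model$labels == c, , drop = FALSE]
      devectorize_fnc(apply(rows, 2, stats::sd))
    })
    list(assignment = m$assignment, correlations = m$correlations,
         mean_maps = lapply(m$assignment, function(c)
           devectorize_fnc(model$centroids[c, ])),
         sd_maps = sd_maps[m$assignment], model = model)
  }

  if ("fbc" %in% methods) {
    bank <- .toy_bank(scenario)
    banded <- apply_filter_bank(w, bank)
    obs <- assemble_observations(banded)
    model <- cluster_states(obs, k = scenario$k, replicates = replicates,
                            seed = scenario$seed + 1L)
    out$fbc <- summarize(model, obs$values)
    fr <- fraction_rates(model, obs)
    bf <- matrix(fr$per_band[1, out$fbc$assignment, ],
                 nrow = length(out$fbc$assignment))
    dimnames(bf) <- list(rownames(refs),
                         paste0("band", seq_len(fr$n_bands)))
    out$fbc$band_fractions <- bf
  }
  if ("swpc" %in% methods) {
    s <- swpc(x, win)
    keep <- rowSums(is.na(s$values)) == 0
    model <- cluster_states(s$values[keep, , drop = FALSE], k = scenario$k,
                            replicates = replicates,
                            seed = scenario$seed + 2L)
    out$swpc <- summarize(model, s$values[keep, , drop = FALSE])
  }
  class(out) <- "toy_report"
  out
}

#' @export
print.toy_report <- function(x, ...) {
  for (m in intersect(c("fbc", "swpc"), names(x))) {
    cat(toupper(m), " matched centroid correlations: ",
        paste(sprintf("%.3f", x[[m]]$correlations), collapse = ", "),
        " (mean ", sprintf("%.3f", mean(x[[m]]$correlations)), ")\n", sep = "")
  }
  if (!is.null(x$fbc$band_fractions)) {
    cat("FBC band fractions of matched clusters:\n")
    print(round(x$fbc$band_fractions, 3))
  }
  invisible(x)
}
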