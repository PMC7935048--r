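# shared fixture builders (everything generated in code)

make_ts <- function(n_time = 200, n_comp = 4, seed = 42, tr = 1) {
  set.seed(seed)
  component_timeseries(matrix(rnorm(n_time * n_comp), n_time, n_comp),
                       tr_seconds = tr, subject_id = paste0("s", seed))
}

# brute-force windowed moments: independent loop per window
brute_moments <- function(x, half_width) {
  n <- length(x)
  idx <- (half_width + 1):(n - half_width)
  L <- 2 * half_width + 1
  m <- vapply(idx, function(t) mean(x[(t - half_width):(t + half_width)]), 0)
  s <- vapply(idx, function(t) {
    w <- x[(t - half_width):(t + half_width)]
    sqrt(sum((w - mean(w))^2) / L)
  }, 0)
  list(mean = m, sd = s)
}

# brute-force SWPC: stats::cor per window
brute_swpc <- function(x, y, half_width) {
  n <- length(x)
  vapply((half_width + 1):(n - half_width), function(t)
    stats::cor(x[(t - half_width):(t + half_width)],
               y[(t - half_width):(t + half_width)]), 0)
}

# brute-force BH step-up over all ranks
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small 2-band bank at fs = 1 for cheap filtering tests
tiny_bank <- function() {
  spec <- filter_design_spec(sampling_hz = 1, n_bands = 2)
  build_filter_bank(spec)
}

# well-separated gaussian blobs for clustering tests
make_blobs <- function(n_per = 50, k = 4, dim = 6, sep = 20, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim), k) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(n_per * dim), n_per), 2, centers[j, ], `+`)))
  list(x = x, labels = rep(seq_len(k), each = n_per), centers = centers)
}

# minimal observation_matrix / state_model builders for unit tests
fake_obs <- function(values, subject, band, time = NULL) {
  if (is.null(time)) time <- seq_len(nrow(values))
  structure(list(values = values,
                 row_index = data.frame(subject = subject, band = band,
                                        time = time),
                 pair_index = pair_index(2),
                 n_bands = max(band), n_dropped = 0L),
            class = "observation_matrix")
}

fake_model <- function(labels, k) {
  structure(list(k = k, centroids = matrix(0, k, 1), labels = labels,
                 inertia = 0, replicate_seeds = integer(0),
                 scale_features = FALSE, scaling = NULL),
            class = "state_model")
}
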