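test_that("windowed moments match the definitions and a brute-force oracle", {
  # constant series: zero variance everywhere
  wm <- windowed_moments(rep(3.5, 50), window_spec(4))
  expect_true(all(wm$mean == 3.5))
  expect_true(all(wm$sd == 0))
  expect_length(wm$mean, 50 - 8)

  # printed ramp: window of 3 around t = 1 (0-based) holds 0, 1, 2
  wm <- windowed_moments(0:10, window_spec(1))
  expect_equal(wm$mean[1], 1)
  expect_equal(wm$sd[1], sqrt(2 / 3))

  # random series vs independent per-window loop
  set.seed(11)
  x <- rnorm(300)
  for (hw in c(2, 7, 20)) {
    wm <- windowed_moments(x, window_spec(hw))
    bf <- brute_moments(x, hw)
    expect_lt(max(abs(wm$mean - bf$mean)), 1e-12)
    expect_lt(max(abs(wm$sd - bf$sd)), 1e-12)
  }

  expect_error(windowed_moments(1:5, window_spec(3)), "does not fit")
})

test_that("pair product trajectory has the right pair structure and symmetries", {
  expect_equal(nrow(pair_index(47)), 1081)

  set.seed(2)
  base <- rnorm(120)
  x <- component_timeseries(cbind(base, base, -base), tr_seconds = 2)
  w <- pair_product_trajectory(x, window_spec(5))
  expect_equal(ncol(w$values), 3)
  # identical pair: squared z-score, non-negative
  expect_true(all(w$values[, 1] >= 0))
  # sign-flipped pair equals the negated self-pair trajectory
  expect_equal(w$values[, 2], -w$values[, 1])

  # pair ordering is lexicographic with i < j
  pr <- pair_index(4)
  expect_equal(pr[, 1], c(1, 1, 1, 2, 2, 3))
  expect_equal(pr[, 2], c(2, 3, 4, 3, 4, 4))
})

test_that("zero-variance windows yield missing values with a warning", {
  x <- component_timeseries(cbind(c(rep(1, 30), rnorm(30)), rnorm(60)),
                            tr_seconds = 1)
  expect_warning(w <- pair_product_trajectory(x, window_spec(3)),
                 "zero variance")
  expect_true(anyNA(w$values))
  # all-constant component: every pair involving it is all-missing
  x2 <- component_timeseries(cbind(rep(2, 40), rnorm(40)), tr_seconds = 1)
  expect_warning(w2 <- pair_product_trajectory(x2, window_spec(3)))
  expect_true(all(is.na(w2$values)))
})

test_that("swpc is exact windowed Pearson correlation in [-1, 1]", {
  set.seed(3)
  base <- rnorm(100)
  x <- component_timeseries(cbind(base, 2 * base + 1, -base), tr_seconds = 1)
  r <- swpc(x, window_spec(4))
  expect_true(all(abs(r$values[, 1] - 1) < 1e-12))   # y = ax + b, a > 0
  expect_true(all(abs(r$values[, 2] + 1) < 1e-12))   # y = -x

  # random data: oracle and range
  xs <- make_ts(150, 3, seed = 9)
  r <- swpc(xs, window_spec(6))
  expect_true(all(r$values >= -1 & r$values <= 1))
  bf <- brute_swpc(xs$values[, 1], xs$values[, 2], 6)
  expect_lt(max(abs(r$values[, 1] - bf)), 1e-10)
})

test_that("swpc time-mean recovers a constant correlation (Monte Carlo)", {
  set.seed(1234)
  n <- 20000
  rho <- 0.5
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- component_timeseries(cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2),
                            tr_seconds = 1)
  r <- swpc(x, window_spec(50))
  # windowed sample correlation is slightly biased toward 0; 3 SEs of the mean
  L <- 101
  bias_corrected <- rho * (1 - (1 - rho^2) / (2 * L))
  se <- sd(r$values[, 1]) / sqrt(n / L)   # ~independent windows
  expect_lt(abs(mean(r$values[, 1]) - bias_corrected), 3 * se)
})

test_that("convolution form approximates direct SWPC and matches it exactly under global moments", {
  # kernel normalization: w identically 1 maps to 1
  w1 <- structure(list(values = matrix(1, 60, 1), pair_index = pair_index(2),
                       window = window_spec(4), time_offset = 4L,
                       tr_seconds = 1, component_ids = c("a", "b"),
                       subject_id = "t"),
                  class = "pair_product")
  g <- swpc_via_convolution(w1)
  expect_true(all(abs(g$values - 1) < 1e-12))
  expect_equal(nrow(g$values), 60 - 8)
  expect_equal(g$time_offset, 8L)

  # global-moment substitution: moving average of global z-score products
  # equals Eq.-1-style correlation computed with the same global moments
  set.seed(21)
  n <- 200; hw <- 7; L <- 2 * hw + 1
  x <- rnorm(n); y <- rnorm(n)
  zx <- (x - mean(x)) / (sd(x) * sqrt((n - 1) / n))
  zy <- (y - mean(y)) / (sd(y) * sqrt((n - 1) / n))
  wg <- structure(list(values = matrix(zx * zy, ncol = 1),
                       pair_index = pair_index(2), window = window_spec(hw),
                       time_offset = hw, tr_seconds = 1,
                       component_ids = c("a", "b"), subject_id = "t"),
                  class = "pair_product")
  g <- swpc_via_convolution(wg)
  direct_global <- vapply((hw + 1):(n - hw), function(t)
    sum(zx[(t - hw):(t + hw)] * zy[(t - hw):(t + hw)]) / L, 0)
  expect_lt(max(abs(g$values[, 1] - direct_global)), 1e-12)

  # smooth AR(1) pair with slowly oscillating coupling: convolution and
  # direct forms track closely when real connectivity dynamics are present
  set.seed(8)
  n <- 3000
  rho <- 0.8 * cos(2 * pi * 0.003 * (1:n))
  z1 <- as.numeric(stats::filter(rnorm(n), 0.3, method = "recursive"))
  z2 <- as.numeric(stats::filter(rnorm(n), 0.3, method = "recursive"))
  xs <- component_timeseries(cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2),
                             tr_seconds = 1)
  hw <- 15
  direct <- swpc(xs, window_spec(hw))
  conv <- swpc_via_convolution(pair_product_trajectory(xs, window_spec(hw)))
  shared_direct <- direct$values[(hw + 1):(nrow(direct$values) - hw), 1]
  expect_gte(cor(shared_direct, conv$values[, 1]), 0.95)
})

test_that("static FNC matches per-pair correlation with unit diagonal", {
  set.seed(5)
  tt <- seq_len(200)
  x <- component_timeseries(
    cbind(sin(2 * pi * 5 * tt / 200), cos(2 * pi * 5 * tt / 200), rnorm(200)),
    tr_seconds = 1)
  m <- static_fnc(x)
  expect_equal(diag(m), rep(1, 3), ignore_attr = TRUE)
  expect_lt(abs(m[1, 2]), 1e-10)   # orthogonal over whole cycles
  expect_equal(m, t(m))
  # brute-force oracle
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(m[i, j], cor(x$values[, i], x$values[, j]))
  # duplicated component
  xd <- component_timeseries(cbind(x$values[, 1], x$values[, 1]), tr_seconds = 1)
  expect_equal(static_fnc(xd)[1, 2], 1)
  # zero-variance component is flagged missing
  xz <- component_timeseries(cbind(rep(1, 50), rnorm(50)), tr_seconds = 1)
  expect_warning(mz <- static_fnc(xz), "zero-variance")
  expect_true(is.na(mz[1, 2]))
})

test_that("pair product of standardized white noise is centered on zero", {
  set.seed(99)
  x <- make_ts(4000, 2, seed = 99)
  w <- pair_product_trajectory(x, window_spec(10))
  expect_lt(abs(mean(w$values[, 1])), 3 / sqrt(nrow(w$values)))
})
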