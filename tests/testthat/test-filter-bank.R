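test_that("spectrum tiling reproduces the reference band edges", {
  tiles <- tile_spectrum(10, 0.5)
  expect_equal(tiles$f_lo[1], 0)
  expect_equal(tiles$f_hi[1], 0.025)
  expect_equal(tiles$f_hi[6], 0.150)
  expect_equal(tiles$f_lo[10], 0.225)
  expect_equal(tiles$f_hi[10], 0.250)
  one <- tile_spectrum(1, 2)
  expect_equal(c(one$f_lo, one$f_hi), c(0, 1))
})

test_that("every default-bank filter is stable and meets the realized specs", {
  bank <- build_filter_bank(filter_design_spec(sampling_hz = 0.5))
  expect_length(bank$filters, 10)
  for (f in bank$filters) {
    expect_true(f$realized$stable)
    expect_gte(f$realized$min_stopband_atten_db, 30)
    expect_lte(f$realized$max_passband_loss_db, 3)
    poles <- fbconn:::.sos_poles(f$sos)
    expect_lt(max(Mod(poles)), 1)
  }
  # band 1 is low-pass with DC in the passband; band N reaches Nyquist
  expect_equal(bank$filters[[1]]$type, "low")
  expect_equal(bank$filters[[10]]$type, "high")
  m0 <- Mod(fbconn:::.sos_response(bank$filters[[1]]$sos,
                                   bank$filters[[1]]$gain, 0))
  expect_lt(-20 * log10(m0), 3)
})

test_that("bank construction is robust across band counts", {
  for (nb in 5:12) {
    bank <- build_filter_bank(filter_design_spec(sampling_hz = 0.5, n_bands = nb))
    edges <- t(vapply(bank$filters, function(f) f$passband_edges, numeric(2)))
    # contiguous coverage of [0, Nyquist]
    expect_equal(edges[1, 1], 0)
    expect_equal(edges[nb, 2], 0.25)
    if (nb > 1) expect_equal(edges[-1, 1], edges[-nb, 2])
  }
})

test_that("zero-phase filtering has no phase shift and strong band separation", {
  bank <- tiny_bank()
  n <- 2048
  tt <- 0:(n - 1)
  # in-band sinusoid for band 1 (passband [0, 0.25] at fs = 1)
  f_in <- 0.1
  x <- sin(2 * pi * f_in * tt)
  y <- zero_phase_filter(x, bank$filters[[1]])
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # stopband sinusoid: forward-backward doubles the 30 dB single-pass spec
  f_stop <- 0.45   # beyond band 1's stopband edge
  xs <- sin(2 * pi * f_stop * tt)
  ys <- zero_phase_filter(xs, bank$filters[[1]])
  core <- 200:(n - 200)   # ignore edge transients
  atten_db <- -20 * log10(max(abs(ys[core])))
  expect_gte(atten_db, 60)

  # constant series passes the low band nearly unchanged
  yc <- zero_phase_filter(rep(2, 500), bank$filters[[1]])
  expect_true(all(abs(yc - 2) < 2 * (1 - 10^(-3 / 20))))

  # energy separation: in-band sinusoid nearly absent from the other band
  y2 <- zero_phase_filter(x, bank$filters[[2]])
  sep_db <- 20 * log10(sqrt(mean(y[core]^2)) / sqrt(mean(y2[core]^2)))
  expect_gte(sep_db, 40)

  expect_error(zero_phase_filter(rnorm(10), bank$filters[[1]]), "too short")
})

test_that("band outputs concentrate spectral mass in their own passband", {
  set.seed(31)
  bank <- build_filter_bank(filter_design_spec(sampling_hz = 1, n_bands = 4))
  x <- rnorm(4096)
  for (f in bank$filters) {
    y <- zero_phase_filter(x, f)
    sp <- Mod(stats::fft(y))^2
    freqs <- (seq_along(sp) - 1) / length(sp)   # cycles/sample
    half <- freqs <= 0.5
    in_band <- half & freqs >= f$passband_edges[1] - 1e-12 &
      freqs <= f$passband_edges[2] + 1e-12
    expect_gte(sum(sp[in_band]) / sum(sp[half]), 0.8)
  }
})

test_that("summed band outputs reconstruct the unfiltered trajectory", {
  set.seed(17)
  bank <- build_filter_bank(filter_design_spec(sampling_hz = 0.5))
  w <- rnorm(3000)
  rec <- Reduce(`+`, lapply(bank$filters, function(f) zero_phase_filter(w, f)))
  rel_l2 <- sqrt(sum((rec - w)^2) / sum(w^2))
  expect_lte(rel_l2, 0.1)

  # zero trajectory maps to zero in every band
  z <- rep(0, 500)
  for (f in bank$filters)
    expect_true(all(zero_phase_filter(z, f) == 0))
})

test_that("apply_filter_bank fills the band x time x pair array", {
  x <- make_ts(300, 3, seed = 12)
  w <- pair_product_trajectory(x, window_spec(5))
  bank <- tiny_bank()
  banded <- apply_filter_bank(w, bank)
  expect_equal(dim(banded$values), c(2, 300 - 10, 3))
  expect_false(anyNA(banded$values))
  # each slice equals filtering the corresponding column directly
  expect_equal(banded$values[2, , 3],
               zero_phase_filter(w$values[, 3], bank$filters[[2]]))
})

test_that("bank JSON export round-trips bit-exactly", {
  bank <- tiny_bank()
  path <- withr::local_tempfile(fileext = ".json")
  bank_to_json(bank, path)
  back <- bank_from_json(path)
  expect_identical(length(back$filters), length(bank$filters))
  for (i in seq_along(bank$filters)) {
    expect_identical(back$filters[[i]]$sos, bank$filters[[i]]$sos)
    expect_identical(back$filters[[i]]$gain, bank$filters[[i]]$gain)
    expect_identical(back$filters[[i]]$passband_edges,
                     bank$filters[[i]]$passband_edges)
  }
  # filtering with the re-imported bank is byte-identical
  set.seed(3); x <- rnorm(400)
  expect_identical(zero_phase_filter(x, back$filters[[2]]),
                   zero_phase_filter(x, bank$filters[[2]]))
})
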