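test_that("observation assembly preserves values and row bookkeeping", {
  bank <- tiny_bank()
  subs <- lapply(c(21, 22), function(s) {
    x <- make_ts(150, 3, seed = s)
    apply_filter_bank(pair_product_trajectory(x, window_spec(5)), bank)
  })
  obs <- assemble_observations(subs)
  expect_equal(nrow(obs$values), 2 * 2 * 140)   # subjects x bands x time
  expect_equal(ncol(obs$values), 3)

  # indexing round trip: each row equals the source array slice
  set.seed(7)
  for (r in sample(nrow(obs$values), 20)) {
    ri <- obs$row_index[r, ]
    s <- match(ri$subject, vapply(subs, function(b) b$subject_id, ""))
    expect_equal(obs$values[r, ], subs[[s]]$values[ri$band, ri$time, ])
  }

  # single subject, single band: row count = trajectory length
  one <- assemble_observations(subs[[1]])
  expect_equal(nrow(one$values), 2 * 140)

  # mismatched windows are a configuration error
  other <- apply_filter_bank(
    pair_product_trajectory(make_ts(150, 3, seed = 5), window_spec(7)), bank)
  expect_error(assemble_observations(list(subs[[1]], other)), "window")
})

test_that("state clustering recovers planted structure and is reproducible", {
  blobs <- make_blobs(n_per = 40, k = 4, seed = 2)
  model <- cluster_states(blobs$x, k = 4, replicates = 5, seed = 10)

  # perfect recovery up to permutation
  tab <- table(model$labels, blobs$labels)
  expect_equal(sort(apply(tab, 1, max)), sort(table(blobs$labels)),
               ignore_attr = TRUE)
  expect_equal(max(apply(tab > 0, 1, sum)), 1)

  # inertia equals brute-force recomputation from centroids and labels
  inertia_bf <- sum(vapply(seq_len(nrow(blobs$x)), function(i)
    sum((blobs$x[i, ] - model$centroids[model$labels[i], ])^2), 0))
  expect_equal(model$inertia, inertia_bf, tolerance = 1e-10)

  # identical seed and input give identical labels and centroids
  model2 <- cluster_states(blobs$x, k = 4, replicates = 5, seed = 10)
  expect_identical(model$labels, model2$labels)
  expect_identical(model$centroids, model2$centroids)

  # k = 1: centroid is the grand mean
  m1 <- cluster_states(blobs$x, k = 1, replicates = 2, seed = 3)
  expect_equal(as.numeric(m1$centroids), colMeans(blobs$x))

  # states are ordered by decreasing occupancy
  expect_true(!is.unsorted(rev(tabulate(model$labels, 4))))

  expect_error(cluster_states(blobs$x[1:3, ], k = 5), "exceeds")
})

test_that("best-of-replicates selection picks the lowest inertia", {
  blobs <- make_blobs(n_per = 30, k = 3, seed = 6)
  model <- cluster_states(blobs$x, k = 3, replicates = 8, seed = 4)
  # each replicate, re-run standalone, cannot beat the selected model
  for (s in model$replicate_seeds[1:4]) {
    set.seed(s)
    cen <- fbconn:::.kmeanspp_centers(blobs$x, 3)
    km <- suppressWarnings(stats::kmeans(blobs$x, cen, iter.max = 100,
                                         algorithm = "Lloyd"))
    expect_gte(km$tot.withinss, model$inertia - 1e-8)
  }
})

test_that("elbow curve is non-increasing with zero floor at distinct rows", {
  set.seed(13)
  x <- matrix(rnorm(60 * 4), 60)
  curve <- elbow_curve(x, 1:6, replicates = 5, seed = 2)
  expect_true(all(diff(curve$inertia) <= 1e-8))

  blobs <- make_blobs(n_per = 25, k = 4, seed = 3)
  cb <- elbow_curve(blobs$x, 1:6, replicates = 5, seed = 2)
  drops <- -diff(cb$inertia) / cb$inertia[-length(cb$inertia)]
  expect_equal(which.max(drops) + 1, 4)   # largest relative drop at true k

  xu <- matrix(rnorm(5 * 3), 5)
  expect_lt(elbow_curve(xu, 5, replicates = 2, seed = 1)$inertia, 1e-20)
})

test_that("fraction rates conserve mass and match expectations", {
  # all observations in one state
  obs <- fake_obs(matrix(0, 40, 1), subject = rep("s1", 40),
                  band = rep(1:2, each = 20))
  fr <- fraction_rates(fake_model(rep(1L, 40), k = 3), obs)
  expect_equal(fr$overall["s1", ], c(1, 0, 0), ignore_attr = TRUE)
  expect_equal(fr$per_band["s1", , 1], c(1, 0, 0), ignore_attr = TRUE)

  # uniform random labels over k = 8: each fraction near 1/8
  set.seed(77)
  n <- 4000
  labels <- sample.int(8, n, replace = TRUE)
  obs <- fake_obs(matrix(0, n, 1), subject = rep("s1", n),
                  band = rep(1:2, each = n / 2))
  fr <- fraction_rates(fake_model(labels, k = 8), obs)
  ci <- 3 * sqrt((1 / 8) * (7 / 8) / (n / 2))
  expect_true(all(abs(fr$per_band["s1", , ] - 1 / 8) < ci))

  # conservation for every subject x band
  expect_equal(colSums(fr$per_band["s1", , ]), c(1, 1), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(fr$per_band >= 0 & fr$per_band <= 1))
})

test_that("centroid similarity is pairwise Pearson correlation", {
  set.seed(41)
  a <- matrix(rnorm(3 * 10), 3)
  expect_equal(diag(centroid_similarity(a, a)), rep(1, 3))
  expect_equal(diag(centroid_similarity(a, -a)), rep(-1, 3))
  sim <- centroid_similarity(a, a[c(2, 1, 3), ])
  for (i in 1:3) for (j in 1:3)
    expect_equal(sim[i, j], cor(a[i, ], a[c(2, 1, 3), ][j, ]))
  flat <- rbind(a[1:2, ], rep(1, 10))
  expect_warning(s2 <- centroid_similarity(flat, a), "zero-variance")
  expect_true(all(is.na(s2[3, ])))
})

test_that("state matching is an exact optimal assignment", {
  set.seed(51)
  ref <- matrix(rnorm(4 * 12), 4)
  # permuted reference is recovered exactly
  perm <- c(3, 1, 4, 2)
  m <- match_states(ref[perm, ], ref)
  expect_equal(m$assignment, order(perm))
  expect_equal(m$correlations, rep(1, 4))

  # a sign flip matches at -1
  est <- ref; est[2, ] <- -est[2, ]
  m2 <- match_states(est, ref)
  expect_equal(m2$assignment, 1:4)
  expect_equal(m2$correlations[2], -1)

  # random case equals exhaustive search over all 24 assignments
  est <- matrix(rnorm(4 * 12), 4)
  sim <- centroid_similarity(est, ref)
  perms <- rbind(
    do.call(rbind, lapply(1:4, function(a)
      do.call(rbind, lapply(setdiff(1:4, a), function(b) {
        rest <- setdiff(1:4, c(a, b))
        rbind(c(a, b, rest), c(a, b, rev(rest)))
      })))))
  scores <- apply(perms, 1, function(p) sum(sim[cbind(p, 1:4)]))
  m3 <- match_states(est, ref)
  expect_equal(sum(m3$correlations), max(scores), tolerance = 1e-12)

  expect_error(match_states(est[1:3, ], ref), "equally many")
})
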