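# Connectivity-state clustering and fraction-rate frequency profiles.

#' Assemble a clustering observation matrix
#'
#' Concatenates banded connectivity across subjects and bands into one matrix
#' (rows = observations, columns = pair features), with a deterministic
#' (subject, band, time) row order. Rows containing missing values are dropped
#' with a warning reporting the count.
#'
#' @param banded A single [apply_filter_bank()] result or a list of them (one
#'   per subject).
#' @return Object of class `observation_matrix` with `values` (rows x P),
#'   `row_index` (data frame: `subject`, `band`, `time`), `pair_index`,
#'   `n_bands`, `n_dropped`.
#' @export
assemble_observations <- function(banded) {
  if (inherits(banded, "banded_connectivity")) banded <- list(banded)
  stopifnot(length(banded) >= 1,
            all(vapply(banded, inherits, TRUE, "banded_connectivity")))
  ref <- banded[[1]]
  for (b in banded[-1]) {
    if (!identical(dim(b$values)[c(1, 3)], dim(ref$values)[c(1, 3)]) &&
        dim(b$values)[3] != dim(ref$values)[3])
      stop("subjects have mismatched band or pair dimensions")
    if (!identical(b$pair_index, ref$pair_index))
      stop("subjects have mismatched pair ordering")
    if (!identical(vapply(b$bank$filters, function(f) f$passband_edges, numeric(2)),
                   vapply(ref$bank$filters, function(f) f$passband_edges, numeric(2))))
      stop("subjects were filtered with different banks")
    if (b$window$half_width != ref$window$half_width)
      stop("subjects use different window specifications")
  }
  blocks <- list(); idx <- list(); k <- 0L
  for (s in seq_along(banded)) {
    arr <- banded[[s]]$values
    sid <- banded[[s]]$subject_id
    for (band in seq_len(dim(arr)[1])) {
      k <- k + 1L
      blocks[[k]] <- arr[band, , , drop = TRUE]
      if (!is.matrix(blocks[[k]]))
        blocks[[k]] <- matrix(blocks[[k]], ncol = dim(arr)[3])
      idx[[k]] <- data.frame(subject = sid, band = band,
                             time = seq_len(dim(arr)[2]))
    }
  }
  values <- do.call(rbind, blocks)
  row_index <- do.call(rbind, idx)
  drop <- rowSums(is.na(values)) > 0
  if (any(drop)) {
    warning(sum(drop), " observation row(s) with missing values dropped")
    values <- values[!drop, , drop = FALSE]
    row_index <- row_index[!drop, , drop = FALSE]
  }
  structure(list(values = values, row_index = row_index,
                 pair_index = ref$pair_index,
                 n_bands = dim(ref$values)[1], n_dropped = sum(drop)),
            class = "observation_matrix")
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat("<observation_matrix> ", nrow(x$values), " observations x ",
      ncol(x$values), " pair features (",
      length(unique(x$row_index$subject)), " subject(s), ",
      x$n_bands, " band(s))\n", sep = "")
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then each
# new center sampled with probability proportional to squared distance to the
# nearest chosen center
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  cen <- matrix(NA_real_, k, ncol(x))
  cen[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, cen[1, ])^2)
    for (j in 2:k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1, prob = d2) else sample.int(n, 1)
      cen[j, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, cen[j, ])^2))
    }
  }
  cen
}

#' Cluster connectivity observations into states
#'
#' k-means with squared Euclidean distance, k-means++ initialization, and
#' best-of-`replicates` selection by within-cluster sum of squares. States are
#' relabeled in order of decreasing overall occupancy for stable reporting.
#'
#' @param obs An [assemble_observations()] result (or plain numeric matrix).
#' @param k Number of states (default 8).
#' @param replicates Number of restarts (default 30).
#' @param seed Integer seed; all replicate seeds derive from it.
#' @param scale_features Standardize columns before clustering (default FALSE;
#'   the raw filtered connectivity values are clustered).
#' @param iter_max Lloyd iteration cap per replicate.
#' @return Object of class `state_model`: `k`, `centroids` (k x P), `labels`,
#'   `inertia`, `replicate_seeds`, `scale_features`, plus the centering/scaling
#'   used (if any).
#' @export
cluster_states <- function(obs, k = 8L, replicates = 30L, seed = 1L,
                           scale_features = FALSE, iter_max = 100L) {
  x <- if (inherits(obs, "observation_matrix")) obs$values else as.matrix(obs)
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (nrow(x) < k) stop("k = ", k, " exceeds number of observations ", nrow(x))
  scl <- NULL
  if (scale_features) {
    scl <- list(center = colMeans(x), sd = apply(x, 2, stats::sd))
    scl$sd[scl$sd == 0] <- 1
    x <- sweep(sweep(x, 2, scl$center), 2, scl$sd, "/")
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  best <- NULL
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    cen <- .kmeanspp_centers(x, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = cen, iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("all k-means replicates failed (empty clusters?)")
  # deterministic state order: decreasing occupancy, ties by first appearance
  counts <- tabulate(best$cluster, nbins = k)
  ord <- order(-counts, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(k = as.integer(k),
                 centroids = best$centers[ord, , drop = FALSE],
                 labels = relabel[best$cluster],
                 inertia = best$tot.withinss,
                 replicate_seeds = rep_seeds,
                 scale_features = scale_features, scaling = scl),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("<state_model> k = ", x$k, ", ", length(x$labels),
      " observations, inertia = ", format(x$inertia), "\n", sep = "")
  invisible(x)
}

#' Within-cluster distance across candidate k (elbow curve)
#'
#' @param obs Observations as in [cluster_states()].
#' @param k_values Integer vector of cluster counts to evaluate.
#' @param replicates,seed Passed to [cluster_states()].
#' @return Data frame with `k` and `inertia` (total within-cluster sum of
#'   squares of the best replicate).
#' @export
elbow_curve <- function(obs, k_values, replicates = 30L, seed = 1L) {
  res <- vapply(k_values, function(k)
    cluster_states(obs, k = k, replicates = replicates, seed = seed)$inertia,
    0)
  data.frame(k = k_values, inertia = res)
}

#' Fraction rates per state, per band and overall
#'
#' For each subject, the fraction of (retained) time points assigned to each
#' state, computed within every band separately and across all bands combined.
#' A state's fraction-rate profile across bands is its connectivity frequency
#' profile.
#'
#' @param model A [cluster_states()] result.
#' @param obs The [assemble_observations()] result it was fit to.
#' @return Object of class `fraction_rate_table`: `per_band` (array
#'   subject x state x band), `overall` (matrix subject x state), `subjects`,
#'   `k`, `n_bands`.
#' @export
fraction_rates <- function(model, obs) {
  stopifnot(inherits(model, "state_model"),
            inherits(obs, "observation_matrix"))
  if (length(model$labels) != nrow(obs$values))
    stop("label count does not match observation count")
  subjects <- unique(obs$row_index$subject)
  k <- model$k; nb <- obs$n_bands
  per_band <- array(NA_real_, c(length(subjects), k, nb),
                    dimnames = list(subjects, paste0("state", seq_len(k)),
                                    paste0("band", seq_len(nb))))
  overall <- matrix(NA_real_, length(subjects), k,
                    dimnames = list(subjects, paste0("state", seq_len(k))))
  empty <- 0L
  for (s in seq_along(subjects)) {
    in_s <- obs$row_index$subject == subjects[s]
    overall[s, ] <- tabulate(model$labels[in_s], nbins = k) / sum(in_s)
    for (b in seq_len(nb)) {
      in_sb <- in_s & obs$row_index$band == b
      if (!any(in_sb)) { empty <- empty + 1L; next }
      per_band[s, , b] <- tabulate(model$labels[in_sb], nbins = k) / sum(in_sb)
    }
  }
  if (empty > 0)
    warning(empty, " empty subject-band cell(s); fractions left missing")
  structure(list(per_band = per_band, overall = overall,
                 subjects = subjects, k = k, n_bands = nb),
            class = "fraction_rate_table")
}

#' @export
print.fraction_rate_table <- function(x, ...) {
  cat("<fraction_rate_table> ", length(x$subjects), " subject(s) x ",
      x$k, " states x ", x$n_bands, " band(s)\n", sep = "")
  invisible(x)
}

#' Tidy data frame of fraction rates
#'
#' @param x A [fraction_rates()] result.
#' @return Data frame with `subject`, `state`, `band` (`"all"` for the
#'   overall rates) and `fraction`.
#' @export
fraction_rates_long <- function(x) {
  stopifnot(inherits(x, "fraction_rate_table"))
  rows <- list()
  for (s in seq_along(x$subjects)) {
    rows[[length(rows) + 1L]] <- data.frame(
      subject = x$subjects[s], state = seq_len(x$k), band = "all",
      fraction = x$overall[s, ])
    for (b in seq_len(x$n_bands))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = x$subjects[s], state = seq_len(x$k),
        band = as.character(b), fraction = x$per_band[s, , b])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between two sets of centroids
#'
#' Pearson correlation between every pair of vectorized centroids (rows).
#'
#' @param a,b Centroid matrices (states x features) or `state_model` objects.
#' @return Matrix `nrow(a)` x `nrow(b)` of correlations; zero-variance
#'   centroids give missing entries with a warning.
#' @export
centroid_similarity <- function(a, b) {
  a <- if (inherits(a, "state_model")) a$centroids else as.matrix(a)
  b <- if (inherits(b, "state_model")) b$centroids else as.matrix(b)
  if (ncol(a) != ncol(b)) stop("centroid feature lengths differ")
  flat_a <- apply(a, 1, stats::sd) == 0
  flat_b <- apply(b, 1, stats::sd) == 0
  if (any(flat_a) || any(flat_b))
    warning("zero-variance centroid(s); corresponding entries are missing")
  out <- suppressWarnings(stats::cor(t(a), t(b)))
  out[flat_a, ] <- NA_real_
  out[, flat_b] <- NA_real_
  out
}

# exact optimal assignment maximizing total score, by dynamic programming
# over subsets of columns (O(k^2 2^k)); deterministic tie-break: the DP
# scans rows in order and keeps the first maximizer
.optimal_assignment <- function(score) {
  k <- nrow(score)
  nstates <- bitwShiftL(1L, k)
  val <- rep(-Inf, nstates); val[1] <- 0
  choice <- matrix(NA_integer_, nstates, 1)
  for (mask in 0:(nstates - 1)) {
    if (!is.finite(val[mask + 1])) next
    i <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) != 0) + 1L  # next row
    if (i > k) next
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0) next
      nm <- bitwOr(mask, bit)
      cand <- val[mask + 1] + score[i, j]
      if (cand > val[nm + 1] + 1e-15) {
        val[nm + 1] <- cand
        choice[nm + 1, 1] <- j
      }
    }
  }
  # backtrack
  assign <- integer(k)
  mask <- nstates - 1L
  for (i in k:1) {
    j <- choice[mask + 1, 1]
    assign[i] <- j
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  assign
}

#' Match estimated states to reference states
#'
#' One-to-one assignment of estimated to reference centroids maximizing the
#' total Pearson correlation (exact optimal assignment, not greedy).
#'
#' @param estimated,reference Centroid matrices (same number of rows and same
#'   feature length) or `state_model` objects.
#' @return List with `assignment` (for each reference index, the matched
#'   estimated index) and `correlations` (the matched correlation per
#'   reference).
#' @export
match_states <- function(estimated, reference) {
  est <- if (inherits(estimated, "state_model")) estimated$centroids else as.matrix(estimated)
  ref <- if (inherits(reference, "state_model")) reference$centroids else as.matrix(reference)
  if (nrow(est) != nrow(ref))
    stop("need equally many estimated and reference states (",
         nrow(est), " vs ", nrow(ref), ")")
  sim <- centroid_similarity(est, ref)   # est x ref
  if (anyNA(sim)) stop("cannot match states: missing similarity entries")
  # rows of the DP = reference states, columns = estimated states
  assign <- .optimal_assignment(t(sim))
  list(assignment = assign,
       correlations = sim[cbind(assign, seq_len(nrow(ref)))])
}
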