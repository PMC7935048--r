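# Two-group comparison of fraction rates with false-discovery-rate control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: monotone, capped at 1. A comparison is significant
#' when its adjusted p-value is at or below `q`.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and logical `significant`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= q)
}

# Welch t or Mann-Whitney comparison of one state's fractions; returns
# c(statistic, p). Degenerate (zero-variance) inputs are resolved by the
# mean difference: equal means give (0, 1).
.two_sample <- function(xa, xb, test) {
  if (test == "wilcoxon") {
    ht <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
    return(c(statistic = unname(ht$statistic), p = ht$p.value))
  }
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
    d <- mean(xa) - mean(xb)
    if (d == 0) return(c(statistic = 0, p = 1))
    return(c(statistic = sign(d) * Inf, p = 0))
  }
  ht <- stats::t.test(xa, xb, var.equal = FALSE)
  c(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Compare fraction rates between two groups
#'
#' Per-state two-sample test (Welch's unequal-variance t-test by default, or
#' Mann-Whitney) of subject fraction rates between exactly two groups, with
#' Benjamini-Hochberg correction across the states. With `scope = "per_band"`
#' the comparison is repeated within every band, correcting across states
#' within each band.
#'
#' @param table A [fraction_rates()] result.
#' @param groups Named vector/factor mapping subject IDs to group labels
#'   (exactly two distinct labels, at least two subjects per group).
#' @param scope `"overall"` (default) or `"per_band"`.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param q_level FDR level (default 0.05).
#' @return Object of class `group_comparison`: a data frame `results` with
#'   columns `state`, (`band`,) group means, `statistic`, `raw_p`,
#'   `adjusted_p`, `significant`, plus `q_level`, `n_comparisons`, `groups`.
#' @export
compare_fraction_rates <- function(table, groups, scope = c("overall", "per_band"),
                                   test = c("welch", "wilcoxon"),
                                   q_level = 0.05) {
  stopifnot(inherits(table, "fraction_rate_table"))
  scope <- match.arg(scope); test <- match.arg(test)
  groups <- groups[table$subjects]
  if (anyNA(groups)) stop("missing group label for some subject(s)")
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2) stop("need exactly two group labels, got ", length(lv))
  ga <- table$subjects[groups == lv[1]]
  gb <- table$subjects[groups == lv[2]]
  if (length(ga) < 2 || length(gb) < 2)
    stop("each group needs at least 2 subjects (", lv[1], ": ", length(ga),
         ", ", lv[2], ": ", length(gb), ")")

  one_scope <- function(mat, band = NA) {
    res <- t(vapply(seq_len(table$k), function(s)
      .two_sample(mat[ga, s], mat[gb, s], test), c(statistic = 0, p = 0)))
    fdr <- fdr_correct(res[, "p"], q = q_level)
    data.frame(state = seq_len(table$k), band = band,
               mean_a = colMeans(mat[ga, , drop = FALSE]),
               mean_b = colMeans(mat[gb, , drop = FALSE]),
               statistic = res[, "statistic"], raw_p = res[, "p"],
               adjusted_p = fdr$adjusted, significant = fdr$significant)
  }

  results <- if (scope == "overall") {
    one_scope(table$overall)
  } else {
    do.call(rbind, lapply(seq_len(table$n_bands), function(b)
      one_scope(table$per_band[, , b], band = b)))
  }
  if (scope == "overall") results$band <- NULL
  rownames(results) <- NULL
  names(results)[names(results) == "mean_a"] <- paste0("mean_", lv[1])
  names(results)[names(results) == "mean_b"] <- paste0("mean_", lv[2])
  structure(list(results = results, q_level = q_level,
                 n_comparisons = table$k, groups = lv, test = test,
                 scope = scope),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$groups[1], " vs ", x$groups[2], " (",
      x$test, ", ", x$scope, "), FDR q = ", x$q_level, "\n", sep = "")
  print(x$results, digits = 4)
  invisible(x)
}
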