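# Subsample-bootstrap median test.
#
# For each feature, the deficiency-associated residues (small group) are
# compared to the remainder (large group) with a resampling procedure
# designed to be insensitive to the large difference in group sizes: in
# each of n_iter iterations, |small| elements are drawn from the large
# group (without replacement by default, i.e. a subsample) and the
# fraction of iterations in which the resampled median exceeds the small
# group's median is the one-sided p-value.

#' Subsample-bootstrap median test
#'
#' @param large numeric values of the larger group
#' @param small numeric values of the smaller group
#' @param n_iter resampling iterations (default 10000)
#' @param seed RNG seed; the result is bit-reproducible given the seed
#' @param replace draw with replacement (default `FALSE`: subsampling)
#' @param statistic summary compared per iteration; the median defines the
#'   p-value, the mean is available for exploration
#' @return object of class `fv_boot_test`: feature-agnostic list with
#'   n_small, n_large, n_iter, statistic values of both groups, `p_value`
#'   (= #\{stat(resample) > stat(small)\} / n_iter, a multiple of 1/n_iter)
#'   and its complement, and the seed
#' @export
bootstrap_median_test <- function(large, small, n_iter = 10000L, seed = 1L,
                                  replace = FALSE,
                                  statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  large <- large[!is.na(large)]; small <- small[!is.na(small)]
  n_small <- length(small); n_large <- length(large)
  if (n_small < 1L) stop("small group is empty")
  if (!replace && n_large < n_small) {
    stop("larger group smaller than the subsample size; use replace = TRUE")
  }
  stat <- if (statistic == "median") stats::median else mean
  stat_small <- stat(small)
  count <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_iter)) {
      if (stat(sample(large, n_small, replace = replace)) > stat_small) {
        hits <- hits + 1L
      }
    }
    hits
  })
  structure(
    list(n_small = n_small, n_large = n_large, n_iter = as.integer(n_iter),
         statistic = statistic,
         stat_small = stat_small, stat_large_full = stat(large),
         p_value = count / n_iter, p_complement = 1 - count / n_iter,
         seed = as.integer(seed), replace = replace),
    class = "fv_boot_test"
  )
}

#' @export
print.fv_boot_test <- function(x, ...) {
  cat(sprintf(
    "subsample-bootstrap %s test: n_small=%d n_large=%d iter=%d\n  %s(small)=%.4g %s(large)=%.4g  p=%.4g (complement %.4g)\n",
    x$statistic, x$n_small, x$n_large, x$n_iter,
    x$statistic, x$stat_small, x$statistic, x$stat_large_full,
    x$p_value, x$p_complement))
  invisible(x)
}

#' Per-feature group comparison of a feature matrix
#'
#' Runs [bootstrap_median_test()] for every registry feature, comparing
#' label-1 residues (small group) to label-0 residues (large group).
#' No multiple-testing correction is applied.
#'
#' @param fm feature matrix from [assemble_feature_matrix()] or
#'   [generate_feature_table()]
#' @param n_iter,seed,replace,statistic passed through; per-feature seeds
#'   are derived as `seed + feature index`
#' @return data.frame with one row per feature: feature, n_small, n_large,
#'   median_small, median_large_full, p_value, p_complement, seed
#' @export
compare_feature_groups <- function(fm, n_iter = 10000L, seed = 1L,
                                   replace = FALSE, statistic = "median") {
  stopifnot("label" %in% names(fm))
  feats <- intersect(feature_registry(), names(fm))
  res <- lapply(seq_along(feats), function(j) {
    f <- feats[j]
    t <- bootstrap_median_test(fm[[f]][fm$label == 0L], fm[[f]][fm$label == 1L],
                               n_iter = n_iter, seed = seed + j,
                               replace = replace, statistic = statistic)
    data.frame(feature = f, n_small = t$n_small, n_large = t$n_large,
               median_small = t$stat_small, median_large_full = t$stat_large_full,
               p_value = t$p_value, p_complement = t$p_complement,
               seed = t$seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
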