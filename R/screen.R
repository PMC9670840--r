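#' Univariate z-score outlier mask
#'
#' Flags values whose absolute standardized score, computed from the sample
#' mean and sample SD of the input in a single pass (no iterative
#' re-screening), exceeds the threshold. Used for line lengths, where the
#' screening convention is |z| > 3.
#'
#' @param values numeric vector (>= 2 values, nonzero SD).
#' @param threshold z cutoff, default 3.
#' @return Logical mask, `TRUE` = outlier.
#' @export
zscore_outliers <- function(values, threshold = 3) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero standard deviation")
  abs((values - mean(values)) / s) > threshold
}

#' Bivariate Mahalanobis outlier mask
#'
#' Flags points whose squared Mahalanobis distance from the sample mean,
#' using the maximum-likelihood (1/n) sample covariance in a single pass,
#' exceeds the threshold. The default threshold 13.82 is the chi-square(2)
#' quantile at p = 0.999 (13.8155 to four figures), i.e. the conventional
#' multivariate screening cutoff on the squared-distance scale.
#'
#' @param xy numeric matrix or data.frame with two columns (length, width).
#' @param threshold squared-distance cutoff, default 13.82.
#' @return Logical mask, `TRUE` = outlier.
#' @export
mahalanobis_outliers <- function(xy, threshold = 13.82) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 points")
  S <- stats::cov(xy) * (n - 1) / n
  if (!is.finite(det(S)) || det(S) < 1e-12)
    stop("singular sample covariance")
  stats::mahalanobis(xy, colMeans(xy), S) > threshold
}

#' Screen a particle table for outliers per shape category
#'
#' Applies the pre-mixture screening rules separately within each shape
#' category: lines are screened on length with an absolute standardized
#' value > `zscore_threshold`; films and fragments on (length, width) with a
#' squared Mahalanobis distance > `maha_threshold`. Screening is a single
#' pass (no re-estimation after removal).
#'
#' @param table particle data.frame.
#' @param zscore_threshold cutoff for lines (default 3 SD).
#' @param maha_threshold squared Mahalanobis cutoff for films and fragments
#'   (default 13.82, the chi-square(2) 0.999 quantile).
#' @return An object of class `screening`: list with `kept` and `removed`
#'   particle tables and a per-category `rules` summary.
#' @export
#' @examples
#' tab <- generate_particles(n = 2000, seed = 7)
#' s <- screen_particles(tab)
#' nrow(s$kept) + nrow(s$removed) == nrow(tab)
screen_particles <- function(table, zscore_threshold = 3, maha_threshold = 13.82) {
  out <- rep(FALSE, nrow(table))
  rules <- list()
  for (cat in intersect(CATEGORIES, unique(table$category))) {
    idx <- which(table$category == cat)
    if (cat == "line") {
      mask <- zscore_outliers(table$length_mm[idx], zscore_threshold)
      rule <- "zscore"; thr <- zscore_threshold
    } else {
      mask <- mahalanobis_outliers(
        cbind(table$length_mm[idx], table$width_mm[idx]), maha_threshold)
      rule <- "mahalanobis"; thr <- maha_threshold
    }
    out[idx[mask]] <- TRUE
    rules[[cat]] <- data.frame(category = cat, rule = rule, threshold = thr,
                               n = length(idx), n_removed = sum(mask),
                               stringsAsFactors = FALSE)
  }
  structure(list(kept = table[!out, , drop = FALSE],
                 removed = table[out, , drop = FALSE],
                 rules = do.call(rbind, rules)),
            class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  cat(sprintf("Outlier screening: removed %d of %d particles\n",
              nrow(x$removed), nrow(x$removed) + nrow(x$kept)))
  print(x$rules, row.names = FALSE)
  invisible(x)
}
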