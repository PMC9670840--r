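#' Information criteria for a mixture fit
#'
#' AIC = -2*loglik + 2p and BIC = -2*loglik + p*log(N), with p the
#' constrained free-parameter count.
#'
#' @param loglik maximized log-likelihood (or a `mixture_fit`).
#' @param npar free-parameter count (ignored when a fit is given).
#' @param N sample size (ignored when a fit is given).
#' @return Named numeric vector with `AIC` and `BIC`.
#' @export
#' @examples
#' information_criteria(-100, 3, 50)
information_criteria <- function(loglik, npar, N) {
  if (inherits(loglik, "mixture_fit")) {
    fit <- loglik
    loglik <- fit$loglik; npar <- fit$npar; N <- fit$N
  }
  c(AIC = -2 * loglik + 2 * npar, BIC = -2 * loglik + npar * log(N))
}

#' Normalized entropy of a posterior classification matrix
#'
#' Returns `1 - sum(-P log P) / (N log K)`, with `0 log 0 := 0`. 1 means
#' perfectly separated classes, 0 maximal confusion (uniform posteriors).
#'
#' @param P N x K posterior matrix (rows sum to 1); structural zeros allowed.
#' @return Scalar in `[0, 1]`.
#' @export
entropy_normalized <- function(P) {
  P <- as.matrix(P)
  K <- ncol(P)
  if (K < 2) stop("entropy is undefined for K = 1")
  Pl <- P * log(P) # 0 * log(0) := 0
  Pl[P == 0] <- 0
  H <- -sum(Pl)
  1 - H / (nrow(P) * log(K))
}

#' Average posterior classification probability per class (AvePP)
#'
#' For each class k, the mean posterior probability of class k among
#' particles modally assigned to k. A class with no modal members is
#' reported as `NA` with a warning.
#'
#' @param P N x K posterior matrix.
#' @param type `"class_average"` (AvePP, default) or `"per_particle"`
#'   (per class, the minimum modal probability among its members).
#' @return Numeric vector of length K.
#' @seealso [min_posterior_prob()]
#' @export
avepp <- function(P, type = c("class_average", "per_particle")) {
  type <- match.arg(type)
  P <- as.matrix(P)
  modal <- max.col(P, ties.method = "first")
  out <- vapply(seq_len(ncol(P)), function(k) {
    members <- modal == k
    if (!any(members)) return(NA_real_)
    if (type == "class_average") mean(P[members, k]) else min(P[members, k])
  }, numeric(1))
  if (anyNA(out)) warning("class(es) with no modal members: ",
                          paste(which(is.na(out)), collapse = ", "))
  out
}

#' Minimum posterior classification probability over classes
#'
#' @inheritParams avepp
#' @return The minimum of [avepp()] over classes with modal members.
#' @export
min_posterior_prob <- function(P, type = c("class_average", "per_particle")) {
  min(avepp(P, type), na.rm = TRUE)
}

#' Bootstrapped likelihood-ratio test for K vs K-1 classes
#'
#' Parametric bootstrap: both models are fitted to the data and the observed
#' statistic `2 * (loglik_K - loglik_{K-1})` is referred to its bootstrap
#' distribution under the fitted (K-1)-class model. The p-value is
#' `(1 + #{LRT_b >= LRT_obs}) / (B + 1)`.
#'
#' @param x data as in [fit_mixture()].
#' @param K number of classes of the larger model (>= 2).
#' @param covariance covariance structure for both models.
#' @param B bootstrap replicates (>= 19).
#' @param n_starts,max_iter,tol EM settings used for all fits (kept modest by
#'   default because the bootstrap refits 2B models).
#' @param seed integer seed driving data simulation and refits.
#' @param max_retries per-replicate refit retries before aborting.
#' @return List with `p_value`, `lrt_obs`, `lrt_boot`, and both fits.
#' @export
blrt <- function(x, K, covariance = c("equal", "free"), B = 100,
                 n_starts = 5, max_iter = 1000, tol = 1e-7, seed = NULL,
                 max_retries = 3) {
  covariance <- match.arg(covariance)
  if (K < 2) stop("K must be >= 2")
  if (B < 19) stop("B must be >= 19")
  seeds <- derive_seeds(seed, 2L + 2L * B * (1L + max_retries))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[[si]] }
  fit0 <- fit_mixture(x, K - 1, covariance, n_starts, max_iter, tol, seed = nxt())
  fit1 <- fit_mixture(x, K, covariance, n_starts, max_iter, tol, seed = nxt())
  lrt_obs <- max(0, 2 * (fit1$loglik - fit0$loglik))
  n <- fit0$N
  lrt_boot <- numeric(B)
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      xb <- .simulate_fit(fit0, n, seed = nxt())
      r <- tryCatch({
        f0 <- suppressWarnings(fit_mixture(xb, K - 1, covariance, n_starts,
                                           max_iter, tol, seed = nxt()))
        f1 <- suppressWarnings(fit_mixture(xb, K, covariance, n_starts,
                                           max_iter, tol, seed = nxt()))
        max(0, 2 * (f1$loglik - f0$loglik))
      }, error = function(e) NULL)
      if (!is.null(r)) { lrt_boot[b] <- r; ok <- TRUE; break }
    }
    if (!ok) stop(sprintf("bootstrap replicate %d failed after %d retries", b, max_retries))
  }
  list(p_value = (1 + sum(lrt_boot >= lrt_obs)) / (B + 1),
       lrt_obs = lrt_obs, lrt_boot = lrt_boot,
       fit_small = fit0, fit_large = fit1)
}

#' Class-enumeration report over K = 1..K_max
#'
#' Fits mixtures with 1 to `K_max` classes and tabulates the five selection
#' criteria: BIC (with AIC for reference), the bootstrapped likelihood-ratio
#' test against K-1 classes, normalized entropy, the minimum average
#' posterior classification probability, and the smallest class share.
#' [select_classes()] turns the table into a chosen K with per-criterion
#' flags.
#'
#' @inheritParams fit_mixture
#' @param K_max largest number of classes to consider.
#' @param blrt_B bootstrap replicates for the BLRT column; `0` skips the
#'   BLRT (the column is `NA`).
#' @param blrt_starts EM starts used inside the bootstrap.
#' @return A `selection_report`: data.frame with one row per K and the list
#'   of fits in `attr(, "fits")`.
#' @export
enumerate_classes <- function(x, K_max = 5, covariance = c("equal", "free"),
                              n_starts = 20, blrt_B = 100, blrt_starts = 5,
                              max_iter = 2000, tol = 1e-8, seed = NULL) {
  covariance <- match.arg(covariance)
  seeds <- derive_seeds(seed, 2L * K_max)
  fits <- vector("list", K_max)
  rows <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    fit <- suppressWarnings(
      fit_mixture(x, K, covariance, n_starts, max_iter, tol, seed = seeds[[K]]))
    fits[[K]] <- fit
    p_blrt <- NA_real_
    if (K >= 2 && blrt_B >= 19) {
      p_blrt <- blrt(x, K, covariance, B = blrt_B, n_starts = blrt_starts,
                     seed = seeds[[K_max + K]])$p_value
    }
    rows[[K]] <- data.frame(
      K = K, loglik = fit$loglik, npar = fit$npar,
      AIC = fit$AIC, BIC = fit$BIC, blrt_p = p_blrt,
      entropy = fit$entropy,
      min_avepp = if (K >= 2) min_posterior_prob(fit$posterior) else 1,
      smallest_class = min(vapply(fit$params, `[[`, numeric(1), "weight"))
    )
  }
  report <- do.call(rbind, rows)
  class(report) <- c("selection_report", "data.frame")
  attr(report, "fits") <- fits
  report
}

#' Choose the number of classes from an enumeration report
#'
#' Walks K upward and retains K as long as, compared with K-1: the BIC
#' improves by more than `bic_tol` (smaller differences are treated as
#' non-decisive and resolved toward the smaller model, per Occam's razor),
#' the BLRT is significant at `alpha` (ignored when unavailable), the
#' smallest class holds at least `smallest_min` of the sample, and the
#' minimum average posterior classification probability is at least
#' `avepp_min`. The first K that fails stops the walk, so strengthening any
#' criterion can only lower the chosen K. All flags are returned so a human
#' can override.
#'
#' @param report a `selection_report` or a data.frame with columns `K`,
#'   `BIC`, `blrt_p`, `min_avepp`, `smallest_class` (and optionally
#'   `entropy`).
#' @param bic_tol BIC improvements at or below this are non-decisive
#'   (default 10).
#' @param alpha BLRT significance level.
#' @param avepp_min minimum acceptable AvePP (default 0.90).
#' @param smallest_min minimum acceptable smallest-class share (default 0.10).
#' @return List with `chosen_K`, a per-K `flags` data.frame, and `note`.
#' @export
select_classes <- function(report, bic_tol = 10, alpha = 0.05,
                           avepp_min = 0.90, smallest_min = 0.10) {
  if (!nrow(report)) stop("empty report")
  report <- report[order(report$K), , drop = FALSE]
  flags <- data.frame(K = report$K, bic_improves = NA, blrt_significant = NA,
                      smallest_ok = NA, avepp_ok = NA, retained = FALSE)
  chosen <- report$K[1]
  note <- character(0)
  flags$retained[1] <- TRUE
  for (i in seq_len(nrow(report))[-1]) {
    dbic <- report$BIC[i - 1] - report$BIC[i]
    flags$bic_improves[i] <- dbic > bic_tol
    flags$blrt_significant[i] <- if (is.na(report$blrt_p[i])) NA
      else report$blrt_p[i] < alpha
    flags$smallest_ok[i] <- report$smallest_class[i] >= smallest_min
    flags$avepp_ok[i] <- report$min_avepp[i] >= avepp_min
    pass <- isTRUE(flags$bic_improves[i]) &&
      !isFALSE(flags$blrt_significant[i]) &&
      flags$smallest_ok[i] && flags$avepp_ok[i]
    if (!pass) {
      if (!isTRUE(flags$bic_improves[i]) && dbic > 0)
        note <- c(note, sprintf(
          "K=%d: BIC improvement %.2f below tolerance %g; smaller model retained (Occam)",
          report$K[i], dbic, bic_tol))
      break
    }
    chosen <- report$K[i]
    flags$retained[i] <- TRUE
  }
  list(chosen_K = chosen, flags = flags,
       note = if (length(note)) paste(note, collapse = "; ") else "")
}
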