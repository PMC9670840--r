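# Cluster-robust covariance for mixture ML estimates.
#
# V = A^{-1} B A^{-1} with A the observed information (numerical Hessian of
# the mixture log-likelihood at the MLE, central finite differences with
# step 1e-5 * (1 + |theta|)) and B the outer product of per-cluster score
# sums. Parameters live on the reporting scale: free weights w_1..w_{K-1}
# (w_K by difference), per-class means and variances, one covariance per
# pooling group.

.theta_pack <- function(fit) {
  p <- fit$engine_params
  K <- fit$K
  th <- p$w[-K]
  nm <- paste0("w_", seq_len(K - 1))
  for (k in seq_len(K)) {
    lab <- gsub(" ", "", fit$params[[k]]$label)
    th <- c(th, p$mu[[k]], p$s2[[k]])
    nm <- c(nm, paste0("mu_", lab, "_", names(p$mu[[k]])),
            paste0("s2_", lab, "_", names(p$s2[[k]])))
  }
  for (g in unique(fit$pool[!is.na(fit$pool)])) {
    k <- which(fit$pool == g)[1]
    th <- c(th, p$cv[k])
    nm <- c(nm, paste0("cov_g", g))
  }
  stats::setNames(th, nm)
}

.theta_unpack <- function(theta, fit) {
  K <- fit$K
  p <- fit$engine_params
  i <- K - 1
  w <- c(theta[seq_len(K - 1)], 1 - sum(theta[seq_len(K - 1)]))
  mu <- p$mu; s2 <- p$s2; cv <- p$cv
  for (k in seq_len(K)) {
    d <- length(p$mu[[k]])
    mu[[k]][] <- theta[i + seq_len(d)]; i <- i + d
    s2[[k]][] <- theta[i + seq_len(d)]; i <- i + d
  }
  for (g in unique(fit$pool[!is.na(fit$pool)])) {
    i <- i + 1
    cv[which(fit$pool == g)] <- theta[i]
  }
  list(w = w, mu = mu, s2 = s2, cv = cv)
}

# log-likelihood (optionally restricted to a row subset) as a function of theta
.ll_theta <- function(theta, fit, rows = NULL) {
  params <- .theta_unpack(theta, fit)
  if (any(params$w <= 0) || any(unlist(params$s2) <= 0)) return(NA_real_)
  X <- fit$X; allowed <- fit$allowed
  if (!is.null(rows)) {
    X <- X[rows, , drop = FALSE]
    if (!is.null(allowed)) allowed <- allowed[rows, , drop = FALSE]
  }
  L <- sweep(.logdens(X, params, fit$class_def), 2, log(params$w), `+`)
  if (!is.null(allowed)) L[!allowed] <- -Inf
  sum(logrowsumexp(L))
}

.num_grad <- function(f, theta) {
  h <- 1e-5 * (1 + abs(theta))
  vapply(seq_along(theta), function(j) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    (f(tp) - f(tm)) / (2 * h[j])
  }, numeric(1))
}

.num_hess <- function(f, theta) {
  p <- length(theta)
  h <- 1e-5 * (1 + abs(theta))
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    tp <- theta; tp[i] <- tp[i] + h[i]
    tm <- theta; tm[i] <- tm[i] - h[i]
    H[i, i] <- (f(tp) - 2 * f0 + f(tm)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      tpp <- theta; tpp[i] <- tpp[i] + h[i]; tpp[j] <- tpp[j] + h[j]
      tpm <- theta; tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
      tmp <- theta; tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
      tmm <- theta; tmm[i] <- tmm[i] - h[i]; tmm[j] <- tmm[j] - h[j]
      H[i, j] <- H[j, i] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Cluster-robust (sandwich) standard errors for a mixture fit
#'
#' Computes `A^-1 B A^-1` where `A` is the observed information and `B` the
#' outer product of per-cluster score sums, clusters being sampling hauls.
#' This accounts for the nonindependence of particles collected in the same
#' haul. Model-based SEs (`A^-1` alone) are reported alongside; Wald 95%
#' intervals use the sandwich SEs, and variance parameters whose lower Wald
#' bound is negative are flagged (symmetric intervals on the variance scale
#' can undershoot zero).
#'
#' @param fit a converged `mixture_fit` or `joint_fit`.
#' @param cluster_ids vector of cluster (haul) identifiers, one per
#'   observation used in the fit; at least 2 distinct clusters.
#' @return data.frame with columns `parameter`, `estimate`, `se_model`,
#'   `se_sandwich`, `ci_lo`, `ci_hi`, `flag_negative_bound`. The full
#'   sandwich covariance is in `attr(, "vcov")`.
#' @export
sandwich_se <- function(fit, cluster_ids) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (length(cluster_ids) != fit$N)
    stop("cluster_ids must have one entry per observation")
  clusters <- split(seq_len(fit$N), cluster_ids)
  if (length(clusters) < 2) stop("need at least 2 clusters")
  theta <- .theta_pack(fit)

  A <- -.num_hess(function(th) .ll_theta(th, fit), theta)
  G <- t(vapply(clusters,
                function(rows) .num_grad(function(th) .ll_theta(th, fit, rows), theta),
                numeric(length(theta))))
  B <- crossprod(G)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular observed information; sandwich SEs unavailable"))
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  se_sw <- sqrt(pmax(diag(V), 0))
  se_mb <- sqrt(pmax(diag(Ainv), 0))

  # weight of the last class by the delta method (w_K = 1 - sum of free w)
  K <- fit$K
  iw <- seq_len(K - 1)
  one <- rep(1, K - 1)
  sw_last <- sqrt(max(drop(t(one) %*% V[iw, iw, drop = FALSE] %*% one), 0))
  mb_last <- sqrt(max(drop(t(one) %*% Ainv[iw, iw, drop = FALSE] %*% one), 0))
  lab_last <- paste0("w_", K)

  out <- data.frame(
    parameter = c(names(theta), lab_last),
    estimate = c(theta, 1 - sum(theta[iw])),
    se_model = c(se_mb, mb_last),
    se_sandwich = c(se_sw, sw_last),
    stringsAsFactors = FALSE
  )
  out$ci_lo <- out$estimate - stats::qnorm(0.975) * out$se_sandwich
  out$ci_hi <- out$estimate + stats::qnorm(0.975) * out$se_sandwich
  out$flag_negative_bound <- grepl("^s2_", out$parameter) & out$ci_lo < 0
  attr(out, "vcov") <- V
  attr(out, "n_clusters") <- length(clusters)
  out
}
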