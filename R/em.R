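# EM engine for normal mixtures over particle dimensions.
#
# Supports per-class univariate (length only; lines) and bivariate
# (length, width; films/fragments) components in one likelihood, membership
# restriction via structural zeros, and the constraint that the length-width
# covariance is shared across the classes of a pooling group while variances
# stay class-specific.
#
# The constrained M-step has no closed form: the moment solution (class
# scatter diagonals + pooled cross-moment) is used as a candidate and then
# refined by coordinate ascent on the exact Q function (1-D optimize over the
# shared covariance, per-class 2-D Nelder-Mead over the variances on an
# unconstrained parameterization). Only Q-improving moves are accepted, so
# every iteration is a generalized EM step and the observed-data
# log-likelihood is nondecreasing.

VAR_FLOOR <- 1e-6 # mm^2; prevents degenerate spikes

# per-class log density matrix N x K; X is N x 2 (col 2 NA for lines)
.logdens <- function(X, params, class_def) {
  K <- length(class_def)
  L <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    mu <- params$mu[[k]]; s2 <- params$s2[[k]]
    if (class_def[[k]]$use_width) {
      L[, k] <- logdbvn(X[, 1], X[, 2], mu[1], mu[2], s2[1], s2[2], params$cv[k])
    } else {
      L[, k] <- stats::dnorm(X[, 1], mu[1], sqrt(s2[1]), log = TRUE)
    }
  }
  L
}

# E-step: posteriors and log-likelihood, log-sum-exp stabilized
.estep <- function(X, params, class_def, allowed = NULL) {
  L <- sweep(.logdens(X, params, class_def), 2, log(params$w), `+`)
  if (!is.null(allowed)) L[!allowed] <- -Inf
  ll_i <- logrowsumexp(L)
  if (any(!is.finite(ll_i))) stop("non-finite mixture density")
  P <- exp(L - ll_i)
  list(P = P, loglik = sum(ll_i))
}

# Q contribution of the covariance structure of one pooled group,
# from per-class sufficient statistics (ML scatter about the class mean)
.q_group <- function(a, b, cc, Nk, Sxx, Syy, Sxy) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || !is.finite(cc)) return(-Inf)
  d <- a * b - cc * cc
  if (any(d <= 0) || any(a <= 0) || any(b <= 0)) return(-Inf)
  sum(-0.5 * Nk * (2 * log(2 * pi) + log(d) +
                     (b * Sxx - 2 * cc * Sxy + a * Syy) / d))
}

# maximize the group Q over (variances, shared covariance)
.solve_group <- function(a_old, b_old, c_old, Nk, Sxx, Syy, Sxy) {
  nk_tot <- sum(Nk)
  a <- pmax(Sxx, VAR_FLOOR); b <- pmax(Syy, VAR_FLOOR)
  cc <- sum(Nk * Sxy) / nk_tot
  lim <- 0.9999 * min(sqrt(a * b))
  cc <- sign(cc) * min(abs(cc), lim)
  q_cand <- .q_group(a, b, cc, Nk, Sxx, Syy, Sxy)
  q_old <- .q_group(a_old, b_old, c_old, Nk, Sxx, Syy, Sxy)
  if (is.finite(q_old) && q_old > q_cand) {
    a <- a_old; b <- b_old; cc <- c_old; q_best <- q_old
  } else q_best <- q_cand
  if (length(Nk) > 1L) { # pooled constraint active: refine on the exact Q
    for (round in 1:2) {
      lim <- 0.9999 * min(sqrt(a * b))
      opt <- stats::optimize(function(cv) .q_group(a, b, cv, Nk, Sxx, Syy, Sxy),
                             lower = -lim, upper = lim, maximum = TRUE,
                             tol = 1e-10)
      if (opt$objective > q_best) { cc <- opt$maximum; q_best <- opt$objective }
      for (k in seq_along(Nk)) {
        fk <- function(uv) {
          bk <- exp(uv[2]); ak <- cc * cc / bk + exp(uv[1])
          .q_group(ak, bk, cc, Nk[k], Sxx[k], Syy[k], Sxy[k])
        }
        init <- c(log(max(a[k] - cc * cc / b[k], 1e-10)), log(b[k]))
        o <- stats::optim(init, fk, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 200, reltol = 1e-12))
        cand_b <- exp(o$par[2]); cand_a <- cc * cc / cand_b + exp(o$par[1])
        q_new <- .q_group(replace(a, k, cand_a), replace(b, k, cand_b), cc,
                          Nk, Sxx, Syy, Sxy)
        if (q_new > q_best) { a[k] <- cand_a; b[k] <- cand_b; q_best <- q_new }
      }
    }
  }
  list(a = pmax(a, VAR_FLOOR), b = pmax(b, VAR_FLOOR), cc = cc,
       floor_hit = any(a <= VAR_FLOOR) || any(b <= VAR_FLOOR))
}

# M-step under the spec's constraint menu; pool[k] groups bivariate classes
# sharing a covariance (NA for univariate classes, distinct ids = free)
.mstep <- function(X, P, class_def, pool, params_old) {
  K <- length(class_def)
  Nk <- colSums(P)
  if (any(Nk < 1e-6)) stop("empty class in M-step (posterior mass ~ 0)")
  w <- Nk / nrow(X)
  mu <- vector("list", K); s2 <- vector("list", K)
  cv <- rep(NA_real_, K)
  Sxx <- Syy <- Sxy <- numeric(K)
  floor_hit <- FALSE
  for (k in seq_len(K)) {
    p <- P[, k]
    mx <- sum(p * X[, 1]) / Nk[k]
    dx <- X[, 1] - mx
    Sxx[k] <- sum(p * dx * dx) / Nk[k]
    if (class_def[[k]]$use_width) {
      # rows without width (lines) have structurally zero posterior here,
      # but 0 * NA would poison the sums
      y <- X[, 2]
      y[is.na(y)] <- 0
      my <- sum(p * y) / Nk[k]
      dy <- y - my
      Syy[k] <- sum(p * dy * dy) / Nk[k]
      Sxy[k] <- sum(p * dx * dy) / Nk[k]
      mu[[k]] <- c(length = mx, width = my)
    } else {
      mu[[k]] <- c(length = mx)
      s2[[k]] <- c(length = max(Sxx[k], VAR_FLOOR))
      floor_hit <- floor_hit || Sxx[k] < VAR_FLOOR
    }
  }
  for (g in unique(pool[!is.na(pool)])) {
    ks <- which(!is.na(pool) & pool == g)
    sol <- .solve_group(
      a_old = vapply(ks, function(k) params_old$s2[[k]][1], 0),
      b_old = vapply(ks, function(k) params_old$s2[[k]][2], 0),
      c_old = params_old$cv[ks[1]],
      Nk = Nk[ks], Sxx = Sxx[ks], Syy = Syy[ks], Sxy = Sxy[ks])
    for (j in seq_along(ks)) {
      s2[[ks[j]]] <- c(length = sol$a[j], width = sol$b[j])
      cv[ks[j]] <- sol$cc
    }
    floor_hit <- floor_hit || sol$floor_hit
  }
  list(w = w, mu = mu, s2 = s2, cv = cv, floor_hit = floor_hit)
}

.run_em <- function(X, params, class_def, pool, allowed, max_iter, tol) {
  ll_prev <- -Inf
  floor_hit <- FALSE
  trace_ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    e <- .estep(X, params, class_def, allowed)
    trace_ll <- c(trace_ll, e$loglik)
    if (is.finite(ll_prev) && e$loglik - ll_prev < tol) {
      return(list(params = params, loglik = e$loglik, P = e$P,
                  n_iter = it, converged = TRUE, floor_hit = floor_hit,
                  trace = trace_ll))
    }
    ll_prev <- e$loglik
    params <- .mstep(X, e$P, class_def, pool, params)
    floor_hit <- floor_hit || params$floor_hit
  }
  e <- .estep(X, params, class_def, allowed)
  list(params = params, loglik = e$loglik, P = e$P, n_iter = max_iter,
       converged = FALSE, floor_hit = floor_hit, trace = c(trace_ll, e$loglik))
}

# free-parameter count: (K-1) weights + means + variances + one covariance
# per pooling group (1 if equal across classes, K if free, 0 if univariate)
.count_npar <- function(class_def, pool) {
  K <- length(class_def)
  d <- vapply(class_def, function(cl) if (cl$use_width) 2L else 1L, 0L)
  (K - 1L) + 2L * sum(d) + length(unique(pool[!is.na(pool)]))
}

# k-means style initialization on standardized dimensions, with jitter
.init_start <- function(X, K, class_def, pool, start_seed) {
  if (!is.null(start_seed)) set.seed(start_seed)
  use_w <- vapply(class_def, `[[`, logical(1), "use_width")
  Z <- if (all(use_w)) X else X[, 1, drop = FALSE]
  Z <- scale(Z)
  if (K == 1L) {
    grp <- rep(1L, nrow(Z))
  } else {
    centers <- Z[sample.int(nrow(Z), K), , drop = FALSE] +
      matrix(stats::rnorm(K * ncol(Z), 0, 0.1), K)
    # note: kmeans would read a 1x1 centers matrix as a cluster *count*,
    # hence the explicit K == 1 branch above
    km <- tryCatch(stats::kmeans(Z, centers = centers, iter.max = 25),
                   error = function(e) NULL)
    grp <- if (is.null(km)) sample.int(K, nrow(Z), replace = TRUE) else km$cluster
  }
  # guard against empty groups
  for (k in seq_len(K)) if (!any(grp == k)) grp[sample.int(length(grp), 2)] <- k
  P <- matrix(1e-3, nrow(X), K)
  P[cbind(seq_len(nrow(X)), grp)] <- 1
  P <- P / rowSums(P)
  dummy <- list(w = rep(1 / K, K),
                mu = lapply(class_def, function(cl)
                  if (cl$use_width) c(length = 0, width = 0) else c(length = 0)),
                s2 = lapply(class_def, function(cl)
                  if (cl$use_width) c(length = 1, width = 1) else c(length = 1)),
                cv = ifelse(use_w, 0, NA_real_))
  .mstep(X, P, class_def, pool, dummy)
}

# order classes ascending by mean length (within category for joint fits)
.relabel <- function(params, P, class_def) {
  cats <- vapply(class_def, function(cl) cl$category %||% "all", "")
  ord <- integer(0)
  for (cat in unique(cats)) {
    ks <- which(cats == cat)
    ord <- c(ord, ks[order(vapply(ks, function(k) params$mu[[k]][1], 0))])
  }
  list(params = list(w = params$w[ord], mu = params$mu[ord],
                     s2 = params$s2[ord], cv = params$cv[ord]),
       P = P[, ord, drop = FALSE],
       class_def = class_def[ord])
}

#' Fit a Gaussian mixture to particle dimensions by EM
#'
#' Maximum-likelihood estimation of a K-class normal mixture over length
#' (univariate input) or length and width (two-column input), with the
#' covariance structure used for floating-debris latent class analysis:
#' means and variances vary freely across classes while the length-width
#' covariance is either held equal across classes (`"equal"`, the default,
#' matching the retained published models) or free per class (`"free"`).
#'
#' Estimation runs EM from `n_starts` k-means-style initializations on
#' standardized dimensions with jitter and keeps the solution with the
#' highest log-likelihood. The log-likelihood is nondecreasing at every
#' iteration (the constrained M-step only accepts Q-improving updates);
#' convergence is declared when the gain drops below `tol`. Classes are
#' relabeled ascending by mean length, so class 1 is always the
#' smaller-particle class. Variances are floored at 1e-6 mm^2; a fit that
#' ends on the floor carries a warning.
#'
#' @param x numeric vector of lengths, or a two-column matrix/data.frame of
#'   (length, width) in mm.
#' @param K number of latent classes (>= 1).
#' @param covariance `"equal"` (shared across classes) or `"free"`; ignored
#'   for univariate input.
#' @param n_starts number of random initializations (default 20).
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param seed integer seed controlling all initializations.
#' @return An object of class `mixture_fit`: parameters per class (`weight`,
#'   `mean`, `var`, `cov`, derived correlation), `loglik`, `npar`, `AIC`,
#'   `BIC`, the posterior matrix `posterior`, `entropy` (for K >= 2),
#'   `converged`, `n_iter`, and the data/structure needed for robust
#'   standard errors and bootstrapping.
#' @seealso [fit_joint()], [sandwich_se()], [blrt()]
#' @export
#' @examples
#' x <- c(rnorm(150, 2, 0.5), rnorm(100, 8, 2))
#' fit <- fit_mixture(x, K = 2, n_starts = 5, seed = 1)
#' fit$params[[2]]$mean
fit_mixture <- function(x, K, covariance = c("equal", "free"), n_starts = 20,
                        max_iter = 2000, tol = 1e-8, seed = NULL) {
  covariance <- match.arg(covariance)
  stop_if_not_count(K, "K")
  if (is.data.frame(x)) x <- as.matrix(x)
  dims <- if (is.matrix(x)) ncol(x) else 1L
  if (!dims %in% 1:2) stop("x must be a vector or a two-column matrix")
  X <- if (dims == 1L) cbind(as.numeric(x), NA_real_) else cbind(x[, 1], x[, 2])
  if (any(!is.finite(X[, 1])) || (dims == 2L && any(!is.finite(X[, 2]))))
    stop("data must be finite")
  N <- nrow(X)
  if (N <= K * dims) stop("too few observations for the requested model")
  class_def <- replicate(K, list(use_width = dims == 2L, category = NULL),
                         simplify = FALSE)
  pool <- if (dims == 2L) {
    if (covariance == "equal") rep(1L, K) else seq_len(K)
  } else rep(NA_integer_, K)

  if (K == 1L) {
    P <- matrix(1, N, 1)
    dummy <- .init_start(X, 1L, class_def, pool, start_seed = NULL)
    params <- .mstep(X, P, class_def, pool, dummy)
    e <- .estep(X, params, class_def)
    res <- list(params = params, loglik = e$loglik, P = e$P, n_iter = 0L,
                converged = TRUE, floor_hit = FALSE)
  } else {
    seeds <- derive_seeds(seed, n_starts)
    res <- NULL
    for (s in seq_len(n_starts)) {
      r <- tryCatch({
        init <- .init_start(X, K, class_def, pool, seeds[[s]])
        .run_em(X, init, class_def, pool, NULL, max_iter, tol)
      }, error = function(e) NULL)
      if (!is.null(r) && (is.null(res) || r$loglik > res$loglik)) res <- r
    }
    if (is.null(res)) stop("no EM start converged")
  }
  rel <- .relabel(res$params, res$P, class_def)
  if (res$floor_hit) warning("variance floor (1e-6 mm^2) hit during estimation")
  .build_fit(X, rel$params, rel$P, class_def, pool, res,
             covariance = covariance, allowed = NULL, category = NULL)
}

# assemble the public fit object
.build_fit <- function(X, params, P, class_def, pool, res, covariance,
                       allowed, category, labels = NULL) {
  K <- length(class_def)
  N <- nrow(X)
  npar <- .count_npar(class_def, pool)
  classes <- lapply(seq_len(K), function(k) {
    cl <- list(label = labels[k] %||% paste0("Class ", k),
               category = class_def[[k]]$category %||% NA_character_,
               weight = params$w[k], mean = params$mu[[k]], var = params$s2[[k]],
               cov = params$cv[k],
               r = if (class_def[[k]]$use_width)
                 params$cv[k] / sqrt(prod(params$s2[[k]])) else NA_real_)
    cl
  })
  ic <- information_criteria(res$loglik, npar, N)
  structure(list(
    K = K, covariance = covariance, N = N,
    params = classes, loglik = res$loglik, npar = npar,
    AIC = ic[["AIC"]], BIC = ic[["BIC"]],
    posterior = P,
    entropy = if (K >= 2) entropy_normalized(P) else NA_real_,
    converged = res$converged, n_iter = res$n_iter,
    floor_hit = res$floor_hit,
    loglik_trace = res$trace %||% res$loglik,
    X = X, class_def = class_def, pool = pool, allowed = allowed,
    category = category,
    engine_params = params
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-class normal mixture (N = %d, %s covariance)\n",
              x$K, x$N, x$covariance))
  cat(sprintf("  loglik = %.2f, npar = %d, AIC = %.2f, BIC = %.2f%s\n",
              x$loglik, x$npar, x$AIC, x$BIC,
              if (!is.na(x$entropy)) sprintf(", entropy = %.3f", x$entropy) else ""))
  if (!x$converged) cat("  WARNING: EM did not converge\n")
  for (cl in x$params) {
    r <- if (is.na(cl$r)) "" else sprintf(", r = %.3f", cl$r)
    cat(sprintf("  %-11s w = %.4f, M = (%s), s2 = (%s)%s\n",
                cl$label, cl$weight,
                paste(sprintf("%.3f", cl$mean), collapse = ", "),
                paste(sprintf("%.3f", cl$var), collapse = ", "), r))
  }
  invisible(x)
}

# simulate from a fitted mixture (used by the bootstrap LRT)
.simulate_fit <- function(fit, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- sample.int(fit$K, n, replace = TRUE,
                  prob = vapply(fit$params, `[[`, numeric(1), "weight"))
  X <- matrix(NA_real_, n, 2)
  for (j in seq_len(fit$K)) {
    idx <- which(k == j)
    if (!length(idx)) next
    cl <- fit$params[[j]]
    if (length(cl$mean) == 1L) {
      X[idx, 1] <- stats::rnorm(length(idx), cl$mean[1], sqrt(cl$var[1]))
    } else {
      s1 <- sqrt(cl$var[1]); s2 <- sqrt(cl$var[2])
      rho <- cl$cov / (s1 * s2)
      z1 <- stats::rnorm(length(idx)); z2 <- stats::rnorm(length(idx))
      X[idx, 1] <- cl$mean[1] + s1 * z1
      X[idx, 2] <- cl$mean[2] + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
    }
  }
  if (all(is.na(X[, 2]))) X[, 1] else X
}
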