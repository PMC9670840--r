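uni_def <- function(K) replicate(K, list(use_width = FALSE, category = NULL),
                                 simplify = FALSE)
biv_def <- function(K) replicate(K, list(use_width = TRUE, category = NULL),
                                 simplify = FALSE)

test_that("E-step posteriors and loglik match direct summation", {
  x <- c(1.2, 2.5, 3.1, 7.8, 9.0)
  X <- cbind(x, NA_real_)
  params <- list(w = c(0.4, 0.6), mu = list(c(length = 2), c(length = 8)),
                 s2 = list(c(length = 1.5), c(length = 4)), cv = c(NA, NA))
  e <- floatmix:::.estep(X, params, uni_def(2))
  expect_equal(e$loglik, oracle_loglik_uni(x, c(0.4, 0.6), c(2, 8), c(1.5, 4)),
               tolerance = 1e-10)
  expect_equal(rowSums(e$P), rep(1, 5), tolerance = 1e-10)
  # K = 1: posteriors exactly 1, loglik = sum of log normal densities
  e1 <- floatmix:::.estep(X, list(w = 1, mu = list(c(length = 3)),
                                  s2 = list(c(length = 2)), cv = NA), uni_def(1))
  expect_identical(unname(e1$P[, 1]), rep(1, 5))
  expect_equal(e1$loglik, sum(dnorm(x, 3, sqrt(2), log = TRUE)), tolerance = 1e-12)
  # two identical classes: posteriors equal the weights
  pp <- list(w = c(0.3, 0.7), mu = list(c(length = 4), c(length = 4)),
             s2 = list(c(length = 2), c(length = 2)), cv = c(NA, NA))
  esym <- floatmix:::.estep(X, pp, uni_def(2))
  expect_equal(esym$P, matrix(c(0.3, 0.7), 5, 2, byrow = TRUE), tolerance = 1e-12)
})

test_that("M-step recovers closed forms and pools the covariance correctly", {
  set.seed(8)
  X <- cbind(rnorm(40, 5, 2), rnorm(40, 3, 1))
  n <- nrow(X)
  ml_cov <- cov(X) * (n - 1) / n

  # all posterior mass in one class -> sample mean and ML covariance
  P1 <- matrix(1, n, 1)
  dummy <- list(w = 1, mu = list(c(length = 0, width = 0)),
                s2 = list(c(length = 1, width = 1)), cv = 0)
  m1 <- floatmix:::.mstep(X, P1, biv_def(1), pool = 1L, dummy)
  expect_equal(unname(m1$mu[[1]]), unname(colMeans(X)), tolerance = 1e-10)
  expect_equal(unname(m1$s2[[1]]), unname(diag(ml_cov)), tolerance = 1e-10)
  expect_equal(m1$cv[1], ml_cov[1, 2], tolerance = 1e-10)

  # duplicated identical memberships: pooled covariance equals single-class ML value
  P2 <- cbind(0.5, 0.5)[rep(1, n), ]
  dummy2 <- list(w = c(0.5, 0.5), mu = rep(list(c(length = 0, width = 0)), 2),
                 s2 = rep(list(c(length = 1, width = 1)), 2), cv = c(0, 0))
  m2 <- floatmix:::.mstep(X, P2, biv_def(2), pool = c(1L, 1L), dummy2)
  expect_equal(m2$cv[1], ml_cov[1, 2], tolerance = 1e-8)
  expect_equal(m2$cv[1], m2$cv[2])

  # free vs equal on the same posterior: identical means/weights, covariances differ
  set.seed(9)
  P3 <- matrix(runif(n * 2), n)
  P3 <- P3 / rowSums(P3)
  m_eq <- floatmix:::.mstep(X, P3, biv_def(2), pool = c(1L, 1L), dummy2)
  m_fr <- floatmix:::.mstep(X, P3, biv_def(2), pool = c(1L, 2L), dummy2)
  expect_equal(m_eq$mu, m_fr$mu, tolerance = 1e-10)
  expect_equal(m_eq$w, m_fr$w, tolerance = 1e-12)
  expect_equal(m_fr$cv[1] == m_fr$cv[2], FALSE)
  expect_equal(m_eq$cv[1], m_eq$cv[2])
})

test_that("K = 1 EM reproduces the analytic solution to 1e-8", {
  set.seed(21)
  X <- cbind(rnorm(200, 4, 1.5), rnorm(200, 2, 0.8))
  fit <- fit_mixture(X, K = 1)
  n <- nrow(X)
  ml_cov <- cov(X) * (n - 1) / n
  expect_equal(unname(fit$params[[1]]$mean), unname(colMeans(X)), tolerance = 1e-8)
  expect_equal(unname(fit$params[[1]]$var), unname(diag(ml_cov)), tolerance = 1e-8)
  expect_equal(fit$params[[1]]$cov, ml_cov[1, 2], tolerance = 1e-8)
  # loglik equals the direct bivariate normal loglik
  ll <- sum(mvtnorm_ll <- {
    S <- ml_cov; mu <- colMeans(X)
    d <- sweep(X, 2, mu)
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * rowSums((d %*% solve(S)) * d)
  })
  expect_equal(fit$loglik, ll, tolerance = 1e-8)

  x <- rnorm(50, 7, 2)
  f1 <- fit_mixture(x, K = 1)
  expect_equal(f1$params[[1]]$mean[["length"]], mean(x), tolerance = 1e-10)
  expect_equal(f1$params[[1]]$var[["length"]], var(x) * 49 / 50, tolerance = 1e-10)
})

test_that("EM loglik is monotone nondecreasing across data shapes and structures", {
  set.seed(55)
  cases <- list(
    list(x = c(rnorm(80, 0, 1), rnorm(60, 4, 2)), K = 2, cov = "equal"),
    list(x = cbind(c(rnorm(70, 2, 0.7), rnorm(90, 6, 2)),
                   c(rnorm(70, 1, 0.4), rnorm(90, 4, 1.5))), K = 2, cov = "equal"),
    list(x = cbind(rnorm(150, 3, 1), rnorm(150, 2, 0.6)), K = 3, cov = "free")
  )
  for (cs in cases) {
    fit <- suppressWarnings(fit_mixture(cs$x, cs$K, covariance = cs$cov,
                                        n_starts = 4, seed = 1))
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
    expect_equal(rowSums(fit$posterior), rep(1, fit$N), tolerance = 1e-10)
    expect_equal(sum(vapply(fit$params, `[[`, numeric(1), "weight")), 1,
                 tolerance = 1e-10)
    for (cl in fit$params) { # covariance matrices stay positive definite
      if (length(cl$var) == 2) expect_gt(prod(cl$var) - cl$cov^2, 0)
    }
  }
})

test_that("small-instance maximized loglik matches a direct-optimization oracle", {
  # two tight groups of four: the interior optimum dominates degenerate spikes
  x <- c(0.10, 0.22, 0.31, 0.40, 5.10, 5.19, 5.32, 5.45)
  fit <- fit_mixture(x, K = 2, n_starts = 10, seed = 3)
  expect_equal(fit$loglik, oracle_max_loglik_uni2(x), tolerance = 1e-4)

  # bivariate cross-check: direct optimization started at the EM solution
  # cannot improve the equal-covariance loglik by more than 1e-4
  set.seed(77)
  X <- cbind(c(rnorm(60, 1, 0.5), rnorm(60, 4, 1)),
             c(rnorm(60, 1, 0.4), rnorm(60, 3, 0.8)))
  fb <- fit_mixture(X, K = 2, covariance = "equal", n_starts = 6, seed = 2)
  nll <- function(th) {
    w <- plogis(th[1])
    m <- matrix(th[2:5], 2); v <- matrix(exp(th[6:9]), 2); cc <- th[10]
    if (cc^2 >= min(v[1, ] * v[2, ])) return(1e10)
    dens <- function(k, wk) {
      det <- v[1, k] * v[2, k] - cc^2
      dx <- X[, 1] - m[1, k]; dy <- X[, 2] - m[2, k]
      q <- (v[2, k] * dx^2 - 2 * cc * dx * dy + v[1, k] * dy^2) / det
      wk * exp(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
    }
    -sum(log(dens(1, w) + dens(2, 1 - w)))
  }
  # matrix(th[...], 2) is column-wise, so the layout is (len1, wid1, len2, wid2)
  th0 <- c(qlogis(fb$params[[1]]$weight),
           fb$params[[1]]$mean, fb$params[[2]]$mean,
           log(c(fb$params[[1]]$var, fb$params[[2]]$var)),
           fb$params[[1]]$cov)
  o <- suppressWarnings(optim(th0, nll, control = list(maxit = 3000, reltol = 1e-13)))
  expect_lt(-o$value - fb$loglik, 1e-4)
})

test_that("fits are invariant to row permutation up to relabeling", {
  set.seed(60)
  X <- cbind(c(rnorm(100, 2, 0.6), rnorm(80, 6, 1.5)),
             c(rnorm(100, 1.5, 0.4), rnorm(80, 4, 1)))
  f1 <- fit_mixture(X, K = 2, n_starts = 5, seed = 4)
  f2 <- fit_mixture(X[sample(nrow(X)), ], K = 2, n_starts = 5, seed = 4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$params[[1]]$mean, f2$params[[1]]$mean, tolerance = 1e-3)
})

test_that("free-parameter counts respect the constraint structure", {
  set.seed(14)
  x <- c(rnorm(100, 1), rnorm(100, 6))
  X <- cbind(x, rnorm(200, 2))
  expect_equal(fit_mixture(x, 2, n_starts = 3, seed = 1)$npar, 5)   # 1 weight + 2 means + 2 vars
  expect_equal(fit_mixture(X, 2, "equal", n_starts = 3, seed = 1)$npar, 10) # + 4 means + 4 vars + 1 shared cov
  expect_equal(fit_mixture(X, 2, "free", n_starts = 3, seed = 1)$npar, 11)  # shared cov -> 2 free covs
})

test_that("classes come back ordered by mean length with weights to match", {
  set.seed(91)
  x <- c(rnorm(200, 10, 1), rnorm(100, 2, 0.5)) # big class listed first on input
  f <- fit_mixture(x, K = 2, n_starts = 5, seed = 1)
  expect_lt(f$params[[1]]$mean[["length"]], f$params[[2]]$mean[["length"]])
  expect_lt(f$params[[1]]$weight, f$params[[2]]$weight)
})

test_that("degenerate inputs error cleanly", {
  expect_error(fit_mixture(c(1, 2), K = 3), "too few")
  expect_error(fit_mixture(c(1, 2, NA, 4), K = 1), "finite")
  expect_error(fit_mixture(rnorm(10), K = 0), "positive integer")
})
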