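test_that("information criteria follow their definitions", {
  ic <- information_criteria(-100, 3, 50)
  expect_equal(ic[["AIC"]], 206)
  expect_equal(ic[["BIC"]], 200 + 3 * log(50)) # 211.736
  ic0 <- information_criteria(-100, 0, 50)
  expect_equal(ic0[["AIC"]], ic0[["BIC"]])
  expect_equal(ic0[["AIC"]], 200)
  # BIC - AIC = p (ln N - 2) for any fit
  set.seed(3)
  f <- fit_mixture(rnorm(120, 5, 2), K = 2, n_starts = 3, seed = 1)
  expect_equal(f$BIC - f$AIC, f$npar * (log(f$N) - 2), tolerance = 1e-9)
})

test_that("normalized entropy spans confusion to perfect separation", {
  P_sep <- diag(3)[rep(1:3, 10), ]
  expect_equal(entropy_normalized(P_sep), 1)
  P_conf <- matrix(1 / 4, 20, 4)
  expect_equal(entropy_normalized(P_conf), 0)
  expect_error(entropy_normalized(matrix(1, 10, 1)), "K = 1")
  # invariant to class relabeling
  set.seed(12)
  P <- matrix(rexp(60), 20); P <- P / rowSums(P)
  expect_equal(entropy_normalized(P[, c(3, 1, 2)]), entropy_normalized(P))
  expect_true(entropy_normalized(P) >= 0 && entropy_normalized(P) <= 1)
})

test_that("AvePP handles separation, ties and relabeling", {
  P_sep <- diag(2)[rep(1:2, 15), ]
  expect_equal(min_posterior_prob(P_sep), 1)
  # two indistinguishable classes: everything ties at 0.5
  P_tie <- matrix(0.5, 30, 2)
  expect_warning(m <- min_posterior_prob(P_tie), "no modal members")
  expect_equal(m, 0.5)
  set.seed(4)
  P <- matrix(rexp(80), 20); P <- P / rowSums(P)
  expect_equal(sort(avepp(P[, c(2, 1, 4, 3)])), sort(avepp(P)))
  # per-particle variant bounds the class average from below
  expect_true(all(avepp(P, "per_particle") <= avepp(P) + 1e-12))
})

test_that("BLRT separates the obvious and validates its inputs", {
  set.seed(1)
  x <- c(rnorm(100, 0, 1), rnorm(80, 10, 1)) # 10 SDs apart
  b <- blrt(x, K = 2, B = 19, n_starts = 3, seed = 4)
  expect_equal(b$p_value, 1 / 20) # observed LRT beats every bootstrap draw
  b2 <- blrt(x, K = 2, B = 19, n_starts = 3, seed = 4)
  expect_identical(b$p_value, b2$p_value) # reproducible under fixed seed
  expect_identical(b$lrt_boot, b2$lrt_boot)
  expect_error(blrt(x, K = 2, B = 0), "B must be >= 19")
  expect_error(blrt(x, K = 1, B = 99), "K must be >= 2")
})

test_that("enumeration report carries the five criteria and picks 2 for a 2-class world", {
  set.seed(6)
  x <- c(rnorm(250, 2, 0.7), rnorm(150, 9, 2))
  # B = 39 so the smallest attainable p (1/40) clears alpha = 0.05
  rep <- enumerate_classes(x, K_max = 3, n_starts = 5, blrt_B = 39,
                           blrt_starts = 2, seed = 8)
  expect_equal(rep$K, 1:3)
  expect_true(all(c("BIC", "blrt_p", "entropy", "min_avepp", "smallest_class")
                  %in% names(rep)))
  expect_true(is.na(rep$blrt_p[1]))
  expect_true(all(diff(rep$loglik) > -1e-6)) # loglik nondecreasing in K
  sel <- select_classes(rep)
  expect_equal(sel$chosen_K, 2)
})

test_that("selection reproduces the published per-category decisions", {
  # lines: 3-class BIC only trivially lower, entropy favours 2 -> choose 2
  lines <- data.frame(K = 1:3, BIC = c(4000, 3700, 3694),
                      blrt_p = c(NA, 0.001, 0.001),
                      entropy = c(NA, 0.85, 0.62),
                      min_avepp = c(1, 0.95, 0.93),
                      smallest_class = c(1, 0.40, 0.25))
  expect_equal(select_classes(lines)$chosen_K, 2)
  expect_match(select_classes(lines)$note, "Occam")

  # fragments: 3-class min posterior 0.79 and smallest class 5% -> choose 2
  frags <- data.frame(K = 1:3, BIC = c(30000, 28000, 27500),
                      blrt_p = c(NA, 0.001, 0.001),
                      entropy = c(NA, 0.90, 0.95),
                      min_avepp = c(1, 0.93, 0.79),
                      smallest_class = c(1, 0.23, 0.05))
  expect_equal(select_classes(frags)$chosen_K, 2)

  single <- data.frame(K = 1, BIC = 1000, blrt_p = NA, entropy = NA,
                       min_avepp = 1, smallest_class = 1)
  expect_equal(select_classes(single)$chosen_K, 1)
  expect_error(select_classes(single[0, ]), "empty")
})

test_that("strengthening a criterion can only decrease the chosen K", {
  set.seed(9)
  for (i in 1:25) {
    Kmax <- sample(2:5, 1)
    rep <- data.frame(K = 1:Kmax,
                      BIC = cumsum(c(5000, -runif(Kmax - 1, 0, 400))),
                      blrt_p = c(NA, runif(Kmax - 1, 0, 0.2)),
                      entropy = runif(Kmax, 0.5, 1),
                      min_avepp = runif(Kmax, 0.7, 1),
                      smallest_class = runif(Kmax, 0.02, 0.5))
    base <- select_classes(rep)$chosen_K
    expect_lte(select_classes(rep, avepp_min = 0.97)$chosen_K, base)
    expect_lte(select_classes(rep, smallest_min = 0.3)$chosen_K, base)
    expect_lte(select_classes(rep, bic_tol = 200)$chosen_K, base)
    expect_lte(select_classes(rep, alpha = 0.01)$chosen_K, base)
  }
})

test_that("BLRT p-values are roughly uniform under the null (reduced scale)", {
  # scaled down for runtime: n = 100, B = 19, 24 replications
  pvals <- vapply(1:24, function(i) {
    set.seed(5000 + i)
    x <- rnorm(100)
    blrt(x, K = 2, B = 19, n_starts = 2, seed = i,
         max_iter = 150, tol = 1e-6)$p_value
  }, numeric(1))
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.7)
  expect_lte(mean(pvals <= 0.05), 0.2)
})
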