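# build a synthetic posterior with known separation: the intended class gets
# posterior `conf`, the remainder is spread over the others
fuzzy_posterior <- function(true, K, conf) {
  P <- matrix((1 - conf) / (K - 1), length(true), K)
  P[cbind(seq_along(true), true)] <- conf
  P
}

# a coherent classification world: the latent true class is drawn FROM each
# posterior row, so the posterior honestly describes assignment uncertainty
# (as a fitted mixture's posterior does) and D matches real misclassification
fuzzy_world <- function(n, K, conf, weights = rep(1 / K, K)) {
  intended <- sample.int(K, n, replace = TRUE, prob = weights)
  P <- fuzzy_posterior(intended, K, conf)
  true <- vapply(seq_len(n), function(i) sample.int(K, 1, prob = P[i, ]), 0L)
  list(P = P, true = true, modal = max.col(P, ties.method = "first"))
}

test_that("classification-error matrix behaves at the extremes", {
  P_sep <- diag(3)[rep(1:3, 8), ]
  expect_equal(classification_error_matrix(P_sep), diag(3))
  P_half <- matrix(0.5, 20, 2)
  expect_warning(D <- classification_error_matrix(P_half), "no modal members")
  expect_equal(unname(D[, 1]), c(1, 1)) # ties all assigned to class 1
  set.seed(2)
  true <- sample(1:6, 4000, replace = TRUE)
  D6 <- classification_error_matrix(fuzzy_posterior(true, 6, 0.9))
  expect_equal(unname(rowSums(D6)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(diag(D6) >= 0.8)) # consistent with strong separation
})

test_that("with D = identity the three-step test reduces to the naive cross-tab", {
  set.seed(3)
  assign <- sample(1:3, 600, replace = TRUE)
  outcome <- sample(c("PE", "PP", "other"), 600, replace = TRUE,
                    prob = c(0.8, 0.15, 0.05))
  res <- distal_categorical_test(assign, diag(3), outcome)
  expect_equal(unname(res$proportions), unname(res$naive), tolerance = 1e-12)
  naive_tab <- prop.table(table(assign, outcome), 1)
  expect_equal(unname(res$proportions), unname(matrix(naive_tab, 3)),
               tolerance = 1e-12)
})

test_that("three-step type-I error is controlled when profiles are identical", {
  set.seed(11)
  rejections <- vapply(1:40, function(i) {
    w <- fuzzy_world(900, 3, 0.85)
    D <- classification_error_matrix(w$P)
    outcome <- sample(c("PE", "PP"), 900, replace = TRUE, prob = c(0.85, 0.15))
    any(distal_categorical_test(w$modal, D, outcome)$tests$p_value < 0.05)
  }, logical(1))
  expect_lte(mean(rejections), 0.25) # ~alpha per outcome level
})

test_that("three-step detects class-dependent polymer composition at full size", {
  set.seed(12)
  n <- 6942
  w <- fuzzy_world(n, 6, 0.9, weights = c(289, 195, 714, 139, 4338, 1267) / 6942)
  D <- classification_error_matrix(w$P)
  pe_share <- c(0.95, 0.75, 0.95, 0.75, 0.95, 0.75)[w$true]
  outcome <- ifelse(runif(n) < pe_share, "PE", "PP")
  res <- distal_categorical_test(w$modal, D, outcome)
  expect_true(all(res$tests$df == 5))
  expect_true(all(res$tests$p_value < 0.001))
})

test_that("misclassification correction improves on the naive estimator on average", {
  set.seed(13)
  profiles <- rbind(c(0.95, 0.04, 0.01), c(0.70, 0.25, 0.05))
  tv <- replicate(30, {
    w <- fuzzy_world(700, 2, 0.8)
    D <- classification_error_matrix(w$P)
    outcome <- vapply(w$true, function(k)
      sample(c("PE", "PP", "other"), 1, prob = profiles[k, ]), "")
    res <- distal_categorical_test(w$modal, D, outcome)
    lv <- colnames(res$proportions)
    ref <- profiles[, match(lv, c("PE", "PP", "other"))]
    c(corrected = sum(abs(res$proportions - ref)) / 2,
      naive = sum(abs(res$naive - ref)) / 2)
  })
  expect_lt(mean(tv["corrected", ]), mean(tv["naive", ]))
})

test_that("three-step input validation", {
  expect_error(distal_categorical_test(rep(1:2, 10), diag(2), rep("PE", 20)),
               "at least 2")
  bad_D <- matrix(c(0.7, 0.6, 0.3, 0.3), 2)
  expect_error(distal_categorical_test(rep(1:2, 10), bad_D,
                                       rep(c("PE", "PP"), 10)), "sum to 1")
})

test_that("height correlations recover generated structure in the large-fragment class", {
  set.seed(14)
  n <- 900
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  tab <- data.frame(
    length_mm = 5.3 + 2.3 * z1,
    width_mm = 3.4 + 1.16 * (0.15 * z1 + sqrt(1 - 0.15^2) * z2),
    height_mm = 2 + 0.8 * (0.24 * (0.15 * z1 + sqrt(1 - 0.15^2) * z2) +
                             sqrt(1 - 0.24^2) * z3)
  )
  res <- height_correlations(tab, assignments = rep(6L, n), class_label = 6L)
  expect_equal(res$n, n)
  se <- 1 / sqrt(n - 3)
  expect_lt(abs(res$r_width_height - 0.24), 3 * se)
  expect_lt(abs(res$r_length_height - 0.24 * 0.15), 3 * se)
  expect_equal(res$missing_fraction, 0)

  # heights independent of everything: both correlations near zero
  tab$height_mm <- rnorm(n, 2, 0.8)
  res0 <- height_correlations(tab, rep(6L, n), 6L)
  expect_lt(abs(res0$r_length_height), 3 * se)

  tab$height_mm <- 2 # constant height -> one warning per correlation
  expect_warning(expect_warning(
    resc <- height_correlations(tab, rep(6L, n), 6L), "constant"), "constant")
  expect_true(is.na(resc$r_width_height))
  expect_error(height_correlations(tab[1:2, ], rep(6L, 2), 6L), "fewer than 3")
})
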