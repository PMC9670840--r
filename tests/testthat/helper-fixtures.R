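# shared fixtures and independent oracles for the test suite

# a small, fully valid particle table built in code
make_particle_table <- function(n_per_cat = 10) {
  n <- 3 * n_per_cat
  data.frame(
    particle_id = sprintf("P%03d", seq_len(n)),
    haul_id = rep(c("H01", "H02"), length.out = n),
    category = rep(c("line", "film", "fragment"), each = n_per_cat),
    length_mm = rep(c(12, 4, 3), each = n_per_cat) + seq_len(n) * 0.01,
    width_mm = c(rep(NA_real_, n_per_cat),
                 rep(c(2, 1.5), each = n_per_cat) + seq_len(2 * n_per_cat) * 0.005),
    height_mm = NA_real_,
    polymer = rep(c("PE", "PP", "other"), length.out = n),
    stringsAsFactors = FALSE
  )
}

# independent mixture log-likelihood by direct summation (univariate)
oracle_loglik_uni <- function(x, w, mu, s2) {
  dens <- rowSums(vapply(seq_along(w),
                         function(k) w[k] * dnorm(x, mu[k], sqrt(s2[k])),
                         numeric(length(x))))
  sum(log(dens))
}

# independent maximized loglik for a univariate 2-class mixture:
# direct optimization over (logit weight, means, log sds) from a start grid
oracle_max_loglik_uni2 <- function(x) {
  nll <- function(th) {
    w <- stats::plogis(th[1])
    s <- pmax(exp(th[4:5]), sqrt(1e-6)) # same variance floor as the EM
    d <- w * dnorm(x, th[2], s[1]) + (1 - w) * dnorm(x, th[3], s[2])
    -sum(log(pmax(d, 1e-300)))
  }
  qs <- unname(quantile(x, c(0.25, 0.75)))
  starts <- list(
    c(0, qs[1], qs[2], log(sd(x) / 2), log(sd(x) / 2)),
    c(0, min(x), max(x), log(sd(x) / 4), log(sd(x) / 4)),
    c(1, mean(x), mean(x) + sd(x), log(sd(x)), log(sd(x) / 2))
  )
  best <- Inf
  for (s0 in starts) {
    o <- suppressWarnings(optim(s0, nll, control = list(maxit = 5000, reltol = 1e-14)))
    o <- suppressWarnings(optim(o$par, nll, method = "BFGS",
                                control = list(maxit = 1000, reltol = 1e-14)))
    best <- min(best, o$value)
  }
  -best
}

# build a particle table from exact-model draws (no truncation at all:
# the published parameters describe the fitted latent normals, so the
# recovery loop must simulate from exactly those normals)
recovery_table <- function(n, seed) {
  d <- sample_mixture(reference_model(), n, seed = seed, truncate_at = NULL)
  data.frame(
    particle_id = sprintf("P%06d", seq_len(n)),
    haul_id = sprintf("H%02d", ((seq_len(n) - 1L) %% 20L) + 1L),
    category = d$category,
    length_mm = d$length_mm,
    width_mm = d$width_mm,
    stringsAsFactors = FALSE
  )
}
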