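#' Generate a synthetic particle table
#'
#' Draws `n` particles from the latent-class structure of a generator
#' configuration: the latent class is drawn from the class weights, dimensions
#' from the class's (multivariate) normal distribution, polymer type from the
#' class's polymer profile, and hauls are assigned round-robin with an
#' optional additive per-haul shift on both dimensions. Particles whose
#' length falls below the detection limit (or whose width is nonpositive) are
#' redrawn from their class, so the configured weights describe the
#' *observable* population. With `outlier_rate > 0`, that fraction of rows is
#' replaced by draws from a wide uniform envelope and marked in `is_outlier`,
#' to give downstream screening something to find.
#'
#' Fragments with any dimension above 5 mm additionally receive a height
#' (heights were only measured for large particles), generated with a
#' configurable correlation to the width residual.
#'
#' Note that the latent normal classes assign length and width independently
#' of their order, so a generated row can have `width_mm > length_mm` even
#' though measured Feret diameters cannot; [read_particles()] enforces the
#' ordering on ingest. The generator leaves draws untouched so that refitting
#' recovers the generating parameters.
#'
#' @param config a [generator_config()]; defaults to [reference_config()].
#' @param n number of particles (> 0).
#' @param seed integer seed for reproducibility; identical seeds give
#'   identical tables.
#' @return A data.frame with columns `particle_id`, `haul_id`, `category`,
#'   `length_mm`, `width_mm` (`NA` for lines), `height_mm`, `polymer`, plus
#'   generator bookkeeping columns `class` (true latent class index) and
#'   `is_outlier`.
#' @export
#' @examples
#' tab <- generate_particles(n = 500, seed = 1)
#' table(tab$category)
generate_particles <- function(config = reference_config(), n, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  stop_if_not_count(n, "n")
  if (!is.null(seed)) set.seed(seed)

  classes <- config$model$classes
  K <- length(classes)
  w <- vapply(classes, `[[`, numeric(1), "weight")
  cls <- sample.int(K, n, replace = TRUE, prob = w)
  haul <- sprintf("H%02d", ((seq_len(n) - 1L) %% config$n_hauls) + 1L)
  shift <- if (config$haul_effect_sd > 0) {
    stats::setNames(stats::rnorm(config$n_hauls, 0, config$haul_effect_sd),
                    sprintf("H%02d", seq_len(config$n_hauls)))
  } else {
    stats::setNames(numeric(config$n_hauls), sprintf("H%02d", seq_len(config$n_hauls)))
  }

  len <- wid <- rep(NA_real_, n)
  draw_class <- function(cl, m, offset) {
    mu <- cl$mean + offset
    if (length(cl$mean) == 1L) {
      cbind(stats::rnorm(m, mu[1], sqrt(cl$var[1])), NA_real_)
    } else {
      s1 <- sqrt(cl$var[1]); s2 <- sqrt(cl$var[2])
      rho <- cl$cov / (s1 * s2)
      z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
      cbind(mu[1] + s1 * z1,
            mu[2] + s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
    }
  }
  for (k in seq_len(K)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    # per-haul shifts are additive on the class mean of both dimensions
    off <- shift[haul[idx]]
    d <- draw_class(classes[[k]], length(idx), 0)
    d[, 1] <- d[, 1] + off
    if (length(classes[[k]]$mean) == 2L) d[, 2] <- d[, 2] + off
    # detection limit / positivity by rejection: redraw offending rows
    bad <- d[, 1] < config$detection_limit |
      (!is.na(d[, 2]) & d[, 2] <= 0)
    guard <- 0L
    while (any(bad)) {
      r <- draw_class(classes[[k]], sum(bad), 0)
      r[, 1] <- r[, 1] + off[bad]
      if (length(classes[[k]]$mean) == 2L) r[, 2] <- r[, 2] + off[bad]
      d[bad, ] <- r
      bad <- d[, 1] < config$detection_limit | (!is.na(d[, 2]) & d[, 2] <= 0)
      guard <- guard + 1L
      if (guard > 10000L) stop("rejection sampling failed; detection limit too high for class parameters")
    }
    len[idx] <- d[, 1]
    wid[idx] <- d[, 2]
  }

  polymer <- character(n)
  for (k in seq_len(K)) {
    idx <- which(cls == k)
    if (!length(idx)) next
    p <- config$polymer_profiles[[k]]
    polymer[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }

  category <- vapply(classes, `[[`, character(1), "category")[cls]

  # contaminating outliers drawn from a wide uniform envelope
  is_out <- rep(FALSE, n)
  if (config$outlier_rate > 0) {
    is_out <- stats::runif(n) < config$outlier_rate
    m <- sum(is_out)
    if (m) {
      len[is_out] <- stats::runif(m, max(config$detection_limit, 1), 150)
      oi <- which(is_out)
      biv <- category[oi] != "line"
      wid[oi[biv]] <- stats::runif(sum(biv), 0.2, 20)
    }
  }

  # heights for large fragments, correlated with the width residual
  hgt <- rep(NA_real_, n)
  hc <- config$height
  large <- which(category == "fragment" &
                   (len > 5 | (!is.na(wid) & wid > 5)) & !is_out)
  if (length(large)) {
    cl_large <- classes[cls[large]]
    zl <- (len[large] - vapply(cl_large, function(cl) cl$mean[1], 0)) /
      sqrt(vapply(cl_large, function(cl) cl$var[1], 0))
    zw <- (wid[large] - vapply(cl_large, function(cl) cl$mean[2], 0)) /
      sqrt(vapply(cl_large, function(cl) cl$var[2], 0))
    rho <- vapply(cl_large, function(cl) cl$cov / sqrt(prod(cl$var)), 0)
    # coefficients so that corr(h, z_length) = r_length, corr(h, z_width) = r_width
    b <- (hc$r_width - hc$r_length * rho) / (1 - rho^2)
    a <- hc$r_length - b * rho
    c2 <- pmax(1 - a^2 - b^2 - 2 * a * b * rho, 0)
    gen_h <- function(i) hc$mean + hc$sd *
      (a[i] * zl[i] + b[i] * zw[i] + sqrt(c2[i]) * stats::rnorm(length(i)))
    h <- gen_h(seq_along(large))
    bad <- which(h <= 0)
    while (length(bad)) { # physical positivity
      h[bad] <- gen_h(bad)
      bad <- which(h <= 0)
    }
    hgt[large] <- h
  }

  data.frame(
    particle_id = sprintf("P%06d", seq_len(n)),
    haul_id = haul,
    category = category,
    length_mm = len,
    width_mm = wid,
    height_mm = hgt,
    polymer = polymer,
    class = cls,
    is_outlier = is_out,
    stringsAsFactors = FALSE
  )
}
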