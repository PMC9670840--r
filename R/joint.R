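#' Fit the combined six-class mixture model
#'
#' Combines the per-category two-class models into a single mixture over all
#' particles: one likelihood with six classes whose membership is restricted
#' by the observed shape category (structural zeros in the posterior, the
#' dummy-variable device), line classes contributing a univariate normal over
#' length and film/fragment classes bivariate normals with the length-width
#' covariance pooled within each category. Starting values come from the
#' three per-category two-class fits, after which EM is run on the joint
#' likelihood. Classes are ordered Line 1-2, Film 1-2, Fragment 1-2, each
#' pair ascending by mean length.
#'
#' @param table particle data.frame (screened) with `category`, `length_mm`,
#'   `width_mm`, and (for robust SEs) `haul_id`.
#' @param n_starts random starts for the per-category fits.
#' @param se `"sandwich"` computes haul-clustered sandwich standard errors
#'   (requires `haul_id` and >= 2 hauls); `"none"` skips them.
#' @param seed integer seed.
#' @param max_iter,tol EM settings.
#' @return A `mixture_fit` (subclass `joint_fit`) with the per-category fits
#'   in `$category_fits` and, when requested, `$se` (a parameter table with
#'   model-based and sandwich SEs and Wald 95% CIs).
#' @export
fit_joint <- function(table, n_starts = 20, se = c("sandwich", "none"),
                      seed = NULL, max_iter = 2000, tol = 1e-8) {
  se <- match.arg(se)
  missing_cat <- setdiff(CATEGORIES, unique(table$category))
  if (length(missing_cat))
    stop("category absent from table: ", paste(missing_cat, collapse = ", "))
  n_cat <- table(table$category)
  if (any(n_cat < 10))
    stop("category with fewer than 10 particles: ",
         paste(names(n_cat)[n_cat < 10], collapse = ", "))
  seeds <- derive_seeds(seed, 3L)

  cat_fits <- list(
    line = fit_mixture(table$length_mm[table$category == "line"], K = 2,
                       n_starts = n_starts, max_iter = max_iter, tol = tol,
                       seed = seeds[[1]]),
    film = fit_mixture(cbind(table$length_mm, table$width_mm)[table$category == "film", ],
                       K = 2, covariance = "equal", n_starts = n_starts,
                       max_iter = max_iter, tol = tol, seed = seeds[[2]]),
    fragment = fit_mixture(cbind(table$length_mm, table$width_mm)[table$category == "fragment", ],
                           K = 2, covariance = "equal", n_starts = n_starts,
                           max_iter = max_iter, tol = tol, seed = seeds[[3]])
  )

  N <- nrow(table)
  X <- cbind(table$length_mm, table$width_mm)
  X[table$category == "line", 2] <- NA_real_
  class_def <- list(
    list(use_width = FALSE, category = "line"),
    list(use_width = FALSE, category = "line"),
    list(use_width = TRUE, category = "film"),
    list(use_width = TRUE, category = "film"),
    list(use_width = TRUE, category = "fragment"),
    list(use_width = TRUE, category = "fragment")
  )
  pool <- c(NA, NA, 1L, 1L, 2L, 2L)
  allowed <- matrix(FALSE, N, 6)
  cat_block <- c(line = 1L, film = 3L, fragment = 5L)
  for (cat in CATEGORIES) {
    rows <- table$category == cat
    allowed[rows, cat_block[[cat]] + 0:1] <- TRUE
  }

  # assemble joint starting values: category share x within-category weight
  share <- as.numeric(n_cat[CATEGORIES]) / N
  params <- list(w = numeric(6), mu = vector("list", 6), s2 = vector("list", 6),
                 cv = rep(NA_real_, 6))
  for (ci in seq_along(CATEGORIES)) {
    f <- cat_fits[[CATEGORIES[ci]]]
    for (j in 1:2) {
      k <- cat_block[[CATEGORIES[ci]]] + j - 1L
      params$w[k] <- share[ci] * f$params[[j]]$weight
      params$mu[[k]] <- f$params[[j]]$mean
      params$s2[[k]] <- f$params[[j]]$var
      params$cv[k] <- f$params[[j]]$cov
    }
  }

  res <- .run_em(X, params, class_def, pool, allowed, max_iter, tol)
  rel <- .relabel(res$params, res$P, class_def)
  labels <- c("Line 1", "Line 2", "Film 1", "Film 2", "Fragment 1", "Fragment 2")
  fit <- .build_fit(X, rel$params, rel$P, rel$class_def, pool, res,
                    covariance = "equal", allowed = allowed,
                    category = table$category, labels = labels)
  class(fit) <- c("joint_fit", class(fit))
  fit$category_fits <- cat_fits
  if (se == "sandwich") {
    if (!"haul_id" %in% names(table) || length(unique(table$haul_id)) < 2) {
      warning("haul_id missing or fewer than 2 hauls; skipping sandwich SEs")
    } else {
      fit$se <- sandwich_se(fit, table$haul_id)
    }
  }
  fit
}

#' Convert a fitted joint model to a `mixture_model`
#'
#' @param fit a `joint_fit` from [fit_joint()].
#' @return A [mixture_model()] usable with [mixture_pdf()] and
#'   [sample_mixture()].
#' @export
model_from_fit <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  classes <- lapply(fit$params, function(cl) {
    list(label = cl$label, category = cl$category %||% "fragment",
         weight = cl$weight, mean = cl$mean, var = cl$var, cov = cl$cov,
         r = cl$r)
  })
  mixture_model(classes, n_total = fit$N, source = "fit")
}

#' Mixture probability density of a particle characteristic
#'
#' Evaluates the overall density \eqn{p(x) = \sum_i n_i\,N(x; M_i, s_i)} of a
#' single characteristic under a six-class (or any) mixture model, where
#' \eqn{n_i} are the number fractions. Bivariate classes are marginalized
#' analytically (a normal's marginals are normal). For `characteristic =
#' "width"` the line classes carry no width, so they are excluded and the
#' number fractions renormalized over the remaining classes; the
#' renormalization constant is attached as attribute `"fraction_renorm"`.
#'
#' @param x numeric vector of evaluation points (mm).
#' @param model a [mixture_model()].
#' @param characteristic `"length"` or `"width"`.
#' @return Density values; attributes record any renormalization.
#' @seealso [mixture_pdf_bivariate()]
#' @export
#' @examples
#' grid <- seq(0, 40, by = 0.1)
#' dens <- mixture_pdf(grid, reference_model())
mixture_pdf <- function(x, model, characteristic = c("length", "width")) {
  characteristic <- match.arg(characteristic)
  stopifnot(inherits(model, "mixture_model"))
  keep <- vapply(model$classes, function(cl) characteristic %in% names(cl$mean),
                 logical(1))
  if (!any(keep)) stop("no class carries characteristic ", characteristic)
  w <- vapply(model$classes[keep], `[[`, numeric(1), "weight")
  renorm <- sum(w)
  w <- w / renorm
  dens <- numeric(length(x))
  for (j in seq_along(w)) {
    cl <- model$classes[keep][[j]]
    dens <- dens + w[j] * stats::dnorm(x, cl$mean[[characteristic]],
                                       sqrt(cl$var[[characteristic]]))
  }
  attr(dens, "fraction_renorm") <- renorm
  attr(dens, "classes_used") <- vapply(model$classes[keep], `[[`, character(1), "label")
  dens
}

#' Bivariate mixture density over (length, width)
#'
#' Joint density over the width-bearing classes (lines excluded, number
#' fractions renormalized), for Monte-Carlo risk assessment uses that sample
#' both characteristics jointly.
#'
#' @param length_mm,width_mm numeric vectors (recycled to common length).
#' @param model a [mixture_model()].
#' @return Density values with renormalization attributes.
#' @export
mixture_pdf_bivariate <- function(length_mm, width_mm, model) {
  stopifnot(inherits(model, "mixture_model"))
  keep <- vapply(model$classes, function(cl) length(cl$mean) == 2L, logical(1))
  w <- vapply(model$classes[keep], `[[`, numeric(1), "weight")
  renorm <- sum(w)
  w <- w / renorm
  dens <- numeric(max(length(length_mm), length(width_mm)))
  for (j in seq_along(w)) {
    cl <- model$classes[keep][[j]]
    dens <- dens + w[j] * exp(logdbvn(length_mm, width_mm,
                                      cl$mean[1], cl$mean[2],
                                      cl$var[1], cl$var[2], cl$cov))
  }
  attr(dens, "fraction_renorm") <- renorm
  dens
}

#' Sample particles from a mixture model
#'
#' Draws the class index from the number fractions and the characteristics
#' from the class's (multivariate) normal. Draws with nonpositive dimensions
#' are redrawn by default (physical particles have positive size); set
#' `truncate_at = NULL` to keep the raw normal draws.
#'
#' @param model a [mixture_model()].
#' @param n number of draws (> 0).
#' @param seed integer seed; fixed seeds reproduce draws exactly.
#' @param truncate_at lower bound (mm) below which a draw's length is
#'   rejected and redrawn (widths are redrawn below 0); `NULL` disables.
#' @return data.frame with `class`, `label`, `category`, `length_mm`,
#'   `width_mm`.
#' @export
#' @examples
#' draws <- sample_mixture(reference_model(), 1000, seed = 42)
#' mean(draws$length_mm)
sample_mixture <- function(model, n, seed = NULL, truncate_at = 0) {
  stopifnot(inherits(model, "mixture_model"))
  stop_if_not_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  K <- length(model$classes)
  w <- vapply(model$classes, `[[`, numeric(1), "weight")
  k <- sample.int(K, n, replace = TRUE, prob = w)
  len <- wid <- rep(NA_real_, n)
  for (j in seq_len(K)) {
    idx <- which(k == j)
    if (!length(idx)) next
    cl <- model$classes[[j]]
    draw <- function(m) {
      if (length(cl$mean) == 1L) {
        cbind(stats::rnorm(m, cl$mean[1], sqrt(cl$var[1])), NA_real_)
      } else {
        s1 <- sqrt(cl$var[1]); s2 <- sqrt(cl$var[2])
        rho <- cl$cov / (s1 * s2)
        z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
        cbind(cl$mean[1] + s1 * z1,
              cl$mean[2] + s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
      }
    }
    d <- draw(length(idx))
    if (!is.null(truncate_at)) {
      bad <- d[, 1] <= truncate_at | (!is.na(d[, 2]) & d[, 2] <= 0)
      while (any(bad)) {
        d[bad, ] <- draw(sum(bad))
        bad <- d[, 1] <= truncate_at | (!is.na(d[, 2]) & d[, 2] <= 0)
      }
    }
    len[idx] <- d[, 1]
    wid[idx] <- d[, 2]
  }
  data.frame(
    class = k,
    label = vapply(model$classes, `[[`, character(1), "label")[k],
    category = vapply(model$classes, `[[`, character(1), "category")[k],
    length_mm = len, width_mm = wid,
    stringsAsFactors = FALSE
  )
}
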