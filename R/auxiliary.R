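#' Classification-error matrix from a posterior matrix
#'
#' `D[k, j]` estimates the probability that a particle truly in class k is
#' modally assigned to class j, computed from the posterior classification
#' matrix: `D[k, j] = sum of P[i, k] over i modally assigned to j, divided by
#' sum of P[i, k]`. Rows sum to 1; a perfectly separated posterior gives the
#' identity matrix.
#'
#' @param P N x K posterior matrix.
#' @return K x K matrix `D`.
#' @export
classification_error_matrix <- function(P) {
  P <- as.matrix(P)
  K <- ncol(P)
  modal <- max.col(P, ties.method = "first")
  if (length(unique(modal)) < K)
    warning("class(es) with no modal members: ",
            paste(setdiff(seq_len(K), unique(modal)), collapse = ", "))
  D <- vapply(seq_len(K), function(j) colSums(P[modal == j, , drop = FALSE]),
              numeric(K))
  sweep(D, 1, colSums(P), `/`)
}

#' Three-step distal-outcome test for a categorical auxiliary variable
#'
#' Implements the modal-assignment maximum-likelihood correction: modal class
#' assignments are cross-tabulated with the outcome, the misclassification
#' system `observed-by-assigned = t(D) %*% true-by-class` is solved for the
#' true class-by-outcome table (negative solutions clipped to zero), and each
#' outcome category is tested for equal proportions across classes with a
#' delta-method Wald chi-square on K-1 degrees of freedom. With `D` equal to
#' the identity the corrected proportions equal the naive modal
#' cross-tabulation exactly.
#'
#' @param assignments integer vector of modal class assignments (1..K).
#' @param D K x K classification-error matrix from
#'   [classification_error_matrix()].
#' @param outcome factor/character vector of outcomes, same length as
#'   `assignments`; must have >= 2 observed levels. `NA`s are dropped with a
#'   message.
#' @return A `three_step` list: `proportions` (corrected class-by-outcome),
#'   `naive` (modal cross-tab proportions), `tests` (per outcome level:
#'   chi-square, df, p-value), `D`, `n_used`, `n_dropped`.
#' @export
distal_categorical_test <- function(assignments, D, outcome) {
  keep <- !is.na(outcome)
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " observation(s) with missing outcome dropped")
  assignments <- assignments[keep]
  outcome <- factor(outcome[keep])
  if (nlevels(outcome) < 2) stop("outcome must have at least 2 observed levels")
  K <- nrow(D)
  if (!isTRUE(all.equal(rowSums(D), rep(1, K), tolerance = 1e-6)))
    stop("rows of D must sum to 1")
  A <- table(factor(assignments, levels = seq_len(K)), outcome) # J x L counts
  A <- matrix(as.numeric(A), K, dimnames = dimnames(A))
  Tn <- tryCatch(solve(t(D), A), error = function(e)
    stop("singular classification-error matrix"))
  Tn[Tn < 0] <- 0 # nonnegativity clipping
  class_tot <- rowSums(Tn)
  if (any(class_tot <= 0)) stop("a corrected class has zero mass")
  theta <- Tn / class_tot

  # delta-method Wald test per outcome level: t_l = M a_l, M = solve(t(D));
  # conditional on assigned counts n_j, Var(a_jl) = n_j p_jl (1 - p_jl)
  M <- solve(t(D))
  n_assigned <- rowSums(A)
  tests <- lapply(seq_len(ncol(A)), function(l) {
    p_obs <- ifelse(n_assigned > 0, A[, l] / n_assigned, 0)
    Va <- diag(n_assigned * p_obs * (1 - p_obs), K)
    Vt <- M %*% Va %*% t(M)
    # theta_kl = t_kl / Ntilde_k with Ntilde fixed at the corrected totals
    Vth <- Vt / (class_tot %o% class_tot)
    C <- cbind(diag(K - 1), -1) # contrasts vs last class
    q <- drop(C %*% theta[, l])
    W <- C %*% Vth %*% t(C)
    stat <- tryCatch(drop(t(q) %*% solve(W, q)), error = function(e) NA_real_)
    data.frame(outcome = colnames(A)[l], chisq = stat, df = K - 1,
               p_value = stats::pchisq(stat, K - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  naive <- sweep(A, 1, pmax(n_assigned, 1), `/`)
  structure(list(proportions = theta, naive = naive,
                 tests = do.call(rbind, tests), D = D,
                 n_used = length(assignments), n_dropped = n_dropped),
            class = "three_step")
}

#' @export
print.three_step <- function(x, ...) {
  cat(sprintf("Three-step distal outcome analysis (n = %d, dropped = %d)\n",
              x$n_used, x$n_dropped))
  cat("Corrected class-by-outcome proportions:\n")
  print(round(x$proportions, 3))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Height correlations within one latent class
#'
#' Pearson correlations of observed height with length and width among the
#' complete-case particles modally assigned to one class (by default the
#' large-fragment class, which holds essentially all height measurements).
#'
#' @param table particle data.frame with `length_mm`, `width_mm`,
#'   `height_mm`.
#' @param assignments modal class assignments, one per row of `table`.
#' @param class_label class (index into the assignment coding) to analyse.
#' @return List with `r_length_height`, `r_width_height`, their 95%
#'   confidence intervals, `n` complete cases and the missingness fraction.
#'   Degenerate inputs (constant height) give `NA` correlations with a
#'   warning.
#' @export
height_correlations <- function(table, assignments, class_label) {
  rows <- which(assignments == class_label)
  if (!length(rows)) stop("no particles assigned to class ", class_label)
  sub <- table[rows, c("length_mm", "width_mm", "height_mm")]
  cc <- stats::complete.cases(sub)
  n <- sum(cc)
  if (n < 3) stop("fewer than 3 complete cases with observed height")
  sub <- sub[cc, ]
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant values; correlation undefined")
      return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    ct <- stats::cor.test(a, b)
    list(est = unname(ct$estimate), ci = unname(ct$conf.int))
  }
  rl <- safe_cor(sub$length_mm, sub$height_mm)
  rw <- safe_cor(sub$width_mm, sub$height_mm)
  list(r_length_height = rl$est, r_length_height_ci = rl$ci,
       r_width_height = rw$est, r_width_height_ci = rw$ci,
       n = n, missing_fraction = 1 - n / length(rows))
}
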