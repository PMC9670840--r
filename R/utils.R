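# internal numerical helpers

# rowwise log-sum-exp of a matrix of log terms; -Inf entries allowed
logrowsumexp <- function(L) {
  m <- do.call(pmax, c(as.data.frame(L), list(na.rm = TRUE)))
  m[!is.finite(m)] <- 0 # all -Inf row would be an upstream bug; keep finite
  m + log(rowSums(exp(L - m)))
}

# log density of a bivariate normal with covariance [a c; c b], vectorized
logdbvn <- function(x, y, mx, my, a, b, c) {
  d <- a * b - c * c
  dx <- x - mx
  dy <- y - my
  q <- (b * dx * dx - 2 * c * dx * dy + a * dy * dy) / d
  -log(2 * pi) - 0.5 * log(d) - 0.5 * q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(n, what = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0 || n != round(n))
    stop(sprintf("`%s` must be a positive integer", what), call. = FALSE)
}

# derive a stream of sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, k))
}

CATEGORIES <- c("line", "film", "fragment")
POLYMERS <- c("PE", "PP", "other", "unknown")
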