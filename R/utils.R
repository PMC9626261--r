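# internal numerical helpers

# log(sum(exp(x))) along rows of a matrix, guarding -Inf rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# draw n vectors from Dirichlet(alpha * mu); rows are draws
rdirichlet_mat <- function(n, shape) {
  k <- length(shape)
  g <- matrix(rgamma(n * k, shape = rep(shape, each = n)), nrow = n)
  # guard against all-zero rows for very small shapes
  z <- rowSums(g)
  bad <- z <= 0 | !is.finite(z)
  if (any(bad)) {
    g[bad, ] <- matrix(rep(shape / sum(shape), sum(bad)), nrow = sum(bad), byrow = TRUE)
    z[bad] <- 1
  }
  g / z
}

#' Sample from a Dirichlet distribution
#'
#' Draws probability vectors from a Dirichlet distribution parameterized by a
#' concentration `alpha` and mean distribution `mu` (so the shape vector is
#' `alpha * mu`).
#'
#' @param n Number of draws.
#' @param alpha Positive concentration parameter.
#' @param mu Mean distribution (non-negative, sums to one).
#' @return A numeric matrix with `n` rows, each a probability vector.
#' @examples
#' th <- rdirichlet(5, alpha = 20, mu = c(0.5, 0.3, 0.2))
#' rowSums(th)
#' @export
rdirichlet <- function(n, alpha, mu) {
  stopifnot(alpha > 0, all(mu >= 0), abs(sum(mu) - 1) < 1e-6)
  rdirichlet_mat(n, alpha * mu)
}

check_prob_vector <- function(p, name = "p", tol = 1e-6) {
  if (any(p < -1e-12)) abort(sprintf("`%s` has negative components", name))
  if (abs(sum(p) - 1) > tol) abort(sprintf("`%s` must sum to 1", name))
  invisible(TRUE)
}

# deterministic per-stage seed derivation from a global seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
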