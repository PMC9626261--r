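#' EM clustering of style vectors with a discrete-distribution mixture
#'
#' Fits a K-component mixture of discrete (categorical) distributions to the
#' count vectors behind a set of style vectors, by expectation-maximization
#' with random restarts. Each song's component likelihood is multinomial
#' over its raw counts, so longer songs carry more evidence.
#' Responsibilities are computed in the log domain; component probabilities
#' are floored at `prob_floor` and renormalized each M-step; iteration stops
#' when the relative log-likelihood change falls below `tol` or after
#' `max_iter` iterations. The best restart by final log-likelihood is kept,
#' and components are put in canonical order (descending mixture weight,
#' ties by lexicographic component vector).
#'
#' @param styles A style table (see [style_tbl]) or a numeric count matrix.
#' @param K Number of mixture components (`>= 1`).
#' @param n_restarts Number of random initializations (default 10).
#' @param seed Integer seed controlling the restarts.
#' @param max_iter,tol Convergence controls.
#' @param prob_floor Floor applied to component probabilities.
#' @param use_counts If `FALSE`, rows are normalized to unit sum before
#'   fitting, weighting every song equally regardless of length.
#' @return An object of class `style_mixture`: list with `K`, `weights`,
#'   `component_probs` (K x D), `loglik` (final data log-likelihood, up to
#'   the count-multinomial constant), `loglik_trace` of the best run, and
#'   `n`. `tidy()` returns per-component weights; `glance()` fit summaries.
#' @examples
#' sim <- sample_ddmm_dataset(example_trajectory_spec(years = 2000:2002))
#' fit <- fit_style_clusters(sim$styles, K = 3, n_restarts = 2, seed = 1)
#' glance(fit)
#' @export
fit_style_clusters <- function(styles, K, n_restarts = 10, seed = 1,
                               max_iter = 500, tol = 1e-8,
                               prob_floor = 1e-8, use_counts = TRUE) {
  counts <- if (is.data.frame(styles)) style_counts(styles) else as.matrix(styles)
  if (!use_counts) counts <- counts / rowSums(counts)
  n <- nrow(counts)
  D <- ncol(counts)
  if (n == 0) abort("no style vectors to cluster")
  if (K < 1) abort("`K` must be at least 1")
  if (K > n) abort("`K` cannot exceed the number of songs")

  if (K == 1) {
    p <- colSums(counts) / sum(counts)
    p <- pmax(p, prob_floor); p <- p / sum(p)
    ll <- sum(counts %*% log(p))
    return(structure(list(K = 1L, weights = 1, component_probs = matrix(p, 1),
                          loglik = ll, loglik_trace = ll, n = n,
                          feature_names = colnames(counts)),
                     class = "style_mixture"))
  }

  run_em <- function() {
    # initialize components from randomly chosen songs, smoothed
    pick <- sample.int(n, K)
    p <- counts[pick, , drop = FALSE] + 0.5 * mean(rowSums(counts)) / D
    p <- p / rowSums(p)
    dimnames(p) <- list(NULL, colnames(counts))
    w <- rep(1 / K, K)
    trace <- numeric(0)
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      lp <- counts %*% t(log(p))              # n x K component log-likelihoods
      lr <- sweep(lp, 2, log(w), "+")
      ll_rows <- row_logsumexp(lr)
      ll <- sum(ll_rows)
      trace <- c(trace, ll)
      r <- exp(lr - ll_rows)                  # responsibilities
      w <- colMeans(r)
      p <- t(r) %*% counts
      p <- pmax(p, prob_floor)
      p <- p / rowSums(p)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
      ll_old <- ll
    }
    list(w = w, p = p, trace = trace, loglik = ll)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_em()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(-best$w, apply(best$p, 1, paste, collapse = ","))
  structure(list(K = as.integer(K), weights = best$w[ord],
                 component_probs = best$p[ord, , drop = FALSE],
                 loglik = best$loglik, loglik_trace = best$trace, n = n,
                 feature_names = colnames(counts)),
            class = "style_mixture")
}

#' @export
print.style_mixture <- function(x, ...) {
  cat(sprintf("Discrete-distribution mixture: K = %d, D = %d, n = %d, logLik = %.2f\n",
              x$K, ncol(x$component_probs), x$n, x$loglik))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.style_mixture <- function(x, ...) {
  tibble(cluster = seq_len(x$K), weight = x$weights,
         component = lapply(seq_len(x$K), function(k) x$component_probs[k, ]))
}

#' @export
glance.style_mixture <- function(x, ...) {
  tibble(K = x$K, n = x$n, logLik = x$loglik, iterations = length(x$loglik_trace))
}

#' Hard cluster assignment of style vectors
#'
#' Assigns each song to the component with the maximal likelihood of its
#' counts (`argmax_k sum_i c_i log p_ki`), with ties broken toward the
#' lowest component index. Mixture weights are not used, so the assignment
#' depends only on the song's own statistics.
#'
#' @param model A fitted [fit_style_clusters()] model.
#' @param styles Style table or count matrix with the same D.
#' @return Integer vector of cluster labels in `1..K`.
#' @export
assign_clusters <- function(model, styles) {
  counts <- if (is.data.frame(styles)) style_counts(styles) else as.matrix(styles)
  if (ncol(counts) != ncol(model$component_probs))
    abort("dimension mismatch between model and styles")
  lp <- counts %*% t(log(model$component_probs))
  max.col(lp, ties.method = "first")
}
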