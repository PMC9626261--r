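#' Replicator dynamics of mixture probabilities
#'
#' Iterates the discrete-time replicator equation
#' `pi_k(t+1) = w_k pi_k(t) / wbar(t)` with mean fitness
#' `wbar(t) = sum_l w_l pi_l(t)`. With constant fitness the solution has the
#' closed form `pi_k(t)` proportional to `pi_k(0) w_k^t`.
#'
#' @param pi0 Initial mixture probabilities.
#' @param fitness Positive cluster fitness values `w_k`, length K.
#' @param steps Number of iterations.
#' @return A `(steps + 1) x K` matrix of mixture probabilities, first row
#'   `pi0`.
#' @examples
#' simulate_replicator(c(0.5, 0.5), c(1.1, 0.9), 3)
#' @export
simulate_replicator <- function(pi0, fitness, steps) {
  check_prob_vector(pi0, "pi0")
  if (any(fitness <= 0)) abort("all fitness values must be positive")
  if (length(fitness) != length(pi0)) abort("`fitness` and `pi0` lengths differ")
  out <- matrix(NA_real_, steps + 1, length(pi0))
  out[1, ] <- pi0
  for (t in seq_len(steps)) {
    wbar <- sum(fitness * out[t, ])
    out[t + 1, ] <- fitness * out[t, ] / wbar
  }
  out
}

#' Specify a time-evolving Dirichlet mixture scenario
#'
#' Declares the ground-truth trajectory of a dynamic Dirichlet mixture used
#' by the simulator: mixture probabilities follow replicator dynamics with
#' constant cluster fitness, concentrations follow a log-linear schedule
#' between start and end values, and mean distributions interpolate linearly
#' between start and end distributions (renormalized).
#'
#' @param years Integer years the scenario covers.
#' @param pi0 Initial mixture probabilities (length K).
#' @param fitness Constant cluster fitness values (length K, default
#'   neutral).
#' @param alpha Start concentrations (length K).
#' @param alpha_end Optional end concentrations (default: constant).
#' @param mu K x D matrix of start mean distributions.
#' @param mu_end Optional K x D end matrix (default: constant).
#' @param n_songs Songs sampled per year.
#' @param n_events Event (count) total per song; controls multinomial noise
#'   on top of the Dirichlet draw.
#' @return An object of class `trajectory_spec` with the per-year true
#'   parameters as a `dmm_trajectory` in `$truth`.
#' @export
trajectory_spec <- function(years, pi0, fitness = rep(1, length(pi0)),
                            alpha, alpha_end = NULL, mu, mu_end = NULL,
                            n_songs = 100, n_events = 200) {
  K <- length(pi0)
  if (!is.matrix(mu) || nrow(mu) != K) abort("`mu` must be a K x D matrix")
  if (length(alpha) != K) abort("`alpha` must have length K")
  if (any(alpha <= 0)) abort("concentrations must be positive")
  Tn <- length(years)
  pis <- simulate_replicator(pi0, fitness, Tn - 1)
  if (is.null(alpha_end)) alpha_end <- alpha
  if (is.null(mu_end)) mu_end <- mu
  frac <- if (Tn == 1) 0 else (seq_len(Tn) - 1) / (Tn - 1)
  truth <- lapply(seq_len(Tn), function(i) {
    a <- exp((1 - frac[i]) * log(alpha) + frac[i] * log(alpha_end))
    m <- (1 - frac[i]) * mu + frac[i] * mu_end
    m <- m / rowSums(m)
    dmm_params(years[i], pis[i, ], a, m)
  })
  structure(list(years = as.integer(years), K = K, D = ncol(mu),
                 truth = new_dmm_trajectory(truth), fitness = fitness,
                 n_songs = n_songs, n_events = n_events),
            class = "trajectory_spec")
}

#' A small built-in three-cluster scenario
#'
#' Convenience scenario used in examples and tests: three well-separated
#' clusters over a 6-dimensional simplex with mildly selective fitness.
#'
#' @param years Years covered (default `1990:2009`).
#' @param n_songs,n_events Sampling sizes per year and per song.
#' @return A [trajectory_spec()].
#' @export
example_trajectory_spec <- function(years = 1990:2009, n_songs = 50,
                                    n_events = 200) {
  mu <- rbind(c(0.55, 0.15, 0.10, 0.10, 0.05, 0.05),
              c(0.05, 0.55, 0.15, 0.05, 0.10, 0.10),
              c(0.10, 0.05, 0.05, 0.15, 0.55, 0.10))
  trajectory_spec(years, pi0 = c(0.5, 0.3, 0.2),
                  fitness = c(0.95, 1.0, 1.06),
                  alpha = c(25, 30, 35), mu = mu,
                  n_songs = n_songs, n_events = n_events)
}

#' Sample a year-stamped dataset from a DDMM scenario
#'
#' For each year and song, draws a cluster from the year's mixture
#' probabilities, a latent probability vector from the cluster's Dirichlet
#' distribution, and (by default) an event-count vector from a multinomial
#' over that vector, mimicking featurized symbolic data of finite length.
#'
#' @param spec A [trajectory_spec()].
#' @param seed Integer seed; sampling is bit-reproducible given the seed.
#' @param observe `"counts"` (default) stores the multinomial proportions as
#'   the style vectors; `"theta"` stores the exact Dirichlet draws (no
#'   multinomial noise).
#' @return A list with `styles` (a style table), `labels` (true cluster
#'   index per song) and `truth` (the generating `dmm_trajectory`).
#' @examples
#' sim <- sample_ddmm_dataset(example_trajectory_spec(years = 2000:2004), seed = 7)
#' table(sim$labels)
#' @export
sample_ddmm_dataset <- function(spec, seed = 1,
                                observe = c("counts", "theta")) {
  observe <- match.arg(observe)
  if (!inherits(spec, "trajectory_spec")) abort("`spec` must be a trajectory_spec")
  set.seed(seed)
  K <- spec$K; D <- spec$D
  total <- spec$n_songs * length(spec$years)
  theta_all <- matrix(NA_real_, total, D)
  labels <- integer(total)
  years <- integer(total)
  n_ev <- numeric(total)
  row <- 0L
  for (yi in seq_along(spec$years)) {
    pars <- spec$truth[[yi]]
    ks <- sample.int(K, spec$n_songs, replace = TRUE, prob = pars$pi)
    for (k in sort(unique(ks))) {
      idx <- which(ks == k)
      th <- rdirichlet_mat(length(idx), pars$alpha[k] * pars$mu[k, ])
      if (observe == "counts") {
        cnt <- apply(th, 1, function(p) rmultinom(1, spec$n_events, p))
        th <- t(cnt) / spec$n_events
      }
      theta_all[row + idx, ] <- th
      labels[row + idx] <- k
    }
    years[row + seq_len(spec$n_songs)] <- spec$years[yi]
    n_ev[row + seq_len(spec$n_songs)] <- spec$n_events
    row <- row + spec$n_songs
  }
  ids <- sprintf("song%05d", seq_len(total))
  styles <- new_style_tbl(theta_all, ids, years, n_ev, "synthetic",
                          sprintf("f%02d", seq_len(D)))
  list(styles = styles, labels = labels, truth = spec$truth, spec = spec)
}

#' Agent-based creator-transmission simulation
#'
#' Simulates a finite population of creators, each carrying a cluster label
#' and a probability-vector trait. Every generation, each new creator first
#' selects a cluster with probability proportional to the cluster's current
#' relative frequency weighted by the cluster fitness `w_k`; it then selects
#' a cultural parent within that cluster with probability proportional to
#' the trait fitness `w(theta, k) = exp(beta * s_k . theta)` (a linear score
#' per cluster), and inherits the parent's trait through Dirichlet copy
#' noise with concentration `kappa` (exact copying at `kappa = Inf`). If a
#' selected cluster has no members, the cluster is resampled among the
#' populated ones (logged). As the population grows the cluster frequencies
#' converge to the deterministic replicator trajectory.
#'
#' @param n_agents Population size per generation.
#' @param generations Number of generations to simulate.
#' @param init List with `k` (integer labels) and `theta` (matrix of traits)
#'   for generation 0; recycled/sampled up to `n_agents` if shorter.
#' @param w_cluster Positive cluster fitness values, length K.
#' @param beta Selection strength of the trait fitness (default 0: neutral).
#' @param score Optional K x D matrix of per-cluster linear score vectors
#'   `s_k` (default zeros).
#' @param kappa Copy-noise concentration (default `Inf`: exact copy).
#' @param seed Integer seed.
#' @return A list with `freq` (`(generations + 1) x K` cluster frequencies),
#'   `cluster_means` (list over generations of K x D mean traits, `NA` for
#'   empty clusters), and `final` (the last generation's `k` and `theta`).
#' @export
simulate_agents <- function(n_agents, generations, init, w_cluster,
                            beta = 0, score = NULL, kappa = Inf, seed = 1) {
  if (n_agents < 1) abort("`n_agents` must be at least 1")
  if (any(w_cluster <= 0)) abort("all cluster fitness values must be positive")
  K <- length(w_cluster)
  D <- ncol(init$theta)
  if (is.null(score)) score <- matrix(0, K, D)
  set.seed(seed)

  k_cur <- init$k
  th_cur <- init$theta
  if (length(k_cur) < n_agents) {
    idx <- sample.int(length(k_cur), n_agents, replace = TRUE)
    k_cur <- k_cur[idx]; th_cur <- th_cur[idx, , drop = FALSE]
  }

  freq <- matrix(0, generations + 1, K)
  cl_means <- vector("list", generations + 1)
  snapshot <- function(g) {
    freq[g, ] <<- tabulate(k_cur, K) / length(k_cur)
    m <- matrix(NA_real_, K, D)
    for (k in seq_len(K)) if (any(k_cur == k))
      m[k, ] <- colMeans(th_cur[k_cur == k, , drop = FALSE])
    cl_means[[g]] <<- m
  }
  snapshot(1)

  for (g in seq_len(generations)) {
    cur_freq <- tabulate(k_cur, K) / n_agents
    p_k <- cur_freq * w_cluster
    if (sum(p_k) <= 0) abort("population collapsed: no populated cluster has positive fitness")
    p_k <- p_k / sum(p_k)
    k_new <- sample.int(K, n_agents, replace = TRUE, prob = p_k)
    empty <- which(tabulate(k_cur, K) == 0)
    if (length(empty) > 0 && any(k_new %in% empty)) {
      n_bad <- sum(k_new %in% empty)
      inform(sprintf("generation %d: resampled %d draw(s) from empty clusters", g, n_bad))
      ok <- setdiff(seq_len(K), empty)
      p_ok <- p_k[ok] / sum(p_k[ok])
      k_new[k_new %in% empty] <- ok[sample.int(length(ok), n_bad, replace = TRUE,
                                               prob = p_ok)]
    }
    th_new <- matrix(NA_real_, n_agents, D)
    for (k in sort(unique(k_new))) {
      members <- which(k_cur == k)
      child <- which(k_new == k)
      w_trait <- exp(beta * drop(th_cur[members, , drop = FALSE] %*% score[k, ]))
      parent <- members[sample.int(length(members), length(child), replace = TRUE,
                                   prob = w_trait)]
      th_p <- th_cur[parent, , drop = FALSE]
      if (is.finite(kappa)) {
        for (j in seq_along(child))
          th_new[child[j], ] <- rdirichlet_mat(1, kappa * pmax(th_p[j, ], 1e-8))
      } else {
        th_new[child, ] <- th_p
      }
    }
    k_cur <- k_new
    th_cur <- th_new
    snapshot(g + 1)
  }
  list(freq = freq, cluster_means = cl_means,
       final = list(k = k_cur, theta = th_cur))
}

#' Sample a melody from bigram mean distributions
#'
#' Generates a playable note table by sequentially sampling pitch and
#' metrical-position transitions from the conditional distributions of
#' bigram tables (each conditional is the row of the table renormalized;
#' rows with zero mass fall back to the table's marginal, logged). Pitches
#' start at middle C's octave; a sampled metrical position at or before the
#' current one advances the bar.
#'
#' @param pitch_mu Pitch bigram probability vector of length 432 (see
#'   [bigram_codec]).
#' @param rhythm_mu Rhythm bigram probability vector of length 2304.
#' @param length Number of notes to generate (`>= 2`).
#' @param seed Integer seed.
#' @param year Year stamp for the emitted table (default 0).
#' @return A note table tibble (`song_id`, `year`, `pitch`, `bar`,
#'   `position`) compatible with [parse_note_table()].
#' @export
sample_bigram_melody <- function(pitch_mu, rhythm_mu, length, seed = 1,
                                 year = 0L) {
  if (length < 2) abort("`length` must be at least 2")
  stopifnot(length(pitch_mu) == 432, length(rhythm_mu) == 2304)
  set.seed(seed)
  Pm <- matrix(pitch_mu, 12, 36, byrow = TRUE)   # rows q', cols q
  Rm <- matrix(rhythm_mu, 48, 48, byrow = TRUE)  # rows b', cols b
  p_marg <- colSums(Pm); b_marg <- colSums(Rm)

  draw_row <- function(mat, row, marg, what) {
    pr <- mat[row, ]
    if (sum(pr) <= 0) {
      inform(sprintf("zero-mass %s conditional; falling back to the marginal", what))
      pr <- marg
    }
    sample.int(ncol(mat), 1, prob = pr)
  }

  pitch <- integer(length); bar <- integer(length); pos <- integer(length)
  qp0 <- sample.int(12, 1, prob = pmax(rowSums(Pm), 1e-12)) - 1L
  pitch[1] <- 60L + qp0
  pos[1] <- sample.int(48, 1, prob = pmax(rowSums(Rm), 1e-12)) - 1L
  bar[1] <- 0L
  for (j in 2:length) {
    qp <- pitch[j - 1] %% 12L
    q <- draw_row(Pm, qp + 1L, p_marg, "pitch") - 1L
    d <- (q - qp) %% 36L
    d_signed <- if (d > 18L) d - 36L else d
    pitch[j] <- pitch[j - 1] + d_signed
    b <- draw_row(Rm, pos[j - 1] + 1L, b_marg, "rhythm") - 1L
    bar[j] <- bar[j - 1] + as.integer(b <= pos[j - 1])
    pos[j] <- b
  }
  tibble(song_id = "generated", year = as.integer(year),
         pitch = pitch, bar = bar, position = pos)
}

#' Match estimated clusters to reference clusters
#'
#' Finds the permutation of estimated clusters that minimizes the total SKL
#' divergence between matched mean distributions, by exhaustive search over
#' permutations (intended for small K).
#'
#' @param mu_ref,mu_est K x D matrices of mean distributions.
#' @param floor Probability floor for the SKL computations.
#' @return Integer vector `perm` such that estimated cluster `perm[k]`
#'   corresponds to reference cluster `k`.
#' @export
match_clusters <- function(mu_ref, mu_est, floor = 1e-6) {
  K <- nrow(mu_ref)
  if (nrow(mu_est) != K) abort("cluster counts differ")
  if (K > 7) abort("exhaustive matching supports K <= 7")
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cost[i, j] <- skl_divergence(mu_ref[i, ], mu_est[j, ], floor = floor)
  perms <- all_permutations(K)
  tot <- vapply(perms, function(p) sum(cost[cbind(seq_len(K), p)]), numeric(1))
  perms[[which.min(tot)]]
}

all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
  }
  out
}
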