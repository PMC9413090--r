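# Shared fixtures and independent oracles, built in code at test time.

# Random probability vector (Dirichlet via normalised gammas).
rand_prob <- function(C) {
  x <- stats::rgamma(C, shape = 1)
  x / sum(x)
}

# Two (or more) well-separated Gaussian blobs: the separable-data oracle
# world where any consistent classifier is near-perfect.
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(8, 8)),
                       sd = 0.5, seed = 1) {
  set.seed(seed)
  C <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(C), function(cl) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
           ncol = ncol(centers)) +
      matrix(centers[cl, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, y = rep(seq_len(C), each = n_per), centers = centers)
}

# Compact drift world for unit tests (the full default world is exercised
# in the acceptance suite).
small_world <- function(seed = 1, ...) {
  simulate_drift(drift_sim_config(C = 3L, D = 6L, B = 3L, n_per_batch = 60L,
                                  seed = seed, ...))
}

# Brute-force MMD oracle: builds the full (Ns+1) x (Ns+1) Gram matrix and
# evaluates the three-term expansion termwise. Independent of the package's
# vectorised path.
brute_mmd <- function(Xs, x, delta) {
  P <- rbind(Xs, x)
  n <- nrow(P)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- exp(-sum((P[i, ] - P[j, ])^2) / (2 * delta^2))
    }
  }
  Ns <- nrow(Xs)
  rad <- mean(G[seq_len(Ns), seq_len(Ns)]) -
    (2 / Ns) * sum(G[seq_len(Ns), n]) + G[n, n]
  sqrt(max(rad, 0))
}

# Direct-summation Hellinger oracle.
brute_hellinger <- function(p, q) {
  sqrt(0.5 * sum((sqrt(p) - sqrt(q))^2))
}

train_target <- function(ds, i_train, i_target) {
  list(train = list(X = ds$batches[[i_train]]$X, y = ds$batches[[i_train]]$y),
       target = list(X = ds$batches[[i_target]]$X, y = ds$batches[[i_target]]$y))
}
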