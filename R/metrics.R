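#' Validate a discrete probability vector
#'
#' Checks that `p` is a numeric vector with non-negative entries summing to 1
#' within `tol`. Used by all divergence primitives before they touch the
#' numbers.
#'
#' @param p Numeric vector of class probabilities.
#' @param tol Tolerance on the deviation of `sum(p)` from 1.
#' @return `p`, invisibly, if valid; otherwise an error is raised.
#' @keywords internal
validate_prob <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("probability vector must be a non-empty numeric vector")
  }
  if (any(p < 0)) {
    stop("probability vector has negative entries")
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("probability vector sums to %.10f, not 1 (tolerance %g)",
                 sum(p), tol))
  }
  invisible(p)
}

#' Hellinger distance between two discrete distributions
#'
#' Computes \eqn{H(p,q) = \frac{1}{\sqrt{2}} \lVert \sqrt{p} - \sqrt{q}
#' \rVert_2} with the square roots taken elementwise. The \eqn{1/\sqrt 2}
#' normalisation bounds the distance in \eqn{[0, 1]}: 0 when the
#' distributions coincide, 1 when their supports are disjoint. Hellinger
#' distance is a proper metric (symmetric, triangle inequality), which is
#' what makes it a well-behaved committee-disagreement measure.
#'
#' @param p,q Probability vectors of equal length (entries >= 0, summing to 1
#'   within `tol`).
#' @param tol Validation tolerance for the unit-sum check.
#' @return A scalar in `[0, 1]`.
#' @examples
#' hellinger(c(1, 0), c(0, 1))        # disjoint supports: 1
#' hellinger(c(1, 0), c(0.5, 0.5))    # sqrt(1 - sqrt(0.5))
#' @export
hellinger <- function(p, q, tol = 1e-8) {
  if (length(p) != length(q)) {
    stop(sprintf("length mismatch: %d vs %d", length(p), length(q)))
  }
  validate_prob(p, tol)
  validate_prob(q, tol)
  sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2)
}

#' Number of unordered committee pairs
#'
#' For `K` committee members the disagreement score sums over all
#' \eqn{K(K-1)/2} unordered pairs, which is also the upper bound of the
#' summed Hellinger disagreement.
#'
#' @param K Integer number of committee members, at least 2.
#' @return `K * (K - 1) / 2` as an integer-valued numeric.
#' @export
pair_count <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K != as.integer(K) || K < 2) {
    stop("K must be a single integer >= 2")
  }
  K * (K - 1) / 2
}

# Pairwise divergence between two n x C posterior matrices, vectorised over
# rows. Returns a length-n vector. `kind` selects the per-pair term.
.pair_divergence <- function(P, Q, kind, eps = 1e-12) {
  switch(kind,
    HD = sqrt(rowSums((sqrt(P) - sqrt(Q))^2)) / sqrt(2),
    KLD = {
      Pf <- pmax(P, eps)
      Qf <- pmax(Q, eps)
      0.5 * (rowSums(Pf * log(Pf / Qf)) + rowSums(Qf * log(Qf / Pf)))
    },
    JSD = {
      M <- (P + Q) / 2
      kl2 <- function(A, B) {
        term <- A * log2(A / B)
        term[A == 0] <- 0
        rowSums(term)
      }
      0.5 * kl2(P, M) + 0.5 * kl2(Q, M)
    },
    stop(sprintf("unknown disagreement kind '%s'", kind))
  )
}

#' Committee disagreement over all member pairs
#'
#' Sums a pairwise divergence over all unordered pairs of committee
#' posteriors for one candidate sample. With `kind = "HD"` (the CDAL
#' criterion) each pair contributes the Hellinger distance between the two
#' members' class posteriors, so the total lies in `[0, pair_count(K)]` and
#' vanishes exactly when the committee is unanimous. `"KLD"` uses the
#' symmetrised Kullback-Leibler divergence \eqn{\frac12(KL(p\|q) +
#' KL(q\|p))} with an `eps` floor on probabilities; `"JSD"` the
#' Jensen-Shannon divergence in base 2, so each pair term lies in `[0, 1]`.
#' KLD and JSD serve as the sample-selection baselines.
#'
#' @param members A `K x C` numeric matrix (or list of `K` equal-length
#'   vectors): one row per committee member, each row a class-posterior
#'   distribution over the same `C` classes.
#' @param kind One of `"HD"`, `"KLD"`, `"JSD"`.
#' @param eps Probability floor used by the KLD baseline.
#' @param tol Validation tolerance for each member row.
#' @return A non-negative scalar.
#' @export
committee_disagreement <- function(members, kind = c("HD", "KLD", "JSD"),
                                   eps = 1e-12, tol = 1e-8) {
  kind <- match.arg(kind)
  if (is.list(members)) {
    lens <- lengths(members)
    if (length(unique(lens)) > 1L) {
      stop(sprintf("member posterior lengths differ: %s",
                   paste(lens, collapse = ", ")))
    }
    members <- do.call(rbind, members)
  }
  if (!is.matrix(members)) members <- as.matrix(members)
  K <- nrow(members)
  if (K < 2L) stop("committee needs at least 2 members")
  apply(members, 1L, validate_prob, tol = tol)
  total <- 0
  for (j in seq_len(K - 1L)) {
    for (h in seq.int(j + 1L, K)) {
      total <- total +
        .pair_divergence(members[j, , drop = FALSE],
                         members[h, , drop = FALSE], kind, eps)
    }
  }
  as.numeric(total)
}

# Disagreement for many candidates at once: `posteriors` is a list of K
# matrices, each n x C (member posteriors over the same n samples). Returns
# a length-n vector. Hot path of score_candidates().
.disagreement_many <- function(posteriors, kind = "HD", eps = 1e-12) {
  K <- length(posteriors)
  n <- nrow(posteriors[[1L]])
  total <- numeric(n)
  for (j in seq_len(K - 1L)) {
    for (h in seq.int(j + 1L, K)) {
      total <- total + .pair_divergence(posteriors[[j]], posteriors[[h]],
                                        kind, eps)
    }
  }
  total
}

#' Gaussian kernel configuration
#'
#' Bundles the Gaussian bandwidth \eqn{\delta} used by the MMD. When `delta`
#' is not given it is derived from the feature dimension by
#' [default_delta()].
#'
#' @param delta Positive bandwidth, or `NULL` to derive it from
#'   `feature_dim`.
#' @param feature_dim Positive integer feature dimension `D`; required when
#'   `delta` is `NULL`.
#' @return A list with elements `delta` and `feature_dim`, class
#'   `"kernel_config"`.
#' @export
kernel_config <- function(delta = NULL, feature_dim = NULL) {
  if (is.null(delta)) {
    if (is.null(feature_dim)) {
      stop("either delta or feature_dim must be supplied")
    }
    delta <- default_delta(feature_dim)
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a single positive number")
  }
  structure(list(delta = delta, feature_dim = feature_dim),
            class = "kernel_config")
}

#' Default Gaussian bandwidth from the feature dimension
#'
#' Returns \eqn{\sqrt{D/2}}, the dimension-based bandwidth heuristic used
#' for the MMD kernel: at the reference sensor array's 128-dimensional
#' feature vector it gives \eqn{\delta = 8}. The bandwidth remains
#' user-overridable through [kernel_config()].
#'
#' @param D Positive integer feature dimension.
#' @return `sqrt(D / 2)`.
#' @examples
#' default_delta(128)  # 8
#' @export
default_delta <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || D != as.integer(D) || D < 1) {
    stop("D must be a single integer >= 1")
  }
  sqrt(D / 2)
}

#' Gaussian (RBF) kernel between two feature vectors
#'
#' \eqn{k(x, y) = \exp(-\lVert x - y \rVert^2 / (2\delta^2))}. Equals 1 iff
#' `x == y` and decreases strictly with the Euclidean distance, so the
#' induced Gram matrices are positive semi-definite and every point has unit
#' self-similarity — the property the MMD expansion relies on.
#'
#' @param x,y Numeric vectors of equal length.
#' @param cfg A [kernel_config()] (or anything with a positive `$delta`).
#' @return A scalar in `(0, 1]`.
#' @export
gaussian_kernel <- function(x, y, cfg) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
  }
  exp(-sum((x - y)^2) / (2 * cfg$delta^2))
}

# Mean of the source-source Gram matrix, (1/Ns^2) sum_i sum_i' k(xi, xi').
# Independent of the candidate, so computed once per source set and reused
# across all candidates.
.source_self_term <- function(Xs, delta) {
  G <- as.matrix(stats::dist(Xs))^2
  mean(exp(-G / (2 * delta^2)))
}

# Squared Euclidean distances between every row of A and every row of B
# (nrow(A) x nrow(B)), via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b.
.cross_sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' MMD between a candidate sample and the source-domain mean embedding
#'
#' The maximum mean discrepancy between the kernel mean embedding of the
#' source set and the embedding of a single candidate point,
#' \deqn{MMD(X_S, x) = \sqrt{\frac{1}{N_S^2}\sum_{i,i'} k(x_{Si}, x_{Si'})
#'   - \frac{2}{N_S}\sum_i k(x_{Si}, x) + k(x, x)}.}
#' A large value means the candidate sits far from the source-domain centre
#' in the RKHS — i.e. it carries much drift information. Since
#' \eqn{k \le 1} the result is bounded by \eqn{\sqrt 2}. The radicand is a
#' squared RKHS norm; if floating-point cancellation drives it slightly
#' negative it is clamped to 0.
#'
#' @param Xs Numeric matrix of source samples, one row per sample.
#' @param x Numeric candidate vector with `ncol(Xs)` entries.
#' @param cfg A [kernel_config()].
#' @param source_term Optional precomputed source-source Gram mean; pass it
#'   when scoring many candidates against the same source set.
#' @return A non-negative scalar, at most `sqrt(2)`.
#' @export
mmd_to_source <- function(Xs, x, cfg, source_term = NULL) {
  Xs <- as.matrix(Xs)
  if (nrow(Xs) < 1L) stop("source set must contain at least one sample")
  if (ncol(Xs) != length(x)) {
    stop(sprintf("dimension mismatch: source has %d features, candidate %d",
                 ncol(Xs), length(x)))
  }
  if (is.null(source_term)) source_term <- .source_self_term(Xs, cfg$delta)
  cross <- exp(-colSums((t(Xs) - x)^2) / (2 * cfg$delta^2))
  rad <- source_term - 2 * mean(cross) + 1
  sqrt(max(rad, 0))
}

# MMD of every row of U against the source set, sharing the source-source
# term across candidates. Returns a length-nrow(U) vector.
.mmd_many <- function(Xs, U, delta, source_term = NULL) {
  Xs <- as.matrix(Xs)
  U <- as.matrix(U)
  if (is.null(source_term)) source_term <- .source_self_term(Xs, delta)
  Kc <- exp(-.cross_sqdist(Xs, U) / (2 * delta^2))
  rad <- source_term - 2 * colMeans(Kc) + 1
  sqrt(pmax(rad, 0))
}
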