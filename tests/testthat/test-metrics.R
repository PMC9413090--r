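test_that("hellinger matches its closed form on boundary and interior cases", {
  expect_identical(hellinger(c(1, 0), c(1, 0)), 0)
  expect_identical(hellinger(c(1, 0), c(0, 1)), 1)
  # frozen from the direct-summation oracle brute_hellinger(c(1,0), c(.5,.5))
  expect_equal(hellinger(c(1, 0), c(0.5, 0.5)), 0.541196100146197,
               tolerance = 1e-12)
  expect_equal(hellinger(c(1, 0), c(0.5, 0.5)),
               sqrt(1 - sqrt(0.5)), tolerance = 1e-12)
})

test_that("hellinger rejects invalid distributions", {
  expect_error(hellinger(c(1, 0), c(1, 0, 0)), "length mismatch")
  expect_error(hellinger(c(1.2, -0.2), c(0.5, 0.5)), "negative")
  expect_error(hellinger(c(0.6, 0.6), c(0.5, 0.5)), "sums to")
})

test_that("hellinger is a symmetric, bounded metric on random distributions", {
  set.seed(42)
  for (i in 1:1000) {
    C <- sample(2:6, 1)
    p <- rand_prob(C); q <- rand_prob(C); r <- rand_prob(C)
    hpq <- hellinger(p, q)
    expect_gte(hpq, 0)
    expect_lte(hpq, 1)
    expect_equal(hpq, hellinger(q, p), tolerance = 1e-12)
    expect_equal(hpq, brute_hellinger(p, q), tolerance = 1e-12)
    expect_lte(hpq, hellinger(p, r) + hellinger(r, q) + 1e-12)
  }
  p <- rand_prob(4)
  expect_equal(hellinger(p, p), 0)
})

test_that("pair_count enumerates unordered pairs", {
  expect_equal(pair_count(2), 1)
  expect_equal(pair_count(3), 3)
  expect_equal(pair_count(4), 6)
  # enumeration oracle
  for (K in 2:8) expect_equal(pair_count(K), nrow(t(combn(K, 2))))
  expect_error(pair_count(1), "K must be")
})

test_that("committee disagreement sums pairwise divergences", {
  unanimous <- matrix(0.5, nrow = 3, ncol = 2)
  expect_equal(committee_disagreement(unanimous, "HD"), 0)
  expect_equal(committee_disagreement(rbind(c(1, 0), c(0, 1)), "HD"), 1)
  # frozen sum of the three pairwise oracle values:
  # H((1,0),(0,1)) + H((1,0),(.5,.5)) + H((0,1),(.5,.5))
  tri <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  expect_equal(committee_disagreement(tri, "HD"), 2.08239220029239,
               tolerance = 1e-10)
  expect_error(committee_disagreement(list(c(1, 0), c(0.2, 0.3, 0.5))),
               "lengths differ")
  expect_error(committee_disagreement(matrix(c(1, 0), nrow = 1)),
               "at least 2")
})

test_that("disagreement kinds respect their bounds on random committees", {
  set.seed(7)
  for (i in 1:300) {
    K <- sample(2:6, 1)
    C <- sample(2:5, 1)
    members <- t(vapply(seq_len(K), function(k) rand_prob(C), numeric(C)))
    hd <- committee_disagreement(members, "HD")
    expect_gte(hd, 0)
    expect_lte(hd, pair_count(K))
    expect_gte(committee_disagreement(members, "KLD"), 0)
    jsd <- committee_disagreement(members, "JSD")
    expect_gte(jsd, 0)
    expect_lte(jsd, pair_count(K) + 1e-10)  # each base-2 pair term <= 1
  }
  identical_members <- matrix(rand_prob(4), nrow = 5, ncol = 4, byrow = TRUE)
  expect_lt(committee_disagreement(identical_members, "HD"), 1e-10)
})

test_that("gaussian kernel evaluates the RBF formula", {
  cfg <- kernel_config(delta = 5)
  v <- c(1.3, -2, 0.5)
  expect_equal(gaussian_kernel(v, v, cfg), 1)
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), cfg), exp(-0.5),
               tolerance = 1e-12)
  # ||x - y||^2 = 2 delta^2 forces exp(-1)
  d <- kernel_config(delta = 2)
  expect_equal(gaussian_kernel(c(0, 0), c(sqrt(8), 0), d), exp(-1),
               tolerance = 1e-12)
  expect_error(gaussian_kernel(c(1, 2), c(1, 2, 3), cfg), "length mismatch")
})

test_that("gaussian kernel Gram matrices are positive semi-definite", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    D <- sample(2:8, 1)
    delta <- stats::runif(1, 0.3, 5)
    X <- matrix(stats::rnorm(n * D), ncol = D)
    cfg <- kernel_config(delta = delta)
    G <- outer(seq_len(n), seq_len(n),
               Vectorize(function(a, b) gaussian_kernel(X[a, ], X[b, ], cfg)))
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("default bandwidth follows the sqrt(D/2) rule", {
  expect_identical(default_delta(128), 8)
  expect_identical(default_delta(2), 1)
  expect_identical(default_delta(32), 4)
  expect_error(default_delta(0), "D must be")
  expect_equal(kernel_config(feature_dim = 128)$delta, 8)
})

test_that("mmd_to_source matches direct evaluation on hand-built cases", {
  cfg <- kernel_config(delta = 5)
  x <- c(0.7, -1.2)
  expect_equal(mmd_to_source(rbind(x), x, cfg), 0)
  # frozen from the explicit triple-summation oracle brute_mmd
  expect_equal(mmd_to_source(rbind(c(0, 0), c(0, 0)), c(3, 4), cfg),
               sqrt(2 - 2 * exp(-0.5)), tolerance = 1e-12)
  expect_equal(mmd_to_source(rbind(c(0, 0), c(0, 0)), c(3, 4), cfg),
               0.887095643419994, tolerance = 1e-10)
  expect_error(mmd_to_source(matrix(0, 2, 3), c(1, 2), cfg), "dimension")
  expect_error(mmd_to_source(matrix(0, 0, 2), c(1, 2), cfg), "at least one")
})

test_that("mmd_to_source agrees with the Gram-matrix oracle and is bounded", {
  set.seed(13)
  for (i in 1:100) {
    Ns <- sample(1:50, 1)
    D <- sample(1:20, 1)
    delta <- stats::runif(1, 0.5, 4)
    Xs <- matrix(stats::rnorm(Ns * D, sd = 2), ncol = D)
    x <- stats::rnorm(D, sd = 2)
    cfg <- kernel_config(delta = delta)
    got <- mmd_to_source(Xs, x, cfg)
    expect_equal(got, brute_mmd(Xs, x, delta), tolerance = 1e-10)
    expect_lte(got, sqrt(2))
  }
})

test_that("mmd_to_source is invariant to source permutation and rigid translation", {
  set.seed(17)
  cfg <- kernel_config(delta = 1.5)
  for (i in 1:50) {
    Ns <- sample(2:30, 1)
    D <- sample(2:10, 1)
    Xs <- matrix(stats::rnorm(Ns * D), ncol = D)
    x <- stats::rnorm(D)
    base <- mmd_to_source(Xs, x, cfg)
    perm <- sample(Ns)
    expect_equal(mmd_to_source(Xs[perm, , drop = FALSE], x, cfg), base,
                 tolerance = 1e-12)
    shift <- stats::rnorm(D, sd = 3)
    Xs2 <- sweep(Xs, 2, shift, "+")
    expect_equal(mmd_to_source(Xs2, x + shift, cfg), base, tolerance = 1e-9)
  }
})
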