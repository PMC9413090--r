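test_that("weighted score evaluates the linear combination", {
  hd <- c(1, 0, 2)
  mmd <- c(0.5, 1, 0)
  expect_equal(weighted_score(hd, mmd, 0.5), c(0.75, 0.5, 1.0))
  expect_equal(weighted_score(hd, mmd, 1), mmd)
  expect_equal(weighted_score(hd, mmd, 0), hd)
  expect_error(weighted_score(hd, mmd, 1.2), "omega1")
})

test_that("score_candidates degenerates to single-criterion rankings", {
  w <- small_world(seed = 6)
  tt <- train_target(w, 1, 3)
  hp <- chair_hyperparams(10, 1 / 6)
  m <- fit_committee(tt$train$X, tt$train$y, K = 4, hp = hp, seed = 2)
  kc <- kernel_config(feature_dim = 6)
  s_mid <- score_candidates(m, tt$train$X, tt$target$X, 0.5, kc)
  s_mmd <- score_candidates(m, tt$train$X, tt$target$X, 1, kc)
  s_hd <- score_candidates(m, tt$train$X, tt$target$X, 0, kc)
  expect_equal(s_mmd$score, s_mid$mmd)
  expect_equal(s_hd$score, s_mid$hd)
  expect_equal(order(-s_mmd$score), order(-s_mid$mmd))
  expect_equal(order(-s_hd$score), order(-s_mid$hd))
  expect_true(all(s_mid$hd <= pair_count(4) + 1e-12))
  expect_true(all(s_mid$mmd <= sqrt(2) + 1e-12))
  expect_error(score_candidates(m, tt$train$X, tt$target$X[0, , drop = FALSE],
                                0.5, kc), "empty")
})

test_that("select_top_n matches a full-sort oracle and breaks ties by id", {
  sc <- data.frame(sample_id = 1:3, score = c(0.75, 0.5, 1.0))
  expect_equal(select_top_n(sc, 2), c(3L, 1L))
  expect_equal(sort(select_top_n(sc, 3)), 1:3)
  ties <- data.frame(sample_id = 1:5, score = rep(0.4, 5))
  expect_equal(select_top_n(ties, 3), 1:3)
  expect_error(select_top_n(sc, 4), "N = 4.*3")

  set.seed(23)
  for (i in 1:200) {
    n <- sample(5:500, 1)
    # duplicate-prone scores exercise the tie rule
    sc <- data.frame(sample_id = seq_len(n),
                     score = round(stats::runif(n), 2))
    N <- sample(seq_len(n), 1)
    got <- select_top_n(sc, N)
    oracle <- sc$sample_id[order(-sc$score, sc$sample_id)][seq_len(N)]
    expect_identical(got, oracle)
  }
})

test_that("apply_selection moves rows with their labels and validates ids", {
  set.seed(31)
  train <- list(X = matrix(stats::rnorm(200), ncol = 2), y = rep(1:2, 50))
  target <- list(X = matrix(stats::rnorm(100), ncol = 2), y = rep(1:2, 25))
  sel <- apply_selection(train, target, c(5L, 1L, 50L))
  expect_equal(nrow(sel$updated_train$X), 103)
  expect_equal(nrow(sel$updated_target$X), 47)
  expect_equal(sel$updated_train$y[101:103], target$y[c(5, 1, 50)])
  expect_equal(sel$updated_train$X[101:103, ], target$X[c(5, 1, 50), ])
  # untouched target rows keep their order
  expect_equal(sel$updated_target$X, target$X[-c(1, 5, 50), ])

  one <- apply_selection(train, target, 7L)
  expect_equal(nrow(one$updated_train$X), 101)
  expect_error(apply_selection(train, target, integer(0)), "at least one")
  expect_error(apply_selection(train, target, c(3L, 3L)), "duplicate")
  expect_error(apply_selection(train, target, 51L), "out of range")
  # re-applying ids after the pool shrank: the rows are gone
  expect_error(apply_selection(sel$updated_train, sel$updated_target, 50L),
               "out of range")
})

test_that("run_cdal conserves samples, labels and is deterministic", {
  w <- small_world(seed = 8)
  tt <- train_target(w, 1, 2)
  hp <- chair_hyperparams(10, 1 / 6)
  r1 <- run_cdal(tt$train, tt$target, N = 10, omega1 = 0.5, hp = hp, seed = 3)
  r2 <- run_cdal(tt$train, tt$target, N = 10, omega1 = 0.5, hp = hp, seed = 3)
  expect_identical(r1$selection$selected_ids, r2$selection$selected_ids)
  expect_identical(r1$accuracy, r2$accuracy)

  sel <- r1$selection
  expect_equal(nrow(sel$updated_train$X), nrow(tt$train$X) + 10)
  expect_equal(nrow(sel$updated_target$X), nrow(tt$target$X) - 10)
  # conservation: every row before appears exactly once after, same labels
  key <- function(X, y) sort(paste(apply(round(X, 10), 1, paste,
                                         collapse = ","), y))
  before <- key(rbind(tt$train$X, tt$target$X), c(tt$train$y, tt$target$y))
  after <- key(rbind(sel$updated_train$X, sel$updated_target$X),
               c(sel$updated_train$y, sel$updated_target$y))
  expect_identical(before, after)
})

test_that("a unanimous committee reduces CDAL to pure-MMD selection", {
  w <- small_world(seed = 9)
  tt <- train_target(w, 1, 3)
  hp <- chair_hyperparams(10, 1 / 6)
  kc <- kernel_config(feature_dim = 6)
  r <- run_cdal(tt$train, tt$target, N = 8, omega1 = 0.5, hp = hp,
                seed = 4, diversify = FALSE)
  mmd_rank <- data.frame(sample_id = seq_len(nrow(tt$target$X)),
                         score = .subset2(score_candidates(
                           fit_committee(tt$train$X, tt$train$y, hp = hp,
                                         seed = 4, diversify = FALSE),
                           tt$train$X, tt$target$X, 1, kc), "mmd"))
  expect_setequal(r$selection$selected_ids, select_top_n(mmd_rank, 8))
})

test_that("score differences cross at most once along the omega1 grid", {
  set.seed(37)
  grid <- seq(0, 1, by = 0.01)
  for (i in 1:200) {
    a <- c(hd = stats::runif(1, 0, 3), mmd = stats::runif(1, 0, 1.4))
    b <- c(hd = stats::runif(1, 0, 3), mmd = stats::runif(1, 0, 1.4))
    d <- vapply(grid, function(w) {
      weighted_score(a["hd"], a["mmd"], w) - weighted_score(b["hd"], b["mmd"], w)
    }, numeric(1))
    sign_changes <- sum(diff(sign(d[d != 0])) != 0)
    expect_lte(sign_changes, 1)
  }
})

test_that("extreme budgets behave: N = |target| - 1 leaves one test sample", {
  w <- small_world(seed = 10)
  tt <- train_target(w, 1, 2)
  hp <- chair_hyperparams(10, 1 / 6)
  nT <- nrow(tt$target$X)
  r <- run_cdal(tt$train, tt$target, N = nT - 1, omega1 = 0.5, hp = hp,
                seed = 1)
  expect_equal(nrow(r$selection$updated_target$X), 1)
  expect_true(r$accuracy %in% c(0, 1))
  expect_error(run_cdal(tt$train, tt$target, N = nT + 1, omega1 = 0.5,
                        hp = hp), "cannot select")
})

test_that("sequential mode picks distinct samples and conserves sizes", {
  w <- small_world(seed = 12)
  tt <- train_target(w, 1, 2)
  hp <- chair_hyperparams(10, 1 / 6)
  r <- run_cdal(tt$train, tt$target, N = 3, omega1 = 0.5, hp = hp,
                seed = 2, sequential = TRUE)
  expect_length(unique(r$selection$selected_ids), 3)
  expect_equal(nrow(r$selection$updated_train$X), nrow(tt$train$X) + 3)
  expect_equal(nrow(r$selection$updated_target$X), nrow(tt$target$X) - 3)
})
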