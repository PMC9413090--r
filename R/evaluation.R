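#' Classification accuracy in percent
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return `100 * mean(y_true == y_pred)`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors must have equal length")
  }
  if (length(y_true) == 0L) return(NA_real_)
  100 * mean(y_true == y_pred)
}

#' Experiment configuration
#'
#' Collects every knob of the evaluation protocols: which drift setting to
#' run, the selection strategy and its weight, the sample budget `N`, the
#' committee size, the kernel bandwidth, the chair grids and the tuning
#' policy for `omega1`.
#'
#' The default chair grid is a compact 3 x 3 decade grid with 3-fold CV,
#' suited to standardised synthetic data; pass `c_grid = 10^(0:15)`,
#' `gamma_grid = 10^(-10:5)`, `folds = 5` for the full benchmark-scale
#' search.
#'
#' @param setting Drift protocol: 1 (fixed batch-1 source) or 2 (sliding
#'   adjacent batches).
#' @param strategy One of `"CDAL"`, `"AL-HD"`, `"AL-KLD"`, `"AL-JSD"`,
#'   `"RANDOM"`.
#' @param N Number of target samples selected per pair (default 30).
#' @param omega1 Fixed MMD weight in `[0, 1]`, or `"grid"` to tune it.
#' @param omega1_grid Candidate weights when tuning (default 0.01..0.99 by
#'   0.01).
#' @param N_grid Budgets swept by [n_sweep()].
#' @param K Committee size.
#' @param delta Gaussian MMD bandwidth; `NULL` derives it from the feature
#'   dimension via [default_delta()].
#' @param hp Fixed [chair_hyperparams()]; `NULL` runs [grid_search_chair()]
#'   per source set.
#' @param c_grid,gamma_grid,folds Chair grid-search controls.
#' @param standardize Standardise features by source statistics before
#'   anything else (default `TRUE`).
#' @param policy `omega1` tuning policy: `"holdout"` validates on a
#'   held-out labelled slice of the selected samples; `"target"`
#'   reproduces test-side tuning on the remaining target set.
#' @param diversify Bootstrap-diversify the committee members (see
#'   [fit_committee()]); turning this off forces a unanimous committee.
#' @param seed Master seed; committee bootstraps, fold assignment, the
#'   random control and the holdout split all derive from it.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(setting = 1L,
                              strategy = c("CDAL", "AL-HD", "AL-KLD",
                                           "AL-JSD", "RANDOM"),
                              N = 30L,
                              omega1 = 0.5,
                              omega1_grid = seq(0.01, 0.99, by = 0.01),
                              N_grid = c(5L, 10L, 20L, 30L, 40L, 50L),
                              K = 4L,
                              delta = NULL,
                              hp = NULL,
                              c_grid = 10^c(0, 2, 4),
                              gamma_grid = 10^c(-2, -1, 0),
                              folds = 3L,
                              standardize = TRUE,
                              policy = c("holdout", "target"),
                              diversify = TRUE,
                              seed = 1L) {
  strategy <- match.arg(strategy)
  policy <- match.arg(policy)
  if (!setting %in% c(1L, 2L)) stop("setting must be 1 or 2")
  if (N < 1L) stop("N must be >= 1")
  if (is.numeric(omega1)) {
    if (omega1 < 0 || omega1 > 1) stop("omega1 must lie in [0, 1]")
  } else if (!identical(omega1, "grid")) {
    stop("omega1 must be a number in [0, 1] or \"grid\"")
  }
  structure(list(setting = as.integer(setting), strategy = strategy,
                 N = as.integer(N), omega1 = omega1,
                 omega1_grid = omega1_grid, N_grid = as.integer(N_grid),
                 K = as.integer(K), delta = delta, hp = hp,
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 folds = as.integer(folds), standardize = standardize,
                 policy = policy, diversify = diversify,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Kernel config for a given feature dimension under this experiment config.
.cfg_kernel <- function(cfg, D) {
  if (is.null(cfg$delta)) kernel_config(feature_dim = D)
  else kernel_config(delta = cfg$delta, feature_dim = D)
}

# Chair hyperparameters for a (standardised) source set: fixed or searched.
.cfg_hp <- function(cfg, train) {
  if (!is.null(cfg$hp)) return(cfg$hp)
  grid_search_chair(train$X, train$y, folds = cfg$folds,
                    c_grid = cfg$c_grid, gamma_grid = cfg$gamma_grid,
                    seed = cfg$seed)
}

# Chair accuracy (%) after moving `ids` from target to train.
.post_selection_accuracy <- function(train, target, ids, hp) {
  sel <- apply_selection(train, target, ids)
  chair <- .fit_chair(sel$updated_train$X, sel$updated_train$y, hp)
  pred <- .chair_only_predict(chair, sel$updated_target$X)
  accuracy(sel$updated_target$y, pred)
}

#' Tune the MMD weight on a source/target pair
#'
#' Fits the committee once, computes the per-candidate disagreement and MMD
#' once, then walks the `omega1` grid: each weight induces a top-`N`
#' selection whose quality is measured under the configured validation
#' policy. Under `policy = "holdout"` a labelled slice (one third, at least
#' two samples) of the selected set is held out; the chair is refit on the
#' source plus the remaining selected samples and validated on the slice —
#' no unlabelled target information enters the choice. Under
#' `policy = "target"` the chair is validated on the post-selection target
#' set itself (test-side tuning, kept for comparability with published
#' protocols). Ties go to the smaller `omega1`. Selections repeated along
#' the grid are evaluated once and cached.
#'
#' @param train,target Lists with elements `X` and `y` (already
#'   standardised if desired).
#' @param cfg An [experiment_config()]; `cfg$omega1_grid`, `cfg$N`,
#'   `cfg$K`, `cfg$policy` and the chair settings are honoured.
#' @param hp Chair hyperparameters; defaults to `.cfg_hp` resolution.
#' @param kind Disagreement kind fed to the scorer.
#' @return A list with `omega1` (the selected weight), `table` (grid
#'   data.frame of `omega1` and validation `accuracy`).
#' @export
optimize_omega1 <- function(train, target, cfg = experiment_config(),
                            hp = NULL, kind = "HD") {
  if (is.null(hp)) hp <- .cfg_hp(cfg, train)
  kc <- .cfg_kernel(cfg, ncol(train$X))
  m <- fit_committee(train$X, train$y, K = cfg$K, hp = hp, seed = cfg$seed,
                     diversify = cfg$diversify)
  base <- score_candidates(m, train$X, target$X, omega1 = 0, cfg = kc,
                           kind = kind)
  N <- cfg$N
  grid <- cfg$omega1_grid
  n_val <- max(2L, floor(N / 3))
  if (cfg$policy == "holdout" && n_val >= N) {
    stop("N too small to hold out a validation slice; use policy = \"target\"")
  }

  cache <- new.env(parent = emptyenv())
  eval_ids <- function(ids) {
    key <- paste(ids, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    acc <- if (cfg$policy == "target") {
      .post_selection_accuracy(train, target, ids, hp)
    } else {
      # average over a few holdout splits: a single slice of ~N/3 labelled
      # samples is too noisy to rank 99 candidate weights
      mean(vapply(1:3, function(r) {
        set.seed(cfg$seed + 211L + r)
        val <- sample(ids, n_val)
        fit_ids <- setdiff(ids, val)
        Xtr <- rbind(as.matrix(train$X),
                     as.matrix(target$X)[fit_ids, , drop = FALSE])
        ytr <- c(train$y, target$y[fit_ids])
        chair <- .fit_chair(Xtr, ytr, hp)
        pred <- .chair_only_predict(chair,
                                    as.matrix(target$X)[val, , drop = FALSE])
        accuracy(target$y[val], pred)
      }, numeric(1)))
    }
    cache[[key]] <- acc
    acc
  }

  accs <- vapply(grid, function(w) {
    sc <- base
    sc$score <- weighted_score(sc$hd, sc$mmd, w)
    ids <- sort(select_top_n(sc, N))
    eval_ids(ids)
  }, numeric(1))

  best <- grid[which.max(accs)]  # which.max takes the first (smallest) tie
  list(omega1 = best, table = data.frame(omega1 = grid, accuracy = accs))
}

# Run one source/target pair under the configured strategy. Inputs are raw
# (unstandardised) train/target lists; returns one result row.
.run_pair <- function(train, target, cfg, hp = NULL) {
  if (cfg$standardize) {
    std <- standardize_by_source(train, target)
    train <- std$train
    target <- std$target
  }
  if (is.null(hp)) hp <- .cfg_hp(cfg, train)
  kc <- .cfg_kernel(cfg, ncol(train$X))
  N <- cfg$N
  if (N > nrow(target$X)) {
    stop(sprintf("N = %d exceeds target batch size %d", N, nrow(target$X)))
  }

  omega1_used <- NA_real_
  if (cfg$strategy == "RANDOM") {
    set.seed(cfg$seed + 977L)
    ids <- sort(sample.int(nrow(target$X), N))
  } else {
    kind <- switch(cfg$strategy,
                   CDAL = "HD", `AL-HD` = "HD",
                   `AL-KLD` = "KLD", `AL-JSD` = "JSD")
    w <- if (cfg$strategy == "CDAL") cfg$omega1 else 0
    if (identical(w, "grid")) {
      w <- optimize_omega1(train, target, cfg, hp = hp, kind = kind)$omega1
    }
    omega1_used <- w
    m <- fit_committee(train$X, train$y, K = cfg$K, hp = hp, seed = cfg$seed,
                       diversify = cfg$diversify)
    sc <- score_candidates(m, train$X, target$X, omega1 = w, cfg = kc,
                           kind = kind)
    ids <- select_top_n(sc, N)
  }
  acc <- .post_selection_accuracy(train, target, ids, hp)
  list(accuracy = acc, omega1 = omega1_used, hp = hp, ids = ids)
}

# Shared driver for the two drift protocols: `pairs` is a list of
# (train_batch, test_batch) index pairs into ds$batches.
.run_pairs <- function(ds, cfg, pairs) {
  rows <- lapply(pairs, function(pr) {
    train_b <- ds$batches[[pr[1L]]]
    test_b <- ds$batches[[pr[2L]]]
    res <- .run_pair(list(X = train_b$X, y = train_b$y),
                     list(X = test_b$X, y = test_b$y), cfg)
    data.frame(train_batch = train_b$batch_id, test_batch = test_b$batch_id,
               strategy = cfg$strategy, N = cfg$N,
               omega1 = res$omega1, c = res$hp$c, gamma = res$hp$gamma,
               accuracy = res$accuracy)
  })
  do.call(rbind, rows)
}

#' Long-term drift protocol (Setting 1)
#'
#' Batch 1 is the drift-free source; every later batch in turn is the
#' drifted target. Each pair runs the configured selection strategy and
#' records the post-selection chair accuracy (%) on the reduced target
#' batch.
#'
#' @param ds A [batched_dataset()] with at least 2 batches.
#' @param cfg An [experiment_config()].
#' @return A data.frame with one row per target batch: `train_batch`,
#'   `test_batch`, `strategy`, `N`, `omega1`, `c`, `gamma`, `accuracy`.
#' @export
run_setting1 <- function(ds, cfg = experiment_config(setting = 1L)) {
  B <- length(ds$batches)
  if (B < 2L) stop("need at least 2 batches")
  .run_pairs(ds, cfg, lapply(2:B, function(k) c(1L, k)))
}

#' Short-term drift protocol (Setting 2)
#'
#' Sliding pairing: batch k is the source and batch k+1 the drifted target,
#' for k = 1 .. B-1.
#'
#' @inheritParams run_setting1
#' @return A data.frame as in [run_setting1()], one row per adjacent pair.
#' @export
run_setting2 <- function(ds, cfg = experiment_config(setting = 2L)) {
  B <- length(ds$batches)
  if (B < 2L) stop("need at least 2 batches")
  .run_pairs(ds, cfg, lapply(seq_len(B - 1L), function(k) c(k, k + 1L)))
}

#' Sweep the selection budget N
#'
#' Re-runs the configured protocol for every budget in `cfg$N_grid`. For
#' the score-based strategies the committee and the per-candidate
#' disagreement/MMD scores are computed once per source/target pair and
#' reused across budgets (only the top-`N` cut, the set update and the
#' chair refit depend on `N`). When `cfg$omega1 = "grid"` the weight is
#' tuned once per pair at `cfg$N` and reused across the sweep. A budget
#' exceeding a target batch size yields an `NA` cell with a warning.
#'
#' @inheritParams run_setting1
#' @return A data.frame with one row per (pair, N).
#' @export
n_sweep <- function(ds, cfg = experiment_config()) {
  B <- length(ds$batches)
  if (B < 2L) stop("need at least 2 batches")
  pairs <- if (cfg$setting == 1L) {
    lapply(2:B, function(k) c(1L, k))
  } else {
    lapply(seq_len(B - 1L), function(k) c(k, k + 1L))
  }

  rows <- list()
  for (pr in pairs) {
    train_b <- ds$batches[[pr[1L]]]
    test_b <- ds$batches[[pr[2L]]]
    train <- list(X = train_b$X, y = train_b$y)
    target <- list(X = test_b$X, y = test_b$y)
    if (cfg$standardize) {
      std <- standardize_by_source(train, target)
      train <- std$train
      target <- std$target
    }
    hp <- .cfg_hp(cfg, train)
    kc <- .cfg_kernel(cfg, ncol(train$X))

    base <- NULL
    w <- NA_real_
    if (cfg$strategy != "RANDOM") {
      kind <- switch(cfg$strategy,
                     CDAL = "HD", `AL-HD` = "HD",
                     `AL-KLD` = "KLD", `AL-JSD` = "JSD")
      w <- if (cfg$strategy == "CDAL") cfg$omega1 else 0
      if (identical(w, "grid")) {
        w <- optimize_omega1(train, target, cfg, hp = hp, kind = kind)$omega1
      }
      m <- fit_committee(train$X, train$y, K = cfg$K, hp = hp,
                         seed = cfg$seed, diversify = cfg$diversify)
      base <- score_candidates(m, train$X, target$X, omega1 = w, cfg = kc,
                               kind = kind)
    }

    for (N in cfg$N_grid) {
      if (N >= nrow(target$X)) {
        warning(sprintf(
          "skipping N = %d for pair %d-%d: target batch has %d samples",
          N, train_b$batch_id, test_b$batch_id, nrow(target$X)))
        acc <- NA_real_
      } else if (cfg$strategy == "RANDOM") {
        set.seed(cfg$seed + 977L + N)
        ids <- sort(sample.int(nrow(target$X), N))
        acc <- .post_selection_accuracy(train, target, ids, hp)
      } else {
        ids <- select_top_n(base, N)
        acc <- .post_selection_accuracy(train, target, ids, hp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        train_batch = train_b$batch_id, test_batch = test_b$batch_id,
        strategy = cfg$strategy, N = N, omega1 = w,
        c = hp$c, gamma = hp$gamma, accuracy = acc)
    }
  }
  do.call(rbind, rows)
}

#' Serialise a run to JSON
#'
#' Full provenance record of a harness run: the configuration (including
#' the master seed), the result table and the package version.
#'
#' @param results Result data.frame from [run_setting1()], [run_setting2()]
#'   or [n_sweep()].
#' @param cfg The [experiment_config()] used.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(results, cfg, path) {
  cfg_plain <- unclass(cfg)
  if (!is.null(cfg_plain$hp)) cfg_plain$hp <- unclass(cfg_plain$hp)
  payload <- list(
    package = "cdal",
    version = as.character(utils::packageVersion("cdal")),
    config = cfg_plain,
    results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
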