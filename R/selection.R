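#' Weighted selection score
#'
#' The CDAL criterion combines the domain-shift term and the committee
#' disagreement linearly: \eqn{Score = \omega_1 \cdot MMD + (1 - \omega_1)
#' \cdot HD}. `omega1 = 1` ranks by MMD alone, `omega1 = 0` by committee
#' disagreement alone.
#'
#' @param hd Non-negative disagreement value(s).
#' @param mmd Non-negative MMD value(s).
#' @param omega1 Weight in `[0, 1]`.
#' @return Numeric score(s), same length as the inputs.
#' @export
weighted_score <- function(hd, mmd, omega1) {
  if (!is.numeric(omega1) || length(omega1) != 1L || omega1 < 0 || omega1 > 1) {
    stop("omega1 must be a single value in [0, 1]")
  }
  omega1 * mmd + (1 - omega1) * hd
}

#' Score every candidate target sample
#'
#' For each row of the query set `U` this computes the committee
#' disagreement (summed pairwise divergence of the member posteriors), the
#' MMD of the candidate against the source-domain mean embedding, and their
#' weighted combination. The source-source Gram term of the MMD does not
#' depend on the candidate and is computed once for the whole call.
#'
#' @param m A [fit_committee()] model.
#' @param Xs Source-domain feature matrix (the current training features).
#' @param U Query-set feature matrix, one candidate per row; must be
#'   non-empty.
#' @param omega1 Weight in `[0, 1]` of the MMD term.
#' @param cfg A [kernel_config()]; defaults to the dimension-derived
#'   bandwidth.
#' @param kind Disagreement kind: `"HD"` (default), `"KLD"` or `"JSD"`.
#' @return A data.frame with columns `sample_id` (row index into `U`),
#'   `hd`, `mmd`, `score`.
#' @export
score_candidates <- function(m, Xs, U, omega1 = 0.5,
                             cfg = kernel_config(feature_dim = ncol(U)),
                             kind = c("HD", "KLD", "JSD")) {
  kind <- match.arg(kind)
  U <- as.matrix(U)
  Xs <- as.matrix(Xs)
  if (nrow(U) == 0L) stop("query set is empty")
  if (ncol(U) != ncol(Xs)) {
    stop(sprintf("dimension mismatch: source has %d features, query %d",
                 ncol(Xs), ncol(U)))
  }
  posts <- .member_posteriors_all(m, U)
  hd <- .disagreement_many(posts, kind = kind)
  mmd <- .mmd_many(Xs, U, cfg$delta)
  data.frame(sample_id = seq_len(nrow(U)), hd = hd, mmd = mmd,
             score = weighted_score(hd, mmd, omega1))
}

#' Select the top-N scoring candidates
#'
#' Returns the `sample_id`s of the `N` largest scores; ties are broken
#' deterministically towards the smaller `sample_id`.
#'
#' @param scores A data.frame as returned by [score_candidates()] (needs
#'   columns `sample_id` and `score`).
#' @param N Number of samples to select, `1 <= N <= nrow(scores)`.
#' @return Integer vector of `N` sample ids.
#' @export
select_top_n <- function(scores, N) {
  if (!is.numeric(N) || length(N) != 1L || N < 1) {
    stop("N must be a single integer >= 1")
  }
  if (N > nrow(scores)) {
    stop(sprintf("cannot select N = %d samples from a query set of %d",
                 N, nrow(scores)))
  }
  ord <- order(-scores$score, scores$sample_id)
  scores$sample_id[ord[seq_len(N)]]
}

#' Move selected samples from the target set to the training set
#'
#' The selected rows leave the target pool and join the training set with
#' their ground-truth labels, which play the role of the expert annotator
#' (on a benchmark the true labels are known). Row order of the untouched
#' samples is preserved on both sides.
#'
#' @param train,target Lists with elements `X` (feature matrix) and `y`
#'   (labels).
#' @param selected Distinct, in-range row indices into `target$X`.
#' @return A list of class `"selection_result"` with `selected_ids`,
#'   `updated_train`, `updated_target`.
#' @export
apply_selection <- function(train, target, selected) {
  nT <- nrow(target$X)
  selected <- as.integer(selected)
  if (length(selected) < 1L) stop("at least one sample must be selected")
  if (anyDuplicated(selected)) stop("duplicate indices in selection")
  if (any(selected < 1L | selected > nT)) {
    stop(sprintf("selection indices out of range 1..%d", nT))
  }
  keep <- setdiff(seq_len(nT), selected)
  structure(list(
    selected_ids = selected,
    updated_train = list(
      X = rbind(as.matrix(train$X), as.matrix(target$X)[selected, , drop = FALSE]),
      y = c(train$y, target$y[selected])),
    updated_target = list(
      X = as.matrix(target$X)[keep, , drop = FALSE],
      y = target$y[keep])
  ), class = "selection_result")
}

#' Run one round of cross-domain active learning
#'
#' The full CDAL pass: fit the committee on the training set, score every
#' target sample by weighted disagreement + MMD, select the top `N` in one
#' batch, move them (with their labels) into the training set, refit the
#' chair on the enlarged training set, and report its accuracy on the
#' reduced target set.
#'
#' With `sequential = TRUE` the picks are made one at a time, refitting the
#' committee and rescoring the remaining pool after each pick (the slower,
#' fully adaptive variant of the loop); the default is the single-pass
#' batch selection.
#'
#' @param train,target Lists with elements `X` and `y`.
#' @param N Number of target samples to transfer.
#' @param omega1 MMD weight in `[0, 1]`.
#' @param K Number of committee members.
#' @param hp [chair_hyperparams()] for the chair.
#' @param cfg [kernel_config()]; defaults to the dimension-derived
#'   bandwidth.
#' @param kind Disagreement kind.
#' @param seed Seed for the committee fit.
#' @param sequential Rescore after every pick instead of one batch pass.
#' @param diversify Passed to [fit_committee()].
#' @return A list with `selection` (a `"selection_result"`, `$scores`
#'   attached), `accuracy` (fraction correct on the updated target set),
#'   `model` (the refit chair committee).
#' @export
run_cdal <- function(train, target, N, omega1 = 0.5, K = 4L,
                     hp = chair_hyperparams(10, 1 / ncol(train$X)),
                     cfg = kernel_config(feature_dim = ncol(train$X)),
                     kind = c("HD", "KLD", "JSD"), seed = 1L,
                     sequential = FALSE, diversify = TRUE) {
  kind <- match.arg(kind)
  if (N > nrow(target$X)) {
    stop(sprintf("cannot select N = %d samples from a target set of %d",
                 N, nrow(target$X)))
  }
  if (sequential) {
    cur_train <- train
    cur_target <- target
    picked <- integer(0)
    remaining_ids <- seq_len(nrow(target$X))
    all_scores <- NULL
    for (i in seq_len(N)) {
      m <- fit_committee(cur_train$X, cur_train$y, K = K, hp = hp,
                         seed = seed, diversify = diversify)
      sc <- score_candidates(m, cur_train$X, cur_target$X, omega1, cfg, kind)
      pick_local <- select_top_n(sc, 1L)
      picked <- c(picked, remaining_ids[pick_local])
      remaining_ids <- remaining_ids[-pick_local]
      step <- apply_selection(cur_train, cur_target, pick_local)
      cur_train <- step$updated_train
      cur_target <- step$updated_target
    }
    sel <- apply_selection(train, target, picked)
    scores <- NULL
  } else {
    m <- fit_committee(train$X, train$y, K = K, hp = hp, seed = seed,
                       diversify = diversify)
    scores <- score_candidates(m, train$X, target$X, omega1, cfg, kind)
    picked <- select_top_n(scores, N)
    sel <- apply_selection(train, target, picked)
  }
  sel$scores <- scores
  final <- fit_committee(sel$updated_train$X, sel$updated_train$y, K = K,
                         hp = hp, seed = seed, diversify = diversify)
  pred <- chair_predict(final, sel$updated_target$X)
  acc <- if (length(pred)) mean(pred == sel$updated_target$y) else NA_real_
  list(selection = sel, accuracy = acc, model = final)
}
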