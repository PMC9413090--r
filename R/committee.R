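#' Chair hyperparameters
#'
#' Penalty `c` and Gaussian-kernel width `gamma` for the SVM chair, with the
#' cross-validated accuracy attained when they were chosen by
#' [grid_search_chair()].
#'
#' @param c Positive SVM cost.
#' @param gamma Positive RBF kernel parameter.
#' @param cv_accuracy Cross-validated accuracy in `[0, 1]` (`NA` when the
#'   parameters were set by hand).
#' @return A list of class `"chair_hyperparams"`.
#' @export
chair_hyperparams <- function(c, gamma, cv_accuracy = NA_real_) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0) stop("c must be positive")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be positive")
  }
  structure(list(c = c, gamma = gamma, cv_accuracy = cv_accuracy),
            class = "chair_hyperparams")
}

# Canonical factor representation of integer class labels: levels are the
# sorted unique labels of the *training* set, shared by chair and members.
.as_class_factor <- function(y, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(y))
  factor(y, levels = classes)
}

# Feature matrix -> data.frame with stable column names for nnet::multinom.
.as_member_frame <- function(X, y = NULL) {
  X <- as.matrix(X)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(y)) df$.y <- y
  df
}

# Fit one softmax (multinomial logistic) member with light L2 regularisation.
# Weight initialisation in nnet is random, so the caller seeds the RNG.
.fit_member <- function(X, y_factor, decay = 1e-3, maxit = 200L) {
  df <- .as_member_frame(X, y_factor)
  nnet::multinom(.y ~ ., data = df, decay = decay, maxit = maxit,
                 trace = FALSE, MaxNWts = 5000L)
}

# Posterior matrix (n x C) from one member, with columns in class order even
# in the two-class case where multinom returns a single-column probability.
.member_probs <- function(member, X, classes) {
  df <- .as_member_frame(X)
  pr <- stats::predict(member, newdata = df, type = "probs")
  if (is.null(dim(pr))) {
    if (length(classes) == 2L) {
      pr <- cbind(1 - pr, pr)
    } else {
      pr <- matrix(pr, nrow = 1L)
    }
  }
  pr <- as.matrix(pr)
  colnames(pr) <- as.character(classes)
  unname_rows <- rownames(pr)
  if (!is.null(unname_rows)) rownames(pr) <- NULL
  pr
}

#' Fit a query-by-committee model
#'
#' Trains the chair — a Gaussian-kernel SVM used for the final class
#' decision — and `K` probabilistic committee members, multinomial softmax
#' classifiers whose class posteriors feed the disagreement score. Members
#' are diversified by fitting each on an independent bootstrap resample of
#' the training set (redrawn until every class is present); with
#' `diversify = FALSE` all members see the full training set and the
#' committee is unanimous by construction, which reduces CDAL scoring to a
#' pure MMD ranking. The whole fit is deterministic given `seed`.
#'
#' @param X Numeric feature matrix, one row per sample.
#' @param y Integer class labels.
#' @param K Number of committee members, at least 2.
#' @param hp [chair_hyperparams()] for the SVM chair.
#' @param seed Master seed; per-member seeds are derived from it.
#' @param diversify Bootstrap-resample the members? Default `TRUE`.
#' @param decay L2 penalty of the softmax members.
#' @return A list of class `"committee_model"` with elements `chair`,
#'   `members`, `classes`, `K`, `seed`, `hp`.
#' @export
fit_committee <- function(X, y, K = 4L, hp = chair_hyperparams(10, 1 / ncol(X)),
                          seed = 1L, diversify = TRUE, decay = 1e-3) {
  X <- as.matrix(X)
  if (!is.numeric(K) || length(K) != 1L || K < 2) {
    stop("K must be a single integer >= 2")
  }
  K <- as.integer(K)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training set must contain >= 2 classes")
  yf <- .as_class_factor(y, classes)

  chair <- e1071::svm(X, yf, kernel = "radial", cost = hp$c,
                      gamma = hp$gamma, scale = FALSE)

  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, K)
  members <- vector("list", K)
  n <- nrow(X)
  for (k in seq_len(K)) {
    set.seed(member_seeds[k])
    if (diversify) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == length(classes)) break
      }
      if (length(unique(y[idx])) < length(classes)) {
        stop("could not draw a bootstrap resample containing every class")
      }
    } else {
      idx <- seq_len(n)
    }
    members[[k]] <- .fit_member(X[idx, , drop = FALSE], yf[idx], decay = decay)
  }

  structure(list(chair = chair, members = members, classes = classes,
                 K = K, seed = seed, hp = hp, D = ncol(X)),
            class = "committee_model")
}

#' @export
print.committee_model <- function(x, ...) {
  cat(sprintf(
    "Query-by-committee model: SVM chair (c=%g, gamma=%g), %d softmax members, %d classes, D=%d\n",
    x$hp$c, x$hp$gamma, x$K, length(x$classes), x$D))
  invisible(x)
}

#' Committee posteriors for one candidate sample
#'
#' Queries every committee member for its class posterior at `x`. The rows
#' of the result are the `K` probability distributions entering the
#' pairwise-disagreement sum.
#'
#' @param m A [fit_committee()] model.
#' @param x Numeric vector with the training feature dimension.
#' @return A `K x C` matrix; each row is a valid probability vector, columns
#'   named by class.
#' @export
member_posteriors <- function(m, x) {
  if (length(x) != m$D) {
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 m$D, length(x)))
  }
  out <- t(vapply(m$members, function(mem) {
    .member_probs(mem, matrix(x, nrow = 1L), m$classes)[1L, ]
  }, numeric(length(m$classes))))
  colnames(out) <- as.character(m$classes)
  out
}

# All member posteriors over a whole query matrix: list of K (n x C)
# matrices. Batch form of member_posteriors() used by score_candidates().
.member_posteriors_all <- function(m, U) {
  U <- as.matrix(U)
  if (ncol(U) != m$D) {
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 m$D, ncol(U)))
  }
  lapply(m$members, function(mem) .member_probs(mem, U, m$classes))
}

#' Predict class labels with the chair
#'
#' @param m A [fit_committee()] model.
#' @param X Feature matrix (possibly zero rows).
#' @return Integer labels drawn from the model's class set, one per row.
#' @export
chair_predict <- function(m, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(integer(0))
  if (ncol(X) != m$D) {
    stop(sprintf("dimension mismatch: model expects %d features, got %d",
                 m$D, ncol(X)))
  }
  as.integer(as.character(stats::predict(m$chair, X)))
}

# Fit just the chair SVM (used for post-selection refits and omega1 tuning,
# where the committee is not needed).
.fit_chair <- function(X, y, hp) {
  X <- as.matrix(X)
  yf <- .as_class_factor(y)
  e1071::svm(X, yf, kernel = "radial", cost = hp$c, gamma = hp$gamma,
             scale = FALSE)
}

.chair_only_predict <- function(chair, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(integer(0))
  as.integer(as.character(stats::predict(chair, X)))
}

#' Grid search for the SVM chair hyperparameters
#'
#' Stratified k-fold cross-validation over a log-spaced `(c, gamma)` grid;
#' defaults follow the decade grids `c` in `10^(0:15)` and `gamma` in
#' `10^(-10:5)`. Ties are broken towards the smaller `c`, then the smaller
#' `gamma` — the least complex model among the equally accurate ones.
#'
#' @param X Feature matrix.
#' @param y Integer class labels.
#' @param folds Number of stratified CV folds (>= 2); every class must have
#'   at least `folds` samples.
#' @param c_grid,gamma_grid Numeric grids searched exhaustively.
#' @param seed Seed for the fold assignment.
#' @return A [chair_hyperparams()] with `cv_accuracy` filled in.
#' @export
grid_search_chair <- function(X, y, folds = 5L,
                              c_grid = 10^(0:15),
                              gamma_grid = 10^(-10:5),
                              seed = 1L) {
  X <- as.matrix(X)
  if (folds < 2L) stop("folds must be >= 2")
  classes <- sort(unique(y))
  counts <- table(y)
  if (any(counts < folds)) {
    stop(sprintf("class %s has %d samples, fewer than %d folds",
                 names(counts)[which.min(counts)], min(counts), folds))
  }
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in classes) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  yf <- .as_class_factor(y, classes)

  best <- NULL
  for (cc in sort(c_grid)) {
    for (gg in sort(gamma_grid)) {
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        fit <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                          cost = cc, gamma = gg, scale = FALSE)
        pred <- stats::predict(fit, X[!tr, , drop = FALSE])
        correct <- correct + sum(pred == yf[!tr])
      }
      acc <- correct / length(y)
      if (is.null(best) || acc > best$cv_accuracy + 1e-12) {
        best <- chair_hyperparams(cc, gg, acc)
      }
    }
  }
  best
}
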