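#' Construct a batched dataset
#'
#' A batched dataset is the substrate of the source/target partition: an
#' ordered list of per-batch feature matrices and label vectors sharing one
#' feature dimension and one label alphabet.
#'
#' @param batches List of lists with elements `X` (numeric matrix), `y`
#'   (integer labels) and `batch_id`.
#' @return A list of class `"batched_dataset"` with elements `batches`,
#'   `D`, `classes`.
#' @export
batched_dataset <- function(batches) {
  if (length(batches) < 1L) stop("need at least one batch")
  D <- ncol(as.matrix(batches[[1L]]$X))
  for (b in batches) {
    if (nrow(as.matrix(b$X)) < 1L) stop("empty batch not allowed")
    if (ncol(as.matrix(b$X)) != D) stop("batches disagree on feature dimension")
    if (nrow(as.matrix(b$X)) != length(b$y)) {
      stop("feature matrix and labels disagree on sample count")
    }
  }
  classes <- sort(unique(unlist(lapply(batches, `[[`, "y"))))
  structure(list(batches = batches, D = D, classes = classes),
            class = "batched_dataset")
}

#' @export
print.batched_dataset <- function(x, ...) {
  ns <- vapply(x$batches, function(b) nrow(as.matrix(b$X)), integer(1))
  cat(sprintf("Batched dataset: %d batches, D = %d, %d classes; n per batch: %s\n",
              length(x$batches), x$D, length(x$classes),
              paste(ns, collapse = ", ")))
  invisible(x)
}

# Parse one LIBSVM-style line. The label field is either an integer class
# or "class;concentration" (the concentration is discarded). Returns
# list(label, idx, val).
.parse_libsvm_line <- function(line, file, lineno) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  if (length(toks) < 1L || toks[1L] == "") {
    stop(sprintf("%s:%d: empty line", file, lineno))
  }
  lab_tok <- strsplit(toks[1L], ";", fixed = TRUE)[[1L]][1L]
  label <- suppressWarnings(as.integer(lab_tok))
  if (is.na(label)) {
    stop(sprintf("%s:%d: malformed label field '%s'", file, lineno, toks[1L]))
  }
  idx <- integer(0)
  val <- numeric(0)
  if (length(toks) > 1L) {
    parts <- strsplit(toks[-1L], ":", fixed = TRUE)
    ok <- vapply(parts, length, integer(1)) == 2L
    if (!all(ok)) {
      stop(sprintf("%s:%d: malformed feature token '%s'",
                   file, lineno, toks[-1L][which(!ok)[1L]]))
    }
    idx <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(idx) || anyNA(val) || any(idx < 1L)) {
      stop(sprintf("%s:%d: malformed feature token", file, lineno))
    }
  }
  list(label = label, idx = idx, val = val)
}

#' Load a directory of per-batch drift files
#'
#' Reads files `batch1.dat`, `batch2.dat`, ... in LIBSVM-style sparse text:
#' one sample per line, `label index:value index:value ...`, feature
#' indices 1-based on disk (disk index i maps to matrix column i), absent
#' indices dense-filled with 0. The label field may be a bare integer class
#' or `class;concentration` — the concentration annotation is accepted and
#' discarded. If the files disagree on the maximum feature index a warning
#' is emitted and all batches are padded to the global dimension.
#'
#' @param path Directory containing the batch files.
#' @param pattern Regular expression locating batch files; the first
#'   capture group must be the batch number.
#' @return A [batched_dataset()].
#' @export
load_batches <- function(path, pattern = "^batch([0-9]+)\\.dat$") {
  files <- list.files(path, pattern = pattern)
  if (length(files) == 0L) {
    stop(sprintf("no batch files matching '%s' under %s", pattern, path))
  }
  nums <- as.integer(sub(pattern, "\\1", files))
  files <- files[order(nums)]
  nums <- sort(nums)

  parsed <- lapply(seq_along(files), function(i) {
    fp <- file.path(path, files[i])
    lines <- readLines(fp)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(j) {
      .parse_libsvm_line(lines[j], files[i], j)
    })
    rows
  })

  per_file_D <- vapply(parsed, function(rows) {
    m <- unlist(lapply(rows, `[[`, "idx"))
    if (length(m)) max(m) else 0L
  }, integer(1))
  D <- max(per_file_D)
  if (length(unique(per_file_D)) > 1L) {
    warning(sprintf(
      "batch files disagree on max feature index (%s); padding all to D = %d",
      paste(per_file_D, collapse = ", "), D))
  }
  if (D < 1L) stop("no feature indices found in any batch file")

  batches <- lapply(seq_along(parsed), function(i) {
    rows <- parsed[[i]]
    X <- matrix(0, nrow = length(rows), ncol = D)
    y <- integer(length(rows))
    for (j in seq_along(rows)) {
      X[j, rows[[j]]$idx] <- rows[[j]]$val
      y[j] <- rows[[j]]$label
    }
    list(X = X, y = y, batch_id = nums[i])
  })
  batched_dataset(batches)
}

#' Write a batched dataset as per-batch LIBSVM-style files
#'
#' Inverse of [load_batches()]: one file `batch<id>.dat` per batch, sparse
#' `label index:value` text with exact zeros omitted and 1-based feature
#' indices. `load_batches(write_batches(ds))` reproduces `ds` to within
#' the text round-trip precision (17 significant digits).
#'
#' @param ds A [batched_dataset()].
#' @param path Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_batches <- function(ds, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory %s", path))
  }
  for (b in ds$batches) {
    X <- as.matrix(b$X)
    lines <- vapply(seq_len(nrow(X)), function(j) {
      nz <- which(X[j, ] != 0)
      feats <- if (length(nz)) {
        paste(sprintf("%d:%.17g", nz, X[j, nz]), collapse = " ")
      } else ""
      trimws(paste(b$y[j], feats))
    }, character(1))
    writeLines(lines, file.path(path, sprintf("batch%d.dat", b$batch_id)))
  }
  invisible(path)
}

#' Configuration of the synthetic drift world
#'
#' Parameters of a generative stand-in for a multi-batch sensor-array
#' dataset under drift. Each class is a Gaussian cluster in feature space;
#' across batches the cluster centre decays multiplicatively (loss of
#' sensor sensitivity) and translates along a class-specific direction with
#' a class-specific gain (aging affects different analytes differently),
#' with a mildly superlinear dependence on the batch index so the drift is
#' not a straight line in time.
#'
#' Unspecified structural parameters (`class_means`, `drift_direction`,
#' `drift_gain`) are drawn once, deterministically, from `seed`.
#'
#' @param C Number of classes (default 6, the reference benchmark's gas
#'   count).
#' @param D Feature dimension (default 16).
#' @param B Number of batches (default 5).
#' @param n_per_batch Samples per batch, recycled to length `B`
#'   (default 200).
#' @param class_means `C x D` matrix of batch-1 cluster centres, or `NULL`
#'   to draw them as N(0, 1); with the default scales this makes the
#'   classes separable but overlapping, so a batch-1 classifier starts
#'   near-perfect and loses roughly half its accuracy by the last batch —
#'   the regime drift compensation is for.
#' @param class_scales Per-class cluster standard deviation (default 1).
#' @param drift_direction `C x D` matrix of unit drift directions, or
#'   `NULL` to draw them as normalised mixtures of one shared unit vector
#'   (weight `drift_coherence`) and a class-specific unit vector: sensor
#'   aging is an instrument-level process, so the per-gas drift directions
#'   are correlated but not identical.
#' @param drift_coherence Weight of the shared component in the default
#'   drift directions, in `[0, 1]` (default 0.7); ignored when
#'   `drift_direction` is supplied.
#' @param drift_gain Per-class drift magnitude per batch step, or `NULL`
#'   for an even spread over `[0.2, 1.2]` — strongly gas-specific, with
#'   the least affected class drifting barely beyond its own spread and
#'   the most affected one crossing class boundaries by the last batch.
#' @param decay_rate Multiplicative centre decay per batch, in `(0, 1]`
#'   (default 0.95).
#' @param noise_sd Additional isotropic noise standard deviation
#'   (default 1).
#' @param seed Seed fixing both the structural draws and [simulate_drift()].
#' @return A list of class `"drift_sim_config"`.
#' @export
drift_sim_config <- function(C = 6L, D = 16L, B = 5L, n_per_batch = 200L,
                             class_means = NULL, class_scales = 1,
                             drift_direction = NULL, drift_coherence = 0.7,
                             drift_gain = NULL,
                             decay_rate = 0.95, noise_sd = 1, seed = 1L) {
  if (C < 2L) stop("need at least 2 classes")
  if (D < 1L || B < 1L) stop("D and B must be positive")
  if (decay_rate <= 0 || decay_rate > 1) stop("decay_rate must be in (0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n_per_batch <- rep_len(as.integer(n_per_batch), B)
  if (any(n_per_batch < C)) stop("each batch needs at least C samples")
  class_scales <- rep_len(class_scales, C)
  if (any(class_scales <= 0)) stop("class_scales must be positive")

  set.seed(seed)
  if (is.null(class_means)) {
    class_means <- matrix(stats::rnorm(C * D), nrow = C)
  }
  if (is.null(drift_direction)) {
    if (drift_coherence < 0 || drift_coherence > 1) {
      stop("drift_coherence must lie in [0, 1]")
    }
    shared <- stats::rnorm(D)
    shared <- shared / sqrt(sum(shared^2))
    drift_direction <- t(vapply(seq_len(C), function(cl) {
      own <- stats::rnorm(D)
      own <- own / sqrt(sum(own^2))
      drift_coherence * shared + (1 - drift_coherence) * own
    }, numeric(D)))
  }
  drift_direction <- drift_direction /
    sqrt(rowSums(drift_direction^2))
  if (is.null(drift_gain)) {
    drift_gain <- seq(0.2, 1.2, length.out = C)
  }
  drift_gain <- rep_len(drift_gain, C)
  if (any(drift_gain < 0)) stop("drift_gain must be non-negative")
  if (nrow(class_means) != C || ncol(class_means) != D) {
    stop("class_means must be C x D")
  }
  if (nrow(drift_direction) != C || ncol(drift_direction) != D) {
    stop("drift_direction must be C x D")
  }

  structure(list(C = as.integer(C), D = as.integer(D), B = as.integer(B),
                 n_per_batch = n_per_batch, class_means = class_means,
                 class_scales = class_scales,
                 drift_direction = drift_direction, drift_gain = drift_gain,
                 decay_rate = decay_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "drift_sim_config")
}

#' Simulate a multi-batch drift world
#'
#' Draws batch `b`, class `c` samples from
#' \deqn{N\big(\mu_c \cdot r^{b-1} + (b-1)^{1.2} g_c d_c,\;
#'   (s_c^2 + \sigma^2) I\big)}
#' where \eqn{\mu_c} is the batch-1 class centre, `r` the sensitivity decay
#' rate, \eqn{g_c} and \eqn{d_c} the class-specific drift gain and unit
#' direction, \eqn{s_c} the class scale and \eqn{\sigma} the noise level.
#' The exponent 1.2 makes the displacement mildly superlinear in the batch
#' index. Class labels are balanced as far as the batch size allows.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [drift_sim_config()].
#' @return A [batched_dataset()].
#' @export
simulate_drift <- function(cfg) {
  stopifnot(inherits(cfg, "drift_sim_config"))
  set.seed(cfg$seed + 1L)
  sds <- sqrt(cfg$class_scales^2 + cfg$noise_sd^2)
  batches <- vector("list", cfg$B)
  for (b in seq_len(cfg$B)) {
    n <- cfg$n_per_batch[b]
    y <- rep_len(seq_len(cfg$C), n)
    X <- matrix(0, nrow = n, ncol = cfg$D)
    for (cl in seq_len(cfg$C)) {
      rows <- which(y == cl)
      centre <- cfg$class_means[cl, ] * cfg$decay_rate^(b - 1) +
        (b - 1)^1.2 * cfg$drift_gain[cl] * cfg$drift_direction[cl, ]
      X[rows, ] <- matrix(stats::rnorm(length(rows) * cfg$D, sd = sds[cl]),
                          ncol = cfg$D, byrow = TRUE) +
        matrix(centre, nrow = length(rows), ncol = cfg$D, byrow = TRUE)
    }
    batches[[b]] <- list(X = X, y = y, batch_id = b)
  }
  batched_dataset(batches)
}

#' Standardise features by source statistics
#'
#' Centres and scales both sets by the mean and standard deviation of the
#' source features only, so no target information leaks into the
#' preprocessing. Constant features get unit scale.
#'
#' @param train,target Lists with elements `X` and `y`.
#' @return A list with standardised `train` and `target` plus the `center`
#'   and `scale` vectors used.
#' @export
standardize_by_source <- function(train, target) {
  Xs <- as.matrix(train$X)
  mu <- colMeans(Xs)
  sdv <- apply(Xs, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  scale_one <- function(X) {
    sweep(sweep(as.matrix(X), 2L, mu, "-"), 2L, sdv, "/")
  }
  list(train = list(X = scale_one(train$X), y = train$y),
       target = list(X = scale_one(target$X), y = target$y),
       center = mu, scale = sdv)
}

#' Per-batch PCA projections
#'
#' Projects each batch onto its own first two principal axes — the standard
#' visual check that the batch clouds shift over time. Plotting is left to
#' the caller.
#'
#' @param ds A [batched_dataset()].
#' @return A list, one element per batch, each with `coords` (n x 2),
#'   `explained` (variance fractions of the two components) and
#'   `batch_id`.
#' @export
pca_scatter <- function(ds) {
  if (ds$D < 2L) stop("need at least 2 features for a 2-D projection")
  lapply(ds$batches, function(b) {
    X <- as.matrix(b$X)
    if (nrow(X) < 3L) stop("batch too small for PCA")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    if (pc$sdev[1L] == 0) stop("degenerate (zero-variance) batch")
    vars <- pc$sdev^2
    list(coords = pc$x[, 1:2, drop = FALSE],
         explained = vars[1:2] / sum(vars),
         batch_id = b$batch_id)
  })
}
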