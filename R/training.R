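#' Labeled, clustered sequence dataset
#'
#' Validates the container used by the training pipeline: one row per protein
#' with a binary solubility label and a sequence-similarity cluster id.
#' Clusters are the unit of cross-validation: no cluster may span the
#' train/test boundary.
#'
#' @param x data.frame with columns `id`, `seq`, `label` (0 = insoluble,
#'   1 = soluble) and `cluster` (character).
#' @param require_both_classes Require both labels to be present (the training
#'   contract). Generators may disable this for degenerate parameter choices.
#' @return `x`, with class `labeled_dataset` prepended.
#' @export
labeled_dataset <- function(x, require_both_classes = TRUE) {
  stopifnot(is.data.frame(x))
  need <- c("id", "seq", "label", "cluster")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(x$label %in% c(0, 1))) stop("labels must be binary 0/1 for training")
  if (any(is.na(x$cluster) | !nzchar(as.character(x$cluster))))
    stop("every record needs a cluster id")
  if (require_both_classes && length(unique(x$label)) < 2L)
    stop("both classes (soluble and insoluble) must be present")
  if (!inherits(x, "labeled_dataset")) class(x) <- c("labeled_dataset", class(x))
  x
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the Mann-Whitney statistic via mid-ranks:
#' `(#\{positive > negative\} + 0.5 * #ties) / (n1 * n0)`. Ties receive half
#' credit. Equals the probability that a random positive scores above a random
#' negative. Invariant under any strictly increasing transform of the scores,
#' in particular under adding a constant to all residue weights or scaling
#' them by a positive constant.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), same length as `scores`.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # mid-ranks give the half-credit tie convention
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# n x 20 matrix of residue-composition fractions; SWI under weights w is P %*% w
.composition <- function(seqs) {
  m <- t(vapply(strsplit(seqs, "", fixed = TRUE), function(ch) {
    idx <- match(ch, AA20)
    if (anyNA(idx))
      stop("residue(s) outside the standard alphabet: ",
           paste(unique(ch[is.na(idx)]), collapse = ", "))
    tabulate(idx, nbins = 20L) / length(ch)
  }, numeric(20L)))
  colnames(m) <- AA20
  m
}

#' Group similarity clusters into cross-validation folds
#'
#' Clusters are assigned whole to folds (no cluster ever spans folds) by a
#' deterministic greedy bin-packing: clusters are taken largest-first and each
#' is placed into the currently smallest fold; `seed` breaks ties among
#' equal-sized clusters and equally filled folds.
#'
#' @param clusters Character vector: the cluster id of every record (one entry
#'   per sequence), or a [labeled_dataset()].
#' @param n_folds Number of folds.
#' @param seed Integer seed for tie-breaking.
#' @return Object of class `fold_assignment`: list with `n_folds`,
#'   `fold_of_cluster` (named integer vector) and `fold_of_record` (integer
#'   vector aligned with the input records).
#' @export
build_folds <- function(clusters, n_folds, seed = 1L) {
  if (inherits(clusters, "labeled_dataset") || is.data.frame(clusters))
    clusters <- clusters$cluster
  clusters <- as.character(clusters)
  sizes <- table(clusters)
  if (length(sizes) < n_folds)
    stop("need at least ", n_folds, " clusters to build ", n_folds,
         " folds; got ", length(sizes))
  ord <- withr::with_seed(seed, order(-as.integer(sizes), runif(length(sizes))))
  fold_of_cluster <- setNames(integer(length(sizes)), names(sizes))
  load <- numeric(n_folds)
  tiebreak <- withr::with_seed(seed + 1L, runif(n_folds))
  for (ci in ord) {
    k <- order(load, tiebreak)[1L]
    fold_of_cluster[ci] <- k
    load[k] <- load[k] + as.integer(sizes[ci])
  }
  structure(list(n_folds = as.integer(n_folds),
                 fold_of_cluster = fold_of_cluster,
                 fold_of_record = unname(fold_of_cluster[clusters])),
            class = "fold_assignment")
}

#' Class-balanced bootstrap resample
#'
#' Draws `n_per_class` records with replacement from each class independently,
#' giving `2 * n_per_class` records per sample. Balancing the classes guards
#' the AUC objective against the class imbalance of real expression screens.
#'
#' @param dataset data.frame with at least a `label` column (0/1).
#' @param n_per_class Draws per class.
#' @param seed Integer seed.
#' @return data.frame of resampled records (soluble draws first).
#' @export
bootstrap_resample <- function(dataset, n_per_class, seed = 1L) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  i1 <- which(dataset$label == 1)
  i0 <- which(dataset$label == 0)
  if (!length(i1) || !length(i0))
    stop("both classes must be present to bootstrap-resample")
  idx <- withr::with_seed(seed, c(sample(i1, n_per_class, replace = TRUE),
                                  sample(i0, n_per_class, replace = TRUE)))
  dataset[idx, , drop = FALSE]
}

#' Training configuration
#'
#' Defaults mirror the published pipeline: 10 homology-aware folds, 1000
#' bootstrap resamples per fold of 1000 soluble + 1000 insoluble proteins,
#' Nelder-Mead stopped at a relative score spread of 1e-6 or 5000 iterations.
#'
#' @param n_folds Number of cross-validation folds.
#' @param n_bootstrap Bootstrap resamples per fold.
#' @param n_per_class Records drawn per class in each resample.
#' @param maxit Maximum Nelder-Mead iterations per optimization.
#' @param tol Relative convergence tolerance of the simplex.
#' @param seed Root seed; all randomness (fold tie-breaks, bootstrap draws)
#'   derives from it.
#' @return List of class `training_config`.
#' @export
training_config <- function(n_folds = 10L, n_bootstrap = 1000L,
                            n_per_class = 1000L, maxit = 5000L,
                            tol = 1e-6, seed = 1L) {
  stopifnot(n_folds >= 1, n_bootstrap >= 1, n_per_class >= 1, maxit >= 1, tol > 0)
  structure(list(n_folds = as.integer(n_folds),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_per_class = as.integer(n_per_class),
                 maxit = as.integer(maxit), tol = tol,
                 seed = as.integer(seed)),
            class = "training_config")
}

# core optimizer on a precomputed composition matrix
.optimize_w <- function(P, y, w0, maxit, tol) {
  obj <- function(w) -auc(drop(P %*% w), y)
  fit <- optim(w0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = tol))
  improved <- -fit$value >= -obj(w0)
  w <- if (improved) fit$par else w0  # monotone-improvement guard
  attr(w, "converged") <- fit$convergence == 0L
  attr(w, "auc") <- max(-fit$value, -obj(w0))
  w
}

#' Optimize residue weights to maximize AUC on one sample
#'
#' Derivative-free simplex (Nelder-Mead) maximization of the AUC of
#' SWI-under-candidate-weights against the labels, starting from `initial`.
#' The returned weights never score below the initial weights on the sample
#' (the initial vector is returned if the optimizer fails to improve). If the
#' iteration cap is reached, the best-so-far vector is returned with
#' `attr(, "converged") = FALSE` and a warning.
#'
#' @param sample data.frame with columns `seq` and `label` (both classes
#'   present).
#' @param initial [residue_scale()] of starting weights.
#' @param config [training_config()] (only `maxit` and `tol` are used).
#' @return Named 20-vector of optimized weights with attributes `auc` and
#'   `converged`.
#' @export
optimize_weights <- function(sample, initial = get_scale("smith"),
                             config = training_config()) {
  stopifnot(is.data.frame(sample), all(c("seq", "label") %in% names(sample)))
  if (length(unique(sample$label)) < 2L)
    stop("both classes must be present to optimize weights")
  P <- .composition(sample$seq)
  w <- .optimize_w(P, sample$label, initial$values, config$maxit, config$tol)
  if (!attr(w, "converged"))
    warning("Nelder-Mead hit the iteration cap; returning best-so-far weights")
  w
}

#' Train SWI weights by homology-aware cross-validation
#'
#' The weight-derivation pipeline: sequences are grouped into folds by
#' similarity cluster ([build_folds()]); for each fold, the remaining folds
#' are bootstrap-resampled `n_bootstrap` times with `n_per_class` draws per
#' class, each resample is optimized by Nelder-Mead AUC maximization from the
#' initial weights, and the optimized vectors are averaged into the fold mean
#' `V_k`; training and test AUC are evaluated with `V_k`. The final weights
#' are the arithmetic mean of the fold means. The whole run is reproducible
#' from `config$seed`, and a leakage check asserts that no cluster appears on
#' both sides of any train/test split.
#'
#' @param dataset A [labeled_dataset()] (or data.frame with `id`, `seq`,
#'   `label`, `cluster`).
#' @param initial [residue_scale()] of initial weights (default Smith et al.
#'   normalized B-factors, as in the published pipeline).
#' @param config [training_config()].
#' @return Object of class `trained_weights`: list with `fold_means` (20 x
#'   n_folds matrix), `final` ([residue_scale()]), `train_auc`, `test_auc`,
#'   `initial_train_auc`, `initial_test_auc` (per-fold numeric vectors),
#'   `folds` (the [build_folds()] assignment) and `config`.
#' @export
train_swi <- function(dataset, initial = get_scale("smith"),
                      config = training_config()) {
  dataset <- labeled_dataset(as.data.frame(dataset))
  folds <- build_folds(dataset$cluster, config$n_folds, seed = config$seed)
  P <- .composition(dataset$seq)
  y <- dataset$label
  w0 <- initial$values
  K <- config$n_folds
  fold_means <- matrix(NA_real_, 20L, K, dimnames = list(AA20, NULL))
  train_auc <- test_auc <- init_train <- init_test <- numeric(K)

  withr::with_seed(config$seed, {
    for (k in seq_len(K)) {
      test_idx <- which(folds$fold_of_record == k)
      train_idx <- which(folds$fold_of_record != k)
      # leakage check: a similarity cluster must never span the split
      shared <- intersect(unique(dataset$cluster[test_idx]),
                          unique(dataset$cluster[train_idx]))
      if (length(shared))
        stop("cluster leakage across train/test folds: ",
             paste(shared, collapse = ", "))
      i1 <- train_idx[y[train_idx] == 1]
      i0 <- train_idx[y[train_idx] == 0]
      if (!length(i1) || !length(i0))
        stop("fold ", k, ": training split lacks one class")
      W <- matrix(NA_real_, 20L, config$n_bootstrap)
      for (b in seq_len(config$n_bootstrap)) {
        idx <- c(sample(i1, config$n_per_class, replace = TRUE),
                 sample(i0, config$n_per_class, replace = TRUE))
        W[, b] <- .optimize_w(P[idx, , drop = FALSE], y[idx], w0,
                              config$maxit, config$tol)
      }
      vk <- rowMeans(W)
      fold_means[, k] <- vk
      train_auc[k] <- auc(drop(P[train_idx, ] %*% vk), y[train_idx])
      test_auc[k] <- auc(drop(P[test_idx, ] %*% vk), y[test_idx])
      init_train[k] <- auc(drop(P[train_idx, ] %*% w0), y[train_idx])
      init_test[k] <- auc(drop(P[test_idx, ] %*% w0), y[test_idx])
    }
  })

  final <- residue_scale(
    "trained", rowMeans(fold_means),
    provenance = sprintf(
      "mean of %d fold means (%d bootstraps x %d per class), initialized from '%s'",
      K, config$n_bootstrap, config$n_per_class, initial$name))
  structure(list(fold_means = fold_means, final = final,
                 train_auc = train_auc, test_auc = test_auc,
                 initial_train_auc = init_train, initial_test_auc = init_test,
                 folds = folds, config = config),
            class = "trained_weights")
}

#' @export
print.trained_weights <- function(x, ...) {
  cat("<trained_weights>", ncol(x$fold_means), "folds\n")
  cat(sprintf("  train AUC %.3f +/- %.3f   test AUC %.3f +/- %.3f\n",
              mean(x$train_auc), stats::sd(x$train_auc),
              mean(x$test_auc), stats::sd(x$test_auc)))
  cat(sprintf("  initial-weight test AUC %.3f\n", mean(x$initial_test_auc)))
  invisible(x)
}

#' Fit the SWI-to-solubility logistic calibration
#'
#' Maximum-likelihood fit of `P(soluble) = 1 / (1 + exp(-(a * x + b)))` with
#' `x` the SWI score (single-feature logistic regression). Iterations are
#' capped; under (quasi-)complete separation the capped estimate is returned
#' with the `converged` flag unset.
#'
#' @param scores Numeric SWI scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return A [logistic_calibration()].
#' @export
fit_logistic <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to fit the calibration")
  converged <- TRUE
  fit <- withCallingHandlers(
    glm(labels ~ scores, family = binomial(),
        control = stats::glm.control(maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) converged <- FALSE
  cf <- coef(fit)
  logistic_calibration(a = unname(cf["scores"]), b = unname(cf["(Intercept)"]),
                       converged = converged)
}

#' Greedy centroid clustering of protein sequences
#'
#' A deterministic, fixture-grade stand-in for USEARCH-style clustering at a
#' 40% identity threshold: sequences are processed longest-first; each is
#' assigned to the first existing centroid whose k-mer-estimated identity
#' (shared unique k-mers over the shorter sequence's unique k-mer count)
#' reaches the threshold, otherwise it founds a new centroid. It makes no
#' claim of equivalence with USEARCH's identity definition. His-tag affixes
#' should be trimmed by the caller beforehand ([trim_his_tag()]).
#'
#' @param seqs data.frame with columns `id` and `seq`, or named character
#'   vector of sequences.
#' @param identity_threshold Minimum estimated identity to join a cluster.
#' @param word_length k-mer length for the identity estimate.
#' @return data.frame with columns `id` and `cluster`, in input order.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.4, word_length = 3L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id; ss <- seqs$seq
  } else {
    ss <- unname(seqs)
    ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs)) else names(seqs)
  }
  stopifnot(length(ss) >= 1L, identity_threshold > 0, identity_threshold <= 1)
  kmers <- lapply(ss, function(s) {
    n <- nchar(s)
    if (n < word_length) return(s)
    unique(substring(s, 1:(n - word_length + 1L), word_length:n))
  })
  ord <- order(-nchar(ss))  # longest first; stable for equal lengths
  cluster <- character(length(ss))
  centroids <- integer(0)
  for (i in ord) {
    hit <- 0L
    for (ci in centroids) {
      shorter <- if (length(kmers[[i]]) <= length(kmers[[ci]])) kmers[[i]] else kmers[[ci]]
      longer <- if (length(kmers[[i]]) <= length(kmers[[ci]])) kmers[[ci]] else kmers[[i]]
      ident <- sum(shorter %in% longer) / length(shorter)
      if (ident >= identity_threshold) { hit <- ci; break }
    }
    if (hit == 0L) {
      centroids <- c(centroids, i)
      cluster[i] <- ids[i]
    } else {
      cluster[i] <- ids[hit]
    }
  }
  data.frame(id = ids, cluster = cluster, stringsAsFactors = FALSE)
}
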