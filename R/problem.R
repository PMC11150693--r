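#' Filter a connectivity dataset by a per-pair threshold vector
#'
#' Each off-diagonal entry survives when its magnitude meets the pair's
#' threshold: `B[i,j] = D[i,j]` if `|D[i,j]| >= x[pair(i,j)]`, else 0,
#' applied symmetrically. The diagonal is untouched. Large thresholds thus
#' declare channel pairs uncorrelated.
#'
#' @param dataset a [correlation_dataset()].
#' @param x numeric threshold vector of length `m(m-1)/2` with entries in
#'   \[0, 1\], in [pair_table()] order.
#' @return `m x m x N` array of filtered matrices.
#' @export
filter_dataset <- function(dataset, x) {
  stopifnot(inherits(dataset, "correlation_dataset"))
  m <- dataset$m
  d <- n_pairs(m)
  x <- as.numeric(x)
  if (length(x) != d) {
    stop("threshold vector has length ", length(x), ", expected ", d)
  }
  if (any(x < 0 | x > 1)) stop("thresholds must lie in [0, 1]")
  thr <- matrix(0, m, m)
  pt <- pair_table(m)
  thr[pt] <- x
  thr[pt[, c(2, 1)]] <- x
  A <- dataset$matrices
  keep <- abs(A) >= as.vector(thr)        # thr recycled over samples
  B <- A * keep
  # restore diagonal untouched
  di <- cbind(rep(seq_len(m), dataset$n), rep(seq_len(m), dataset$n),
              rep(seq_len(dataset$n), each = m))
  B[di] <- A[di]
  B
}

#' Channel deletion from filtered connectivity matrices
#'
#' A channel is deleted when, in every sample, it is uncorrelated (zero
#' filtered connectivity) with more than `s` other channels. For each
#' deleted channel its row and column are zeroed in every sample, giving
#' the deleted matrices `C`.
#'
#' @param B `m x m x N` array of filtered matrices (from
#'   [filter_dataset()]).
#' @param s zero-assignment parameter, integer in \[0, m-1\]: the number of
#'   zero-connectivity partners a channel must exceed to qualify for
#'   deletion.
#' @return list with `m_d` (deleted count), `deleted` (logical m-vector),
#'   and `C` (the `m x m x N` array after deletion).
#' @export
count_deleted <- function(B, s) {
  stopifnot(length(dim(B)) == 3L)
  m <- dim(B)[1]
  n <- dim(B)[3]
  s <- as.numeric(s)
  if (length(s) != 1L || is.na(s) || s < 0 || s > m - 1) {
    stop("s must lie in [0, m-1]")
  }
  Z <- B == 0
  # zeros per channel column, per sample, excluding the diagonal entry
  zero_counts <- colSums(Z)                      # m x n
  diag_idx <- cbind(rep(seq_len(m), n), rep(seq_len(m), n),
                    rep(seq_len(n), each = m))
  zero_counts <- zero_counts - matrix(Z[diag_idx], m, n)
  deleted <- apply(zero_counts > s, 1L, all)
  C <- B
  if (any(deleted)) {
    C[deleted, , ] <- 0
    C[, deleted, ] <- 0
  }
  list(m_d = sum(deleted), deleted = deleted, C = C)
}

#' Smoothed channel-deletion objective
#'
#' The early-stage first objective: the average of the zero-element ratio
#' of the deleted matrices and the deleted-channel fraction,
#' \deqn{f_1^* = 0.5\, zero(C)/N_C + 0.5\, m_d/m \in [0, 1].}
#' Zeros are counted over off-diagonal upper-triangle entries only (the
#' diagonal is structurally nonzero and identical for all solutions).
#'
#' @param C `m x m x N` array after channel deletion.
#' @param m_d number of deleted channels.
#' @param m total channel count.
#' @return scalar in \[0, 1\].
#' @export
f1_star <- function(C, m_d, m) {
  stopifnot(length(dim(C)) == 3L, dim(C)[1] == m)
  n <- dim(C)[3]
  pt <- pair_table(m)
  d <- nrow(pt)
  zeros <- sum(vapply(seq_len(n), function(k) sum(C[, , k][pt] == 0),
                      numeric(1)))
  0.5 * zeros / (n * d) + 0.5 * m_d / m
}

#' Classifier contract for the accuracy objective
#'
#' The second objective wraps any classifier that can be fit on feature
#' rows and report cross-validated accuracy. The default is a linear
#' support vector machine with a grid search over the cost parameter,
#' scored by stratified k-fold cross-validation; the best candidate's CV
#' accuracy (in percent) is the objective value.
#'
#' @param kind classifier family; only `"svm_linear"` is built in.
#' @param folds CV fold count (>= 2, default 5).
#' @param grid numeric vector of regularization-cost candidates.
#' @param seed RNG seed for the stratified fold shuffle; fixed so every
#'   solution is scored on identical folds.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = "svm_linear", folds = 5L,
                            grid = c(0.1, 1, 10), seed = 42L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  stopifnot(kind == "svm_linear", length(grid) >= 1L)
  structure(list(kind = kind, folds = folds, grid = as.numeric(grid),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# stratified fold assignment, deterministic in spec$seed
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Classification accuracy objective
#'
#' Vectorizes each deleted matrix into its upper-triangle pair entries,
#' then reports the best cross-validated accuracy over the classifier grid,
#' in percent. Solutions retaining fewer than 2 channels are infeasible for
#' a connectivity-based classifier and score 0.
#'
#' @param C `m x m x N` array after channel deletion.
#' @param labels integer class labels (both classes must be present).
#' @param spec a [classifier_spec()].
#' @param deleted optional logical m-vector of deleted channels, used for
#'   the feasibility check (fewer than 2 retained channels scores 0).
#' @return accuracy in percent, \[0, 100\].
#' @export
f2_accuracy <- function(C, labels, spec = classifier_spec(),
                        deleted = NULL) {
  stopifnot(length(dim(C)) == 3L, inherits(spec, "classifier_spec"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in labels")
  }
  m <- dim(C)[1]
  if (!is.null(deleted) && sum(!deleted) < 2L) return(0)
  pt <- pair_table(m)
  n <- dim(C)[3]
  feats <- t(vapply(seq_len(n), function(k) C[, , k][pt],
                    numeric(nrow(pt))))
  y <- factor(labels)
  fold <- stratified_folds(labels, spec$folds, spec$seed)
  best <- 0
  for (cost in spec$grid) {
    correct <- 0L
    for (f in seq_len(spec$folds)) {
      tr <- fold != f
      if (!any(!tr)) next
      if (length(unique(y[tr])) < 2L) {
        # degenerate training fold: predict its only class
        correct <- correct + sum(y[!tr] == y[tr][1L])
        next
      }
      fit <- e1071::svm(feats[tr, , drop = FALSE], y[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, feats[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc <- 100 * correct / length(y)
    if (acc > best) best <- acc
  }
  best
}

#' Construct a channel selection problem
#'
#' Bundles a connectivity dataset, the deletion parameter `s` and a
#' classifier into a stateful evaluator that counts function evaluations
#' (FE) and caches results by the content hash of the deleted matrices
#' (distinct thresholds often induce identical filtered patterns; cache
#' hits still consume an FE, since FE is the optimization budget unit).
#'
#' @param dataset a [correlation_dataset()] with both classes present.
#' @param s zero-assignment parameter (see [count_deleted()]).
#' @param classifier a [classifier_spec()].
#' @return environment of class `channel_problem` with fields `dataset`,
#'   `s`, `classifier`, `d` (decision length), `m`, `fe` (counter), `cache`.
#' @export
channel_problem <- function(dataset, s, classifier = classifier_spec()) {
  stopifnot(inherits(dataset, "correlation_dataset"))
  if (length(unique(dataset$labels)) < 2L) {
    stop("dataset must contain both classes")
  }
  prob <- new.env(parent = emptyenv())
  prob$dataset <- dataset
  prob$s <- s
  prob$classifier <- classifier
  prob$m <- dataset$m
  prob$d <- n_pairs(dataset$m)
  prob$fe <- 0L
  prob$cache <- new.env(parent = emptyenv())
  class(prob) <- "channel_problem"
  prob
}

#' Evaluate a threshold solution
#'
#' Runs the full objective pipeline for one effective threshold vector:
#' filtering, channel deletion, `f1*`, and classifier accuracy `f2`. The
#' stage selects the objective pair reported: `"early"` gives
#' `(f1*, f2)`, `"late"` gives `(m_d, f2)`. The full evaluation result is
#' cached so a stage switch relabels objectives without recomputation.
#' Every call (cache hit or not) increments the problem's FE counter by 1.
#'
#' @param prob a [channel_problem()].
#' @param x effective threshold vector (length `d`, entries in \[0, 1\]).
#' @param stage `"early"` or `"late"`.
#' @return list with `objectives` (length-2 numeric, maximization),
#'   `m_d`, `deleted`, `f1_star`, `f2`, `zero_ratio`.
#' @export
evaluate_threshold <- function(prob, x, stage = c("early", "late")) {
  stage <- match.arg(stage)
  stopifnot(inherits(prob, "channel_problem"))
  prob$fe <- prob$fe + 1L
  B <- filter_dataset(prob$dataset, x)
  key <- rlang::hash(B)
  res <- prob$cache[[key]]
  if (is.null(res)) {
    del <- count_deleted(B, prob$s)
    m <- prob$m
    n <- dim(del$C)[3]
    pt <- pair_table(m)
    zeros <- sum(vapply(seq_len(n), function(k) sum(del$C[, , k][pt] == 0),
                        numeric(1)))
    zero_ratio <- zeros / (n * nrow(pt))
    f1s <- 0.5 * zero_ratio + 0.5 * del$m_d / m
    f2 <- f2_accuracy(del$C, prob$dataset$labels, prob$classifier,
                      deleted = del$deleted)
    res <- list(m_d = del$m_d, deleted = del$deleted, f1_star = f1s,
                f2 = f2, zero_ratio = zero_ratio)
    prob$cache[[key]] <- res
  }
  obj <- if (stage == "early") c(res$f1_star, res$f2) else c(res$m_d, res$f2)
  c(list(objectives = obj), res)
}

#' Relabel cached objectives for a stage
#'
#' @param eval_result a result of [evaluate_threshold()].
#' @param stage `"early"` or `"late"`.
#' @return length-2 numeric objective vector.
#' @export
stage_objectives <- function(eval_result, stage = c("early", "late")) {
  stage <- match.arg(stage)
  if (stage == "early") c(eval_result$f1_star, eval_result$f2)
  else c(eval_result$m_d, eval_result$f2)
}
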