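#' A windowed multichannel signal
#'
#' One analysis window of an m-channel recording: an `m x T` matrix of
#' amplitudes (channels in rows), a binary class label, and the sampling
#' rate as metadata.
#'
#' @param values numeric `m x T` matrix, channels in rows, `T >= 2`.
#' @param label class label, 0 or 1.
#' @param fs sampling rate in Hz (metadata only).
#' @return object of class `signal_window`.
#' @export
signal_window <- function(values, label, fs = 250) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stop("a window needs T >= 2 time points")
  if (!all(is.finite(values))) stop("non-finite values in window")
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(values = values, label = label, fs = fs),
            class = "signal_window")
}

#' Pearson correlation matrix of a window
#'
#' Linear correlation between every pair of channel signals:
#' \deqn{PCC(i,k) = \frac{1}{T}\sum_t (x_{it}-\mu_i)(x_{kt}-\mu_k) /
#' (\sigma_i \sigma_k).}
#' Symmetric, unit diagonal, entries in \[-1, 1\].
#'
#' @param window a [signal_window()].
#' @return `m x m` correlation matrix.
#' @export
pcc_matrix <- function(window) {
  stopifnot(inherits(window, "signal_window"))
  v <- window$values
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("constant channel(s) with zero standard deviation: ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(v))
  diag(r) <- 1
  r
}

#' Analytic signal via the frequency-domain transform
#'
#' Standard FFT construction: negative frequencies zeroed, positive
#' frequencies doubled, DC (and Nyquist for even length) kept.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value matrix of a window
#'
#' Phase synchronization between channel pairs,
#' \deqn{PLV(i,k) = \frac{1}{T}\left|\sum_t e^{j(\phi_{it}-\phi_{kt})}\right|,}
#' with instantaneous phases from the analytic signal of each channel.
#' Symmetric, unit diagonal, entries in \[0, 1\].
#'
#' @param window a [signal_window()].
#' @return `m x m` PLV matrix.
#' @export
plv_matrix <- function(window) {
  stopifnot(inherits(window, "signal_window"))
  v <- window$values
  m <- nrow(v)
  phases <- t(apply(v, 1L, function(x) Arg(analytic_signal(x))))
  if (m == 1L) phases <- matrix(phases, nrow = 1L)
  ph <- exp(1i * phases)           # m x T unit phasors
  out <- Mod(ph %*% Conj(t(ph))) / ncol(v)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Transfer entropy matrix of a window
#'
#' Directed information flow between channels with a plug-in estimator on
#' equal-width amplitude bins and history length 1:
#' \deqn{TE(i \to k) = \sum p(x_k^{t+1}, x_k^t, x_i^t)
#'   \log\frac{p(x_k^{t+1} \mid x_k^t, x_i^t)}{p(x_k^{t+1} \mid x_k^t)}}
#' (natural log). Zero indicates no detectable directed influence. The
#' matrix is nonnegative, generally asymmetric, with a zero diagonal; entry
#' `[i, k]` is the flow from channel i to channel k.
#'
#' @param window a [signal_window()].
#' @param bins number of equal-width amplitude bins per channel (>= 2).
#' @return `m x m` transfer-entropy matrix.
#' @export
te_matrix <- function(window, bins = 8L) {
  stopifnot(inherits(window, "signal_window"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("bins must be >= 2")
  v <- window$values
  m <- nrow(v)
  Tn <- ncol(v)
  disc <- t(apply(v, 1L, function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(1L, length(x)))
    b <- seq(rng[1], rng[2], length.out = bins + 1L)
    findInterval(x, b, rightmost.closed = TRUE, all.inside = TRUE)
  }))
  if (m == 1L) disc <- matrix(disc, nrow = 1L)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (k in seq_len(m)) {
      if (i == k) next
      out[i, k] <- transfer_entropy_pair(disc[i, ], disc[k, ], Tn)
    }
  }
  out
}

# plug-in TE from discretized source xs to target xk, history 1
transfer_entropy_pair <- function(xs, xk, Tn) {
  tgt_next <- xk[2:Tn]
  tgt_past <- xk[1:(Tn - 1L)]
  src_past <- xs[1:(Tn - 1L)]
  n <- Tn - 1L
  joint3 <- table(tgt_next, tgt_past, src_past) / n
  idx <- which(joint3 > 0, arr.ind = TRUE)
  p3 <- joint3[joint3 > 0]
  p_tp_sp <- table(tgt_past, src_past) / n
  p_tn_tp <- table(tgt_next, tgt_past) / n
  p_tp <- table(tgt_past) / n
  # p(next | past, src) and p(next | past) from the marginals
  cond_full <- p3 / p_tp_sp[cbind(idx[, 2], idx[, 3])]
  cond_red <- p_tn_tp[cbind(idx[, 1], idx[, 2])] / p_tp[idx[, 2]]
  te <- sum(p3 * log(cond_full / cond_red))
  max(te, 0)
}

#' Connectivity dataset from a list of windows
#'
#' Applies one connectivity measure per window and collects the results as
#' an `m x m x N` array plus the class labels: the sample set the channel
#' selection problem operates on.
#'
#' @param windows list of [signal_window()] objects with equal channel count.
#' @param method one of `"pcc"` (default), `"plv"`, `"te"`.
#' @param bins bins for `method = "te"`.
#' @return object of class `correlation_dataset`: list with `matrices`
#'   (`m x m x N`), `labels` (integer N-vector), `method`, `m`, `n`.
#' @export
build_dataset <- function(windows, method = c("pcc", "plv", "te"),
                          bins = 8L) {
  method <- match.arg(method)
  if (length(windows) == 0L) stop("empty window list")
  stopifnot(all(vapply(windows, inherits, logical(1), "signal_window")))
  ms <- vapply(windows, function(w) nrow(w$values), integer(1))
  if (length(unique(ms)) != 1L) {
    stop("mixed channel counts across windows: ",
         paste(unique(ms), collapse = ", "))
  }
  m <- ms[1L]
  fn <- switch(method,
               pcc = pcc_matrix,
               plv = plv_matrix,
               te = function(w) te_matrix(w, bins = bins))
  mats <- vapply(windows, fn, matrix(0, m, m))
  correlation_dataset(mats, vapply(windows, `[[`, integer(1), "label"),
                      method)
}

#' Construct a connectivity dataset from precomputed matrices
#'
#' @param matrices `m x m x N` array (or a list of `m x m` matrices).
#' @param labels integer class labels, length N.
#' @param method connectivity measure the matrices came from.
#' @return a `correlation_dataset`.
#' @export
correlation_dataset <- function(matrices, labels,
                                method = c("pcc", "plv", "te")) {
  method <- match.arg(method)
  if (is.list(matrices)) {
    m <- nrow(matrices[[1L]])
    matrices <- array(unlist(matrices), dim = c(m, m, length(matrices)))
  }
  stopifnot(length(dim(matrices)) == 3L, dim(matrices)[1] == dim(matrices)[2])
  labels <- as.integer(labels)
  if (length(labels) != dim(matrices)[3]) {
    stop("labels length must match sample count")
  }
  structure(list(matrices = matrices, labels = labels, method = method,
                 m = dim(matrices)[1], n = dim(matrices)[3]),
            class = "correlation_dataset")
}

#' @export
print.correlation_dataset <- function(x, ...) {
  cat("<correlation_dataset> ", x$n, " samples, ", x$m, " channels, method=",
      x$method, ", labels 0/1: ", sum(x$labels == 0L), "/",
      sum(x$labels == 1L), "\n", sep = "")
  invisible(x)
}
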