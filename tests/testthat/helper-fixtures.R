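# Shared fixtures, all generated in code.

# 4-channel toy montage: C3/C4 on the equator (left/right), Cz at the apex,
# Fz at the front pole; every pairwise distance is sqrt(2) except C3-C4 = 2.
toy_montage4 <- function() {
  montage(c("C3", "C4", "Cz", "Fz"),
          rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)))
}

# 16-channel montage: a spread subset of the packaged 62-channel cap.
fixture_montage16 <- function() {
  m62 <- montage_62()
  idx <- match(c("F7", "F3", "FZ", "F4", "F8", "T7", "C3", "CZ", "C4",
                 "T8", "P3", "PZ", "P4", "O1", "OZ", "O2"), m62$names)
  montage(m62$names[idx], m62$coords[idx, ], m62$location[idx])
}

# Random symmetric unit-diagonal "correlation" matrices with entries in
# [-1, 1]; a fraction `p_zero` of pair entries is exactly zero so deletion
# logic has structure to chew on.
random_corr_dataset <- function(m, n, seed, p_zero = 0.3) {
  withr::with_seed(seed, {
    mats <- array(0, dim = c(m, m, n))
    pt <- pair_table(m)
    for (k in seq_len(n)) {
      v <- stats::runif(nrow(pt), -1, 1)
      v[stats::runif(nrow(pt)) < p_zero] <- 0
      M <- diag(m)
      M[pt] <- v
      M[pt[, c(2, 1)]] <- v
      mats[, , k] <- M
    }
    correlation_dataset(mats, labels = rep_len(0:1, n))
  })
}

# Small separable connectivity dataset for classifier-dependent tests:
# planted structure, few channels, short windows, fast SVM.
small_problem_dataset <- function(seed = 11L, m = 6L, n_windows = 12L,
                                  T_len = 80L) {
  gen <- synth_generate(synth_spec(m = m, T_len = T_len,
                                   n_windows = n_windows,
                                   informative = 1:3, rho = 0.9,
                                   delta = 1.0, seed = seed))
  build_dataset(gen$windows)
}

# A montage with m generic channels alternating hemispheres (for runs on
# synthetic datasets whose channel count has no packaged montage).
generic_montage <- function(m, seed = 5L) {
  withr::with_seed(seed, {
    coords <- matrix(stats::rnorm(3 * m), ncol = 3)
  })
  montage(paste0("ch", seq_len(m)), coords,
          location = rep_len(c(1L, -1L, 0L), m))
}

# Minimal evaluated individual for selection/metric tests.
stub_individual <- function(objectives, m_d = objectives[1],
                            deleted = NULL, d = 4L) {
  ind <- individual(rep(0.5, d), rep(1L, d))
  ind$objectives <- objectives
  ind$eval <- list(m_d = m_d, deleted = deleted,
                   f1_star = NA_real_, f2 = objectives[2], zero_ratio = NA)
  ind
}

# Brute-force dominance check (maximization): does a dominate b?
brute_dominates <- function(a, b) {
  all(a >= b) && any(a > b)
}

# O(n^2) Pareto ranks by repeated peeling, independent of the package's
# fast-sort bookkeeping.
brute_ranks <- function(objs) {
  n <- nrow(objs)
  rank <- rep(NA_integer_, n)
  r <- 1L
  left <- seq_len(n)
  while (length(left) > 0L) {
    front <- left[vapply(left, function(a) {
      !any(vapply(left, function(b) {
        b != a && brute_dominates(objs[b, ], objs[a, ])
      }, logical(1)))
    }, logical(1))]
    rank[front] <- r
    left <- setdiff(left, front)
    r <- r + 1L
  }
  rank
}

# Naive triple-loop channel deletion: per channel, per sample, count zero
# partners; delete when the count exceeds s in every sample.
brute_count_deleted <- function(B, s) {
  m <- dim(B)[1]; n <- dim(B)[3]
  deleted <- logical(m)
  for (j in seq_len(m)) {
    ok_all <- TRUE
    for (k in seq_len(n)) {
      zeros <- 0L
      for (i in seq_len(m)) {
        if (i != j && B[i, j, k] == 0) zeros <- zeros + 1L
      }
      if (!(zeros > s)) { ok_all <- FALSE; break }
    }
    deleted[j] <- ok_all
  }
  C <- B
  for (j in which(deleted)) { C[j, , ] <- 0; C[, j, ] <- 0 }
  list(m_d = sum(deleted), deleted = deleted, C = C)
}

# Monte-Carlo dominated-area estimate for a 2-D maximization front.
mc_hypervolume <- function(front, ref, n_samples = 1e5, seed = 1) {
  withr::with_seed(seed, {
    hi <- c(max(front[, 1]), max(front[, 2]))
    xs <- stats::runif(n_samples, ref[1], hi[1])
    ys <- stats::runif(n_samples, ref[2], hi[2])
    ord <- order(front[, 1], decreasing = TRUE)
    f1s <- front[ord, 1]
    best_f2 <- cummax(front[ord, 2])
    # K = number of front points with f1 >= x (prefix of the sorted front)
    K <- length(f1s) - findInterval(xs, rev(f1s))
    dominated <- K >= 1L & ys <= best_f2[pmax(K, 1L)]
    p <- mean(dominated)
    area <- (hi[1] - ref[1]) * (hi[2] - ref[2])
    list(hv = p * area, se = sqrt(p * (1 - p) / n_samples) * area)
  })
}
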