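#' Hybrid-encoded individual
#'
#' A candidate solution couples a real `dec` vector (threshold magnitudes)
#' with a binary `mask` vector; the effective threshold vector is their
#' elementwise product, so the mask carries the sparsity of the solution.
#'
#' @param dec numeric vector in \[0, 1\]^d.
#' @param mask integer 0/1 vector of the same length.
#' @return object of class `individual` with fields `dec`, `mask`,
#'   `objectives` (NULL until evaluated), `eval`, `rank`, `crowding`.
#' @export
individual <- function(dec, mask) {
  stopifnot(length(dec) == length(mask),
            all(dec >= 0 & dec <= 1), all(mask %in% c(0L, 1L)))
  structure(list(dec = as.numeric(dec), mask = as.integer(mask),
                 objectives = NULL, eval = NULL,
                 rank = NA_integer_, crowding = NA_real_),
            class = "individual")
}

#' Effective threshold vector of an individual
#'
#' @param ind an [individual()].
#' @return `dec * mask`, elementwise.
#' @export
effective_threshold <- function(ind) {
  ind$dec * ind$mask
}

#' Sequential grouping of decision variables
#'
#' Splits indices `1..d` into `k` contiguous blocks. The nominal block size
#' is the integer closest to `d/k` (ties round half up); the final block
#' absorbs the remainder.
#'
#' @param d number of decision variables.
#' @param k number of groups, `1 <= k <= d`.
#' @return list of `k` integer index vectors (disjoint, contiguous,
#'   covering `1..d`).
#' @export
sequential_groups <- function(d, k) {
  d <- as.integer(d)
  k <- as.integer(k)
  if (k < 1L || k > d) stop("k must lie in [1, d]")
  size <- floor(d / k + 0.5)        # round half up
  if (size < 1L) size <- 1L
  starts <- (seq_len(k) - 1L) * size + 1L
  ends <- pmin(starts + size - 1L, d)
  ends[k] <- d                      # last block takes the remainder
  lapply(seq_len(k), function(g) seq.int(starts[g], ends[g]))
}

# binary tournament on score among candidate indices; returns one index.
# want = "high" picks the larger score, "low" the smaller.
score_tournament <- function(cands, scores, want = c("high", "low")) {
  want <- match.arg(want)
  if (length(cands) == 1L) return(cands)
  pick <- cands[sample.int(length(cands), 2L, replace = FALSE)]
  s <- scores[pick]
  if (want == "high") pick[which.max(s)] else pick[which.min(s)]
}

#' Sparse population initialization
#'
#' Generates the initial population for the sparse channel selection
#' problem. Each individual draws `dec` uniformly on \[0, 1\]^d and a
#' sparsity level `rho ~ U(0, 1)`; `ceiling(rho * d)` mask entries are then
#' activated one at a time by binary tournaments on the geometry scores,
#' biased so that high-score pairs (distant, cross-hemisphere) are
#' activated preferentially under the default bias.
#'
#' @param pop_size number of individuals (>= 2).
#' @param scores a [score_vector()] (or plain numeric vector of length d).
#' @param score_bias `"activate_high_score"` (default) activates high-score
#'   pairs first; `"zero_high_score"` inverts the preference.
#' @return list of [individual()]s. Uses the current RNG state; seed the
#'   session for reproducibility.
#' @export
sparse_init <- function(pop_size, scores,
                        score_bias = c("activate_high_score",
                                       "zero_high_score")) {
  score_bias <- match.arg(score_bias)
  sc <- if (inherits(scores, "score_vector")) scores$scores else scores
  d <- length(sc)
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L) stop("pop_size must be >= 2")
  want <- if (score_bias == "activate_high_score") "high" else "low"
  lapply(seq_len(pop_size), function(i) {
    dec <- stats::runif(d)
    rho <- stats::runif(1L)
    n_on <- min(ceiling(rho * d), d)
    mask <- integer(d)
    remaining <- seq_len(d)
    for (b in seq_len(n_on)) {
      win <- score_tournament(remaining, sc, want)
      mask[win] <- 1L
      remaining <- remaining[remaining != win]
    }
    individual(dec, mask)
  })
}

#' Score-based mask crossover
#'
#' The offspring mask starts from parent `p`. With probability 1/2 a
#' single 0-to-1 flip is attempted: within one randomly chosen variable
#' group, among indices where `p` is 0 and `q` is 1, two candidates are
#' sampled and the higher-score one is activated. Otherwise a single
#' 1-to-0 flip is attempted among in-group indices where `p` is 1 and `q`
#' is 0, deactivating the lower-score candidate. With no candidates the
#' mask is returned unchanged; at most one bit changes.
#'
#' @param p,q parent [individual()]s.
#' @param scores a [score_vector()] or numeric vector.
#' @param groups output of [sequential_groups()].
#' @return integer mask vector for the offspring.
#' @export
score_mask_crossover <- function(p, q, scores, groups) {
  sc <- if (inherits(scores, "score_vector")) scores$scores else scores
  mask <- p$mask
  grp <- groups[[sample.int(length(groups), 1L)]]
  if (stats::runif(1L) < 0.5) {
    cands <- grp[p$mask[grp] == 0L & q$mask[grp] == 1L]
    if (length(cands) > 0L) {
      mask[score_tournament(cands, sc, "high")] <- 1L
    }
  } else {
    cands <- grp[p$mask[grp] == 1L & q$mask[grp] == 0L]
    if (length(cands) > 0L) {
      mask[score_tournament(cands, sc, "low")] <- 0L
    }
  }
  mask
}

#' Score-based mask mutation
#'
#' With probability 1/2 one 0-to-1 flip, else one 1-to-0 flip, with the
#' candidate pair drawn from one randomly chosen variable group and the
#' winner chosen by score as in [score_mask_crossover()]. At most one bit
#' changes.
#'
#' @param o an [individual()] (or its mask via `o$mask`).
#' @param scores a [score_vector()] or numeric vector.
#' @param groups output of [sequential_groups()].
#' @return mutated integer mask vector.
#' @export
score_mask_mutation <- function(o, scores, groups) {
  sc <- if (inherits(scores, "score_vector")) scores$scores else scores
  mask <- o$mask
  grp <- groups[[sample.int(length(groups), 1L)]]
  if (stats::runif(1L) < 0.5) {
    cands <- grp[mask[grp] == 0L]
    if (length(cands) > 0L) mask[score_tournament(cands, sc, "high")] <- 1L
  } else {
    cands <- grp[mask[grp] == 1L]
    if (length(cands) > 0L) mask[score_tournament(cands, sc, "low")] <- 0L
  }
  mask
}

#' Score-based mutation of the real threshold vector
#'
#' Early-stage mutation of `dec`: each index is selected independently with
#' probability `1/d`. A selected index `j` moves up with probability equal
#' to its min-max-normalized score and down otherwise, by a uniform step of
#' magnitude at most `alpha`, clipped to \[0, 1\]. High-score pairs
#' (distant, cross-hemisphere) thus drift toward large thresholds and are
#' filtered out.
#'
#' @param o an [individual()] (its `dec` is mutated).
#' @param scores a [score_vector()] or numeric vector.
#' @param alpha mutation magnitude in \[0, 1\] (default 0.1).
#' @return mutated numeric dec vector.
#' @export
score_dec_mutation <- function(o, scores, alpha = 0.1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  sc <- if (inherits(scores, "score_vector")) scores$scores else scores
  d <- length(sc)
  rng <- range(sc)
  shat <- if (rng[2] > rng[1]) (sc - rng[1]) / (rng[2] - rng[1])
          else rep(0.5, d)
  dec <- o$dec
  sel <- stats::runif(d) < 1 / d
  if (any(sel)) {
    up <- stats::runif(sum(sel)) < shat[sel]
    step <- alpha * stats::runif(sum(sel))
    dec[sel] <- ifelse(up, pmin(1, dec[sel] + step),
                       pmax(0, dec[sel] - step))
  }
  dec
}

#' Simulated binary crossover
#'
#' Standard SBX on two real parent vectors with bounds \[0, 1\]: each
#' coordinate recombines with probability 1/2 using the polynomial spread
#' factor with distribution index `eta`; offspring are clipped to bounds.
#'
#' @param p_dec,q_dec parent vectors in \[0, 1\]^d.
#' @param eta distribution index (default 20).
#' @param prob per-pair crossover probability (default 1).
#' @return list of two offspring vectors.
#' @export
sbx_crossover <- function(p_dec, q_dec, eta = 20, prob = 1) {
  d <- length(p_dec)
  stopifnot(length(q_dec) == d)
  c1 <- p_dec
  c2 <- q_dec
  if (stats::runif(1L) <= prob) {
    # coordinates with (near-)equal parents are copied unchanged
    do <- stats::runif(d) < 0.5 & abs(p_dec - q_dec) > 1e-12
    u <- stats::runif(d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    h1 <- 0.5 * ((1 + beta) * p_dec + (1 - beta) * q_dec)
    h2 <- 0.5 * ((1 - beta) * p_dec + (1 + beta) * q_dec)
    c1[do] <- h1[do]
    c2[do] <- h2[do]
    c1 <- pmin(1, pmax(0, c1))
    c2 <- pmin(1, pmax(0, c2))
  }
  list(c1, c2)
}

#' Polynomial mutation
#'
#' Standard bounded polynomial mutation on \[0, 1\] with distribution
#' index `eta`; each coordinate mutates independently with probability
#' `prob` (default `1/d`). Used for the real vector in the late stage.
#'
#' @param dec numeric vector in \[0, 1\]^d.
#' @param eta distribution index (default 20).
#' @param prob per-coordinate mutation probability (default `1/length(dec)`).
#' @return mutated vector in \[0, 1\]^d.
#' @export
polynomial_mutation <- function(dec, eta = 20, prob = 1 / length(dec)) {
  d <- length(dec)
  sel <- stats::runif(d) < prob
  if (!any(sel)) return(dec)
  x <- dec[sel]
  u <- stats::runif(sum(sel))
  # bounds [0, 1]: delta1 = x, delta2 = 1 - x
  lo <- u < 0.5
  pow <- 1 / (eta + 1)
  deltaq <- numeric(sum(sel))
  val <- ifelse(lo,
                2 * u + (1 - 2 * u) * (1 - x)^(eta + 1),
                2 * (1 - u) + 2 * (u - 0.5) * (1 - (1 - x))^(eta + 1))
  deltaq[lo] <- val[lo]^pow - 1
  deltaq[!lo] <- 1 - val[!lo]^pow
  dec[sel] <- pmin(1, pmax(0, x + deltaq))
  dec
}

#' Binary tournament parent selection
#'
#' Draws a mating pool of `n` parents by repeated pairwise contests:
#' lower Pareto rank wins; rank ties go to the larger crowding distance;
#' full ties are broken uniformly.
#'
#' @param pop list of evaluated [individual()]s with `rank` and `crowding`
#'   set (see [nondominated_sort()] and [crowding_distance()]).
#' @param n pool size (default `length(pop)`).
#' @return integer vector of selected indices into `pop`.
#' @export
binary_tournament <- function(pop, n = length(pop)) {
  ranks <- vapply(pop, `[[`, numeric(1), "rank")
  crowd <- vapply(pop, `[[`, numeric(1), "crowding")
  if (anyNA(ranks) || anyNA(crowd)) {
    stop("population lacks rank/crowding metadata; run selection first")
  }
  vapply(seq_len(n), function(i) {
    ab <- sample.int(length(pop), 2L, replace = TRUE)
    a <- ab[1L]; b <- ab[2L]
    if (ranks[a] < ranks[b]) return(a)
    if (ranks[b] < ranks[a]) return(b)
    if (crowd[a] > crowd[b]) return(a)
    if (crowd[b] > crowd[a]) return(b)
    ab[sample.int(2L, 1L)]
  }, integer(1))
}
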