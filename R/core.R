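#' Run configuration
#'
#' Collects every tunable of the two-stage algorithm with the standard
#' defaults: population 200, budget 20000 evaluations, transition fraction
#' `mu = 0.2`, deletion parameter `s = 40` (for 62-channel data), distance
#' radius `R = 1`, score-mutation magnitude `alpha = 0.1`, SBX/polynomial
#' distribution indices 20, 10 sequential variable groups.
#'
#' @param pop_size population size N (even, >= 4).
#' @param max_fe evaluation budget (>= pop_size).
#' @param mu early-stage budget fraction in \[0, 1\]: the algorithm moves
#'   to the late stage once `mu * max_fe` evaluations are consumed (or
#'   earlier on the diversity trigger).
#' @param s zero-assignment parameter of [count_deleted()].
#' @param R distance radius of [score_vector()].
#' @param alpha magnitude of [score_dec_mutation()].
#' @param eta_sbx,eta_pm distribution indices of SBX and polynomial
#'   mutation.
#' @param group_count number of sequential variable groups.
#' @param seed RNG seed for the whole run.
#' @param classifier a [classifier_spec()].
#' @param score_bias initialization bias of [sparse_init()].
#' @return object of class `run_config`.
#' @export
run_config <- function(pop_size = 200L, max_fe = 20000L, mu = 0.2,
                       s = 40L, R = 1.0, alpha = 0.1,
                       eta_sbx = 20, eta_pm = 20, group_count = 10L,
                       seed = 1L, classifier = classifier_spec(),
                       score_bias = "activate_high_score") {
  pop_size <- as.integer(pop_size)
  max_fe <- as.integer(max_fe)
  if (pop_size < 4L || pop_size %% 2L != 0L) {
    stop("pop_size must be even and >= 4")
  }
  if (max_fe < pop_size) stop("max_fe must be >= pop_size")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  structure(list(pop_size = pop_size, max_fe = max_fe, mu = mu,
                 s = s, R = R, alpha = alpha, eta_sbx = eta_sbx,
                 eta_pm = eta_pm, group_count = as.integer(group_count),
                 seed = as.integer(seed), classifier = classifier,
                 score_bias = score_bias),
            class = "run_config")
}

#' Number of distinct deletion counts in a population
#'
#' The population-diversity measure behind the stage transition: the
#' number of different deleted-channel counts (`m_d` values) realized by
#' the current population.
#'
#' @param pop list of evaluated [individual()]s.
#' @return integer count.
#' @export
ndc <- function(pop) {
  md <- vapply(pop, function(ind) {
    if (is.null(ind$eval)) stop("unevaluated individual in population")
    ind$eval$m_d
  }, numeric(1))
  length(unique(md))
}

#' Early-to-late stage transition test
#'
#' The algorithm leaves the early stage when the consumed evaluation
#' budget reaches `mu * max_fe` (inclusive) or when the population already
#' realizes `m - 2` (or more) distinct deletion counts — i.e., it covers
#' essentially every feasible value of the late-stage first objective
#' (retaining at least 2 channels caps `m_d` at `m - 2`).
#'
#' @param fe evaluations consumed so far.
#' @param ndc_value current [ndc()] of the population.
#' @param config a [run_config()].
#' @param m channel count.
#' @return logical.
#' @export
should_transition <- function(fe, ndc_value, config, m) {
  fe >= config$mu * config$max_fe || ndc_value >= m - 2L
}

#' Fast non-dominated sorting (maximization)
#'
#' Pareto-ranks a set of objective vectors under maximization: a solution
#' dominates another when no objective is smaller and at least one is
#' strictly larger. Rank 1 is the mutually non-dominated front.
#'
#' @param objectives numeric matrix, one row per solution.
#' @return integer vector of ranks (1-based).
#' @export
nondominated_sort <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(integer(0))
  dom_count <- integer(n)
  dominates <- vector("list", n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      diff <- objectives[a, ] - objectives[b, ]
      if (all(diff >= 0) && any(diff > 0)) {
        dominates[[a]] <- c(dominates[[a]], b)
      } else if (all(diff <= 0) && any(diff < 0)) {
        dom_count[a] <- dom_count[a] + 1L
      }
    }
  }
  rank <- integer(n)
  current <- which(dom_count == 0L)
  r <- 1L
  while (length(current) > 0L) {
    rank[current] <- r
    nxt <- integer(0)
    for (a in current) {
      for (b in dominates[[a]]) {
        dom_count[b] <- dom_count[b] - 1L
        if (dom_count[b] == 0L) nxt <- c(nxt, b)
      }
    }
    current <- sort(unique(nxt))
    r <- r + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' NSGA-II crowding: per objective, solutions are sorted and boundary
#' solutions get infinite distance; interior ones accumulate the
#' normalized gap between their neighbors.
#'
#' @param objectives numeric matrix, one row per solution (a single front).
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(numeric(0))
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (obj in seq_len(ncol(objectives))) {
    o <- objectives[, obj]
    ord <- order(o)
    dist[ord[c(1L, n)]] <- Inf
    rng <- o[ord[n]] - o[ord[1L]]
    if (rng > 0) {
      inner <- ord[2L:(n - 1L)]
      dist[inner] <- dist[inner] + (o[ord[3L:n]] - o[ord[1L:(n - 2L)]]) / rng
    }
  }
  dist
}

# attach rank and crowding metadata to a population
rank_population <- function(pop) {
  objs <- do.call(rbind, lapply(pop, `[[`, "objectives"))
  ranks <- nondominated_sort(objs)
  for (r in unique(ranks)) {
    idx <- which(ranks == r)
    cd <- crowding_distance(objs[idx, , drop = FALSE])
    for (q in seq_along(idx)) {
      pop[[idx[q]]]$rank <- r
      pop[[idx[q]]]$crowding <- cd[q]
    }
  }
  pop
}

#' Environmental selection (rank + crowding truncation)
#'
#' Selects the next population from a parent+offspring pool: fill by
#' ascending Pareto rank; split the last partially fitting front by
#' descending crowding distance, breaking ties by pool index so the
#' outcome is deterministic.
#'
#' @param pool list of evaluated [individual()]s (length >= n).
#' @param n survivors to keep.
#' @return list of `n` individuals with `rank`/`crowding` metadata set.
#' @export
environmental_selection <- function(pool, n) {
  if (length(pool) < n) stop("pool smaller than requested survivors")
  pool <- rank_population(pool)
  ranks <- vapply(pool, `[[`, numeric(1), "rank")
  crowd <- vapply(pool, `[[`, numeric(1), "crowding")
  ord <- order(ranks, -crowd, seq_along(pool))
  pool[ord[seq_len(n)]]
}

#' Two-objective hypervolume with the offset reference point
#'
#' Area dominated (under maximization) by the non-dominated subset of a
#' front, relative to the reference point
#' `z = (min f1 - 0.1, min f2 - 0.1)` taken over the front itself.
#'
#' @param front numeric matrix with two columns (objective pairs), or a
#'   2-vector for a single point.
#' @param ref optional explicit reference point; default is the offset
#'   minimum above.
#' @return scalar hypervolume.
#' @export
hypervolume <- function(front, ref = NULL) {
  if (is.null(dim(front))) front <- matrix(front, ncol = 2L)
  front <- as.matrix(front)
  dimnames(front) <- NULL
  if (nrow(front) == 0L) stop("empty front")
  stopifnot(ncol(front) == 2L)
  keep <- nondominated_sort(front) == 1L
  fr <- front[keep, , drop = FALSE]
  # reference point offsets the minima of the Pareto subset, so dominated
  # points cannot move it
  if (is.null(ref)) ref <- c(min(fr[, 1]) - 0.1, min(fr[, 2]) - 0.1)
  fr <- fr[order(fr[, 1], decreasing = TRUE), , drop = FALSE]
  fr <- fr[!duplicated(fr[, 1]), , drop = FALSE]   # safety on ties
  hv <- 0
  prev_f2 <- ref[2]
  for (i in seq_len(nrow(fr))) {
    hv <- hv + (fr[i, 1] - ref[1]) * (fr[i, 2] - prev_f2)
    prev_f2 <- fr[i, 2]
  }
  hv
}

# evaluate a list of individuals in place, honoring the FE budget;
# returns the (possibly truncated) evaluated list
evaluate_population <- function(pop, prob, stage, max_fe) {
  budget <- max_fe - prob$fe
  if (budget <= 0L) return(list())
  if (length(pop) > budget) pop <- pop[seq_len(budget)]
  lapply(pop, function(ind) {
    res <- evaluate_threshold(prob, effective_threshold(ind), stage)
    ind$objectives <- res$objectives
    ind$eval <- res[setdiff(names(res), "objectives")]
    ind
  })
}

# generate one offspring batch of size n from the ranked population
make_offspring <- function(pop, n, scores, groups, stage, config, d) {
  parents <- binary_tournament(pop, n)
  off <- vector("list", n)
  for (i in seq(1L, n, by = 2L)) {
    p <- pop[[parents[i]]]
    q <- pop[[parents[min(i + 1L, n)]]]
    decs <- sbx_crossover(p$dec, q$dec, eta = config$eta_sbx, prob = 1)
    m1 <- score_mask_crossover(p, q, scores, groups)
    m2 <- score_mask_crossover(q, p, scores, groups)
    o1 <- individual(decs[[1L]], m1)
    o2 <- individual(decs[[2L]], m2)
    o1$mask <- score_mask_mutation(o1, scores, groups)
    o2$mask <- score_mask_mutation(o2, scores, groups)
    if (stage == "early") {
      o1$dec <- score_dec_mutation(o1, scores, config$alpha)
      o2$dec <- score_dec_mutation(o2, scores, config$alpha)
    } else {
      o1$dec <- polynomial_mutation(o1$dec, eta = config$eta_pm, prob = 1 / d)
      o2$dec <- polynomial_mutation(o2$dec, eta = config$eta_pm, prob = 1 / d)
    }
    off[[i]] <- o1
    if (i + 1L <= n) off[[i + 1L]] <- o2
  }
  off[!vapply(off, is.null, logical(1))]
}

#' Run the two-stage sparse multi-objective channel selection algorithm
#'
#' The main loop: geometry scores and sequential variable groups are
#' derived from the montage; the population is created by [sparse_init()]
#' and evolved generationally with binary-tournament mating, SBX on the
#' real vectors, score-based mask crossover/mutation, and a
#' stage-dependent real-vector mutation (score-based early, polynomial
#' late). The early stage maximizes `(f1*, f2)`; once
#' [should_transition()] fires, cached evaluations are relabeled to the
#' late-stage objectives `(m_d, f2)` at zero evaluation cost and the run
#' continues until the budget is exhausted.
#'
#' @param dataset a [correlation_dataset()] with both classes.
#' @param mon a [montage()] with `m` equal to the dataset channel count.
#' @param config a [run_config()].
#' @return object of class `tsmoea_result`: list with `archive` (rank-1
#'   individuals of the final population), `population`, `history` (one
#'   data.frame row per generation: `gen, fe, stage, ndc, hv, best_f2,
#'   max_md`), `config`, `scores`, and `fe` consumed.
#' @export
tsmoea_run <- function(dataset, mon, config = run_config()) {
  stopifnot(inherits(dataset, "correlation_dataset"),
            inherits(mon, "montage"), inherits(config, "run_config"))
  m <- dataset$m
  if (length(mon$names) != m) {
    stop("montage has ", length(mon$names), " channels, dataset has ", m)
  }
  set.seed(config$seed)
  scores <- score_vector(mon, config$R)
  d <- n_pairs(m)
  groups <- sequential_groups(d, min(config$group_count, d))
  prob <- channel_problem(dataset, config$s, config$classifier)
  stage <- "early"
  if (config$mu == 0) stage <- "late"   # no early-stage budget at all

  pop <- sparse_init(config$pop_size, scores, config$score_bias)
  pop <- evaluate_population(pop, prob, stage, config$max_fe)
  pop <- rank_population(pop)

  history <- list()
  gen <- 0L
  log_gen <- function() {
    objs <- do.call(rbind, lapply(pop, `[[`, "objectives"))
    fr <- objs[nondominated_sort(objs) == 1L, , drop = FALSE]
    history[[length(history) + 1L]] <<- data.frame(
      gen = gen, fe = prob$fe, stage = stage, ndc = ndc(pop),
      hv = hypervolume(fr),
      best_f2 = max(vapply(pop, function(i) i$eval$f2, numeric(1))),
      max_md = max(vapply(pop, function(i) i$eval$m_d, numeric(1))))
  }
  log_gen()

  while (prob$fe < config$max_fe) {
    if (stage == "early" &&
        should_transition(prob$fe, ndc(pop), config, m)) {
      stage <- "late"
      pop <- lapply(pop, function(ind) {
        ind$objectives <- stage_objectives(ind$eval, stage)
        ind
      })
      pop <- rank_population(pop)
    }
    off <- make_offspring(pop, config$pop_size, scores, groups, stage,
                          config, d)
    off <- evaluate_population(off, prob, stage, config$max_fe)
    if (length(off) > 0L) {
      pop <- environmental_selection(c(pop, off), config$pop_size)
    }
    gen <- gen + 1L
    log_gen()
  }

  objs <- do.call(rbind, lapply(pop, `[[`, "objectives"))
  archive <- pop[nondominated_sort(objs) == 1L]
  structure(list(archive = archive, population = pop,
                 history = do.call(rbind, history), config = config,
                 scores = scores, fe = prob$fe),
            class = "tsmoea_result")
}

#' @export
print.tsmoea_result <- function(x, ...) {
  cat("<tsmoea_result> ", length(x$archive), " archive solutions, ",
      x$fe, " evaluations, ", nrow(x$history), " generations logged\n",
      sep = "")
  md <- vapply(x$archive, function(i) i$eval$m_d, numeric(1))
  f2 <- vapply(x$archive, function(i) i$eval$f2, numeric(1))
  cat(" deleted channels: ", paste(sort(unique(md)), collapse = " "),
      "\n best accuracy: ", sprintf("%.2f%%", max(f2)), "\n", sep = "")
  invisible(x)
}
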