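#' Specification of a synthetic windowed EEG-like recording
#'
#' Defines a generator of per-window multichannel signals in which a
#' planted subset `S` of channels carries class-dependent shared structure
#' and every other channel is independent noise. Within `S`, each channel
#' mixes a common latent series (amplitude-scaled by class) with
#' independent noise, so the per-window connectivity matrices show a dense
#' informative block over `S` and near-zero entries elsewhere — the sparse
#' correlation structure the channel selection problem assumes.
#'
#' For a channel in `S`, `x = a_c * rho * z + noise_sd * e` with latent
#' `z ~ N(0,1)`, noise `e ~ N(0,1)` and class amplitude
#' `a_c = 1 -/+ delta/2` (class 0 low, class 1 high), giving an expected
#' within-`S` correlation of about
#' `a_c^2 rho^2 / (a_c^2 rho^2 + noise_sd^2)` — class-dependent, so the
#' correlation features carry label information for the accuracy
#' objective.
#'
#' @param m channel count.
#' @param T_len samples per window.
#' @param n_windows windows per class (>= 2).
#' @param informative integer index set `S` of planted channels
#'   (`|S| >= 2`).
#' @param rho latent coupling weight in \[0, 1\].
#' @param delta class separation of the latent amplitude (effect size).
#' @param noise_sd background noise standard deviation.
#' @param fs nominal sampling rate (metadata).
#' @param seed RNG seed for [synth_generate()].
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(m = 16L, T_len = 250L, n_windows = 60L,
                       informative = 1:6, rho = 0.9, delta = 1.0,
                       noise_sd = 1.0, fs = 250, seed = 1L) {
  m <- as.integer(m)
  informative <- as.integer(informative)
  if (length(informative) < 2L) stop("need at least 2 informative channels")
  if (length(informative) > m || any(informative < 1L | informative > m)) {
    stop("informative channel indices must lie in 1..m")
  }
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (n_windows < 2L) stop("need at least 2 windows per class")
  structure(list(m = m, T_len = as.integer(T_len),
                 n_windows = as.integer(n_windows),
                 informative = informative, rho = rho, delta = delta,
                 noise_sd = noise_sd, fs = fs, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate synthetic windows with planted correlated channels
#'
#' @param spec a [synth_spec()].
#' @return list with `windows` (list of [signal_window()], class labels
#'   balanced and interleaved 0/1) and `ground_truth` (list with the
#'   planted set `S` and the generator parameters). Deterministic in
#'   `spec$seed`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  windows <- withr::with_seed(spec$seed, {
    lapply(seq_len(2L * spec$n_windows), function(w) {
      label <- (w - 1L) %% 2L              # interleave classes 0,1,0,1,...
      amp <- 1 + (if (label == 1L) spec$delta / 2 else -spec$delta / 2)
      z <- stats::rnorm(spec$T_len)
      v <- matrix(stats::rnorm(spec$m * spec$T_len, sd = spec$noise_sd),
                  nrow = spec$m)
      v[spec$informative, ] <- v[spec$informative, ] +
        matrix(rep(amp * spec$rho * z, each = length(spec$informative)),
               nrow = length(spec$informative))
      signal_window(v, label, spec$fs)
    })
  })
  list(windows = windows,
       ground_truth = list(S = spec$informative, spec = spec))
}

#' Planted-structure recovery score of an archive
#'
#' Measures how well the optimizer's deletions avoid the planted
#' informative channels: over archive solutions whose deletion count lies
#' in `band`, the mean fraction of deleted channels that fall OUTSIDE the
#' planted set `S`. 1 means only noise channels were deleted; random
#' deletion with `|S| = m/2` gives about 0.5 in expectation.
#'
#' @param archive list of evaluated [individual()]s (e.g.
#'   `tsmoea_run(...)$archive`).
#' @param ground_truth the `ground_truth` element of [synth_generate()].
#' @param band length-2 numeric: inclusive `m_d` range of the solutions to
#'   score (default `c(1, Inf)`, i.e., everything that deletes at least
#'   one channel).
#' @return fraction in \[0, 1\].
#' @export
planted_recovery_score <- function(archive, ground_truth,
                                   band = c(1, Inf)) {
  if (length(archive) == 0L) stop("empty archive")
  S <- ground_truth$S
  md <- vapply(archive, function(i) i$eval$m_d, numeric(1))
  sel <- which(md >= band[1] & md <= band[2])
  if (length(sel) == 0L) {
    stop("no archive solutions with m_d in [", band[1], ", ", band[2], "]")
  }
  fracs <- vapply(sel, function(k) {
    del <- which(archive[[k]]$eval$deleted)
    sum(!(del %in% S)) / length(del)
  }, numeric(1))
  mean(fracs)
}
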