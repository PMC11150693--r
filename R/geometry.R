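#' Electrode montage
#'
#' A montage holds the scalp electrode labels, their 3-D positions on a
#' unit sphere, and a hemisphere code per channel: `+1` left, `-1` right,
#' `0` midline. Positions drive the inter-electrode distance matrix and the
#' per-pair score assignment used by the sparse genetic operators.
#'
#' @param names character vector of unique channel labels (length >= 3).
#' @param coords numeric matrix, one row per channel, columns x, y, z.
#'   Rows are normalized to unit length on construction.
#' @param location optional integer vector in \{-1, 0, 1\}; when `NULL` the
#'   hemisphere is inferred from the 10-20 naming convention (odd digit
#'   suffix = left, even = right, trailing 'z'/'Z' = midline).
#' @return An object of class `montage` with fields `names`, `coords`
#'   (unit rows) and `location`.
#' @examples
#' mon <- montage(c("C3", "Cz", "C4"),
#'                rbind(c(-1, 0, 0), c(0, 0, 1), c(1, 0, 0)))
#' mon$location  # 1 0 -1
#' @export
montage <- function(names, coords, location = NULL) {
  names <- as.character(names)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(names) < 3L) {
    stop("a montage needs at least 3 channels, got ", length(names))
  }
  if (anyDuplicated(names)) {
    stop("duplicate channel names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (nrow(coords) != length(names) || ncol(coords) != 3L) {
    stop("coords must be a ", length(names), " x 3 matrix")
  }
  if (!all(is.finite(coords))) stop("non-finite coordinate")
  nrm <- sqrt(rowSums(coords^2))
  if (any(nrm < 1e-12)) {
    stop("zero-norm coordinate for channel ",
         paste(names[nrm < 1e-12], collapse = ", "))
  }
  coords <- coords / nrm
  dimnames(coords) <- NULL
  if (is.null(location)) {
    location <- infer_hemisphere(names)
  } else {
    location <- as.integer(location)
    if (length(location) != length(names) ||
        !all(location %in% c(-1L, 0L, 1L))) {
      stop("location must be one of -1, 0, 1 for every channel")
    }
  }
  structure(list(names = names, coords = coords, location = location),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$names), " channels, ",
      n_pairs(length(x$names)), " pairs\n", sep = "")
  cat(" left/midline/right: ", sum(x$location == 1L), "/",
      sum(x$location == 0L), "/", sum(x$location == -1L), "\n", sep = "")
  invisible(x)
}

#' Infer hemisphere codes from 10-20 channel names
#'
#' Odd trailing digit = left (+1), even = right (-1), 'z'/'Z' suffix =
#' midline (0).
#'
#' @param names character vector of channel labels.
#' @return integer vector in \{-1, 0, 1\}.
#' @export
infer_hemisphere <- function(names) {
  vapply(names, function(nm) {
    last <- substring(nm, nchar(nm))
    if (last %in% c("z", "Z")) return(0L)
    if (grepl("[0-9]$", nm)) {
      num <- as.integer(sub(".*?([0-9]+)$", "\\1", nm))
      return(if (num %% 2L == 1L) 1L else -1L)
    }
    stop("cannot infer hemisphere from channel name '", nm,
         "'; provide a location column")
  }, integer(1), USE.NAMES = FALSE)
}

#' Load a montage from a TSV file
#'
#' Expected columns: `name x y z` and optionally `location`. Coordinates may
#' be on any scale; they are projected to the unit sphere. Without a
#' `location` column hemisphere codes are inferred from the 10-20 naming
#' convention.
#'
#' @param path path to a tab-separated montage file with a header row.
#' @return a [montage()] object.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("montage file must have columns 'name x y z' (tab-separated); got: ",
         paste(names(tab), collapse = ", "))
  }
  loc <- if ("location" %in% names(tab)) tab$location else NULL
  montage(tab$name, as.matrix(tab[, c("x", "y", "z")]), loc)
}

#' Packaged 62-channel 10-20 montage
#'
#' Standard spherical positions for a 62-electrode cap laid out on the
#' international 10-20/10-10 grid, generated from the canonical inclination
#' and azimuth angles on a unit-sphere head model.
#'
#' @return a [montage()] with 62 channels (1891 channel pairs).
#' @export
montage_62 <- function() {
  load_montage(system.file("extdata", "montage_62_1020.tsv",
                           package = "tsmoea", mustWork = TRUE))
}

#' Number of unordered channel pairs
#'
#' @param m channel count.
#' @return `m * (m - 1) / 2`.
#' @export
n_pairs <- function(m) {
  m <- as.integer(m)
  (m * (m - 1L)) %/% 2L
}

#' Channel-pair index map
#'
#' Unordered off-diagonal pairs `(i, j)`, `i < j`, are flattened in
#' row-major upper-triangle order: (1,2), (1,3), ..., (1,m), (2,3), ...
#' This single ordering is used for thresholds, scores and feature vectors
#' throughout the package.
#'
#' @param m channel count.
#' @return integer matrix with `m(m-1)/2` rows and columns `i`, `j`;
#'   row `p` holds the pair with linear index `p`.
#' @examples
#' pair_table(4)  # 6 rows: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
#' @export
pair_table <- function(m) {
  m <- as.integer(m)
  if (m < 2L) stop("m must be >= 2")
  i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(k) (k + 1L):m),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Linear index of a channel pair
#'
#' @param i,j channel indices with `i < j` (1-based, vectorized).
#' @param m channel count.
#' @return 1-based linear index in row-major upper-triangle order.
#' @export
pair_index <- function(i, j, m) {
  stopifnot(all(i < j), all(j <= m), all(i >= 1))
  ((i - 1L) * (2L * m - i)) %/% 2L + (j - i)
}

#' Inter-electrode distance matrix
#'
#' Euclidean distances between electrode positions on the unit sphere.
#' Symmetric, zero diagonal, entries bounded by 2 (antipodal points).
#'
#' @param mon a [montage()].
#' @return `m x m` numeric matrix with channel names as dimnames.
#' @export
distance_matrix <- function(mon) {
  stopifnot(inherits(mon, "montage"))
  dm <- as.matrix(stats::dist(mon$coords))
  dimnames(dm) <- list(mon$names, mon$names)
  dm
}

#' Geometry-based score assignment for channel pairs
#'
#' Each decision variable (channel pair) receives a score from electrode
#' geometry: with `DM` the pairwise distance, `Max(DM)` its maximum and `R`
#' the channel radius,
#' \deqn{Score(k,l) = (DM - R) / (2 (Max(DM) + R))}
#' when the channels share a hemisphere;
#' \deqn{DM / (2 (Max(DM) + R))} when hemispheres differ and `DM < R`; and
#' \deqn{(DM + R) / (2 (Max(DM) + R))} when hemispheres differ and
#' `DM >= R`. A midline channel paired with a lateral one counts as a
#' different-hemisphere pair; two midline channels count as same-hemisphere.
#' Distant cross-hemisphere pairs thus score highest.
#'
#' @param mon a [montage()].
#' @param R channel radius, in the same (unit-sphere) distance units;
#'   must be positive. Default 1.
#' @return object of class `score_vector`: list with `scores` (length
#'   `m(m-1)/2`, pair order of [pair_table()]), `R`, `max_dm`, `min_dm`.
#' @export
score_vector <- function(mon, R = 1.0) {
  stopifnot(inherits(mon, "montage"))
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("R must be a single positive number")
  }
  dm <- distance_matrix(mon)
  pt <- pair_table(length(mon$names))
  d_pair <- dm[pt]
  max_dm <- max(dm)
  min_dm <- min(dm[upper.tri(dm)])
  loc <- mon$location
  same <- loc[pt[, "i"]] == loc[pt[, "j"]]
  denom <- 2 * (max_dm + R)
  scores <- ifelse(same, (d_pair - R) / denom,
                   ifelse(d_pair < R, d_pair / denom, (d_pair + R) / denom))
  structure(list(scores = as.numeric(scores), R = R,
                 max_dm = max_dm, min_dm = min_dm),
            class = "score_vector")
}
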