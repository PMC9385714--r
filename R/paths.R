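#' Sample unique direct mutational paths
#'
#' A direct mutational path from the all-wild to the all-mutant genotype
#' is an ordering of the `N` loci; sampling draws uniform random
#' permutations and deduplicates until `n_paths` unique paths are
#' collected.
#'
#' @param N Number of loci.
#' @param n_paths Number of unique paths; must not exceed `N!`.
#' @return Integer matrix with `n_paths` rows; each row a permutation of
#'   `1..N` giving the order in which loci mutate.
#' @export
sample_unique_paths <- function(N, n_paths) {
  stopifnot(N >= 1L, n_paths >= 1L)
  if (log(n_paths) > lfactorial(N) + 1e-9) {
    stop("n_paths exceeds N! = ", exp(lfactorial(N)))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- matrix(NA_integer_, nrow = n_paths, ncol = N)
  got <- 0L
  while (got < n_paths) {
    p <- sample.int(N)
    key <- paste(p, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[got, ] <- p
    }
  }
  out
}

#' Enumerate all N! direct paths
#'
#' Exhaustive counterpart of [sample_unique_paths()] for small `N`,
#' used as the brute-force oracle.
#'
#' @param N Number of loci (capped at 8).
#' @return Integer matrix with `N!` rows.
#' @export
enumerate_all_paths <- function(N) {
  stopifnot(N >= 1L, N <= 8L)
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  m <- perms(seq_len(N))
  storage.mode(m) <- "integer"
  m
}

#' Minimum activity along mutational paths
#'
#' Walks each path's genotype chain from all-wild to all-mutant and
#' returns the minimum RA over the `N - 1` strict intermediates (the
#' anchors are the known-active endpoints; set `include_endpoints` to
#' score them too). A path traversing a genotype absent from the
#' landscape (`NA`) is non-evaluable and yields `NA`.
#'
#' @param paths Integer path matrix (rows are locus orders).
#' @param ra Numeric vector of length `2^N`, RA in binary order, `NA`
#'   for missing genotypes.
#' @param include_endpoints Score the two anchors as well.
#' @return Numeric vector of per-path minimum RA.
#' @export
path_min_activity <- function(paths, ra, include_endpoints = FALSE) {
  if (is.vector(paths)) paths <- matrix(paths, nrow = 1L)
  N <- ncol(paths)
  if (length(ra) != 2^N) stop("ra must have length 2^ncol(paths)")
  idx <- rep(0L, nrow(paths))
  m <- rep(Inf, nrow(paths))
  if (include_endpoints) m <- pmin(m, ra[1L], ra[length(ra)])
  steps <- if (N >= 2L) seq_len(N - 1L) else integer(0)
  for (s in steps) {
    idx <- idx + bitwShiftL(1L, paths[, s] - 1L)
    m <- pmin(m, ra[idx + 1L])
  }
  if (N == 1L && !include_endpoints) m <- rep(Inf, nrow(paths))
  as.numeric(m)
}

#' Neutral-path accessibility across thresholds
#'
#' For each neutrality threshold, the fraction of evaluable sampled
#' paths whose minimum intermediate RA meets the threshold. Paths
#' crossing genotypes missing from the landscape are excluded from both
#' numerator and denominator and counted separately.
#'
#' @param paths Integer path matrix.
#' @param ra RA vector in binary order (`NA` = missing genotype).
#' @param thresholds Numeric vector of neutrality thresholds.
#' @param include_endpoints See [path_min_activity()].
#' @return Data frame of class `path_report` with columns `threshold`,
#'   `n_evaluable`, `n_neutral`, `fraction`; non-evaluable path count in
#'   `attr(, "n_non_evaluable")`.
#' @export
accessibility_curve <- function(paths, ra, thresholds = c(0.2, 0.4, 0.6),
                                include_endpoints = FALSE) {
  m <- path_min_activity(paths, ra, include_endpoints)
  ok <- !is.na(m)
  out <- data.frame(
    threshold = thresholds,
    n_evaluable = sum(ok),
    n_neutral = vapply(thresholds, function(t) sum(m[ok] >= t), integer(1L)))
  out$fraction <- ifelse(out$n_evaluable > 0,
                         out$n_neutral / out$n_evaluable, NaN)
  attr(out, "n_non_evaluable") <- sum(!ok)
  class(out) <- c("path_report", "data.frame")
  out
}
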