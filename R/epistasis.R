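#' Floor-clamp relative activities before taking logarithms
#'
#' RA values of exactly zero are artifacts of finite sequencing depth;
#' before log-space analysis they are clamped below at `floor`
#' (default 1e-3).
#'
#' @param ra Numeric vector of RA values.
#' @param floor Positive clamp value.
#' @return `log(pmax(ra, floor))`.
#' @export
log_ra <- function(ra, floor = 1e-3) {
  stopifnot(floor > 0)
  log(pmax(ra, floor))
}

#' Log-additive expectation model
#'
#' Stores the RA of every assayed single mutant, keyed by its `posBASE`
#' token. The expected RA of a multi-mutant is the product of its
#' constituent single-mutant RAs (a sum in log space); a genotype whose
#' constituent singles are absent from the model cannot be scored.
#'
#' @param activity Activity table (or data frame) containing the single
#'   mutants: columns `sequence` and `RA_mean` (or `ra`).
#' @param wt Wild-type sequence.
#' @param floor RA floor used in log space, see [log_ra()].
#' @return Object of class `log_additive_model`.
#' @export
log_additive_model <- function(activity, wt, floor = 1e-3) {
  ra <- if ("RA_mean" %in% names(activity)) activity$RA_mean else activity$ra
  stopifnot(!is.null(ra), "sequence" %in% names(activity))
  d <- hamming(wt, activity$sequence)
  singles <- which(d == 1L)
  if (length(singles) == 0L) stop("no single mutants in the activity table")
  tokens <- vapply(activity$sequence[singles], function(s)
    name_variant(mutations_between(wt, s)), character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(tokens)) stop("duplicated single-mutant entries")
  structure(list(wt = wt,
                 log_m = stats::setNames(log_ra(ra[singles], floor), tokens),
                 floor = floor),
            class = "log_additive_model")
}

#' Expected RA under the log-additive model
#'
#' `ln(expRA) = sum_i ln(M_i) gamma_i` over the variant's constituent
#' single mutants; the wild type maps to 1.
#'
#' @param seqs Character vector of genotype sequences.
#' @param model A [log_additive_model()].
#' @return Numeric vector of expected RA values.
#' @export
expected_ra_log_additive <- function(seqs, model) {
  stopifnot(inherits(model, "log_additive_model"))
  vapply(seqs, function(s) {
    ms <- mutations_between(model$wt, s)
    if (nrow(ms) == 0L) return(1.0)
    tokens <- paste0(ms$pos, ms$base)
    lm <- model$log_m[tokens]
    if (anyNA(lm)) {
      stop("single mutant(s) missing from the model: ",
           paste(tokens[is.na(lm)], collapse = ", "))
    }
    exp(sum(lm))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the mean of the
#' observed values; may be negative for predictions worse than the mean.
#'
#' @param observed,expected Equal-length numeric vectors.
#' @return Scalar R-squared.
#' @export
r_squared <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed vector is constant: R^2 undefined")
  1 - sum((observed - expected)^2) / ss_tot
}

#' Fraction of neutral mutants by Hamming distance
#'
#' For each distance class `n` present in the landscape, the fraction of
#' assayed variants at Hamming distance `n` from the reference whose RA
#' meets the neutrality threshold.
#'
#' @param landscape Data frame with columns `sequence` and `ra` (or an
#'   activity table with `RA_mean`).
#' @param reference Reference sequence (WT or another anchor).
#' @param cfg A [neutrality_config()].
#' @return Data frame with columns `n`, `n_variants`, `n_neutral`,
#'   `omega`.
#' @export
neutral_fraction_by_distance <- function(landscape, reference,
                                         cfg = neutrality_config()) {
  ra <- if ("RA_mean" %in% names(landscape)) landscape$RA_mean else landscape$ra
  stopifnot(!is.null(ra))
  d <- hamming(reference, landscape$sequence)
  agg <- stats::aggregate(list(n_variants = ra),
                          by = list(n = d), FUN = length)
  neu <- stats::aggregate(list(n_neutral = ra >= cfg$threshold),
                          by = list(n = d), FUN = sum)
  out <- merge(agg, neu, by = "n")
  out$omega <- out$n_neutral / out$n_variants
  out[order(out$n), ]
}

#' Fit the directional epistasis model
#'
#' Fits `omega(n) = exp(-alpha * n^beta)` to the decline of the neutral
#' fraction with mutation count by nonlinear least squares (initial
#' values alpha = 0.5, beta = 1; positivity bounds). `alpha` is the
#' robustness decay parameter (lower alpha, more robust); `beta` the
#' strength of directional epistasis (`beta > 1` an excess of negative
#' epistasis, `beta < 1` positive, `beta = 1` balanced or absent).
#'
#' @param omega_table Data frame with columns `n` (distance, >= 1) and
#'   `omega` (fractions in (0, 1]); typically distances 1-3.
#' @return Object of class `directional_fit`: list with `alpha`, `beta`,
#'   their standard errors, `fitted`, `residuals`, and the `nls` fit.
#' @export
fit_directional_epistasis <- function(omega_table) {
  d <- omega_table[omega_table$n >= 1, c("n", "omega")]
  if (nrow(d) < 2L) stop("need at least two distance classes with n >= 1")
  if (any(d$omega <= 0 | d$omega > 1)) {
    stop("omega values must lie in (0, 1]")
  }
  # canonical starting values alpha = 0.5, beta = 1; fall back to a small
  # grid when the gradient is singular there (e.g. near-flat omega)
  starts <- list(c(0.5, 1), c(0.1, 1), c(1, 1), c(0.05, 0.5), c(2, 2))
  fit <- NULL
  last_err <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(omega ~ exp(-alpha * n^beta), data = d,
                        start = list(alpha = s[1], beta = s[2]),
                        lower = c(alpha = 1e-9, beta = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("directional-epistasis fit failed to converge: ", last_err)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(alpha = NA_real_, beta = NA_real_))
  structure(list(alpha = unname(est["alpha"]), beta = unname(est["beta"]),
                 alpha_se = unname(se["alpha"]), beta_se = unname(se["beta"]),
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 fit = fit),
            class = "directional_fit")
}

#' @export
print.directional_fit <- function(x, ...) {
  cat(sprintf("omega(n) = exp(-alpha n^beta): alpha = %.4f (SE %.4f), beta = %.4f (SE %.4f)\n",
              x$alpha, x$alpha_se, x$beta, x$beta_se))
  invisible(x)
}

## ---- Walsh-Hadamard machinery -------------------------------------------

#' Dense epistasis operator matrices
#'
#' Builds the `2^N x 2^N` matrices of the epistasis decompositions by
#' their defining recursions: `G_{n+1} = [[G_n, 0], [-G_n, G_n]]`
#' (relative, single-reference epistasis, `e_rel = G w`), the Hadamard
#' matrix `H_{n+1} = [[H_n, H_n], [H_n, -H_n]]`, and the diagonal
#' weighting `V_{n+1} = [[V_n/2, 0], [0, -V_n]]`, so that
#' `e_avg = V H w` is the background-averaged decomposition. Dense
#' construction is capped (default N <= 12) and retained as the
#' brute-force oracle for the fast transforms.
#'
#' @param N Number of biallelic loci.
#' @param cap Maximum N for dense construction.
#' @return List with matrices `G`, `H`, `V`.
#' @export
build_epistasis_matrices <- function(N, cap = 12L) {
  stopifnot(N >= 0L)
  if (N > cap) stop("dense matrices capped at N = ", cap)
  G <- H <- V <- matrix(1, 1L, 1L)
  for (i in seq_len(N)) {
    Z <- matrix(0, nrow(G), ncol(G))
    G <- rbind(cbind(G, Z), cbind(-G, G))
    H <- rbind(cbind(H, H), cbind(H, -H))
    V <- rbind(cbind(V / 2, Z), cbind(Z, -V))
  }
  list(G = G, H = H, V = V)
}

# In-place 2x2 butterfly over every bit level: the fast O(n log n)
# implementation of any Kronecker power of a 2x2 matrix. m2 acts on
# (value at bit=0, value at bit=1) pairs.
.bitwise_butterfly <- function(w, m2) {
  n <- length(w)
  N <- as.integer(round(log2(n)))
  if (2^N != n) stop("length of w must be a power of two")
  idx_all <- 0:(n - 1L)
  for (b in seq_len(N) - 1L) {
    step <- bitwShiftL(1L, b)
    i0 <- which(bitwAnd(idx_all, step) == 0L)
    i1 <- i0 + step
    a <- w[i0]
    d <- w[i1]
    w[i0] <- m2[1L, 1L] * a + m2[1L, 2L] * d
    w[i1] <- m2[2L, 1L] * a + m2[2L, 2L] * d
  }
  w
}

# Diagonal of V: (1/2)^(N - k) * (-1)^k for a term of order k.
.v_diag <- function(N) {
  k <- popcount(0:(2^N - 1L))
  (0.5)^(N - k) * (-1)^k
}

#' Fast Walsh-Hadamard epistasis transforms
#'
#' Computes the relative (`e_rel = G w`) and background-averaged
#' (`e_avg = V H w`) epistatic coefficients of a complete biallelic
#' landscape by in-place butterfly passes, without materialising the
#' dense matrices. `w` holds ln(RA) in binary order (genotype index =
#' integer value of its bit vector, locus 1 = least-significant bit);
#' the interaction order of term `i` is the popcount of `i`.
#'
#' @param w Numeric vector of length `2^N` of ln(RA) values in binary
#'   order.
#' @return Object of class `wh_decomposition`: list with `N`, `w`,
#'   `e_rel`, `e_avg`, and per-term `order`.
#' @export
wh_decompose <- function(w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  n <- length(w)
  N <- as.integer(round(log2(n)))
  if (2^N != n) stop("length of w must be a power of two")
  e_rel <- .bitwise_butterfly(w, matrix(c(1, -1, 0, 1), 2L))
  e_avg <- .v_diag(N) * .bitwise_butterfly(w, matrix(c(1, 1, 1, -1), 2L))
  structure(list(N = N, w = w, e_rel = e_rel, e_avg = e_avg,
                 order = popcount(seq_len(n) - 1L)),
            class = "wh_decomposition")
}

#' Invert an epistatic coefficient vector back to ln(RA)
#'
#' `w = G^-1 e_rel` or `w = (V H)^-1 e_avg`, computed by fast
#' butterflies (`G^-1` is the Kronecker power of `[[1,0],[1,1]]`;
#' `(VH)^-1 = H V^-1 / 2^N` since `H H = 2^N I`).
#'
#' @param e Coefficient vector of length `2^N`.
#' @param basis `"relative"` for `e_rel`, `"averaged"` for `e_avg`.
#' @return Numeric vector `w` of ln(RA) values in binary order.
#' @export
wh_inverse <- function(e, basis = c("averaged", "relative")) {
  basis <- match.arg(basis)
  n <- length(e)
  N <- as.integer(round(log2(n)))
  if (2^N != n) stop("length of e must be a power of two")
  if (basis == "relative") {
    .bitwise_butterfly(e, matrix(c(1, 1, 0, 1), 2L))
  } else {
    .bitwise_butterfly(e / .v_diag(N), matrix(c(1, 1, 1, -1), 2L)) / n
  }
}

#' Truncated reconstruction of a landscape from low-order terms
#'
#' Zeroes every epistatic coefficient of interaction order greater than
#' `max_order` and applies the inverse transform; `max_order = N`
#' reproduces `w` exactly.
#'
#' @param dec A [wh_decompose()] result.
#' @param max_order Highest interaction order retained (0..N).
#' @param basis Coefficient basis to truncate, see [wh_inverse()].
#' @return Reconstructed `w` vector.
#' @export
reconstruct_truncated <- function(dec, max_order,
                                  basis = c("averaged", "relative")) {
  basis <- match.arg(basis)
  stopifnot(inherits(dec, "wh_decomposition"),
            max_order >= 0L, max_order <= dec$N)
  e <- if (basis == "averaged") dec$e_avg else dec$e_rel
  e[dec$order > max_order] <- 0
  wh_inverse(e, basis)
}

#' R-squared of truncated reconstructions per interaction order
#'
#' For each truncation order `k = 0..N`, reconstructs ln(RA) from the
#' coefficients of order at most `k` and reports the coefficient of
#' determination against the observed values, together with the
#' cumulative fraction of terms used. Optionally restricts the
#' comparison to variants whose Hamming distance from the all-wild
#' genotype exceeds the truncation order.
#'
#' @param dec A [wh_decompose()] result.
#' @param basis Coefficient basis, see [wh_inverse()].
#' @param beyond_order_only If `TRUE`, score only variants with more
#'   mutations than the included order.
#' @return Data frame with columns `max_order`, `r2`, `term_fraction`.
#' @export
reconstruction_profile <- function(dec, basis = c("averaged", "relative"),
                                   beyond_order_only = FALSE) {
  basis <- match.arg(basis)
  N <- dec$N
  k_obs <- popcount(seq_along(dec$w) - 1L)
  out <- data.frame(max_order = 0:N, r2 = NA_real_,
                    term_fraction = vapply(0:N, function(k) term_fraction(N, k),
                                           numeric(1L)))
  for (k in 0:N) {
    rec <- reconstruct_truncated(dec, k, basis)
    sel <- if (beyond_order_only) k_obs > k else rep(TRUE, length(rec))
    out$r2[out$max_order == k] <-
      if (sum(sel) >= 2L && stats::var(dec$w[sel]) > 0) {
        r_squared(dec$w[sel], rec[sel])
      } else NA_real_
  }
  out
}

#' Cumulative fraction of epistatic terms up to an order
#'
#' `sum_{j<=k} choose(N, j) / 2^N`; for N = 16 and k = 2 this is
#' 137/65536, about 0.2% of all terms.
#'
#' @param N Number of loci.
#' @param k Maximum interaction order.
#' @return Scalar fraction.
#' @export
term_fraction <- function(N, k) {
  stopifnot(k >= 0L, k <= N)
  sum(choose(N, 0:k)) / 2^N
}

## ---- reciprocal sign epistasis ------------------------------------------

#' Classify reciprocal sign epistasis on a genotype square
#'
#' A pair of genotypes at Hamming distance 2 (`ab`, `AB`) with both
#' intermediate single mutants (`Ab`, `aB`) shows reciprocal sign
#' epistasis when both endpoints have strictly higher, or both strictly
#' lower, RA than both intermediates. The classification is symmetric in
#' the endpoints and in the intermediates.
#'
#' @param ra_ab,ra_AB,ra_Ab,ra_aB Numeric vectors of RA values
#'   (vectorised over squares).
#' @return Logical vector.
#' @export
classify_reciprocal_sign <- function(ra_ab, ra_AB, ra_Ab, ra_aB) {
  if (anyNA(c(ra_ab, ra_AB, ra_Ab, ra_aB))) {
    stop("missing RA value on a square")
  }
  lo <- pmin(ra_ab, ra_AB) > pmax(ra_Ab, ra_aB)
  hi <- pmax(ra_ab, ra_AB) < pmin(ra_Ab, ra_aB)
  lo | hi
}

#' Enumerate distance-2 genotype squares in a sequence landscape
#'
#' Finds every unordered pair of genotypes at Hamming distance 2 whose
#' two intermediate single mutants are also present in the dataset, and
#' classifies each square for reciprocal sign epistasis. The reference
#' of a pair is the member closest to `wt`; `reference_distance` is its
#' Hamming distance from `wt`.
#'
#' @param landscape Data frame with columns `sequence` and `ra` (or
#'   `RA_mean`).
#' @param wt Wild-type sequence used only to bin pairs by reference
#'   distance.
#' @return Data frame with one row per square: `ab`, `AB`, `Ab`, `aB`,
#'   `reference_distance`, `reciprocal_sign`.
#' @export
enumerate_square_pairs <- function(landscape, wt) {
  ra <- if ("RA_mean" %in% names(landscape)) landscape$RA_mean else landscape$ra
  seqs <- landscape$sequence
  stopifnot(!is.null(ra), !anyDuplicated(seqs))
  n <- length(seqs)
  if (n < 2L) {
    return(data.frame(ab = character(0), AB = character(0),
                      Ab = character(0), aB = character(0),
                      reference_distance = integer(0),
                      reciprocal_sign = logical(0)))
  }
  X <- one_hot(seqs)
  L <- nchar(seqs[1L])
  # pairwise Hamming distances via one-hot inner products
  D <- L - tcrossprod(X)
  pair <- which(upper.tri(D) & D == 2L, arr.ind = TRUE)
  lookup <- stats::setNames(seq_len(n), seqs)
  d_wt <- hamming(wt, seqs)
  rows <- vector("list", nrow(pair))
  for (r in seq_len(nrow(pair))) {
    i <- pair[r, 1L]
    j <- pair[r, 2L]
    ms <- mutations_between(seqs[i], seqs[j])
    int1 <- apply_mutations(seqs[i], ms[1L, , drop = FALSE])
    int2 <- apply_mutations(seqs[i], ms[2L, , drop = FALSE])
    k1 <- lookup[int1]
    k2 <- lookup[int2]
    if (is.na(k1) || is.na(k2)) next
    ref_first <- d_wt[i] <= d_wt[j]
    rows[[r]] <- data.frame(
      ab = if (ref_first) seqs[i] else seqs[j],
      AB = if (ref_first) seqs[j] else seqs[i],
      Ab = int1, aB = int2,
      reference_distance = min(d_wt[i], d_wt[j]),
      reciprocal_sign = classify_reciprocal_sign(ra[i], ra[j],
                                                 ra[k1], ra[k2]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(ab = character(0), AB = character(0),
                      Ab = character(0), aB = character(0),
                      reference_distance = integer(0),
                      reciprocal_sign = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Reciprocal sign epistasis census of a complete biallelic landscape
#'
#' Vectorised census over all `2^N * choose(N, 2) / 2` distance-2 pairs
#' of a combinatorially complete landscape stored in binary order
#' (missing genotypes allowed as `NA`: their pairs are skipped). Pairs
#' are binned by the Hamming distance of the reference (the endpoint
#' closer to the all-wild genotype at index 0).
#'
#' @param ra Numeric vector of length `2^N` of RA values in binary
#'   order; `NA` marks genotypes absent from the dataset.
#' @return List with `per_distance` (data frame `reference_distance`,
#'   `n_subgraphs`, `n_reciprocal`, `fraction`), and totals `n_pairs`,
#'   `n_reciprocal`, `fraction`.
#' @export
reciprocal_sign_census <- function(ra) {
  n <- length(ra)
  N <- as.integer(round(log2(n)))
  if (2^N != n) stop("ra must have length 2^N")
  idx <- 0:(n - 1L)
  k_idx <- popcount(idx)
  ref_d <- integer(0)
  rs <- logical(0)
  for (i in seq_len(N) - 1L) {
    bi <- bitwShiftL(1L, i)
    for (j in seq_len(N) - 1L) {
      if (j <= i) next
      bj <- bitwShiftL(1L, j)
      # squares anchored at genotypes with bits i and j clear
      base <- idx[bitwAnd(idx, bi) == 0L & bitwAnd(idx, bj) == 0L]
      a <- ra[base + 1L]          # 00
      b <- ra[base + bi + 1L]     # 10
      c <- ra[base + bj + 1L]     # 01
      d <- ra[base + bi + bj + 1L] # 11
      ok <- !(is.na(a) | is.na(b) | is.na(c) | is.na(d))
      if (!any(ok)) next
      # diagonal pair {00, 11} with intermediates {10, 01}
      rs1 <- classify_reciprocal_sign(a[ok], d[ok], b[ok], c[ok])
      rd1 <- pmin(k_idx[base + 1L], k_idx[base + bi + bj + 1L])[ok]
      # diagonal pair {10, 01} with intermediates {00, 11}
      rs2 <- classify_reciprocal_sign(b[ok], c[ok], a[ok], d[ok])
      rd2 <- pmin(k_idx[base + bi + 1L], k_idx[base + bj + 1L])[ok]
      ref_d <- c(ref_d, rd1, rd2)
      rs <- c(rs, rs1, rs2)
    }
  }
  if (length(rs) == 0L) {
    per <- data.frame(reference_distance = integer(0),
                      n_subgraphs = integer(0), n_reciprocal = integer(0),
                      fraction = numeric(0))
    return(list(per_distance = per, n_pairs = 0L, n_reciprocal = 0L,
                fraction = NaN))
  }
  per <- stats::aggregate(list(n_subgraphs = rs), by =
                            list(reference_distance = ref_d), FUN = length)
  per$n_reciprocal <- stats::aggregate(list(x = rs), by =
                                         list(d = ref_d), FUN = sum)$x
  per$fraction <- per$n_reciprocal / per$n_subgraphs
  list(per_distance = per,
       n_pairs = length(rs),
       n_reciprocal = sum(rs),
       fraction = mean(rs))
}
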