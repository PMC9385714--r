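#' Default assay layout for simulated sequencing runs
#'
#' Fixed barcodes and constant flanks used by the read simulator; any
#' real run supplies its own layout via [assay_spec()].
#'
#' @param core_length Core length of the simulated library.
#' @param max_low_quality_bases,min_total_reads See [assay_spec()].
#' @return An [assay_spec()].
#' @export
default_assay_spec <- function(core_length = 35L,
                               max_low_quality_bases = 1L,
                               min_total_reads = 100L) {
  assay_spec(ligated_barcode = "CGTGAT",
             unligated_barcode = "TCAAGC",
             core_flank_5p = "GGTCTCA",
             core_flank_3p = "TGAGACC",
             core_length = core_length,
             max_low_quality_bases = max_low_quality_bases,
             min_total_reads = min_total_reads)
}

#' Spectrum specification for landscape simulation
#'
#' Describes a sparse background-averaged epistasis spectrum: how many
#' nonzero terms each interaction order carries and at what magnitude.
#' The simulated landscape is obtained by the inverse weighted
#' Walsh-Hadamard transform of coefficients drawn from this spectrum.
#'
#' @param N Number of biallelic loci (at most 16 for full enumeration).
#' @param terms_per_order Integer vector of length `N + 1` (orders
#'   `0..N`): number of nonzero coefficients per order. The order-0
#'   entry is forced to 1 (it anchors the wild-type activity).
#' @param coef_sd Numeric vector (recycled to length `N + 1`): standard
#'   deviation of the nonzero coefficients per order.
#' @param noise_sd Gaussian measurement noise added to ln(RA).
#' @return Object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(N = 16L,
                          terms_per_order = NULL,
                          coef_sd = NULL,
                          noise_sd = 0) {
  stopifnot(N >= 1L, N <= 16L, noise_sd >= 0)
  if (is.null(terms_per_order)) {
    # sparse, low-order-dominated spectrum: all singles, a minority of
    # pairs and triples, nothing above order 3
    terms_per_order <- c(1L, N, round(choose(N, 2) / 4),
                         round(choose(N, 3) / 16), rep(0L, max(0L, N - 3L)))
    terms_per_order <- terms_per_order[seq_len(N + 1L)]
  }
  if (is.null(coef_sd)) coef_sd <- 0.8 * 0.5^(0:N)
  stopifnot(length(terms_per_order) == N + 1L)
  coef_sd <- rep_len(coef_sd, N + 1L)
  terms_per_order <- pmin(as.integer(terms_per_order), choose(N, 0:N))
  terms_per_order[1L] <- 1L
  structure(list(N = as.integer(N), terms_per_order = terms_per_order,
                 coef_sd = coef_sd, noise_sd = noise_sd),
            class = "spectrum_spec")
}

#' Simulate a complete landscape from a known epistasis spectrum
#'
#' Draws sparse background-averaged coefficients per the spectrum,
#' applies the inverse weighted Walsh-Hadamard transform to obtain
#' ln(RA) for all `2^N` genotypes, shifts the landscape so the all-wild
#' genotype has RA exactly 1, and optionally adds Gaussian noise to
#' ln(RA). Both the landscape and its ground-truth coefficient vector
#' are returned, so spectrum-recovery can be tested end to end.
#'
#' @param spec A [spectrum_spec()].
#' @return List with `w` (noisy ln(RA), binary order), `ra`
#'   (`exp(w)`), `e_avg_true` (ground-truth coefficients of the
#'   noise-free landscape), `w_true`, and `spec`.
#' @export
simulate_landscape_from_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  N <- spec$N
  n <- 2^N
  ord <- popcount(0:(n - 1L))
  e <- numeric(n)
  for (k in 0:N) {
    m <- spec$terms_per_order[k + 1L]
    if (m == 0L) next
    pool <- which(ord == k)
    pick <- if (length(pool) == 1L) pool else
      pool[sample.int(length(pool), m)]
    e[pick] <- stats::rnorm(m, 0, spec$coef_sd[k + 1L])
  }
  w <- wh_inverse(e, "averaged")
  # anchor the wild type at RA = 1; a constant shift only moves the
  # order-0 coefficient
  shift <- w[1L]
  w <- w - shift
  e[1L] <- e[1L] - shift
  w_noisy <- if (spec$noise_sd > 0) {
    w + stats::rnorm(n, 0, spec$noise_sd)
  } else w
  list(w = w_noisy, ra = exp(w_noisy), e_avg_true = e, w_true = w,
       spec = spec)
}

# Is each mutation set (given as indices) on the ridge? A genotype with
# mutation set S of size k is neutral when max(S) <= k + width(k) - 1,
# with the window width interpolating linearly from width_wt near the
# wild type to width_mut at the far anchor. Constant width reproduces a
# classic prefix-window ridge; growing width emulates the empirically
# observed robustness gain along the adaptive path.
.on_ridge <- function(idx, N, width_wt, width_mut, blob_radius = 0L,
                      chain_order = seq_len(N), module_size = 0L) {
  k <- popcount(idx)
  width <- width_wt + (width_mut - width_wt) * k / N
  # rank of each locus along the ridge's mutational order
  chain_rank <- integer(N)
  chain_rank[chain_order] <- seq_len(N)
  bits <- index_to_bits(idx, N)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  maxrank <- do.call(pmax, lapply(seq_len(N), function(i)
    bits[, i] * chain_rank[i]))
  on_band <- k == 0L | maxrank <= k + width - 1 | k >= N - blob_radius
  if (module_size > 0L) {
    module_loci <- chain_order[seq_len(module_size)]
    has_module <- rowSums(bits[, module_loci, drop = FALSE]) == module_size
    on_band | has_module
  } else {
    on_band
  }
}

#' Simulate a two-anchor neutral network
#'
#' Builds a complete biallelic landscape in which the all-wild and
#' all-mutant genotypes are both neutral anchors joined by a tunable
#' neutral band (the "ridge"), and every off-band genotype is
#' deleterious. A genotype with mutation set `S` of size `k` is on the
#' band when `max(S) <= k + width - 1`: `ridge_width = 1` leaves a
#' single neutral chain (exactly one accessible locus order), while
#' `ridge_width = N` makes the entire space neutral. Setting
#' `width_mut > ridge_width` widens the band toward the far anchor,
#' grading mutational robustness upward along the path. On-band
#' genotypes draw RA uniformly from `[threshold, 1]`, off-band
#' genotypes from `[0, threshold / 2]` (a safety margin around the
#' neutrality boundary); the anchors are pinned at RA 1 (wild type) and
#' 0.63 (far anchor, the activity of the 16-mutation variant the
#' package's defaults emulate).
#'
#' For `N <= 6` the exact accessible-path fraction is computed by
#' exhaustive enumeration and attached as `true_accessibility`.
#'
#' @param N Number of loci.
#' @param ridge_width Band width at the wild-type end (1..N).
#' @param cfg A [neutrality_config()].
#' @param width_mut Band width at the far anchor; defaults to
#'   `ridge_width` (constant band).
#' @param blob_radius Radius of a fully neutral module around the far
#'   anchor: every genotype within `blob_radius` mutations of the
#'   all-mutant genotype is neutral regardless of the band. Default 0
#'   (no module). This emulates the robust structural module observed
#'   around the evolved distant anchor.
#' @param chain_order Permutation of `1..N` giving the order in which
#'   loci mutate along the ridge. The default (identity) puts the ridge
#'   on contiguous low-index loci; a scattered order interleaves the
#'   ridge across the sequence, making ridge genotypes fragile to
#'   one-point crossover while leaving the robust module unaffected.
#' @param module_size Size `m` of a co-occurring mutation module: every
#'   genotype carrying all of the first `m` ridge mutations (in
#'   `chain_order`) is neutral regardless of its other loci. Such a
#'   module is closed under one-point crossover, emulating a robust
#'   structural unit like the restructured stem of the evolved distant
#'   anchor. Default 0 (none).
#' @param L Core length of the embedded sequences (`>= N`); loci occupy
#'   core positions `1..N`.
#' @param mut_anchor_ra RA pinned at the far anchor.
#' @return List of class `two_anchor_landscape`: `ra` (length `2^N`,
#'   binary order), `neutral`, `map` (a [locus_map()]), `sequences`
#'   (all `2^N` decoded genotypes), `wt`, `mut`, `threshold`,
#'   `true_accessibility` (N <= 6, else `NA`).
#' @export
simulate_two_anchor_network <- function(N, ridge_width,
                                        cfg = neutrality_config(),
                                        width_mut = ridge_width,
                                        blob_radius = 0L,
                                        chain_order = seq_len(N),
                                        module_size = 0L,
                                        L = max(2L * N, N + 4L),
                                        mut_anchor_ra = 0.63) {
  stopifnot(N >= 1L, ridge_width >= 1L, ridge_width <= N,
            width_mut >= 1L, width_mut <= N, L >= N,
            blob_radius >= 0L, blob_radius < N,
            module_size >= 0L, module_size <= N,
            length(chain_order) == N, all(sort(chain_order) == seq_len(N)),
            inherits(cfg, "neutrality_config"))
  if (mut_anchor_ra < cfg$threshold) {
    stop("infeasible ridge: the far anchor must itself be neutral")
  }
  n <- 2^N
  idx <- 0:(n - 1L)
  neutral <- .on_ridge(idx, N, ridge_width, width_mut, blob_radius,
                       chain_order, module_size)
  ra <- ifelse(neutral,
               stats::runif(n, cfg$threshold, 1),
               stats::runif(n, 0, cfg$threshold / 2))
  ra[1L] <- 1.0
  ra[n] <- mut_anchor_ra
  wt <- paste(rep_len(RNA_BASES, L), collapse = "")
  wt_ch <- .chars(wt)
  mut_ch <- wt_ch
  shift <- match(wt_ch[seq_len(N)], RNA_BASES) %% 4L + 1L
  mut_ch[seq_len(N)] <- RNA_BASES[shift]
  mut <- paste(mut_ch, collapse = "")
  map <- locus_map(wt, mut)
  sequences <- vapply(idx, function(i) decode_binary(index_to_bits(i, N), map),
                      character(1L))
  true_acc <- NA_real_
  if (N <= 6L) {
    all_paths <- enumerate_all_paths(N)
    mins <- path_min_activity(all_paths, ra)
    true_acc <- mean(mins >= cfg$threshold)
  }
  structure(list(ra = ra, neutral = ra >= cfg$threshold, map = map,
                 sequences = sequences, wt = wt, mut = mut,
                 threshold = cfg$threshold,
                 ridge_width = ridge_width, width_mut = width_mut,
                 blob_radius = blob_radius, module_size = module_size,
                 chain_order = chain_order,
                 true_accessibility = true_acc),
            class = "two_anchor_landscape")
}

#' @export
as.data.frame.two_anchor_landscape <- function(x, ...) {
  data.frame(index = seq_along(x$ra) - 1L,
             sequence = x$sequences,
             ra = x$ra,
             neutral = x$neutral,
             stringsAsFactors = FALSE)
}

#' Read-simulation specification
#'
#' Conditions of the simulated sequencing assay: wild-type fraction
#' ligated, per-variant per-replicate depth (Poisson around the mean,
#' optionally negative-binomial via `dispersion`), number of
#' replicates, and the assay layout for FASTQ emission.
#'
#' @param fl_wt Wild-type fraction ligated, in (0, 1].
#' @param mean_depth Mean total reads per variant per replicate.
#' @param dispersion `NULL` for Poisson depth; otherwise the
#'   negative-binomial size parameter (smaller = more dispersed).
#' @param n_replicates Number of replicates (the pipeline consumes 2).
#' @param assay An [assay_spec()] for FASTQ emission.
#' @param low_quality_prob Per-base probability that a core base call
#'   in an emitted read carries quality score 10 (below the filter);
#'   all other bases have quality 37.
#' @return Object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(fl_wt = 0.5, mean_depth = 1000,
                          dispersion = NULL, n_replicates = 2L,
                          assay = default_assay_spec(),
                          low_quality_prob = 0) {
  stopifnot(fl_wt > 0, fl_wt <= 1, mean_depth > 0,
            n_replicates >= 1L, inherits(assay, "assay_spec"),
            low_quality_prob >= 0, low_quality_prob <= 1)
  structure(list(fl_wt = fl_wt, mean_depth = mean_depth,
                 dispersion = dispersion,
                 n_replicates = as.integer(n_replicates),
                 assay = assay, low_quality_prob = low_quality_prob),
            class = "read_sim_spec")
}

#' Simulate per-variant read counts
#'
#' For each variant and replicate, the total depth is drawn around
#' `mean_depth` and the ligated count is binomial with success
#' probability `RA * FL_wt` (clipped at 1 with a warning), so the
#' recovered fraction ligated encodes the variant's relative activity.
#'
#' @param landscape Data frame with columns `sequence` and `ra`; must
#'   include the wild type with `ra = 1`.
#' @param spec A [read_sim_spec()].
#' @return Data frame with columns `sequence`, `replicate`,
#'   `n_ligated`, `n_unligated`.
#' @export
simulate_read_counts <- function(landscape, spec = read_sim_spec()) {
  stopifnot(inherits(spec, "read_sim_spec"),
            all(c("sequence", "ra") %in% names(landscape)))
  p <- landscape$ra * spec$fl_wt
  if (any(p > 1)) {
    warning("RA * FL_wt exceeds 1 for ", sum(p > 1),
            " variant(s); clipped")
    p <- pmin(p, 1)
  }
  nvar <- nrow(landscape)
  out <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    depth <- if (is.null(spec$dispersion)) {
      stats::rpois(nvar, spec$mean_depth)
    } else {
      stats::rnbinom(nvar, size = spec$dispersion, mu = spec$mean_depth)
    }
    n_lig <- stats::rbinom(nvar, depth, p)
    out[[r]] <- data.frame(sequence = landscape$sequence,
                           replicate = r,
                           n_ligated = n_lig,
                           n_unligated = depth - n_lig,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Emit simulated reads as FASTQ
#'
#' Writes one FASTQ file per replicate; each read is
#' `barcode + 5' flank + core (DNA) + 3' flank` with the pool encoded
#' by the barcode. Core base calls carry quality 37 except a
#' `low_quality_prob` fraction downgraded to 10 to exercise the quality
#' filter. Read order is shuffled within each file.
#'
#' @param counts Count table from [simulate_read_counts()].
#' @param spec A [read_sim_spec()].
#' @param path_prefix Output prefix; files are
#'   `<prefix>_rep<r>.fastq`.
#' @return Character vector of the written file paths.
#' @export
simulate_fastq <- function(counts, spec, path_prefix) {
  stopifnot(inherits(spec, "read_sim_spec"))
  a <- spec$assay
  paths <- character(0)
  for (r in sort(unique(counts$replicate))) {
    cts <- counts[counts$replicate == r, ]
    core_dna <- chartr("U", "T", cts$sequence)
    seqs <- c(rep(paste0(a$ligated_barcode, a$core_flank_5p, core_dna,
                         a$core_flank_3p), cts$n_ligated),
              rep(paste0(a$unligated_barcode, a$core_flank_5p, core_dna,
                         a$core_flank_3p), cts$n_unligated))
    ord <- sample.int(length(seqs))
    seqs <- seqs[ord]
    read_len <- nchar(seqs[1L])
    core_start <- nchar(a$ligated_barcode) + nchar(a$core_flank_5p) + 1L
    core_end <- core_start + a$core_length - 1L
    qmat <- matrix(37L, nrow = length(seqs), ncol = read_len)
    if (spec$low_quality_prob > 0) {
      hit <- matrix(stats::runif(length(seqs) * a$core_length) <
                      spec$low_quality_prob,
                    nrow = length(seqs))
      qcore <- qmat[, core_start:core_end, drop = FALSE]
      qcore[hit] <- 10L
      qmat[, core_start:core_end] <- qcore
    }
    quals <- apply(qmat, 1L, function(q) intToUtf8(q + 33L))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0("read_", seq_along(x))
    path <- paste0(path_prefix, "_rep", r, ".fastq")
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
    paths <- c(paths, path)
  }
  paths
}
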