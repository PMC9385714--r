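test_that("spectrum-generated landscapes honour their ground truth", {
  set.seed(71)
  # order <= 1 spectrum: a purely additive landscape
  sp1 <- spectrum_spec(N = 6, terms_per_order = c(1, 6, rep(0, 5)),
                       coef_sd = 0.5)
  sim1 <- simulate_landscape_from_spectrum(sp1)
  expect_equal(sim1$w[1], 0)  # wild type anchored at RA 1
  map <- toy_locus_map(6)
  lsc <- binary_landscape_df(exp(sim1$w), map)
  model <- log_additive_model(lsc, map$wt_sequence, floor = 1e-12)
  multi <- popcount(0:(2^6 - 1)) >= 2
  exp_ra <- expected_ra_log_additive(lsc$sequence[multi], model)
  expect_equal(r_squared(sim1$w[multi], log(exp_ra)), 1, tolerance = 1e-9)
  # forward transform recovers the drawn coefficients exactly
  dec <- wh_decompose(sim1$w)
  expect_lt(max(abs(dec$e_avg - sim1$e_avg_true)), 1e-9)
})

test_that("order-3 spectra reconstruct exactly at truncation order 3", {
  set.seed(72)
  sp <- spectrum_spec(N = 8, terms_per_order = c(1, 8, 7, 5, rep(0, 5)),
                      coef_sd = c(0.5, 0.5, 0.4, 0.3))
  sim <- simulate_landscape_from_spectrum(sp)
  prof <- reconstruction_profile(wh_decompose(sim$w))
  expect_equal(prof$r2[prof$max_order == 3], 1, tolerance = 1e-9)
  expect_lt(prof$r2[prof$max_order == 2], 1 - 1e-6)
  # Gaussian measurement noise perturbs the recovered coefficients
  sp_noisy <- spectrum_spec(N = 8, terms_per_order = c(1, 8, 7, 5, rep(0, 5)),
                            coef_sd = c(0.5, 0.5, 0.4, 0.3), noise_sd = 0.1)
  sim_n <- simulate_landscape_from_spectrum(sp_noisy)
  dec_n <- wh_decompose(sim_n$w)
  expect_gt(max(abs(dec_n$e_avg - sim_n$e_avg_true)), 1e-6)
})

test_that("two-anchor networks keep their anchors neutral at any width", {
  set.seed(73)
  for (w in c(1, 2, 4)) {
    la <- simulate_two_anchor_network(N = 4, ridge_width = w)
    expect_equal(la$ra[1], 1)
    expect_gte(la$ra[16], la$threshold)
    expect_true(la$neutral[1] && la$neutral[16])
    # off-band genotypes sit safely below the threshold
    expect_true(all(la$ra[!la$neutral] < la$threshold / 2))
  }
  # the full-width band makes every path accessible
  la_full <- simulate_two_anchor_network(N = 4, ridge_width = 4)
  expect_equal(la_full$true_accessibility, 1)
  # a width-1 band leaves exactly one accessible locus order
  la_chain <- simulate_two_anchor_network(N = 4, ridge_width = 1)
  expect_equal(la_chain$true_accessibility, 1 / factorial(4))
  expect_error(simulate_two_anchor_network(N = 4, ridge_width = 1,
                                           mut_anchor_ra = 0.1),
               "infeasible")
})

test_that("robust modules around the far anchor behave as constructed", {
  set.seed(74)
  # blob_radius: everything within 2 mutations of the far anchor is neutral
  la <- simulate_two_anchor_network(N = 8, ridge_width = 2, blob_radius = 2,
                                    L = 10)
  k <- popcount(seq_along(la$ra) - 1L)
  expect_true(all(la$neutral[k >= 6]))
  # module_size: a co-occurring mutation module is exactly crossover-closed
  lm <- simulate_two_anchor_network(N = 8, ridge_width = 1, module_size = 6,
                                    L = 10)
  bits <- index_to_bits(seq_along(lm$ra) - 1L, 8)
  in_module <- rowSums(bits[, 1:6, drop = FALSE]) == 6L
  expect_true(all(lm$neutral[in_module]))
  module_seqs <- lm$sequences[in_module]
  for (i in 1:30) {
    p <- sample(module_seqs, 2)
    child <- one_point_crossover(p[1], p[2])
    kid_bits <- encode_binary(child, lm$map)
    expect_identical(kid_bits[1:6], rep(1L, 6))
  }
})

test_that("read counts encode activity through the ligated fraction", {
  set.seed(75)
  map <- toy_locus_map(4, L = 8)
  lsc <- binary_landscape_df(c(1, runif(15, 0.05, 1)), map)
  spec <- read_sim_spec(fl_wt = 0.5, mean_depth = 4000,
                        assay = default_assay_spec(core_length = 8L))
  cts <- simulate_read_counts(lsc, spec)
  expect_identical(nrow(cts), 32L)
  expect_identical(sort(unique(cts$replicate)), 1:2)
  r1 <- cts[cts$replicate == 1, ]
  fl <- fraction_ligated(r1$n_ligated, r1$n_unligated)
  expect_lt(max(abs(fl - lsc$ra * 0.5)), 0.05)
  # clipping warning when RA * FL_wt exceeds 1
  hot <- data.frame(sequence = lsc$sequence[1:2], ra = c(1, 3))
  expect_warning(simulate_read_counts(hot, read_sim_spec(fl_wt = 0.5)),
                 "clipped")
  # negative-binomial depth dispersion widens the depth distribution
  set.seed(76)
  d_pois <- simulate_read_counts(lsc, spec)
  spec_nb <- read_sim_spec(fl_wt = 0.5, mean_depth = 4000, dispersion = 2,
                           assay = default_assay_spec(core_length = 8L))
  d_nb <- simulate_read_counts(lsc, spec_nb)
  expect_gt(stats::var(d_nb$n_ligated + d_nb$n_unligated),
            stats::var(d_pois$n_ligated + d_pois$n_unligated))
})

test_that("low-depth variants are discarded downstream", {
  set.seed(77)
  map <- toy_locus_map(2, L = 6)
  lsc <- binary_landscape_df(c(1, 0.6, 0.4, 0.8), map)
  spec <- read_sim_spec(mean_depth = 500,
                        assay = default_assay_spec(core_length = 6L,
                                                   min_total_reads = 100L))
  cts <- simulate_read_counts(lsc, spec)
  # starve one variant below the depth filter in replicate 2
  starved <- lsc$sequence[3]
  sel <- cts$sequence == starved & cts$replicate == 2L
  cts$n_ligated[sel] <- 20L
  cts$n_unligated[sel] <- 20L
  at <- merge_replicates(cts, lsc$sequence[1], spec$assay)
  expect_false(starved %in% at$sequence)
  expect_identical(attr(at, "n_discarded"), 1L)
})

test_that("generators and FASTQ emission are deterministic under a fixed seed", {
  map <- toy_locus_map(3, L = 8)
  set.seed(78)
  la1 <- simulate_two_anchor_network(N = 5, ridge_width = 2)
  set.seed(78)
  la2 <- simulate_two_anchor_network(N = 5, ridge_width = 2)
  expect_identical(la1$ra, la2$ra)
  lsc <- binary_landscape_df(c(1, runif(7, 0.1, 1)), map)
  spec <- read_sim_spec(mean_depth = 60,
                        assay = default_assay_spec(core_length = 8L),
                        low_quality_prob = 0.01)
  set.seed(79)
  cts1 <- simulate_read_counts(lsc, spec)
  f1 <- simulate_fastq(cts1, spec, withr::local_tempfile())
  set.seed(79)
  cts2 <- simulate_read_counts(lsc, spec)
  f2 <- simulate_fastq(cts2, spec, withr::local_tempfile())
  expect_identical(cts1, cts2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  expect_identical(readLines(f1[2]), readLines(f2[2]))
})

test_that("the simulate -> sequence -> quantify -> decompose loop recovers the spectrum", {
  set.seed(80)
  sp <- spectrum_spec(N = 6, terms_per_order = c(1, 6, 4, 2, rep(0, 3)),
                      coef_sd = c(0.4, 0.4, 0.3, 0.25))
  sim <- simulate_landscape_from_spectrum(sp)
  map <- toy_locus_map(6)
  lsc <- binary_landscape_df(exp(sim$w), map)
  rmse <- vapply(c(200, 5000), function(depth) {
    spec <- read_sim_spec(fl_wt = 0.1, mean_depth = depth,
                          assay = default_assay_spec(core_length = 12L,
                                                     min_total_reads = 20L))
    cts <- simulate_read_counts(lsc, spec)
    at <- merge_replicates(cts, map$wt_sequence, spec$assay)
    idx <- vapply(at$sequence, function(s)
      bits_to_index(encode_binary(s, map)), numeric(1)) + 1
    w_hat <- numeric(2^6)
    w_hat[idx] <- log_ra(at$RA_mean)
    sqrt(mean((wh_decompose(w_hat)$e_avg - sim$e_avg_true)^2))
  }, numeric(1))
  # deeper sequencing recovers the epistatic spectrum more accurately;
  # the residual at depth 5000 reflects binomial noise on small RA values
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], 0.2)
})
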