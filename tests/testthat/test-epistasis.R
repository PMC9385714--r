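test_that("log-additive expectation multiplies constituent single-mutant activities", {
  wt <- "AAAA"
  singles <- enumerate_single_mutants(wt)
  act <- data.frame(sequence = c(wt, singles),
                    ra = c(1, rep(0.5, 12)))
  act$ra[act$sequence == "CAAA"] <- 0.5
  act$ra[act$sequence == "ACAA"] <- 0.4
  model <- log_additive_model(act, wt)
  expect_equal(expected_ra_log_additive(wt, model), 1)
  expect_equal(expected_ra_log_additive("CCAA", model), 0.2)
  expect_error(expected_ra_log_additive("CCAA",
                                        log_additive_model(act[1:3, ], wt)),
               "missing")
})

test_that("log-additive model is exact on an additive landscape", {
  set.seed(21)
  wt <- random_genotype(10)
  seqs <- c(wt, enumerate_single_mutants(wt), sample_k_mutants(wt, 2, 150),
            sample_k_mutants(wt, 3, 150))
  lsc <- additive_activity(wt, seqs)
  model <- log_additive_model(lsc, wt)
  multi <- lsc[hamming(wt, lsc$sequence) >= 2, ]
  exp_ra <- expected_ra_log_additive(multi$sequence, model)
  expect_equal(r_squared(log(multi$ra), log(exp_ra)), 1, tolerance = 1e-10)
})

test_that("coefficient of determination matches its closed form", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
})

test_that("neutral fraction by distance recovers constructed fractions", {
  wt <- "AAAAAA"
  singles <- enumerate_single_mutants(wt)   # 18
  doubles <- enumerate_double_mutants(wt)   # 135
  lsc <- data.frame(sequence = c(wt, singles, doubles),
                    ra = c(1,
                           rep(c(1, 0.05), c(9, 9)),
                           rep(c(0.5, 0.01), c(27, 108))))
  om <- neutral_fraction_by_distance(lsc, wt)
  expect_equal(om$omega[om$n == 0], 1)
  expect_equal(om$omega[om$n == 1], 0.5)
  expect_equal(om$omega[om$n == 2], 0.2)
  expect_identical(om$n_variants, c(1L, 18L, 135L))
})

test_that("directional epistasis fit recovers parameters", {
  # noise-free self-consistency
  alpha <- 0.5
  beta <- 1.2
  tab <- data.frame(n = 1:3, omega = exp(-alpha * (1:3)^beta))
  fit <- fit_directional_epistasis(tab)
  expect_equal(fit$alpha, alpha, tolerance = 1e-4)
  expect_equal(fit$beta, beta, tolerance = 1e-4)
  expect_error(fit_directional_epistasis(data.frame(n = 1:2,
                                                    omega = c(1.2, 0.5))),
               "0, 1")
  # under binomial sampling noise the estimates stay within a few SEs
  set.seed(22)
  ok <- replicate(20, {
    omega_hat <- rbinom(3, 1000, exp(-alpha * (1:3)^beta)) / 1000
    f <- fit_directional_epistasis(data.frame(n = 1:3, omega = omega_hat))
    abs(f$alpha - alpha) < 3 * max(f$alpha_se, 0.02) &&
      abs(f$beta - beta) < 3 * max(f$beta_se, 0.02)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("dense G, H, V matrices match their printed one-locus forms and recursions", {
  m <- build_epistasis_matrices(1)
  expect_identical(m$H, matrix(c(1, 1, 1, -1), 2))
  expect_identical(m$G, matrix(c(1, -1, 0, 1), 2))
  expect_identical(m$V, matrix(c(0.5, 0, 0, -1), 2))
  m3 <- build_epistasis_matrices(3)
  expect_identical(dim(m3$G), c(8L, 8L))
  # block recursion spot check: lower-left of G_3 is -G_2
  expect_identical(m3$G[5:8, 1:4], -build_epistasis_matrices(2)$G)
  expect_error(build_epistasis_matrices(13), "capped")
})

test_that("fast Walsh-Hadamard transforms agree with the dense oracle", {
  set.seed(23)
  for (N in c(2, 5, 8)) {
    m <- build_epistasis_matrices(N)
    w <- rnorm(2^N)
    dec <- wh_decompose(w)
    expect_lt(max(abs(dec$e_rel - as.numeric(m$G %*% w))), 1e-9)
    expect_lt(max(abs(dec$e_avg - as.numeric(m$V %*% (m$H %*% w)))), 1e-9)
    expect_lt(max(abs(wh_inverse(dec$e_rel, "relative") - w)), 1e-9)
    expect_lt(max(abs(wh_inverse(dec$e_avg, "averaged") - w)), 1e-9)
    expect_identical(tabulate(dec$order + 1L, N + 1L),
                     as.integer(choose(N, 0:N)))
  }
  expect_error(wh_decompose(rnorm(6)), "power of two")
})

test_that("transform structure: constants and additive landscapes", {
  # constant landscape: a single order-0 background-averaged term
  dec <- wh_decompose(rep(2.5, 16))
  expect_equal(dec$e_avg[1], 2.5)
  expect_lt(max(abs(dec$e_avg[-1])), 1e-12)
  # additive landscape: no terms above order 1 in either basis
  set.seed(24)
  N <- 6
  eff <- rnorm(N, 0, 0.7)
  w <- vapply(0:(2^N - 1), function(i)
    sum(eff[which(index_to_bits(i, N) == 1L)]), numeric(1))
  dec2 <- wh_decompose(w)
  expect_lt(max(abs(dec2$e_avg[dec2$order >= 2])), 1e-12)
  expect_lt(max(abs(dec2$e_rel[dec2$order >= 2])), 1e-12)
})

test_that("relative-basis truncation at order 1 equals the log-additive model", {
  set.seed(25)
  N <- 5
  map <- toy_locus_map(N)
  w <- rnorm(2^N, 0, 0.5)
  w[1] <- 0  # wild type at RA 1
  lsc <- binary_landscape_df(exp(w), map)
  dec <- wh_decompose(w)
  rec1 <- reconstruct_truncated(dec, 1, basis = "relative")
  model <- log_additive_model(lsc, map$wt_sequence, floor = 1e-12)
  exp_ra <- expected_ra_log_additive(lsc$sequence, model)
  expect_equal(rec1, log(exp_ra), tolerance = 1e-9)
})

test_that("truncated reconstruction is exact at full order and mean-only at order 0", {
  set.seed(26)
  w <- rnorm(2^7)
  dec <- wh_decompose(w)
  expect_equal(reconstruct_truncated(dec, 7), w, tolerance = 1e-10)
  rec0 <- reconstruct_truncated(dec, 0, basis = "averaged")
  expect_equal(rec0, rep(mean(w), 2^7), tolerance = 1e-10)
  prof <- reconstruction_profile(dec)
  expect_equal(prof$r2[prof$max_order == 7], 1, tolerance = 1e-10)
  expect_equal(prof$r2[prof$max_order == 0], 0, tolerance = 1e-10)
  expect_error(reconstruct_truncated(dec, 9), "max_order")
})

test_that("term fractions count binomial coefficients", {
  expect_equal(term_fraction(16, 2), 137 / 65536)
  expect_identical(sprintf("%.1f%%", 100 * term_fraction(16, 2)), "0.2%")
  expect_equal(term_fraction(16, 16), 1)
  expect_equal(term_fraction(3, 1), 0.5)
})

test_that("reciprocal sign epistasis classification is symmetric and strict", {
  expect_true(classify_reciprocal_sign(1, 1, 0.1, 0.1))
  expect_true(classify_reciprocal_sign(0.1, 0.1, 1, 1))
  # swapping endpoints or intermediates does not change the call
  expect_identical(classify_reciprocal_sign(1, 0.9, 0.1, 0.2),
                   classify_reciprocal_sign(0.9, 1, 0.2, 0.1))
  # an additive square (multiplicative RA) is never reciprocal sign
  expect_false(classify_reciprocal_sign(1, 0.25 * 0.5, 0.25, 0.5))
  expect_error(classify_reciprocal_sign(1, NA, 0.5, 0.5), "missing")
})

test_that("square-pair enumeration finds complete and censored squares", {
  map <- toy_locus_map(2, L = 6)
  lsc <- binary_landscape_df(c(1, 0.1, 0.1, 1), map)
  sq <- enumerate_square_pairs(lsc, map$wt_sequence)
  # a complete 2-locus landscape holds exactly 2 distance-2 pairs
  expect_identical(nrow(sq), 2L)
  expect_setequal(sq$reference_distance, c(0L, 1L))
  expect_identical(sq$reciprocal_sign[sq$reference_distance == 0L], TRUE)
  # dropping a single mutant censors every square that uses it
  sq2 <- enumerate_square_pairs(lsc[-2, ], map$wt_sequence)
  expect_identical(nrow(sq2), 0L)
})

test_that("binary census agrees exactly with sequence-space enumeration", {
  set.seed(27)
  for (N in c(4, 6)) {
    map <- toy_locus_map(N)
    ra <- exp(rnorm(2^N, 0, 1))
    cen <- reciprocal_sign_census(ra)
    expect_identical(cen$n_pairs, as.integer(2^N * choose(N, 2) / 2))
    sq <- enumerate_square_pairs(binary_landscape_df(ra, map),
                                 map$wt_sequence)
    expect_identical(nrow(sq), cen$n_pairs)
    expect_identical(sum(sq$reciprocal_sign), cen$n_reciprocal)
    per_seq <- tapply(sq$reciprocal_sign, sq$reference_distance, sum)
    per_cen <- setNames(cen$per_distance$n_reciprocal,
                        cen$per_distance$reference_distance)
    expect_equal(per_seq[names(per_cen)], per_cen, ignore_attr = TRUE)
  }
})

test_that("additive landscapes carry no reciprocal sign epistasis", {
  set.seed(28)
  N <- 6
  eff <- rnorm(N, -0.3, 0.8)
  w <- vapply(0:(2^N - 1), function(i)
    sum(eff[which(index_to_bits(i, N) == 1L)]), numeric(1))
  cen <- reciprocal_sign_census(exp(w))
  expect_identical(cen$n_reciprocal, 0L)
  # missing genotypes only remove pairs, never misclassify them
  ra <- exp(w)
  ra[sample.int(2^N, 10)] <- NA
  cen2 <- reciprocal_sign_census(ra)
  expect_identical(cen2$n_reciprocal, 0L)
  expect_lt(cen2$n_pairs, cen$n_pairs)
})
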