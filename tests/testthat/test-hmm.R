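# Poisson HMM: EM fitting, Viterbi/posterior decoding, block building and
# homozygous fractions.

test_that("EM recovers well-separated emission rates and never decreases", {
  true <- as_hmm(c(0.5, 20), matrix(c(.99, .01, .01, .99), 2), c(.5, .5))
  sims <- simulate(true, nsim = 100, length_out = 500, seed = 101)
  fit <- fit_poisson_hmm(lapply(sims, `[[`, "counts"), K = 2)
  expect_true(all(abs(fit$lambda - c(0.5, 20)) / c(0.5, 20) <= 0.10))
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  expect_true(fit$converged)
  # relabelling by ascending lambda makes the fit invariant to the
  # initialisation order
  fit_rev <- fit_poisson_hmm(lapply(sims, `[[`, "counts"), K = 2,
                             lambda_init = c(25, 0.3))
  expect_equal(fit_rev$lambda, fit$lambda, tolerance = 1e-3)
})

test_that("constant counts give a degenerate fit equal to one Poisson", {
  x <- rep(3L, 80)
  fit <- fit_poisson_hmm(list(x), K = 2)
  expect_equal(fit$lambda, c(3, 3), tolerance = 0.05)
  expect_equal(fit$loglik, sum(dpois(x, 3, log = TRUE)), tolerance = 1e-4)
})

test_that("all-zero counts warn and floor the rates", {
  expect_warning(fit <- fit_poisson_hmm(list(rep(0L, 50)), K = 2), "zero")
  expect_true(all(fit$lambda <= 0.01))
})

test_that("Viterbi equals the exhaustive-path argmax on random chains", {
  set.seed(202)
  for (i in 1:200) {
    K <- sample(c(2, 3, 4), 1)
    T_ <- sample(2:ifelse(K == 2, 12, 8), 1)
    pr <- rand_hmm_params(K)
    counts <- rpois(T_, sample(pr$lam, T_, replace = TRUE))
    hmm <- as_hmm(pr$lam, pr$A, pr$pi0)
    best <- brute_viterbi(counts, pr$lam, pr$A, pr$pi0)
    vit <- viterbi_decode(hmm, counts)
    expect_lt(score_path(best, counts, pr$lam, pr$A, pr$pi0) -
                score_path(vit, counts, pr$lam, pr$A, pr$pi0), 1e-8)
  }
})

test_that("Viterbi tie-breaks toward the lower state and handles the classics", {
  # sticky two-state example
  hmm <- as_hmm(c(0.5, 20), matrix(c(.99, .01, .01, .99), 2), c(.5, .5))
  counts <- c(0, 0, 25, 30, 0, 0)
  expect_equal(viterbi_decode(hmm, counts), c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_equal(viterbi_decode(hmm, counts),
               brute_viterbi(counts, hmm$lambda, hmm$A, hmm$pi0))
  # all-zero counts, ascending lambda, uniform rows: state 0 everywhere
  hmm2 <- as_hmm(c(1, 2), matrix(0.5, 2, 2), c(.5, .5))
  expect_equal(viterbi_decode(hmm2, rep(0, 6)), rep(0L, 6))
  # exact ties (equal rates) also resolve to state 0
  hmm3 <- as_hmm(c(2, 2), matrix(0.5, 2, 2), c(.5, .5))
  expect_equal(viterbi_decode(hmm3, rep(0, 6)), rep(0L, 6))
})

test_that("posteriors are normalised and match exhaustive summation", {
  set.seed(303)
  for (i in 1:25) {
    K <- sample(2:4, 1)
    pr <- rand_hmm_params(K)
    counts <- rpois(3, 5)
    hmm <- as_hmm(pr$lam, pr$A, pr$pi0)
    g <- posterior_decode(hmm, counts)
    expect_equal(rowSums(g), rep(1, 3), tolerance = 1e-9)
    expect_equal(g, brute_posterior(counts, pr$lam, pr$A, pr$pi0),
                 tolerance = 1e-8)
  }
  # identical rates: posteriors equal the chain occupancy, whatever the data
  A <- matrix(c(.9, .1, .3, .7), 2, byrow = TRUE)
  hmm_flat <- as_hmm(c(4, 4), A, c(.2, .8))
  g <- posterior_decode(hmm_flat, c(0, 9, 2, 5))
  occ <- c(.2, .8)
  for (t in 1:4) {
    expect_equal(g[t, ], occ, tolerance = 1e-9)
    occ <- as.numeric(occ %*% A)
  }
})

test_that("decoding a window_counts object keeps the grid structure", {
  panel <- shared_panel()
  grid <- window_grid(chrom_lengths(panel$gm), 1e4)
  wc <- window_het_counts(panel$gm, grid)
  fit <- fit_poisson_hmm(wc, K = 2)
  paths <- viterbi_decode(fit, wc)
  expect_s3_class(paths, "state_paths")
  expect_equal(dim(paths$states), dim(wc$counts))
  # per-line decoding agrees with decoding that line's sequences alone
  l1 <- wc$counts[1, wc$grid$chrom == "chr2"]
  expect_equal(unname(paths$states[1, wc$grid$chrom == "chr2"]),
               viterbi_decode(fit, as.numeric(l1)))
})

test_that("states_to_blocks run-length encodes and round-trips", {
  grid <- window_grid(c(chr1 = 50000), 1e4)
  b <- states_to_blocks(c(0L, 0L, 1L, 1L, 0L), grid)
  expect_equal(b$start, c(0, 20000, 40000))
  expect_equal(b$end, c(20000, 40000, 50000))
  expect_equal(b$state, c(0L, 1L, 0L))
  expect_equal(blocks_to_states(b, grid), c(0L, 0L, 1L, 1L, 0L))
  # single-state path gives one block per chromosome
  grid2 <- window_grid(c(chr1 = 20000, chr2 = 20000), 1e4)
  b2 <- states_to_blocks(rep(1L, 4), grid2)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n_windows, c(2L, 2L))
  # adjacent blocks always differ in state
  set.seed(9)
  st <- sample(0:1, 25, replace = TRUE)
  grid3 <- window_grid(c(chr1 = 250000), 1e4)
  b3 <- states_to_blocks(st, grid3)
  expect_true(all(diff(b3$state) != 0))
  expect_equal(blocks_to_states(b3, grid3), st)
})

test_that("homozygous_fraction aggregates spans and honours exclusions", {
  grid <- window_grid(c(chr1 = 20000, chr2 = 30000), 1e4)
  b <- states_to_blocks(c(1L, 1L, 0L, 0L, 0L), grid)
  expect_equal(unname(homozygous_fraction(b)), 3 / 5)
  expect_equal(unname(homozygous_fraction(b, exclude_chroms = "chr1")), 1)
  expect_error(homozygous_fraction(b, exclude_chroms = c("chr1", "chr2")),
               "excluded")
  ball <- states_to_blocks(rep(0L, 5), grid)
  expect_equal(unname(homozygous_fraction(ball)), 1)
})

test_that("model-object methods behave", {
  true <- as_hmm(c(1, 10), matrix(c(.95, .05, .2, .8), 2, byrow = TRUE),
                 c(.7, .3))
  sims <- simulate(true, nsim = 20, length_out = 100, seed = 5)
  expect_equal(length(sims), 20)
  expect_true(all(vapply(sims, function(s) all(s$counts >= 0), TRUE)))
  fit <- fit_poisson_hmm(lapply(sims, `[[`, "counts"), K = 2)
  co <- coef(fit)
  expect_named(co, c("lambda", "A", "pi0"))
  expect_equal(rowSums(co$A), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(co$pi0), 1, tolerance = 1e-9)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 1 + 2 + 2)
  expect_output(print(fit), "Poisson-emission HMM")
  expect_output(print(summary(fit)), "expected_dwell")
  v1 <- predict(fit, sims[[1]]$counts)
  expect_equal(v1, viterbi_decode(fit, sims[[1]]$counts))
  p1 <- predict(fit, sims[[1]]$counts, type = "posterior")
  expect_equal(dim(p1), c(100, 2))
  f <- tempfile()
  write_hmm_params(fit, f)
  expect_true(any(grepl("^lambda", readLines(f))))
})
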