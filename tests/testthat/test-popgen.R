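# F_ST, nucleotide diversity, LD decay, moment inbreeding coefficient and
# eta-squared heritability.

test_that("Hudson F_ST is 1 on fixed differences and unbiased at equality", {
  s <- site_fst_hudson(0, 1000, 1, 1000)
  expect_equal(s$num / s$den, 1, tolerance = 1e-2)
  # p1 = p2 = 0.5 with finite samples: expectation ~ 0 over replicates
  set.seed(21)
  n <- 20
  p1 <- rbinom(4000, n, 0.5) / n
  p2 <- rbinom(4000, n, 0.5) / n
  s2 <- site_fst_hudson(p1, n, p2, n)
  expect_lt(abs(mean(s2$num) / mean(s2$den)), 0.02)
})

test_that("splitting one panmictic pool gives genome-wide F_ST about zero", {
  set.seed(22)
  m <- 4000
  p <- runif(m, 0.05, 0.95)
  geno <- t(replicate(40, rbinom(m, 2, p)))
  storage.mode(geno) <- "integer"
  gm <- make_gm(geno, pos = sort(sample.int(4e6, m)),
                chrom_lengths = c(chr1 = 4e6))
  ids <- gm$sample_ids
  f1 <- allele_freqs(gm, ids[1:20])
  f2 <- allele_freqs(gm, ids[21:40])
  s <- site_fst_hudson(f1$p, f1$n, f2$p, f2$n)
  expect_lt(abs(sum(s$num) / sum(s$den)), 0.02)
})

test_that("windowed F_ST honours the SNP floor and matches a loop oracle", {
  set.seed(23)
  m <- 120
  geno <- rbind(t(replicate(6, rbinom(m, 2, 0.5))),
                t(replicate(6, rbinom(m, 2, 0.5))))
  storage.mode(geno) <- "integer"
  pos <- sort(sample.int(30000, m))
  gm <- make_gm(geno, pos = pos, chrom_lengths = c(chr1 = 30000))
  grid <- window_grid(c(chr1 = 30000), 1e4)
  ids <- gm$sample_ids
  fst <- windowed_fst(gm, grid, ids[1:6], ids[7:12], min_snps = 5)
  # independent loop over windows
  f1 <- allele_freqs(gm, ids[1:6]); f2 <- allele_freqs(gm, ids[7:12])
  comp <- site_fst_hudson(f1$p, f1$n, f2$p, f2$n)
  for (w in seq_len(nrow(grid))) {
    inw <- (pos - 1) >= grid$start[w] & (pos - 1) < grid$end[w] & comp$den > 0
    if (sum(inw) >= 5)
      expect_equal(fst$value[w], sum(comp$num[inw]) / sum(comp$den[inw]))
  }
  # a window of pure fixed differences has F_ST 1
  gfix <- make_gm(rbind(matrix(0L, 4, 60), matrix(2L, 4, 60)),
                  pos = sort(sample.int(9000, 60)),
                  chrom_lengths = c(chr1 = 10000))
  gridf <- window_grid(c(chr1 = 10000), 1e4)
  ids_f <- gfix$sample_ids
  vf <- windowed_fst(gfix, gridf, ids_f[1:4], ids_f[5:8], min_snps = 50)
  expect_equal(vf$value, 1, tolerance = 1e-2)
  expect_true(is.na(windowed_fst(gfix, gridf, ids_f[1:4], ids_f[5:8],
                                 min_snps = 61)$value))
})

test_that("nucleotide diversity reproduces the worked 0.002 example", {
  # one diploid (n = 2 alleles) heterozygous at 2 sites in a 1000-bp window
  gm <- make_gm(matrix(c(1L, 1L), 1), pos = c(100L, 600L),
                chrom_lengths = c(chr1 = 1000))
  grid <- window_grid(c(chr1 = 1000), 1000)
  expect_equal(nucleotide_diversity(gm, grid)$value, 0.002)
  # identical samples -> zero everywhere; empty window -> 0, not missing
  gm2 <- make_gm(rbind(c(0L, 2L), c(0L, 2L)), pos = c(100L, 600L),
                 chrom_lengths = c(chr1 = 2000))
  grid2 <- window_grid(c(chr1 = 2000), 1000)
  pw <- nucleotide_diversity(gm2, grid2)
  expect_equal(pw$value, c(0, 0))
})

test_that("pi, F_ST and r2 are invariant to swapping ref/alt labels", {
  set.seed(24)
  m <- 60
  geno <- t(replicate(10, rbinom(m, 2, runif(m, .2, .8))))
  storage.mode(geno) <- "integer"
  pos <- sort(sample.int(9000, m))
  gm <- make_gm(geno, pos = pos, chrom_lengths = c(chr1 = 10000))
  flip <- gm
  flip$geno <- 2L - gm$geno   # swap ref/alt at every site
  grid <- window_grid(c(chr1 = 10000), 1e4)
  expect_equal(nucleotide_diversity(flip, grid)$value,
               nucleotide_diversity(gm, grid)$value)
  ids <- gm$sample_ids
  expect_equal(windowed_fst(flip, grid, ids[1:5], ids[6:10], min_snps = 1)$value,
               windowed_fst(gm, grid, ids[1:5], ids[6:10], min_snps = 1)$value)
  expect_equal(ld_pairs_r2(flip, max_dist = 2000)$r2,
               ld_pairs_r2(gm, max_dist = 2000)$r2)
})

test_that("r2 basics: identity, sign invariance, independence baseline", {
  gm <- make_gm(cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L)),
                pos = c(10L, 20L, 30L))
  pr <- ld_pairs_r2(gm, max_dist = 100)
  expect_equal(pr$r2, rep(1, 3))
  expect_true(all(pr$pos_j > pr$pos_i))
  # independent sites: mean r2 ~ 1/(n-1)
  set.seed(25)
  n <- 30; m <- 200
  geno <- t(replicate(n, rbinom(m, 2, 0.5)))
  storage.mode(geno) <- "integer"
  gmi <- make_gm(geno, pos = sort(sample.int(9000, m)),
                 chrom_lengths = c(chr1 = 10000))
  pri <- ld_pairs_r2(gmi, max_dist = 1e4)
  expect_equal(mean(pri$r2), 1 / (n - 1), tolerance = 0.25)
  # zero-variance and low-overlap pairs are skipped with a tally
  gz <- make_gm(cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 1L), c(-1L, -1L, 2L, 1L)),
                pos = c(10L, 20L, 30L))
  pz <- ld_pairs_r2(gz, max_dist = 100, min_shared = 3)
  expect_gte(attr(pz, "n_skipped"), 2)
})

test_that("LD decay bins are left-closed and behave on edge cases", {
  pairs <- data.frame(chrom = "chr1", pos_i = 1L, pos_j = 151L,
                      dist = rep(150L, 5), r2 = c(.1, .2, .3, .4, .5))
  prof <- ld_decay_profile(pairs, bin_width = 100, max_dist = 1000)
  expect_equal(prof$bin_left_bp, seq(0, 900, 100))
  expect_equal(prof$mean_r2[2], 0.3)
  expect_true(all(is.na(prof$mean_r2[-2])))
  expect_equal(prof$n_pairs[2], 5)
  # perfect LD everywhere -> populated bins are all 1
  gm <- make_gm(matrix(rep(c(0L, 0L, 2L, 2L), 6), 4), pos = (1:6) * 120L)
  prof2 <- ld_decay_profile(ld_pairs_r2(gm, max_dist = 1000), 100, 1000)
  expect_true(all(abs(prof2$mean_r2[prof2$n_pairs > 0] - 1) < 1e-9))
})

test_that("LD decays with distance on a simulated inbred panel", {
  panel <- shared_panel()
  keep <- panel$gm$variants$chrom %in% c("chr2", "chr3")
  gm <- subset_geno(panel$gm, variants = which(keep))
  gm <- filter_variants(gm, min_maf = 0.10)
  pairs <- ld_pairs_r2(gm, max_dist = 1e4)
  prof <- ld_decay_profile(pairs, 100, 1e4)
  ok <- !is.na(prof$mean_r2)
  rho <- cor(prof$bin_left_bp[ok], prof$mean_r2[ok], method = "spearman")
  expect_lt(rho, 0)
})

test_that("moment inbreeding coefficient matches pedigree expectations", {
  # fully homozygous sample -> F = 1
  set.seed(26)
  m <- 500
  p <- runif(m, .2, .8)
  ref <- list(p = p, n = rep(100L, m))
  hom <- matrix(2L * rbinom(m, 1, p), 1)
  gm_hom <- make_gm(hom, pos = seq_len(m) * 10L)
  expect_equal(unname(inbreeding_coefficient_moment(gm_hom, ref)), 1,
               tolerance = 1e-9)
  # Hardy-Weinberg samples -> F ~ 0 on average
  hw <- t(replicate(60, rbinom(m, 2, p)))
  storage.mode(hw) <- "integer"
  gm_hw <- make_gm(hw, pos = seq_len(m) * 10L)
  f_hw <- inbreeding_coefficient_moment(gm_hw, ref)
  expect_lt(abs(mean(f_hw)), 0.03)
  # generation-9 full-sib lines vs true founder frequencies -> F ~ 0.859
  panel <- shared_panel()
  keep <- panel$gm$variants$chrom != "chr1"
  gm <- subset_geno(panel$gm, variants = which(keep))
  refp <- list(p = panel$founder_freqs$p[keep],
               n = rep(1e6, sum(keep)))   # population frequencies, not estimates
  fvals <- inbreeding_coefficient_moment(gm, refp)
  expect_equal(mean(fvals), wright_f(9)[9], tolerance = 0.03)
})

test_that("eta squared matches ANOVA and its sampling expectations", {
  expect_equal(eta_squared_heritability(c(1, 1, 3, 3), c("A", "A", "B", "B")), 1)
  expect_error(eta_squared_heritability(rep(2, 6), rep(c("A", "B"), 3)),
               "zero total variance")
  expect_error(eta_squared_heritability(1:5, rep("A", 5)), "2 groups")
  # equals the SS ratio from stats::lm/anova (independent route)
  set.seed(27)
  v <- rnorm(60); g <- sample(letters[1:6], 60, replace = TRUE)
  a <- anova(lm(v ~ g))
  expect_equal(eta_squared_heritability(v, g),
               a[["Sum Sq"]][1] / sum(a[["Sum Sq"]]))
  # permutation bias under no effect: mean eta^2 ~ (k-1)/(N-1)
  set.seed(28)
  N <- 50; k <- 5
  vv <- rnorm(N); gg <- rep(letters[1:k], each = N / k)
  e <- replicate(400, eta_squared_heritability(vv, sample(gg)))
  expect_lt(abs(mean(e) - (k - 1) / (N - 1)), 0.01)
  # variance components 2 vs 1 -> eta^2 ~ 2/3 at large N
  set.seed(291)
  nl <- 400; npl <- 100
  eff <- rnorm(nl, 0, sqrt(2))
  vals <- rep(eff, each = npl) + rnorm(nl * npl)
  expect_equal(eta_squared_heritability(vals, rep(seq_len(nl), each = npl)),
               2 / 3, tolerance = 0.05)
})

test_that("simulated trait heritability flows through the generator", {
  tr <- simulate_line_trait(sprintf("L%02d", 1:80), n_per_line = 10,
                            between_sd = sqrt(2), within_sd = 1, seed = 30)
  expect_equal(eta_squared_heritability(tr$value, tr$line), 2 / 3,
               tolerance = 0.08)
})
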