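# The inbreeding simulator: founder calibration, meiosis, pedigree truth,
# sex-region forcing, outcrosses and reproducibility.

test_that("founder diversity is calibrated to target_pi", {
  spec <- genome_spec(n_chrom = 4, chrom_length = 2e6, sex_region = NULL)
  cfg <- sim_config(n_founder_pairs = 20, target_pi = 0.0037, seed = 51)
  set.seed(51)
  fs <- simulate_founders(spec, cfg)
  # realised mean pairwise diversity across haplotypes
  pis <- vapply(fs$chrom, function(ch) {
    p <- colMeans(ch$haps)
    n <- nrow(ch$haps)
    sum(2 * p * (1 - p) * n / (n - 1)) / 2e6
  }, numeric(1))
  expect_equal(mean(pis), 0.0037, tolerance = 0.1)
  # target_pi = 0 -> monomorphic
  cfg0 <- sim_config(n_founder_pairs = 4, target_pi = 0, seed = 51)
  set.seed(51)
  fs0 <- simulate_founders(spec, cfg0)
  expect_true(all(vapply(fs0$chrom, function(ch) length(ch$pos) == 0, TRUE)))
  # insufficient user-supplied density errors with the required density
  cfgx <- sim_config(n_founder_pairs = 4, target_pi = 0.0037,
                     n_sites_per_mb = 100, seed = 51)
  expect_error(simulate_founders(spec, cfgx), "sites/Mb")
  # determinism
  set.seed(51); a <- simulate_founders(spec, cfg)
  set.seed(51); b <- simulate_founders(spec, cfg)
  expect_identical(a, b)
})

test_that("meiosis follows the Poisson/uniform crossover model", {
  h1 <- list(ends = 1e6, ids = 1L)
  h2 <- list(ends = 1e6, ids = 2L)
  # rate 0: the gamete is one whole parental haplotype
  set.seed(52)
  for (i in 1:10) {
    g <- meiosis(h1, h2, 1e6, 0)
    expect_length(g$crossovers, 0)
    expect_true(identical(g$gamete, h1) || identical(g$gamete, h2))
  }
  # crossover count: mean over 1e4 meioses within 3 SE of lambda
  set.seed(53)
  rate <- 50  # 0.5 Morgans over 1 Mb keeps the check sharp
  lam <- 1e6 / 1e6 * rate / 100
  ncx <- replicate(1e4, length(meiosis(h1, h2, 1e6, rate)$crossovers))
  expect_lt(abs(mean(ncx) - lam), 3 * sqrt(lam / 1e4))
  # crossover positions uniform (KS at alpha = 0.01)
  set.seed(54)
  cx <- unlist(replicate(3000, meiosis(h1, h2, 1e6, rate)$crossovers))
  expect_gt(ks.test(cx / 1e6, "punif")$p.value, 0.01)
  # the gamete tiles the chromosome
  set.seed(55)
  g <- meiosis(list(ends = c(3e5, 1e6), ids = c(1L, 3L)), h2, 1e6, 300)
  expect_equal(g$gamete$ends[length(g$gamete$ends)], 1e6)
  expect_true(all(diff(g$gamete$ends) > 0))
  expect_true(all(g$gamete$ids[-1] != head(g$gamete$ids, -1)))
})

test_that("the Wright recurrence gives the canonical values", {
  expect_equal(wright_f(9),
               c(0.25, 0.375, 0.5, 0.59375, 0.671875, 0.734375,
                 0.78515625, 0.826171875, 0.859375))
})

test_that("single-generation inbreeding yields about 25% autozygosity", {
  spec <- genome_spec(n_chrom = 6, sex_region = NULL)
  set.seed(56)
  fr <- vapply(1:400, function(i) inbreed_line(1, 1, spec)$autozygous_fraction,
               numeric(1))
  expect_lt(abs(mean(fr) - 0.25), 0.03)
})

test_that("truth segments tile the genome and agree with point sampling", {
  spec <- genome_spec(n_chrom = 3, sex_region = NULL)
  set.seed(57)
  line <- inbreed_line(2, 9, spec)
  seg <- line$segments
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], 1e6)
    if (nrow(s) > 1) expect_equal(s$start[-1], head(s$end, -1))
  }
  # independent estimate: classify a dense point grid by interval lookup
  pts_frac <- mean(vapply(unique(seg$chrom), function(ch) {
    s <- seg[seg$chrom == ch, ]
    x <- seq(0.5, 1e6 - 0.5, length.out = 20000)
    i <- findInterval(x, s$end) + 1
    mean(s$mat_id[i] == s$pat_id[i])
  }, numeric(1)))
  expect_equal(pts_frac, line$autozygous_fraction, tolerance = 1e-3)
  # founder-haplotype ids stay inside the family's id block
  expect_true(all(seg$mat_id %in% (4 * 2 - 3):(4 * 2)))
  expect_true(all(seg$pat_id %in% (4 * 2 - 3):(4 * 2)))
})

test_that("the sex region is forced heterozygous in sampled males", {
  panel <- shared_panel()
  sr <- panel$spec$sex_region
  seg <- panel$truth$segments
  insr <- seg$chrom == sr$chrom & seg$start < sr$end & seg$end > sr$start
  expect_true(all(seg$mat_id[insr] != seg$pat_id[insr]))
  # and the genotype-level heterozygosity is elevated there
  grid <- window_grid(chrom_lengths(panel$gm), 1e4)
  wc <- window_het_counts(panel$gm, grid)
  sex_w <- wc$grid$chrom == sr$chrom & wc$grid$start >= sr$start &
    wc$grid$end <= sr$end
  expect_gt(mean(wc$counts[, sex_w]), 10)
})

test_that("outcrosses reset autozygosity per the recurrence restart", {
  spec <- genome_spec(n_chrom = 8, sex_region = NULL)
  cfg <- sim_config(n_founder_pairs = 20, lines_per_family = 1,
                    generations = 9, outcross_prob = 1,
                    outcross_generation = 5, genotype_error_rate = 0,
                    seed = 58)
  panel <- simulate_panel(spec, cfg)
  # an outcross at generation 5 leaves 4 sib generations: F ~ F_4 = 0.59375
  expect_true(all(panel$truth$summary$outcrossed))
  expect_lt(abs(mean(panel$truth$summary$autozygous_fraction) -
                  wright_f(4)[4]), 0.1)
  # well below the non-outcrossed expectation
  expect_lt(mean(panel$truth$summary$autozygous_fraction), 0.75)
})

test_that("simulated panels are reproducible and round-trip through VCF", {
  spec <- genome_spec(n_chrom = 2, chrom_length = 3e5,
                      sex_region = list(chrom = "chr1", start = 1e5,
                                        end = 1.5e5))
  cfg <- sim_config(n_founder_pairs = 3, lines_per_family = 2,
                    generations = 4, outcross_prob = 0, seed = 59)
  p1 <- simulate_panel(spec, cfg)
  p2 <- simulate_panel(spec, cfg)
  expect_identical(p1$gm$geno, p2$gm$geno)
  expect_identical(p1$truth$summary, p2$truth$summary)
  d <- tempfile()
  write_sim_panel(p1, d)
  gm <- read_vcf(file.path(d, "panel.vcf"))
  expect_equal(unname(gm$geno), unname(p1$gm$geno))
  expect_equal(gm$sample_ids, p1$gm$sample_ids)
  sib <- read_tsv_table(file.path(d, "sibling_pairs.tsv"))
  expect_equal(nrow(sib), 3)
  expect_true(all(table(c(sib$line_a, sib$line_b)) == 1))
})

test_that("het counts separate the two emission regimes the HMM needs", {
  panel <- shared_panel()
  grid <- window_grid(chrom_lengths(panel$gm), 1e4)
  wc <- window_het_counts(panel$gm, grid)
  seg <- panel$truth$segments
  l <- panel$gm$sample_ids[1]
  s <- seg[seg$line == l & seg$chrom == "chr2", ]
  w2 <- which(wc$grid$chrom == "chr2")
  mids <- (wc$grid$start[w2] + wc$grid$end[w2]) / 2
  auto <- s$mat_id[findInterval(mids, s$end) + 1] ==
    s$pat_id[findInterval(mids, s$end) + 1]
  cnt <- wc$counts[l, w2]
  if (any(auto)) expect_lt(mean(cnt[auto]), 2)
  if (any(!auto)) expect_gt(mean(cnt[!auto]), 15)
})
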