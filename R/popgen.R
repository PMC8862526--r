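# Windowed and per-site population-genetic statistics: Hudson's F_ST,
# nucleotide diversity, LD decay, the moment inbreeding coefficient and
# eta-squared broad-sense heritability.

#' Alternate-allele frequencies and allele sample sizes
#'
#' @param gm a [geno_matrix()].
#' @param samples optional subset of samples defining the population.
#' @return list with `p` (alt-allele frequency, NA where no genotypes) and
#'   `n` (non-missing allele count, diploid so always even).
#' @export
allele_freqs <- function(gm, samples = NULL) {
  g <- if (is.null(samples)) gm$geno else
    gm$geno[match(samples, gm$sample_ids), , drop = FALSE]
  if (anyNA(g)) stop("unknown sample name(s)")
  nonmiss <- colSums(g != -1L)
  dos <- g
  dos[dos == -1L] <- 0L
  n <- 2L * nonmiss
  p <- ifelse(n > 0, colSums(dos) / n, NA_real_)
  list(p = p, n = n)
}

#' Per-site components of Hudson's F_ST estimator
#'
#' Returns the numerator and denominator of the Hudson (1992) estimator so
#' windows can be aggregated as a ratio of averages. Sites monomorphic in
#' both populations have zero denominator and are excluded downstream.
#'
#' @param p1,p2 alt- (or derived-) allele frequencies in the two populations.
#' @param n1,n2 allele sample sizes (>= 2).
#' @return data.frame with `num` and `den`.
#' @export
site_fst_hudson <- function(p1, n1, p2, n2) {
  stopifnot(all(n1 >= 2, na.rm = TRUE), all(n2 >= 2, na.rm = TRUE))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = num, den = den)
}

#' Windowed F_ST between two populations
#'
#' Hudson per-site components aggregated per window. The default is the
#' ratio of summed numerators to summed denominators (robust at low
#' per-site information); `method = "mean_of_ratios"` averages per-site
#' ratios instead.
#'
#' @param gm a [geno_matrix()].
#' @param grid a [window_grid()] (10-kb windows in the reference analysis).
#' @param pop1,pop2 character vectors of sample ids.
#' @param min_snps windows with fewer usable SNPs are reported missing.
#' @param method aggregation rule.
#' @return data.frame (class `window_stat`): chrom, start, end, value,
#'   n_snps, log10_n_snps.
#' @export
windowed_fst <- function(gm, grid, pop1, pop2, min_snps = 50L,
                         method = c("ratio_of_averages", "mean_of_ratios")) {
  method <- match.arg(method)
  f1 <- allele_freqs(gm, pop1)
  f2 <- allele_freqs(gm, pop2)
  usable <- f1$n >= 2 & f2$n >= 2
  comp <- site_fst_hudson(f1$p, f1$n, f2$p, f2$n)
  usable <- usable & !is.na(comp$den) & comp$den > 0
  w <- window_index(grid, gm$variants$chrom, gm$variants$pos)
  nw <- nrow(grid)
  n_snps <- tabulate(w[usable], nbins = nw)
  if (method == "ratio_of_averages") {
    num <- rowsum(comp$num[usable], w[usable])
    den <- rowsum(comp$den[usable], w[usable])
    value <- rep(NA_real_, nw)
    value[as.integer(rownames(num))] <- num / den
  } else {
    ratio <- comp$num[usable] / comp$den[usable]
    m <- rowsum(ratio, w[usable])
    value <- rep(NA_real_, nw)
    value[as.integer(rownames(m))] <- m / n_snps[as.integer(rownames(m))]
  }
  value[n_snps < min_snps] <- NA_real_
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    value = value, n_snps = n_snps,
                    log10_n_snps = log10(pmax(n_snps, 1)))
  class(out) <- c("window_stat", "data.frame")
  out
}

#' Windowed nucleotide diversity
#'
#' Per-site unbiased heterozygosity `2 p q n/(n-1)` summed over the SNPs of
#' each window and divided by the full window span (VCF-only input carries
#' no accessibility mask, so monomorphic and unsequenced positions
#' contribute zero). Windows with no genotyped site have value 0.
#'
#' @param gm a [geno_matrix()].
#' @param grid a [window_grid()] (500-kb windows in the reference analysis).
#' @param samples optional population subset.
#' @return data.frame (class `window_stat`): chrom, start, end, value,
#'   n_snps.
#' @export
nucleotide_diversity <- function(gm, grid, samples = NULL) {
  f <- allele_freqs(gm, samples)
  usable <- f$n >= 2
  hs <- ifelse(usable, 2 * f$p * (1 - f$p) * f$n / (f$n - 1), 0)
  w <- window_index(grid, gm$variants$chrom, gm$variants$pos)
  nw <- nrow(grid)
  tot <- rep(0, nw)
  s <- rowsum(hs, w)
  tot[as.integer(rownames(s))] <- s
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    value = tot / (grid$end - grid$start),
                    n_snps = tabulate(w[usable & hs > 0], nbins = nw))
  class(out) <- c("window_stat", "data.frame")
  out
}

#' Write a window statistic as TSV
#'
#' @param ws a `window_stat` data.frame.
#' @param path output file.
#' @export
write_window_stat <- function(ws, path) write_tsv_table(as.data.frame(ws), path)

#' Pairwise r-squared within a distance limit
#'
#' Squared Pearson correlation of genotype dosages over samples non-missing
#' at both sites (composite LD; appropriate for unphased, largely homozygous
#' inbred lines). Pairs with fewer than `min_shared` shared samples or zero
#' variance at either site are skipped (tallied in the `n_skipped`
#' attribute). Apply [filter_variants()] (e.g. MAF > 0.10) first.
#'
#' @param gm a filtered [geno_matrix()].
#' @param max_dist maximum pair distance in bp.
#' @param min_shared minimum co-non-missing samples.
#' @return data.frame: chrom, pos_i, pos_j (1-based), dist, r2.
#' @export
ld_pairs_r2 <- function(gm, max_dist = 1e4, min_shared = 3L) {
  res <- list()
  n_skipped <- 0L
  for (ch in unique(gm$variants$chrom)) {
    vi <- which(gm$variants$chrom == ch)
    pos <- gm$variants$pos[vi]
    D <- gm$geno[, vi, drop = FALSE]
    storage.mode(D) <- "double"
    D[D == -1] <- NA
    m <- length(pos)
    if (m < 2) next
    has_na <- anyNA(D)
    if (!has_na) {
      sd0 <- apply(D, 2, stats::sd)
      Z <- scale(D)
    }
    for (i in seq_len(m - 1)) {
      jmax <- i
      while (jmax < m && pos[jmax + 1] - pos[i] <= max_dist) jmax <- jmax + 1
      if (jmax == i) next
      js <- (i + 1):jmax
      if (!has_na) {
        ok <- sd0[i] > 0 & sd0[js] > 0
        n_skipped <- n_skipped + sum(!ok)
        js <- js[ok]
        if (!length(js)) next
        r <- crossprod(Z[, i], Z[, js, drop = FALSE]) / (nrow(D) - 1)
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, pos_i = pos[i], pos_j = pos[js],
          dist = pos[js] - pos[i], r2 = as.numeric(r)^2)
      } else {
        xi <- D[, i]
        for (j in js) {
          okv <- !is.na(xi) & !is.na(D[, j])
          if (sum(okv) < min_shared) { n_skipped <- n_skipped + 1L; next }
          x <- xi[okv]; y <- D[okv, j]
          if (stats::sd(x) == 0 || stats::sd(y) == 0) { n_skipped <- n_skipped + 1L; next }
          res[[length(res) + 1L]] <- data.frame(
            chrom = ch, pos_i = pos[i], pos_j = pos[j],
            dist = pos[j] - pos[i], r2 = stats::cor(x, y)^2)
        }
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), pos_i = integer(), pos_j = integer(),
               dist = integer(), r2 = numeric())
  attr(out, "n_skipped") <- n_skipped
  out
}

#' LD decay profile: mean r-squared per distance bin
#'
#' Bin `b` covers distances `[bin_width * b, bin_width * (b + 1))`; bins
#' with no pairs are reported missing.
#'
#' @param pairs output of [ld_pairs_r2()].
#' @param bin_width bin width in bp.
#' @param max_dist profile limit in bp.
#' @return data.frame: bin_left_bp, mean_r2, n_pairs.
#' @export
ld_decay_profile <- function(pairs, bin_width = 100L, max_dist = 1e4) {
  lefts <- seq(0, max_dist - 1, by = bin_width)
  bin <- pmin(pairs$dist %/% bin_width, length(lefts) - 1L)
  bin <- bin[pairs$dist <= max_dist]
  r2 <- pairs$r2[pairs$dist <= max_dist]
  mean_r2 <- rep(NA_real_, length(lefts))
  n_pairs <- rep(0L, length(lefts))
  if (length(bin)) {
    agg <- rowsum(cbind(r2, 1), bin)
    idx <- as.integer(rownames(agg)) + 1L
    mean_r2[idx] <- agg[, 1] / agg[, 2]
    n_pairs[idx] <- agg[, 2]
  }
  data.frame(bin_left_bp = lefts, mean_r2 = mean_r2, n_pairs = n_pairs)
}

#' Moment estimator of the inbreeding coefficient
#'
#' PLINK-style method-of-moments F per sample: observed versus expected
#' homozygote counts under Hardy-Weinberg at supplied reference allele
#' frequencies, `F = (O_hom - E_hom) / (L - E_hom)` over the sample's
#' non-missing sites.
#'
#' @param gm a [geno_matrix()].
#' @param reference_freqs list with `p` and `n` per variant (e.g. from
#'   [allele_freqs()] on a founder population or the pooled sample).
#' @return named numeric vector of F, NA where undefined (`L = E_hom`).
#' @export
inbreeding_coefficient_moment <- function(gm, reference_freqs) {
  p <- reference_freqs$p
  n <- reference_freqs$n
  stopifnot(length(p) == ncol(gm$geno), length(n) == ncol(gm$geno))
  site_ok <- !is.na(p) & n >= 2
  e_site <- ifelse(site_ok, 1 - 2 * p * (1 - p) * n / (n - 1), NA_real_)
  out <- vapply(seq_along(gm$sample_ids), function(i) {
    g <- gm$geno[i, ]
    use <- g != -1L & site_ok
    L <- sum(use)
    if (L == 0) return(NA_real_)
    O <- sum(g[use] != 1L)
    E <- sum(e_site[use])
    if (abs(L - E) < 1e-12) return(NA_real_)
    (O - E) / (L - E)
  }, numeric(1))
  names(out) <- gm$sample_ids
  out
}

#' Broad-sense heritability proxy from one-way ANOVA (eta squared)
#'
#' `eta^2 = SS_between / SS_total` across line labels; in a clonal or
#' near-isogenic panel this effect size is read as broad-sense heritability
#' (H^2). No small-sample correction is applied.
#'
#' @param values numeric trait values, one per individual.
#' @param groups line labels.
#' @return eta squared in [0, 1].
#' @export
eta_squared_heritability <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (!any(tab >= 2)) stop("need at least one group with 2 or more values")
  gm_mean <- mean(values)
  ss_total <- sum((values - gm_mean)^2)
  if (ss_total <= 0) stop("zero total variance")
  grp_means <- tapply(values, groups, mean)
  ss_between <- sum(tab * (grp_means[names(tab)] - gm_mean)^2)
  unname(ss_between / ss_total)
}
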