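# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately use naive enumeration/loops, not the
# package's own code paths.

# exhaustive-path Viterbi: argmax over all K^T state paths
brute_viterbi <- function(counts, lam, A, pi0) {
  K <- length(lam); T_ <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logE <- sapply(seq_len(K), function(k) dpois(counts, lam[k], log = TRUE))
  logE <- matrix(logE, nrow = T_)
  sc <- log(pi0)[paths[, 1]]
  for (t in seq_len(T_)) sc <- sc + logE[t, ][paths[, t]]
  if (T_ > 1) {
    lA <- log(A)
    for (t in 2:T_) sc <- sc + lA[cbind(paths[, t - 1], paths[, t])]
  }
  as.integer(paths[which.max(sc), ]) - 1L
}

# exhaustive-path posteriors: sum path weights per (t, state)
brute_posterior <- function(counts, lam, A, pi0) {
  K <- length(lam); T_ <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logE <- matrix(sapply(seq_len(K), function(k) dpois(counts, lam[k], log = TRUE)),
                 nrow = T_)
  sc <- log(pi0)[paths[, 1]]
  for (t in seq_len(T_)) sc <- sc + logE[t, ][paths[, t]]
  if (T_ > 1) {
    lA <- log(A)
    for (t in 2:T_) sc <- sc + lA[cbind(paths[, t - 1], paths[, t])]
  }
  w <- exp(sc - max(sc)); w <- w / sum(w)
  g <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K)) g[t, k] <- sum(w[paths[, t] == k])
  g
}

# log joint probability of one state path (0-based states)
score_path <- function(path, counts, lam, A, pi0) {
  s <- path + 1L
  sc <- log(pi0)[s[1]] + sum(dpois(counts, lam[s], log = TRUE))
  if (length(s) > 1) sc <- sc + sum(log(A)[cbind(head(s, -1), s[-1])])
  sc
}

rand_hmm_params <- function(K) {
  lam <- sort(runif(K, 0.2, 25))
  A <- matrix(runif(K * K, 0.05, 1), K); A <- A / rowSums(A)
  pi0 <- runif(K, 0.05, 1); pi0 <- pi0 / sum(pi0)
  list(lam = lam, A = A, pi0 = pi0)
}

as_hmm <- function(lam, A, pi0) {
  structure(list(K = length(lam), lambda = lam, A = A, pi0 = pi0,
                 use_exposure = FALSE), class = "poisson_hmm")
}

# naive per-window tally of heterozygous / genotyped sites
brute_het_counts <- function(gm, grid) {
  nl <- length(gm$sample_ids); nw <- nrow(grid)
  counts <- matrix(0L, nl, nw); n_sites <- matrix(0L, nl, nw)
  for (w in seq_len(nw)) {
    inw <- gm$variants$chrom == grid$chrom[w] &
      (gm$variants$pos - 1) >= grid$start[w] &
      (gm$variants$pos - 1) < grid$end[w]
    for (l in seq_len(nl)) {
      g <- gm$geno[l, inw]
      counts[l, w] <- sum(g == 1L)
      n_sites[l, w] <- sum(g != -1L)
    }
  }
  list(counts = counts, n_sites = n_sites)
}

# naive pairwise IBS
brute_ibs <- function(gm) {
  n <- length(gm$sample_ids)
  m <- matrix(NA_real_, n, n); diag(m) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- gm$geno[i, ]; b <- gm$geno[j, ]
    ok <- a != -1L & b != -1L
    if (any(ok)) m[i, j] <- m[j, i] <- mean((2 - abs(a[ok] - b[ok])) / 2)
  }
  dimnames(m) <- list(gm$sample_ids, gm$sample_ids)
  m
}

# quick geno_matrix builder: geno is samples x variants
make_gm <- function(geno, chrom = "chr1", pos = NULL, ref = NULL, alt = NULL,
                    sample_ids = NULL, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 10L
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(geno)))
  geno_matrix(geno, chrom, pos, ref, alt, sample_ids = sample_ids,
              chrom_lengths = chrom_lengths)
}

write_test_vcf <- function(path, lines) {
  writeLines(lines, path)
  path
}

jaccard_interval <- function(a1, b1, a2, b2) {
  inter <- max(0, min(b1, b2) - max(a1, a2))
  inter / ((b1 - a1) + (b2 - a2) - inter)
}

# one moderately sized simulated panel shared by several test files
.panel_cache <- new.env(parent = emptyenv())
shared_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    spec <- genome_spec()   # 24 x 1 Mb, sex region chr1:450-550 kb
    cfg <- sim_config(n_founder_pairs = 15, lines_per_family = 2,
                      generations = 9, outcross_prob = 0, seed = 42)
    .panel_cache$panel <- simulate_panel(spec, cfg)
  }
  .panel_cache$panel
}
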