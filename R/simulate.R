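# Full-sib inbreeding genome simulator.
#
# Founder haplotypes are drawn from a neutral folded site-frequency spectrum
# calibrated to a target per-site nucleotide diversity; pedigrees then
# gene-drop founder-haplotype ancestry through G generations of single
# full-sibling-pair matings with Poisson recombination (no interference, no
# new mutation), so the autozygosity ground truth is exact. Genotypes are
# realised from ancestry segments only at the end, which keeps the pedigree
# stage cheap and the truth independent of allele sampling.

#' Describe a simulated genome
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length in bp (scalar or per-chromosome vector). The
#'   default desk-scale genome is 24 x 1 Mb.
#' @param recomb_rate cM/Mb (scalar or per-chromosome); 3 cM/Mb gives about
#'   0.03 expected crossovers per 1-Mb chromosome per meiosis.
#' @param chrom_names chromosome names.
#' @param sex_region optional list(chrom, start, end) (0-based half-open)
#'   kept obligately heterozygous in sampled males; `NULL` disables it.
#' @return object of class `genome_spec`: list with `chroms` (data.frame
#'   chrom/length/rate) and `sex_region`.
#' @export
genome_spec <- function(n_chrom = 24, chrom_length = 1e6, recomb_rate = 3,
                        chrom_names = paste0("chr", seq_len(n_chrom)),
                        sex_region = list(chrom = "chr1", start = 450000,
                                          end = 550000)) {
  chroms <- data.frame(chrom = chrom_names,
                       length = rep_len(chrom_length, n_chrom),
                       rate = rep_len(recomb_rate, n_chrom),
                       stringsAsFactors = FALSE)
  stopifnot(all(chroms$length > 0), all(chroms$rate >= 0))
  if (!is.null(sex_region)) {
    i <- match(sex_region$chrom, chroms$chrom)
    if (is.na(i)) stop("sex_region chromosome not in genome")
    stopifnot(sex_region$start >= 0, sex_region$end <= chroms$length[i],
              sex_region$end > sex_region$start)
  }
  structure(list(chroms = chroms, sex_region = sex_region),
            class = "genome_spec")
}

#' Simulation configuration
#'
#' @param n_founder_pairs wild founder pairs (one family each).
#' @param lines_per_family inbred lines initiated per founder family (2
#'   produces sibling-line pairs).
#' @param generations G generations of single full-sib-pair inbreeding.
#' @param target_pi founder per-site nucleotide diversity (0.0037 emulates a
#'   diverse wild population).
#' @param n_sites_per_mb optional segregating-site density; by default it is
#'   calibrated so the expected per-site heterozygosity equals `target_pi`.
#' @param outcross_prob probability a line suffers one accidental
#'   mid-pedigree outcross to an unrelated line.
#' @param outcross_generation generation at which outcrosses happen
#'   (default: uniform between 2 and G - 1).
#' @param genotype_error_rate per-genotype error probability.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_founder_pairs = 40, lines_per_family = 2,
                       generations = 9, target_pi = 0.0037,
                       n_sites_per_mb = NULL, outcross_prob = 0.05,
                       outcross_generation = NULL,
                       genotype_error_rate = 0.001, seed = 1) {
  stopifnot(generations >= 1, n_founder_pairs >= 1, lines_per_family >= 1,
            target_pi >= 0, target_pi < 0.05,
            outcross_prob >= 0, outcross_prob <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1)
  structure(list(n_founder_pairs = n_founder_pairs,
                 lines_per_family = lines_per_family,
                 generations = generations, target_pi = target_pi,
                 n_sites_per_mb = n_sites_per_mb,
                 outcross_prob = outcross_prob,
                 outcross_generation = outcross_generation,
                 genotype_error_rate = genotype_error_rate, seed = seed),
            class = "sim_config")
}

#' Wright's full-sib inbreeding coefficient recurrence
#'
#' `F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4` with `F_0 = F_{-1} = 0`: the
#' expected autozygous genome fraction after t generations of single
#' full-sibling-pair mating (0.25, 0.375, ..., 0.859375 at t = 9).
#'
#' @param generations number of generations.
#' @return numeric vector `F_1 ... F_G`.
#' @export
wright_f <- function(generations) {
  f <- numeric(generations + 2)   # f[1] = F_{-1}, f[2] = F_0
  for (t in seq_len(generations)) f[t + 2] <- (1 + 2 * f[t + 1] + f[t]) / 4
  f[-(1:2)]
}

# expected per-site heterozygosity 2q(1-q) under the neutral SFS (density
# proportional to 1/i) on a pool of n_hap haplotypes
.sfs_het_mean <- function(n_hap) {
  i <- seq_len(n_hap - 1)
  w <- 1 / i
  q <- i / n_hap
  sum(w * 2 * q * (1 - q)) / sum(w)
}

.draw_sfs_freqs <- function(n_sites, n_hap) {
  i <- seq_len(n_hap - 1)
  sample(i, n_sites, replace = TRUE, prob = 1 / i) / n_hap
}

#' Simulate founder haplotypes
#'
#' Four haplotypes per founder pair. Segregating sites are placed uniformly;
#' derived-allele frequencies are drawn from the neutral SFS and the site
#' density calibrated so the expected per-site heterozygosity between two
#' random haplotypes matches `target_pi`. The reference allele is the true
#' ancestral allele and is recorded as such.
#'
#' @param spec a [genome_spec()].
#' @param cfg a [sim_config()]; `cfg$seed` is NOT applied here (callers own
#'   the RNG stream) — call `set.seed()` first for standalone use.
#' @param chroms optional subset of chromosome names (memory control).
#' @return object of class `founder_set`: per-chromosome list with `pos`,
#'   `q`, `ref`, `alt`, `haps` (n_hap x n_sites 0/1 matrix); plus `n_hap`.
#' @export
simulate_founders <- function(spec, cfg, chroms = NULL) {
  n_hap <- 4L * cfg$n_founder_pairs
  e2pq <- if (n_hap >= 2) .sfs_het_mean(max(n_hap, 4L)) else 0.5
  sel <- spec$chroms
  if (!is.null(chroms)) sel <- sel[sel$chrom %in% chroms, , drop = FALSE]
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(sel))) {
    L <- sel$length[i]
    n_req <- round(cfg$target_pi * L / e2pq)
    if (is.null(cfg$n_sites_per_mb)) {
      n_sites <- n_req
      p_poly <- 1
    } else {
      n_sites <- round(cfg$n_sites_per_mb * L / 1e6)
      if (n_sites < n_req)
        stop("target_pi ", cfg$target_pi, " unachievable at ",
             cfg$n_sites_per_mb, " sites/Mb; need at least ",
             ceiling(n_req * 1e6 / L), " sites/Mb")
      p_poly <- n_req / n_sites
    }
    if (n_sites == 0) {
      out[[sel$chrom[i]]] <- list(pos = integer(), q = numeric(),
                                  ref = character(), alt = character(),
                                  haps = matrix(0L, n_hap, 0))
      next
    }
    pos <- sort(sample.int(L, n_sites))
    q <- .draw_sfs_freqs(n_sites, max(n_hap, 4L))
    if (p_poly < 1) q <- q * stats::rbinom(n_sites, 1, p_poly)
    haps <- matrix(stats::rbinom(n_hap * n_sites, 1L, rep(q, each = n_hap)),
                   n_hap, n_sites)
    storage.mode(haps) <- "integer"
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    out[[sel$chrom[i]]] <- list(pos = pos, q = q, ref = ref,
                                alt = unname(alt), haps = haps)
  }
  structure(list(chrom = out, n_hap = n_hap), class = "founder_set")
}

# ---- haplotype-segment machinery -------------------------------------------
# A haplotype is list(ends, ids): founder-haplotype id per segment, segments
# covering (0, L] with cumulative end positions.

.hap_slice <- function(h, from, to) {
  i1 <- sum(h$ends <= from) + 1L
  i2 <- sum(h$ends < to) + 1L
  ids <- h$ids[i1:i2]
  ends <- c(if (i2 > i1) h$ends[i1:(i2 - 1L)], to)
  list(ends = ends, ids = ids)
}

.hap_merge <- function(ends, ids) {
  r <- rle(ids)
  list(ends = ends[cumsum(r$lengths)], ids = r$values)
}

.hap_id_at <- function(h, x) {
  h$ids[findInterval(x, h$ends, left.open = TRUE) + 1L]
}

#' One meiosis: recombine a parental haplotype pair into a gamete
#'
#' Crossover count is Poisson with mean `length/1e6 * rate/100` (Morgans),
#' positions uniform, no interference; the gamete is the alternating mosaic
#' of the two parental haplotypes starting from a random one.
#'
#' @param h1,h2 parental haplotypes: lists with `ends` (cumulative segment
#'   end positions, last = chromosome length) and `ids` (founder-haplotype
#'   id per segment).
#' @param length chromosome length in bp.
#' @param rate recombination rate in cM/Mb.
#' @return list with `gamete` (a haplotype) and `crossovers` (positions).
#' @export
meiosis <- function(h1, h2, length, rate) {
  stopifnot(rate >= 0)
  ncx <- stats::rpois(1, length / 1e6 * rate / 100)
  first <- sample.int(2L, 1)
  if (ncx == 0) {
    return(list(gamete = if (first == 1L) h1 else h2, crossovers = numeric()))
  }
  cx <- sort(stats::runif(ncx, 0, length))
  bounds <- c(cx, length)
  haps <- list(h1, h2)
  cur <- first
  ends <- numeric(0); ids <- integer(0)
  from <- 0
  for (b in bounds) {
    if (b > from) {
      piece <- .hap_slice(haps[[cur]], from, b)
      ends <- c(ends, piece$ends); ids <- c(ids, piece$ids)
      from <- b
    }
    cur <- 3L - cur
  }
  list(gamete = .hap_merge(ends, ids), crossovers = cx)
}

.founder_individual <- function(spec, id_m, id_p) {
  lapply(seq_len(nrow(spec$chroms)), function(i) {
    L <- spec$chroms$length[i]
    list(m = list(ends = L, ids = id_m), p = list(ends = L, ids = id_p))
  })
}

.child <- function(mother, father, spec) {
  lapply(seq_len(nrow(spec$chroms)), function(i) {
    L <- spec$chroms$length[i]; r <- spec$chroms$rate[i]
    list(m = meiosis(mother[[i]]$m, mother[[i]]$p, L, r)$gamete,
         p = meiosis(father[[i]]$m, father[[i]]$p, L, r)$gamete)
  })
}

# overlay maternal and paternal segment lists into truth segments
.overlay_segments <- function(ind, spec) {
  pieces <- lapply(seq_len(nrow(spec$chroms)), function(i) {
    m <- ind[[i]]$m; p <- ind[[i]]$p
    ends <- sort(unique(c(m$ends, p$ends)))
    starts <- c(0, utils::head(ends, -1))
    mid <- (starts + ends) / 2
    data.frame(chrom = spec$chroms$chrom[i], start = starts, end = ends,
               mat_id = .hap_id_at(m, mid), pat_id = .hap_id_at(p, mid),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

.autozygous_fraction <- function(segments) {
  sum((segments$end - segments$start) * (segments$mat_id == segments$pat_id)) /
    sum(segments$end - segments$start)
}

.hap_set_region <- function(h, from, to, id, L) {
  parts_ends <- numeric(0); parts_ids <- integer(0)
  if (from > 0) {
    s <- .hap_slice(h, 0, from)
    parts_ends <- s$ends; parts_ids <- s$ids
  }
  parts_ends <- c(parts_ends, to); parts_ids <- c(parts_ids, id)
  if (to < L) {
    s <- .hap_slice(h, to, L)
    parts_ends <- c(parts_ends, s$ends); parts_ids <- c(parts_ids, s$ids)
  }
  .hap_merge(parts_ends, parts_ids)
}

.force_sex_region <- function(ind, spec, family) {
  sr <- spec$sex_region
  if (is.null(sr)) return(ind)
  ci <- match(sr$chrom, spec$chroms$chrom)
  L <- spec$chroms$length[ci]
  y_id <- (family - 1L) * 4L + 4L
  x_id <- (family - 1L) * 4L + 3L
  ind[[ci]]$p <- .hap_set_region(ind[[ci]]$p, sr$start, sr$end, y_id, L)
  # the maternal haplotype can never carry the Y-tagged segment
  mids <- .hap_slice(ind[[ci]]$m, max(sr$start, 0), sr$end)
  if (any(mids$ids == y_id)) {
    m <- ind[[ci]]$m
    pe <- numeric(0); pi_ <- integer(0)
    if (sr$start > 0) { s <- .hap_slice(m, 0, sr$start); pe <- s$ends; pi_ <- s$ids }
    mid <- .hap_slice(m, sr$start, sr$end)
    mid$ids[mid$ids == y_id] <- x_id
    pe <- c(pe, mid$ends); pi_ <- c(pi_, mid$ids)
    if (sr$end < L) { s <- .hap_slice(m, sr$end, L); pe <- c(pe, s$ends); pi_ <- c(pi_, s$ids) }
    ind[[ci]]$m <- .hap_merge(pe, pi_)
  }
  ind
}

#' Inbreed one line by single full-sib-pair matings
#'
#' Starts from two F1 siblings of a founder pair; each generation the
#' current brother-sister pair produces two offspring by independent
#' meioses, which become the next generation's parents. After G generations
#' one (male) individual is sampled; if the genome has a sex region, his
#' paternal haplotype is set to the family's Y-tagged founder haplotype
#' across it, keeping the region obligately heterozygous.
#'
#' Operates purely on founder-haplotype ancestry (no alleles), so the
#' returned truth is exact. Callers own the RNG stream (`set.seed()` first).
#'
#' @param family founder-family index (haplotype ids `4*family-3 ...
#'   4*family`).
#' @param generations G >= 1.
#' @param spec a [genome_spec()].
#' @param outcross optional list(generation, donor): at that generation the
#'   second parent is replaced by the donor individual (an unrelated line),
#'   emulating an accidental outcross.
#' @param track_generations record the sampled offspring's autozygous
#'   fraction at every generation.
#' @return list with `individual` (per-chromosome maternal/paternal segment
#'   haplotypes), `segments` (truth table: chrom, start, end, mat_id,
#'   pat_id), `autozygous_fraction`, `per_generation` (or NULL), `family`.
#' @export
inbreed_line <- function(family, generations, spec, outcross = NULL,
                         track_generations = FALSE) {
  stopifnot(generations >= 1)
  base <- (family - 1L) * 4L
  mother <- .founder_individual(spec, base + 1L, base + 2L)
  father <- .founder_individual(spec, base + 3L, base + 4L)
  pair <- list(.child(mother, father, spec), .child(mother, father, spec))
  per_gen <- if (track_generations) numeric(generations) else NULL
  for (g in seq_len(generations)) {
    if (!is.null(outcross) && g == outcross$generation) pair[[2]] <- outcross$donor
    kids <- list(.child(pair[[1]], pair[[2]], spec),
                 .child(pair[[1]], pair[[2]], spec))
    if (track_generations)
      per_gen[g] <- .autozygous_fraction(.overlay_segments(kids[[1]], spec))
    pair <- kids
  }
  sampled <- .force_sex_region(pair[[1]], spec, family)
  segments <- .overlay_segments(sampled, spec)
  list(individual = sampled, segments = segments,
       autozygous_fraction = .autozygous_fraction(segments),
       per_generation = per_gen, family = family)
}

# founder-hap id per site for one haplotype
.ids_for_sites <- function(h, pos) h$ids[findInterval(pos - 0.5, h$ends) + 1L]

#' Simulate a whole inbred-line panel
#'
#' Families of `lines_per_family` lines per founder pair (within-family
#' consecutive pairs are recorded as sibling-line pairs); each line is
#' inbred for G generations, optionally suffering an accidental outcross;
#' genotypes are realised from founder haplotypes with genotype errors
#' injected at the configured rate. All randomness flows from `cfg$seed`.
#'
#' @param spec a [genome_spec()].
#' @param cfg a [sim_config()].
#' @return object of class `sim_panel`: list with `gm` ([geno_matrix()]),
#'   `truth` (list: `segments` long data.frame, `summary` per-line
#'   data.frame), `individuals`, `sibling_pairs`, `ancestral`
#'   (chrom/pos/ancestral_base), `founder_freqs` (true wild-population
#'   derived-allele frequency per site), `expected_F` (`wright_f`), `spec`,
#'   `cfg`.
#' @export
simulate_panel <- function(spec, cfg) {
  set.seed(cfg$seed)
  G <- cfg$generations
  fam <- rep(seq_len(cfg$n_founder_pairs), each = cfg$lines_per_family)
  within <- stats::ave(fam, fam, FUN = seq_along)
  line_ids <- sprintf("L%02d_%d", fam, within)
  n_lines <- length(line_ids)
  spec_donor <- spec; spec_donor$sex_region <- NULL
  lines <- vector("list", n_lines)
  outcrossed <- logical(n_lines)
  out_gen <- rep(NA_integer_, n_lines)
  for (i in seq_len(n_lines)) {
    oc <- NULL
    if (cfg$outcross_prob > 0 && stats::runif(1) < cfg$outcross_prob && G >= 3) {
      g_out <- if (!is.null(cfg$outcross_generation)) cfg$outcross_generation
        else sample(2:(G - 1), 1)
      donor_fam <- sample(setdiff(seq_len(cfg$n_founder_pairs), fam[i]), 1)
      donor <- inbreed_line(donor_fam, g_out, spec_donor)$individual
      oc <- list(generation = g_out, donor = donor)
      outcrossed[i] <- TRUE; out_gen[i] <- g_out
    }
    lines[[i]] <- inbreed_line(fam[i], G, spec, outcross = oc)
  }
  # realise genotypes chromosome by chromosome
  geno_blocks <- vector("list", nrow(spec$chroms))
  var_blocks <- vector("list", nrow(spec$chroms))
  for (ci in seq_len(nrow(spec$chroms))) {
    ch <- spec$chroms$chrom[ci]
    fs <- simulate_founders(spec, cfg, chroms = ch)$chrom[[ch]]
    ns <- length(fs$pos)
    g <- matrix(0L, n_lines, ns)
    if (ns > 0) {
      sidx <- seq_len(ns)
      for (i in seq_len(n_lines)) {
        ind <- lines[[i]]$individual[[ci]]
        am <- fs$haps[cbind(.ids_for_sites(ind$m, fs$pos), sidx)]
        ap <- fs$haps[cbind(.ids_for_sites(ind$p, fs$pos), sidx)]
        g[i, ] <- am + ap
      }
      if (cfg$genotype_error_rate > 0) {
        nerr <- stats::rbinom(1, length(g), cfg$genotype_error_rate)
        if (nerr > 0) {
          idx <- sample.int(length(g), nerr)
          cur <- g[idx]
          g[idx] <- ifelse(cur == 1L, 2L * stats::rbinom(nerr, 1, 0.5), 1L)
        }
      }
    }
    geno_blocks[[ci]] <- g
    var_blocks[[ci]] <- data.frame(chrom = ch, pos = fs$pos, ref = fs$ref,
                                   alt = fs$alt, q = fs$q,
                                   stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_blocks)
  geno <- do.call(cbind, geno_blocks)
  cl <- stats::setNames(spec$chroms$length, spec$chroms$chrom)
  gm <- geno_matrix(geno, variants$chrom, variants$pos, variants$ref,
                    variants$alt, sample_ids = line_ids, chrom_lengths = cl)
  seg <- do.call(rbind, lapply(seq_len(n_lines), function(i)
    cbind(line = line_ids[i], lines[[i]]$segments)))
  summary_df <- data.frame(line = line_ids, family = fam,
                           outcrossed = outcrossed,
                           outcross_generation = out_gen,
                           autozygous_fraction =
                             vapply(lines, `[[`, numeric(1), "autozygous_fraction"))
  sib <- NULL
  if (cfg$lines_per_family >= 2) {
    pr <- lapply(unique(fam), function(f) {
      ids <- line_ids[fam == f]
      k <- length(ids) %/% 2
      if (k == 0) return(NULL)
      data.frame(line_a = ids[2 * seq_len(k) - 1], line_b = ids[2 * seq_len(k)],
                 founder_family_id = f, stringsAsFactors = FALSE)
    })
    sib <- do.call(rbind, pr)
  }
  structure(list(gm = gm,
                 truth = list(segments = seg, summary = summary_df),
                 individuals = lapply(lines, `[[`, "individual"),
                 sibling_pairs = sib,
                 ancestral = data.frame(chrom = variants$chrom,
                                        pos = variants$pos,
                                        ancestral_base = variants$ref,
                                        stringsAsFactors = FALSE),
                 founder_freqs = data.frame(chrom = variants$chrom,
                                            pos = variants$pos,
                                            p = variants$q,
                                            stringsAsFactors = FALSE),
                 expected_F = wright_f(G), spec = spec, cfg = cfg),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", length(x$gm$sample_ids), "lines,",
      nrow(x$gm$variants), "SNPs,", nrow(x$spec$chroms), "chromosomes; G =",
      x$cfg$generations, "\n")
  cat(sprintf("  mean true autozygous fraction: %.4f (expected F_G = %.4f)\n",
              mean(x$truth$summary$autozygous_fraction),
              x$expected_F[length(x$expected_F)]))
  invisible(x)
}

#' Write a simulated panel to disk (VCF + truth/metadata TSVs)
#'
#' @param panel a [simulate_panel()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(panel$gm, file.path(dir, "panel.vcf"))
  write_tsv_table(panel$truth$segments, file.path(dir, "truth_segments.tsv"))
  write_tsv_table(panel$truth$summary, file.path(dir, "truth_summary.tsv"))
  if (!is.null(panel$sibling_pairs))
    write_tsv_table(panel$sibling_pairs, file.path(dir, "sibling_pairs.tsv"))
  write_tsv_table(panel$ancestral, file.path(dir, "ancestral.tsv"))
  invisible(dir)
}

#' Simulate four populations with block-wise introgression
#'
#' A frequency-based model for testing the ABBA-BABA machinery: an ancestral
#' SFS drifts (Balding-Nichols) into a (P1, P2) pair and an earlier-diverged
#' donor P3, while the outgroup O retains the ancestral allele. A fraction
#' `f` of P2's genome (in blocks of `block_len`) is replaced by P3's allele
#' frequencies, and diploid genotypes are sampled per population.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param f admixture fraction from P3 into P2.
#' @param n_per_pop diploid individuals per population.
#' @param target_pi per-site diversity calibrating the SNP density.
#' @param fst_anc,fst_split,fst_tip,fst_donor drift intensities: root ->
#'   common ancestor, ancestor -> (P1,P2) stem, stem -> each tip, ancestor
#'   -> P3.
#' @param block_len introgression block length in bp.
#' @param seed RNG seed.
#' @return list with `gm`, `pops` (named sample-id lists P1/P2/P3/O),
#'   `ancestral` table, `truth_blocks` (chrom, start, end, introgressed)
#'   and `f`.
#' @export
simulate_admixed_populations <- function(chrom_lengths, f, n_per_pop = 30,
                                         target_pi = 0.0037, fst_anc = 0.1,
                                         fst_split = 0.05, fst_tip = 0.02,
                                         fst_donor = 0.3, block_len = 2.5e5,
                                         seed = 1) {
  stopifnot(f >= 0, f <= 1)
  set.seed(seed)
  bn <- function(p, F) {
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  pool <- 200L
  e2pq <- .sfs_het_mean(pool)
  bases <- c("A", "C", "G", "T")
  res_g <- list(); res_v <- list(); res_b <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    n_sites <- round(target_pi * L / e2pq)
    pos <- sort(sample.int(L, n_sites))
    q <- .draw_sfs_freqs(n_sites, pool)
    p_a <- bn(q, fst_anc)
    p3 <- bn(p_a, fst_donor)
    p12 <- bn(p_a, fst_split)
    p1 <- bn(p12, fst_tip)
    p2 <- bn(p12, fst_tip)
    starts <- seq(0, L - 1, by = block_len)
    intro <- stats::runif(length(starts)) < f
    bidx <- findInterval(pos - 1, starts)
    swap <- intro[bidx]
    p2[swap] <- p3[swap]
    res_b[[ch]] <- data.frame(chrom = ch, start = starts,
                              end = pmin(starts + block_len, L),
                              introgressed = intro)
    draw <- function(p, n) {
      m <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), n)
      storage.mode(m) <- "integer"; m
    }
    g <- rbind(draw(p1, n_per_pop), draw(p2, n_per_pop), draw(p3, n_per_pop),
               matrix(0L, n_per_pop, n_sites))
    res_g[[ch]] <- g
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    res_v[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref,
                              alt = unname(alt), stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, res_v)
  geno <- do.call(cbind, res_g)
  ids <- c(paste0("P1_", seq_len(n_per_pop)), paste0("P2_", seq_len(n_per_pop)),
           paste0("P3_", seq_len(n_per_pop)), paste0("O_", seq_len(n_per_pop)))
  gm <- geno_matrix(geno, variants$chrom, variants$pos, variants$ref,
                    variants$alt, sample_ids = ids,
                    chrom_lengths = chrom_lengths)
  list(gm = gm,
       pops = list(P1 = ids[seq_len(n_per_pop)],
                   P2 = ids[n_per_pop + seq_len(n_per_pop)],
                   P3 = ids[2 * n_per_pop + seq_len(n_per_pop)],
                   O = ids[3 * n_per_pop + seq_len(n_per_pop)]),
       ancestral = data.frame(chrom = variants$chrom, pos = variants$pos,
                              ancestral_base = variants$ref,
                              stringsAsFactors = FALSE),
       truth_blocks = do.call(rbind, res_b), f = f)
}

#' Simulate a line-structured quantitative trait
#'
#' Gaussian line effects plus within-line noise, for exercising the
#' heritability stage (expected eta^2 ~ between / (between + within)
#' variance at large samples).
#'
#' @param line_ids line labels.
#' @param n_per_line individuals measured per line.
#' @param between_sd,within_sd standard deviations of line effects and
#'   residuals.
#' @param seed optional RNG seed.
#' @return data.frame with `line` and `value`.
#' @export
simulate_line_trait <- function(line_ids, n_per_line = 3, between_sd = 1,
                                within_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- stats::rnorm(length(line_ids), 0, between_sd)
  data.frame(line = rep(line_ids, each = n_per_line),
             value = rep(eff, each = n_per_line) +
               stats::rnorm(length(line_ids) * n_per_line, 0, within_sd))
}
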