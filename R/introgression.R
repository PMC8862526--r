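# ABBA-BABA introgression scans: polarization against an outgroup/ancestral
# table, Patterson's D and the f_d admixture-fraction statistic in sliding
# windows, following the four-taxon layout (((P1, P2), P3), O) on
# derived-allele frequencies.

#' Polarize allele frequencies against an ancestral-allele table
#'
#' Each biallelic SNP is oriented to its ancestral state: the non-ancestral
#' allele is "derived" and its frequency is reported per population. Sites
#' whose ancestral base is missing, `N`, or matches neither REF nor ALT are
#' dropped (tallied in the `dropped` attribute).
#'
#' @param gm a [geno_matrix()].
#' @param pops named list of sample-id vectors; must contain `P1` (close
#'   reference), `P2` (focal), `P3` (donor) and `O` (outgroup).
#' @param ancestral data.frame with columns chrom, pos, ancestral_base.
#' @return data.frame of class `polarized_freqs`: chrom, pos, p1, p2, p3, pO
#'   (derived-allele frequencies), with attribute `dropped` (named counts).
#' @export
polarize <- function(gm, pops, ancestral) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(pops)),
            all(c("chrom", "pos", "ancestral_base") %in% names(ancestral)))
  key_gm <- paste(gm$variants$chrom, gm$variants$pos)
  key_anc <- paste(ancestral$chrom, ancestral$pos)
  anc <- toupper(ancestral$ancestral_base[match(key_gm, key_anc)])
  no_call <- is.na(anc) | !(anc %in% c("A", "C", "G", "T"))
  is_ref <- !no_call & anc == gm$variants$ref
  is_alt <- !no_call & anc == gm$variants$alt
  mismatch <- !no_call & !is_ref & !is_alt
  keep <- is_ref | is_alt
  fr <- lapply(pops[c("P1", "P2", "P3", "O")],
               function(s) allele_freqs(gm, s))
  derived <- function(f) ifelse(is_ref, f$p, 1 - f$p)[keep]
  out <- data.frame(chrom = gm$variants$chrom[keep],
                    pos = gm$variants$pos[keep],
                    p1 = derived(fr$P1), p2 = derived(fr$P2),
                    p3 = derived(fr$P3), pO = derived(fr$O))
  attr(out, "dropped") <- c(no_ancestral_call = sum(no_call),
                            ancestral_mismatch = sum(mismatch))
  class(out) <- c("polarized_freqs", "data.frame")
  out
}

# shared numerator kernel: S(P1, P2, P3, O) summed over sites
.abba_baba_s <- function(p1, p2, p3, pO) {
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  c(num = sum(abba - baba, na.rm = TRUE), den = sum(abba + baba, na.rm = TRUE))
}

#' Patterson's D statistic over a site set
#'
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)` on derived-allele frequencies;
#' positive D indicates excess allele sharing between P2 and P3.
#'
#' @param freqs a [polarize()] result (or any data.frame with p1, p2, p3,
#'   pO).
#' @return D in [-1, 1], or NA for a zero denominator.
#' @export
d_statistic <- function(freqs) {
  s <- .abba_baba_s(freqs$p1, freqs$p2, freqs$p3, freqs$pO)
  if (s[["den"]] <= 0) return(NA_real_)
  unname(s[["num"]] / s[["den"]])
}

#' The f_d admixture-proportion statistic for a window
#'
#' `f_d = S(P1, P2, P3, O) / S(P1, P_D, P_D, O)` where, site by site, `P_D`
#' is whichever of P2/P3 has the higher derived-allele frequency (Martin et
#' al. 2015). Defined only where the window's D is positive; elsewhere
#' (and for a zero denominator) returns NA.
#'
#' @param freqs a [polarize()] result restricted to one window.
#' @return f_d, or NA when undefined.
#' @export
fd_statistic <- function(freqs) {
  D <- d_statistic(freqs)
  if (is.na(D) || D <= 0) return(NA_real_)
  num <- .abba_baba_s(freqs$p1, freqs$p2, freqs$p3, freqs$pO)[["num"]]
  pd <- pmax(freqs$p2, freqs$p3)
  den <- .abba_baba_s(freqs$p1, pd, pd, freqs$pO)[["num"]]
  if (is.na(den) || den == 0) return(NA_real_)
  unname(num / den)
}

#' Sliding-window D and f_d scan
#'
#' Computes D and f_d in sliding windows (default 500 kb with a half-window
#' step); windows with fewer than `min_snps` polarized SNPs are missing, and
#' f_d is additionally missing where window D <= 0.
#'
#' @param freqs a [polarize()] result.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window,step window size and step in bp.
#' @param min_snps minimum polarized SNPs per window.
#' @return data.frame of class `fd_scan`: chrom, start, end (0-based
#'   half-open), D, fd, n_snps.
#' @export
sliding_fd_scan <- function(freqs, chrom_lengths, window = 5e5, step = window / 2,
                            min_snps = 250L) {
  res <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    sel <- freqs$chrom == ch
    pos <- freqs$pos[sel]
    sub <- freqs[sel, , drop = FALSE]
    starts <- seq(0, max(L - 1, 0), by = step)
    for (s in starts) {
      e <- min(s + window, L)
      ii <- which(pos - 1 >= s & pos - 1 < e)
      n <- length(ii)
      if (n < min_snps) {
        res[[length(res) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                              D = NA_real_, fd = NA_real_,
                                              n_snps = n)
        next
      }
      wfr <- sub[ii, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                            D = d_statistic(wfr),
                                            fd = fd_statistic(wfr), n_snps = n)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("fd_scan", "data.frame")
  out
}

#' Genome-wide mean f_d (the headline sharing fraction)
#'
#' Averages f_d over windows passing the SNP floor. Windows whose D is not
#' positive have no defined f_d; by default they enter the mean as zero
#' (`negative_d = "zero"`), or can be dropped entirely.
#'
#' @param scan a [sliding_fd_scan()] result.
#' @param negative_d how to treat defined windows with D <= 0.
#' @return mean f_d.
#' @export
genome_fd_mean <- function(scan, negative_d = c("zero", "drop")) {
  negative_d <- match.arg(negative_d)
  ok <- !is.na(scan$D)   # window passed min_snps and had informative sites
  fd <- scan$fd[ok]
  D <- scan$D[ok]
  if (negative_d == "zero") fd[is.na(fd) | D <= 0] <- 0
  else { keep <- !is.na(fd); fd <- fd[keep] }
  if (!length(fd)) return(NA_real_)
  mean(fd)
}
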