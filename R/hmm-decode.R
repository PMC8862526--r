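# Decoding fitted Poisson HMMs: Viterbi paths, forward-backward posteriors,
# run-length blocks and genome-wide homozygous fractions.

# batched log-space Viterbi on an S x T count matrix; ties broken toward the
# lower state index (max.col "first" on states ordered by ascending lambda)
.viterbi_group <- function(X, R, lam, A, pi0) {
  S <- nrow(X); T_ <- ncol(X); K <- length(lam)
  logE <- lapply(seq_len(K), function(k) {
    mu <- if (is.null(R)) lam[k] else lam[k] * pmax(R, 1e-12)
    stats::dpois(X, mu, log = TRUE)
  })
  lemat <- function(t) {
    m <- matrix(0, S, K)
    for (k in seq_len(K)) m[, k] <- logE[[k]][, t]
    m
  }
  logA <- log(A); logpi <- log(pi0)
  delta <- matrix(logpi, S, K, byrow = TRUE) + lemat(1)
  psi <- array(0L, c(S, K, T_))
  if (T_ > 1) for (t in 2:T_) {
    newdelta <- matrix(0, S, K)
    le <- lemat(t)
    for (j in seq_len(K)) {
      M <- delta + matrix(logA[, j], S, K, byrow = TRUE)
      b <- max.col(M, ties.method = "first")
      psi[, j, t] <- b
      newdelta[, j] <- M[cbind(seq_len(S), b)] + le[, j]
    }
    delta <- newdelta
  }
  states <- matrix(0L, S, T_)
  states[, T_] <- max.col(delta, ties.method = "first")
  if (T_ > 1) for (t in (T_ - 1):1) {
    states[, t] <- psi[cbind(seq_len(S), states[, t + 1], t + 1)]
  }
  states - 1L
}

.decode_dispatch <- function(object, x, fun) {
  stopifnot(inherits(object, "poisson_hmm"))
  sq <- as_count_sequences(x, use_exposure = isTRUE(object$use_exposure))
  groups <- .group_sequences(sq$seqs, sq$expos)
  out <- vector("list", length(sq$seqs))
  for (gr in groups) {
    res <- fun(gr)
    for (i in seq_along(gr$idx)) out[[gr$idx[i]]] <- res[[i]]
  }
  list(out = out, sq = sq)
}

#' Viterbi decoding of window-count sequences
#'
#' Returns the maximum-probability hidden-state sequence under a fitted
#' [fit_poisson_hmm()] model. Chromosomes are decoded independently, each
#' restarting from the initial distribution; ties are broken toward the
#' lower (more homozygous) state index.
#'
#' @param object a `poisson_hmm`.
#' @param x a numeric vector (one sequence), a list of vectors, or a
#'   [window_het_counts()] result (all lines, all chromosomes).
#' @return for a vector, an integer vector of 0-based states; for a list, a
#'   list of such vectors; for `window_counts`, an object of class
#'   `state_paths`: list with `states` (lines x windows matrix), `grid`,
#'   `sample_ids` and `K`.
#' @export
viterbi_decode <- function(object, x) {
  dd <- .decode_dispatch(object, x, function(gr) {
    st <- .viterbi_group(gr$X, gr$R, object$lambda, object$A, object$pi0)
    lapply(seq_len(nrow(st)), function(i) st[i, ])
  })
  .assemble_paths(dd, x, object$K)
}

.assemble_paths <- function(dd, x, K) {
  if (inherits(x, "window_counts")) {
    nl <- length(x$sample_ids)
    states <- matrix(0L, nl, nrow(x$grid), dimnames = list(x$sample_ids, NULL))
    chrom <- x$grid$chrom
    idx <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
    k <- 0L
    for (l in seq_len(nl)) for (c_i in seq_along(idx)) {
      k <- k + 1L
      states[l, idx[[c_i]]] <- dd$out[[k]]
    }
    return(structure(list(states = states, grid = x$grid,
                          sample_ids = x$sample_ids, K = K),
                     class = "state_paths"))
  }
  if (is.numeric(x)) return(dd$out[[1]])
  dd$out
}

#' @export
print.state_paths <- function(x, ...) {
  cat("state_paths:", nrow(x$states), "lines x", ncol(x$states),
      "windows,", x$K, "states\n")
  invisible(x)
}

#' Forward-backward posterior state probabilities
#'
#' @inheritParams viterbi_decode
#' @return for a vector, a T x K matrix of posteriors (rows sum to 1); for a
#'   list, a list of such matrices; for `window_counts`, a list of per-line
#'   windows x K matrices named by line.
#' @export
posterior_decode <- function(object, x) {
  dd <- .decode_dispatch(object, x, function(gr) {
    fb <- .fb_group(gr$X, gr$R, object$lambda, object$A, object$pi0,
                    want_gamma = TRUE)
    lapply(seq_len(nrow(gr$X)), function(i)
      t(matrix(fb$gamma[i, , ], object$K, ncol(gr$X))))
  })
  if (inherits(x, "window_counts")) {
    nl <- length(x$sample_ids)
    chrom <- x$grid$chrom
    idx <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
    out <- vector("list", nl)
    names(out) <- x$sample_ids
    k <- 0L
    for (l in seq_len(nl)) {
      m <- matrix(0, nrow(x$grid), object$K)
      for (c_i in seq_along(idx)) {
        k <- k + 1L
        m[idx[[c_i]], ] <- dd$out[[k]]
      }
      out[[l]] <- m
    }
    return(out)
  }
  if (is.numeric(x)) return(dd$out[[1]])
  dd$out
}

#' Run-length encode state paths into genomic blocks
#'
#' @param paths a `state_paths` object from [viterbi_decode()], or a single
#'   integer state vector (with `grid` supplied).
#' @param grid required when `paths` is a bare vector.
#' @param line_id label used for a bare vector.
#' @return a `block_set`: data.frame with line, chrom, start, end (0-based
#'   half-open), state, n_windows; blocks tile each chromosome and adjacent
#'   blocks differ in state.
#' @export
states_to_blocks <- function(paths, grid = NULL, line_id = "line") {
  if (inherits(paths, "state_paths")) {
    grid <- paths$grid
    mat <- paths$states
  } else {
    stopifnot(!is.null(grid), length(paths) == nrow(grid))
    mat <- matrix(as.integer(paths), 1, dimnames = list(line_id, NULL))
  }
  chrom <- grid$chrom
  idx <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
  res <- vector("list", nrow(mat) * length(idx))
  k <- 0L
  for (l in seq_len(nrow(mat))) for (c_i in seq_along(idx)) {
    ii <- idx[[c_i]]
    r <- rle(mat[l, ii])
    last <- cumsum(r$lengths)
    first <- c(1L, utils::head(last, -1) + 1L)
    k <- k + 1L
    res[[k]] <- data.frame(line = rownames(mat)[l], chrom = names(idx)[c_i],
                           start = grid$start[ii[first]], end = grid$end[ii[last]],
                           state = r$values, n_windows = r$lengths,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("block_set", "data.frame")
  out
}

#' Reconstruct per-window states from a block set (round-trip of
#' [states_to_blocks()])
#'
#' @param blocks a `block_set` for a single line (or filter by line first).
#' @param grid the [window_grid()] the blocks were called on.
#' @return integer vector of per-window states.
#' @export
blocks_to_states <- function(blocks, grid) {
  states <- rep(NA_integer_, nrow(grid))
  for (i in seq_len(nrow(blocks))) {
    sel <- grid$chrom == blocks$chrom[i] & grid$start >= blocks$start[i] &
      grid$end <= blocks$end[i]
    states[sel] <- blocks$state[i]
  }
  states
}

#' Genome fraction called homozygous per line
#'
#' Span of state-0 blocks over the total span, optionally excluding
#' chromosomes (the sex chromosome stays heterozygous in heterogametic
#' individuals and would bias the genome-wide fraction).
#'
#' @param blocks a `block_set` from [states_to_blocks()].
#' @param exclude_chroms chromosomes excluded from numerator and denominator.
#' @param homozygous_state state index treated as homozygous (default 0, the
#'   lowest-rate state).
#' @return named numeric vector in [0, 1], one entry per line.
#' @export
homozygous_fraction <- function(blocks, exclude_chroms = NULL,
                                homozygous_state = 0L) {
  keep <- !(blocks$chrom %in% exclude_chroms)
  if (!any(keep)) stop("all chromosomes excluded")
  b <- blocks[keep, , drop = FALSE]
  span <- b$end - b$start
  tot <- tapply(span, b$line, sum)
  hom <- tapply(span * (b$state == homozygous_state), b$line, sum)
  out <- as.numeric(hom / tot)
  names(out) <- names(tot)
  out[unique(blocks$line)]
}

#' Export homozygosity blocks as BED
#'
#' 0-based half-open records with the state as the name column and the line
#' id in the fifth column.
#'
#' @param blocks a `block_set`.
#' @param path output file.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(blocks$chrom, blocks$start, blocks$end,
                    paste0("state", blocks$state), blocks$line)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
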