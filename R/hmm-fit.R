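# Poisson-emission HMM for windowed heterozygous-SNP counts.
#
# All lines are fitted jointly: every per-line, per-chromosome window-count
# sequence shares one parameter set, and each sequence restarts from the
# initial distribution (windows are not physically adjacent across
# chromosomes or lines). Scaled forward-backward recursions are used
# throughout, with sequences of equal length processed as batched matrix
# operations.

.LAMBDA_FLOOR <- 1e-3

# normalise x (window_counts / list / vector) into a list of integer vectors,
# with optional per-window exposures carried alongside
as_count_sequences <- function(x, use_exposure = FALSE) {
  if (inherits(x, "window_counts")) {
    chrom <- x$grid$chrom
    idx <- split(seq_along(chrom), factor(chrom, levels = unique(chrom)))
    seqs <- list(); expos <- list(); line <- character(); ch <- character()
    for (l in seq_along(x$sample_ids)) {
      for (c_i in seq_along(idx)) {
        seqs[[length(seqs) + 1L]] <- x$counts[l, idx[[c_i]]]
        if (use_exposure) {
          e <- x$n_sites[l, idx[[c_i]]]
          expos[[length(expos) + 1L]] <- e / max(mean(e[e > 0]), 1)
        }
        line <- c(line, x$sample_ids[l]); ch <- c(ch, names(idx)[c_i])
      }
    }
    return(list(seqs = seqs, expos = if (use_exposure) expos else NULL,
                line = line, chrom = ch))
  }
  if (is.numeric(x)) x <- list(as.integer(x))
  stopifnot(is.list(x), all(vapply(x, is.numeric, TRUE)))
  list(seqs = lapply(x, as.integer), expos = NULL, line = NULL, chrom = NULL)
}

# group sequences of equal length into matrices for batched recursions
.group_sequences <- function(seqs, expos = NULL) {
  lens <- lengths(seqs)
  groups <- split(seq_along(seqs), lens)
  lapply(groups, function(idx) {
    X <- do.call(rbind, seqs[idx])
    R <- if (!is.null(expos)) do.call(rbind, expos[idx]) else NULL
    list(idx = idx, X = X, R = R, T = ncol(X), S = nrow(X))
  })
}

# one scaled forward-backward pass over a batch; returns the log-likelihood
# contribution, EM sufficient statistics and (optionally) posteriors
.fb_group <- function(X, R, lam, A, pi0, want_gamma = FALSE) {
  S <- nrow(X); T_ <- ncol(X); K <- length(lam)
  E <- lapply(seq_len(K), function(k) {
    mu <- if (is.null(R)) lam[k] else lam[k] * pmax(R, 1e-12)
    stats::dpois(X, mu)
  })
  emat <- function(t) {
    m <- matrix(0, S, K)
    for (k in seq_len(K)) m[, k] <- E[[k]][, t]
    m
  }
  sl <- function(arr, t) matrix(arr[, , t], S, K)
  alpha <- array(0, c(S, K, T_))
  cc <- matrix(0, S, T_)
  a <- matrix(pi0, S, K, byrow = TRUE) * emat(1)
  cc[, 1] <- rowSums(a)
  if (any(cc[, 1] <= 0) || anyNA(cc[, 1]))
    stop("numerical underflow in E-step (forward pass); counts incompatible with rates")
  alpha[, , 1] <- a / cc[, 1]
  if (T_ > 1) for (t in 2:T_) {
    a <- (sl(alpha, t - 1) %*% A) * emat(t)
    cc[, t] <- rowSums(a)
    if (any(cc[, t] <= 0) || anyNA(cc[, t]))
      stop("numerical underflow in E-step (forward pass); counts incompatible with rates")
    alpha[, , t] <- a / cc[, t]
  }
  ll <- sum(log(cc))
  # backward pass with on-the-fly accumulation
  lam_num <- numeric(K); lam_den <- numeric(K)
  Aacc <- matrix(0, K, K)
  gamma_arr <- if (want_gamma) array(0, c(S, K, T_)) else NULL
  beta <- matrix(1, S, K)
  g <- sl(alpha, T_)
  if (want_gamma) gamma_arr[, , T_] <- g
  lam_num <- lam_num + colSums(g * X[, T_])
  lam_den <- lam_den + colSums(if (is.null(R)) g else g * R[, T_])
  if (T_ > 1) for (t in (T_ - 1):1) {
    Bnext <- (beta * emat(t + 1)) / cc[, t + 1]
    at <- sl(alpha, t)
    Aacc <- Aacc + crossprod(at, Bnext)
    beta <- Bnext %*% t(A)
    g <- at * beta
    g <- g / rowSums(g)
    if (want_gamma) gamma_arr[, , t] <- g
    lam_num <- lam_num + colSums(g * X[, t])
    lam_den <- lam_den + colSums(if (is.null(R)) g else g * R[, t])
  }
  g1 <- if (T_ > 1) g else sl(alpha, 1)
  list(ll = ll, g1 = colSums(g1), lam_num = lam_num, lam_den = lam_den,
       Aacc = Aacc, gamma = gamma_arr)
}

#' Fit a Poisson-emission hidden Markov model to windowed het counts
#'
#' Baum-Welch (EM) estimation of a K-state HMM whose emissions are Poisson
#' counts of heterozygous SNPs per genomic window. All sequences (one per
#' line per chromosome) are pooled, so the parameters are trained jointly
#' across the panel; decoding is then done per line with [viterbi_decode()]
#' or [posterior_decode()]. States are relabelled by ascending emission rate
#' before return, so state 0 is always the most homozygous.
#'
#' @param x a [window_het_counts()] result, a list of non-negative integer
#'   vectors, or a single vector.
#' @param K number of hidden states (>= 2). Two states separate homozygous
#'   blocks from residual heterozygosity; four give the finer-grained view
#'   used to refine obligate-heterozygous regions.
#' @param max_iter,tol EM stopping rule: stop when the total log-likelihood
#'   improves by less than `tol`, or after `max_iter` iterations.
#' @param lambda_init optional vector of K starting emission rates; by
#'   default the 25th and 97.5th percentiles of the pooled counts (K = 2) or
#'   K quantiles spaced evenly between those probabilities.
#' @param stay_prob initial self-transition probability (sticky start).
#' @param use_exposure if `TRUE` (and `x` is a `window_counts`), emission
#'   means are scaled by each window's genotyped-site count relative to the
#'   sequence mean. Off by default: the block caller is defined on raw
#'   counts.
#' @param seed optional RNG seed (recorded; initialization is deterministic).
#' @return an object of class `poisson_hmm` with elements `K`, `lambda`,
#'   `A` (transition matrix), `pi0`, `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `n_sequences`, `n_obs`.
#' @export
fit_poisson_hmm <- function(x, K = 2L, max_iter = 500L, tol = 1e-6,
                            lambda_init = NULL, stay_prob = 0.99,
                            use_exposure = FALSE, seed = NULL) {
  stopifnot(K >= 2, max_iter >= 1, tol > 0, stay_prob > 0, stay_prob < 1)
  if (!is.null(seed)) set.seed(seed)
  sq <- as_count_sequences(x, use_exposure = use_exposure)
  pooled <- unlist(sq$seqs)
  if (any(pooled < 0)) stop("counts must be non-negative")
  if (all(pooled == 0))
    warning("all window counts are zero; emission rates degenerate at the floor")
  if (is.null(lambda_init)) {
    probs <- seq(0.25, 0.975, length.out = K)
    lam <- as.numeric(stats::quantile(pooled, probs))
  } else {
    stopifnot(length(lambda_init) == K)
    lam <- as.numeric(lambda_init)
  }
  lam <- pmax(lam, .LAMBDA_FLOOR)
  # ensure distinct starting rates even on near-constant counts
  if (any(duplicated(lam))) lam <- lam * (1 + 0.05 * (seq_len(K) - 1)) +
      .LAMBDA_FLOOR * (seq_len(K) - 1)
  A <- matrix((1 - stay_prob) / (K - 1), K, K)
  diag(A) <- stay_prob
  pi0 <- rep(1 / K, K)
  groups <- .group_sequences(sq$seqs, sq$expos)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ll <- 0
    g1 <- numeric(K); lam_num <- numeric(K); lam_den <- numeric(K)
    Aacc <- matrix(0, K, K)
    for (gr in groups) {
      st <- .fb_group(gr$X, gr$R, lam, A, pi0)
      ll <- ll + st$ll
      g1 <- g1 + st$g1
      lam_num <- lam_num + st$lam_num
      lam_den <- lam_den + st$lam_den
      Aacc <- Aacc + st$Aacc
    }
    if (!is.finite(ll)) stop("numerical underflow in E-step; log-likelihood not finite")
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll
    # M-step
    pi0 <- g1 / sum(g1)
    Anew <- A * Aacc
    rs <- rowSums(Anew)
    keep <- rs > 0
    Anew[keep, ] <- Anew[keep, , drop = FALSE] / rs[keep]
    Anew[!keep, ] <- 1 / K
    A <- Anew
    lam <- pmax(lam_num / pmax(lam_den, 1e-300), .LAMBDA_FLOOR)
  }
  ord <- order(lam)
  fit <- list(K = as.integer(K), lambda = lam[ord], A = A[ord, ord, drop = FALSE],
              pi0 = pi0[ord], loglik = trace[length(trace)], loglik_trace = trace,
              iterations = iter, converged = converged,
              n_sequences = length(sq$seqs), n_obs = length(pooled),
              use_exposure = use_exposure, call = match.call())
  class(fit) <- "poisson_hmm"
  fit
}

#' @export
print.poisson_hmm <- function(x, digits = 4, ...) {
  cat("Poisson-emission HMM (", x$K, " states), fitted jointly on ",
      x$n_sequences, " sequences / ", x$n_obs, " windows\n", sep = "")
  cat("  lambda (het SNPs per window, ascending): ",
      paste(signif(x$lambda, digits), collapse = ", "), "\n", sep = "")
  cat("  self-transition: ", paste(signif(diag(x$A), digits), collapse = ", "),
      "\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, digits = 10), " after ",
      x$iterations, " EM iteration(s)",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.poisson_hmm <- function(object, ...) {
  ev <- eigen(t(object$A))
  i <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i]); stat <- stat / sum(stat)
  out <- list(fit = object, stationary = stat,
              expected_dwell = 1 / pmax(1 - diag(object$A), 1e-12))
  class(out) <- "summary.poisson_hmm"
  out
}

#' @export
print.summary.poisson_hmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  tab <- data.frame(state = seq_len(x$fit$K) - 1L,
                    lambda = signif(x$fit$lambda, digits),
                    stationary = signif(x$stationary, digits),
                    expected_dwell_windows = signif(x$expected_dwell, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.poisson_hmm <- function(object, ...) {
  list(lambda = object$lambda, A = object$A, pi0 = object$pi0)
}

#' @export
logLik.poisson_hmm <- function(object, ...) {
  df <- (object$K - 1) + object$K * (object$K - 1) + object$K
  structure(object$loglik, df = df, nobs = object$n_obs, class = "logLik")
}

#' Simulate count sequences from a fitted (or hand-built) Poisson HMM
#'
#' @param object a `poisson_hmm`.
#' @param nsim number of sequences.
#' @param seed optional seed.
#' @param length_out windows per sequence.
#' @param ... unused.
#' @return list of `nsim` lists with integer `states` (0-based) and `counts`.
#' @export
simulate.poisson_hmm <- function(object, nsim = 1, seed = NULL,
                                 length_out = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- object$K
  lapply(seq_len(nsim), function(i) {
    s <- integer(length_out)
    s[1] <- sample.int(K, 1, prob = object$pi0)
    if (length_out > 1) for (t in 2:length_out)
      s[t] <- sample.int(K, 1, prob = object$A[s[t - 1], ])
    counts <- stats::rpois(length_out, object$lambda[s])
    list(states = s - 1L, counts = counts)
  })
}

#' Decode new data with a fitted Poisson HMM
#'
#' @param object a `poisson_hmm`.
#' @param newdata counts: a vector, list of vectors, or `window_counts`.
#' @param type `"viterbi"` (default; most probable state path) or
#'   `"posterior"` (forward-backward state probabilities).
#' @param ... unused.
#' @return see [viterbi_decode()] / [posterior_decode()].
#' @export
predict.poisson_hmm <- function(object, newdata, type = c("viterbi", "posterior"),
                                ...) {
  type <- match.arg(type)
  if (type == "viterbi") viterbi_decode(object, newdata)
  else posterior_decode(object, newdata)
}

#' @export
plot.poisson_hmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
                 xlab = "EM iteration", ylab = "log-likelihood",
                 main = "EM trace", ...)
  ev <- eigen(t(x$A)); i <- which.min(abs(ev$values - 1))
  w <- Re(ev$vectors[, i]); w <- w / sum(w)
  xs <- 0:max(stats::qpois(0.999, max(x$lambda)), 5)
  mix <- sapply(xs, function(v) sum(w * stats::dpois(v, x$lambda)))
  graphics::plot(xs, mix, type = "h", xlab = "het SNPs per window",
                 ylab = "stationary mixture density", main = "Fitted emissions")
  invisible(x)
}

#' Write HMM parameters as a plain-text report
#'
#' @param object a `poisson_hmm`.
#' @param path output file.
#' @export
write_hmm_params <- function(object, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("K\t%d", object$K),
               sprintf("lambda\t%s", paste(object$lambda, collapse = "\t")),
               sprintf("pi0\t%s", paste(object$pi0, collapse = "\t")),
               paste0("A", seq_len(object$K), "\t",
                      apply(object$A, 1, paste, collapse = "\t")),
               sprintf("loglik\t%.10g", object$loglik),
               sprintf("iterations\t%d", object$iterations),
               sprintf("converged\t%s", object$converged)), con)
  invisible(path)
}
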