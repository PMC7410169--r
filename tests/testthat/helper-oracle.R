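# Independent oracles used to check the HMM machinery and the basewise
# metrics. These deliberately use brute force / alternative representations
# and never call the code paths they verify.

# Exact HMM quantities by exhaustive enumeration over all state paths.
# pi: initial distribution; A: single transition matrix or list of L-1
# matrices; E: S x L emissions. Returns the total likelihood, per-column
# posterior marginals, and the posterior probability of each full path.
enumerate_hmm <- function(pi, A, E) {
  S <- nrow(E); L <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  w <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lik <- pi[p[1]] * E[p[1], 1]
    for (c_ in seq_len(L - 1L)) {
      Ac <- if (is.list(A)) A[[c_]] else A
      lik <- lik * Ac[p[c_], p[c_ + 1L]] * E[p[c_ + 1L], c_ + 1L]
    }
    w[r] <- lik
  }
  tot <- sum(w)
  marg <- matrix(0, S, L)
  for (c_ in seq_len(L))
    marg[, c_] <- vapply(seq_len(S), function(s)
      sum(w[paths[, c_] == s]), numeric(1)) / tot
  list(lik = tot, marginals = marg, paths = paths, weights = w / tot)
}

# Log-space forward recursion (alternative numerical regime).
log_forward <- function(pi, A, E) {
  S <- nrow(E); L <- ncol(E)
  la <- log(pi) + log(E[, 1])
  for (c_ in seq_len(L - 1L)) {
    Ac <- if (is.list(A)) A[[c_]] else A
    la <- apply(log(Ac) + la, 2L, function(x) {
      m <- max(x); m + log(sum(exp(x - m)))
    }) + log(E[, c_ + 1L])
  }
  m <- max(la)
  m + log(sum(exp(la - m)))
}

# Exact smoothed marginals by forward-backward on dense matrices.
forward_backward_marginals <- function(hmm) {
  S <- nrow(hmm$E); L <- ncol(hmm$E)
  alpha <- matrix(0, S, L)
  a <- hmm$pi * hmm$E[, 1]
  alpha[, 1] <- a / sum(a)
  for (c_ in seq_len(L - 1L)) {
    a <- as.numeric(crossprod(hmm$A[[c_]], alpha[, c_])) * hmm$E[, c_ + 1L]
    alpha[, c_ + 1L] <- a / sum(a)
  }
  beta <- matrix(0, S, L)
  beta[, L] <- 1
  for (c_ in rev(seq_len(L - 1L))) {
    b <- as.numeric(hmm$A[[c_]] %*% (beta[, c_ + 1L] * hmm$E[, c_ + 1L]))
    beta[, c_] <- b / sum(b)
  }
  post <- alpha * beta
  sweep(post, 2L, colSums(post), `/`)
}

# Basewise TP/FP via per-bp bitmaps (alternative route to interval
# arithmetic).
bitmap_rates <- function(calls, truth, window_bp) {
  truth$individual <- sub("_[12]$", "", truth$lineage)
  out <- list()
  for (b in unique(c(calls$band, truth$band)))
    for (ind in unique(c(calls$individual, truth$individual))) {
      tv <- logical(window_bp); cv <- logical(window_bp)
      tr <- truth[truth$band == b & truth$individual == ind, ]
      for (i in seq_len(nrow(tr)))
        if (tr$end[i] > tr$start[i])
          tv[(tr$start[i] + 1L):tr$end[i]] <- TRUE
      cl <- calls[calls$band == b & calls$individual == ind, ]
      for (i in seq_len(nrow(cl)))
        if (cl$end[i] > cl$start[i])
          cv[(cl$start[i] + 1L):cl$end[i]] <- TRUE
      out[[length(out) + 1L]] <- tibble::tibble(
        band = b, individual = ind,
        tp_bp = sum(cv & tv), fp_bp = sum(cv & !tv),
        truth_bp = sum(tv),
        tp_rate = if (sum(tv)) sum(cv & tv) / sum(tv) else NA_real_,
        fp_rate = sum(cv & !tv) / sum(!tv))
    }
  dplyr::bind_rows(out)
}

# Dense per-column transition matrices for a single-tree instance, built
# from the exported kernel; used to drive the reference forward/backward and
# the enumeration oracle on small cases.
dense_hmm <- function(model, tree, lineage, data, cols = NULL,
                      migration_enabled = TRUE) {
  if (is.null(cols)) cols <- seq_len(ncol(data$geno))
  eng <- argthreader:::span_engine(model, tree, lineage,
                                   migration_enabled = migration_enabled)
  E <- argthreader:::emission_matrix_eng(eng, model, data$geno,
                                         data$col$mu, cols)
  w <- data$col$nbases[cols]
  A <- lapply(seq_len(length(cols) - 1L), function(c_) {
    p0 <- exp(-data$recomb_rate * w[c_] * eng$ell)
    diag(p0) + (1 - p0) * eng$Rhat
  })
  list(eng = eng, pi = eng$pi, A = A, E = E)
}
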