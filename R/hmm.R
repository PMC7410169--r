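#' Enumerate threading states for a local tree
#'
#' The state space of the threading HMM at one column: all (branch, time,
#' population path) triples at which the new branch can coalesce into the
#' fixed local tree. Coalescence requires the new branch's path and the
#' target branch to occupy the same (non-ghost) population at the
#' coalescence time. The root node stands for its own upward continuation,
#' onto which coalescence above the current root is allowed. Under the
#' default at-most-one-migration constraint, migrant paths are pruned
#' whenever the fixed tree already contains a migrant branch.
#'
#' @param tree A [local_tree()] (the partial tree, without the new lineage).
#' @param model A [demog_model()].
#' @param lineage Name of the lineage being threaded.
#' @param max_one_migration Enforce the one-migration-per-location
#'   constraint (default TRUE).
#' @param migration_enabled If FALSE, only the resident path is considered
#'   (used during the start-mig phase of the chain and for
#'   initialization).
#' @return Tibble with columns `node`, `time`, `path`.
#' @export
enumerate_states <- function(tree, model, lineage,
                             max_one_migration = TRUE,
                             migration_enabled = TRUE) {
  eng <- span_engine(model, tree, lineage,
                     migration_enabled = migration_enabled,
                     max_one_migration = max_one_migration)
  tibble::as_tibble(eng$states)
}

# Candidate global path ids for a lineage (anchored at its population, band
# crossings not below its sampling age).
candidate_paths <- function(model, pop, age_idx, migration_enabled) {
  pt <- model$paths
  ids <- which(pt$anchor == pop & (is.na(pt$half) | pt$half >= age_idx))
  if (!migration_enabled) ids <- ids[is.na(pt$half[ids])]
  ids
}

# Per-tree threading engine: state space, coalescent walk arrays, and the
# recombination re-coalescence kernel. All heavy lookups are precomputed
# here once per local tree span.
span_engine <- function(model, tree, lineage,
                        migration_enabled = TRUE,
                        max_one_migration = TRUE) {
  K <- model$grid$K
  g <- model$grid$times_gen
  hg <- model$grid$half_gen
  lin <- model$lineages[model$lineages$lineage == lineage, ]
  if (nrow(lin) != 1L) stop("unknown lineage: ", lineage, call. = FALSE)
  a_s <- lin$age_idx

  # migrant branch already in the fixed tree?
  mig_enabled <- migration_enabled
  if (max_one_migration && mig_enabled &&
      tree_migrant_count(model, tree) > 0L)
    mig_enabled <- FALSE

  cand <- candidate_paths(model, lin$pop, a_s, mig_enabled)
  pmat <- model$paths$mat[cand, , drop = FALSE]      # P x K populations
  P <- length(cand)

  # valid coalescence target counts m[q, j] and branch pops
  root <- tree_root(tree)
  nnode <- length(tree$parent)
  hi <- ifelse(tree$parent == 0L, K, tree$time[pmax(tree$parent, 1L)])
  node_pop <- matrix(model$paths$mat[tree$path, ], nnode, K)  # node x K
  m <- matrix(0, model$npop, K)
  jr <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    if (v == root) {
      jlo <- min(tree$time[v] + 1L, K)
      jr[[v]] <- seq.int(jlo, K)
    } else {
      if (tree$time[v] + 1L > hi[v] - 1L) { jr[[v]] <- integer(0); next }
      jr[[v]] <- seq.int(tree$time[v] + 1L, hi[v] - 1L)
    }
    for (j in jr[[v]]) {
      q <- node_pop[v, j]
      m[q, j] <- m[q, j] + 1
    }
  }
  # above the top grid point only the root continuation is a target
  m[, K] <- 0
  m[node_pop[root, K], K] <- 1

  # discretized coalescence probability c[q, j]; the exposure window for
  # coalescence at grid time j is [h_{j-1}, h_j]
  delta <- c(0, diff(hg), 0)
  cmat <- matrix(0, model$npop, K)
  for (q in seq_len(model$npop)) {
    if (model$pops$ghost[q]) next
    for (j in 2:(K - 1)) {
      if (m[q, j] > 0) {
        Nq <- model$N[q, j]
        if (is.na(Nq) || Nq <= 0)
          stop("population ", model$pop_names[q],
               " has no valid size at time index ", j, call. = FALSE)
        cmat[q, j] <- 1 - exp(-m[q, j] * delta[j] / (2 * Nq))
      }
    }
  }
  cmat[, K] <- 1
  cmat <- pmin(cmat, 1 - 1e-12)
  cmat[, K] <- 1

  # migration-band factors at half time-points, per candidate path
  # (sequential-decision weighting in model band order)
  logB <- matrix(0, P, K)   # logB[p, h] = log factor at half index h (1..K-1)
  if (nrow(model$bands) > 0L && P > 0L) {
    for (pi_ in seq_len(P)) {
      pid <- cand[pi_]
      ch <- model$paths$half[pid]
      cb <- model$paths$band[pid]
      for (h in seq_len(K - 1L)) {
        if (!mig_enabled) break
        if (!is.na(ch) && ch < h) next               # already migrated: no choice
        appl <- which(model$bands$half == h &
                        match(model$bands$dest, model$pop_names) == pmat[pi_, h])
        if (!length(appl)) next
        if (!is.na(ch) && ch == h) {
          b <- which(appl == cb)
          logB[pi_, h] <- log(model$bands$rate[cb]) +
            sum(log1p(-model$bands$rate[appl[seq_len(b - 1L)]]))
        } else {
          logB[pi_, h] <- sum(log1p(-model$bands$rate[appl]))
        }
      }
    }
  }

  # cumulative survival and band-factor arrays (per candidate path)
  #   cumA[p, j] = sum_{k<=j} log(1 - c[pop_p(k), k])
  #   cumB[p, h] = sum_{k<=h} logB[p, k]
  cumA <- matrix(0, P, K)
  cumB <- matrix(0, P, K)   # index h; column K unused
  for (pi_ in seq_len(P)) {
    cc <- cmat[cbind(pmat[pi_, ], seq_len(K))]
    cumA[pi_, ] <- cumsum(log1p(-pmin(cc, 1 - 1e-12)))
    cumB[pi_, ] <- cumsum(c(logB[pi_, seq_len(K - 1L)], 0))
  }

  # state space
  st_node <- integer(0); st_time <- integer(0); st_path <- integer(0)
  st_pidx <- integer(0)
  for (pi_ in seq_len(P)) {
    pid <- cand[pi_]
    ch <- model$paths$half[pid]
    for (v in seq_len(nnode)) {
      js <- jr[[v]]
      js <- js[js >= a_s + 1L | (js == K & a_s == K)]
      if (!length(js)) next
      ok <- pmat[pi_, js] == node_pop[v, js] &
        !model$pops$ghost[pmat[pi_, js]] &
        (if (is.na(ch)) TRUE else ch < js)
      js <- js[ok]
      if (!length(js)) next
      st_node <- c(st_node, rep(v, length(js)))
      st_time <- c(st_time, js)
      st_path <- c(st_path, rep(pid, length(js)))
      st_pidx <- c(st_pidx, rep(pi_, length(js)))
    }
  }
  S <- length(st_node)
  if (S == 0L) stop("empty threading state space (model/data mismatch)",
                    call. = FALSE)

  # walk target terms
  qj <- pmat[cbind(st_pidx, st_time)]
  H <- exp(cumA[cbind(st_pidx, st_time - 1L)] +
             cumB[cbind(st_pidx, st_time - 1L)]) *
    cmat[cbind(qj, st_time)] / m[cbind(qj, st_time)]

  lev <- diff(g)                        # level lengths (generations)
  # Gpre[p, u] = lev[u] * exp(-cumA[p, u] - cumB[p, u-1]) for u = 1..K-1
  Gpre <- matrix(0, P, K - 1L)
  for (pi_ in seq_len(P)) {
    cb0 <- c(0, cumB[pi_, seq_len(K - 2L)])
    Gpre[pi_, ] <- lev * exp(-cumA[pi_, seq_len(K - 1L)] - cb0)
  }
  SG <- cbind(0, t(apply(Gpre, 1L, cumsum)))   # SG[p, u+1] = sum_{k<=u}
  # subtract mass below the sampling age (recombination cannot occur below)
  base <- SG[, a_s, drop = TRUE]

  # first-difference index between candidate paths
  D <- matrix(K + 1L, P, P)
  if (P > 1L) for (p1 in seq_len(P - 1L)) for (p2 in (p1 + 1L):P) {
    d <- which(pmat[p1, ] != pmat[p2, ])[1]
    D[p1, p2] <- D[p2, p1] <- if (is.na(d)) K + 1L else d
  }

  ell <- g[st_time] - g[a_s]            # new-branch length per state
  pi0 <- H * exp(-cumA[cbind(st_pidx, rep(a_s, S))] -
                   (if (a_s >= 2L) cumB[cbind(st_pidx, rep(a_s - 1L, S))] else 0))

  # re-coalescence kernel Rhat[i, t]: recombination level u must lie below
  # both coalescence times and below the first index where the two paths'
  # prefixes differ; SG[p, u] accumulates the level mass weighted by the
  # walk's survival and band factors along target path p
  Dmat <- matrix(D[cbind(rep(st_pidx, times = S), rep(st_pidx, each = S))],
                 S, S)
  U <- pmin(outer(st_time, st_time, pmin), Dmat)      # [i, t]
  Ucl <- pmax(U, a_s)
  SGu <- matrix(SG[cbind(rep(st_pidx, each = S), as.vector(Ucl))], S, S)
  SGu <- SGu - matrix(base[st_pidx], S, S, byrow = TRUE)
  SGu[SGu < 0] <- 0
  Rhat <- sweep(SGu, 2L, H, `*`) / ell
  rs <- rowSums(Rhat)
  if (any(abs(rs - 1) > 1e-6))
    stop("internal error: re-coalescence kernel rows do not sum to 1",
         call. = FALSE)

  states <- list(node = st_node, time = st_time, path = st_path)
  keys <- tree_keys(tree)
  list(states = states, keys = keys[st_node],
       pi = pi0 / sum(pi0), Rhat = Rhat, ell = ell,
       a_s = a_s, cand = cand, pidx = st_pidx,
       cumA = cumA, cumB = cumB, lev = lev, D = D, SG = SG,
       mig_enabled = mig_enabled, tree = tree, lineage = lineage)
}

#' Dense transition matrix between adjacent columns
#'
#' The threading HMM transition matrix for two adjacent columns sharing a
#' local tree: with probability `exp(-r * span_bp * b)` (new branch length
#' `b` in generations) the state is retained; otherwise a recombination is
#' placed uniformly on the new branch and the detached lineage re-coalesces
#' by a discretized coalescent walk over grid times, with migration-band
#' factors `rate` / `1 - rate` applied at half time-points. Rows sum to 1.
#'
#' @param tree The fixed [local_tree()].
#' @param model A [demog_model()].
#' @param lineage Lineage being threaded.
#' @param r Recombination rate per bp per generation.
#' @param span_bp Number of base pairs between the two columns.
#' @inheritParams enumerate_states
#' @return A dense stochastic matrix over [enumerate_states()] rows.
#' @export
transition_matrix <- function(tree, model, lineage, r, span_bp,
                              max_one_migration = TRUE,
                              migration_enabled = TRUE) {
  eng <- span_engine(model, tree, lineage,
                     migration_enabled = migration_enabled,
                     max_one_migration = max_one_migration)
  p0 <- exp(-r * span_bp * eng$ell)
  diag(p0) + (1 - p0) * eng$Rhat
}

# Initial (prior) distribution over threading states.
threading_prior <- function(tree, model, lineage, ...) {
  eng <- span_engine(model, tree, lineage, ...)
  stats::setNames(eng$pi, paste(eng$keys, eng$states$time, eng$states$path))
}

#' Emission likelihoods for threading states
#'
#' Likelihood of one column's alleles given the fixed tree with the new
#' branch attached at each state, under a symmetric two-state
#' (ancestral/derived) mutation model with per-column rates, computed by
#' pruning. Missing alleles contribute likelihood 1; a fully missing column
#' has likelihood 1 in every state.
#'
#' @param tree Fixed [local_tree()].
#' @param model A [demog_model()].
#' @param lineage Lineage being threaded.
#' @param geno Lineages-by-columns 0/1/NA genotype matrix (rownames are
#'   lineage names).
#' @param mu Per-column mutation rates (per generation per column,
#'   compression-scaled).
#' @param cols Columns to evaluate (default all).
#' @param states Optional precomputed [enumerate_states()] result.
#' @return Matrix of likelihoods, states x columns.
#' @export
emission_matrix <- function(tree, model, lineage, geno, mu, cols = NULL,
                            states = NULL, ...) {
  eng <- if (is.list(states) && !is.null(states$Rhat)) states
         else span_engine(model, tree, lineage, ...)
  emission_matrix_eng(eng, model, geno, mu, cols)
}

emission_matrix_eng <- function(eng, model, geno, mu, cols = NULL) {
  tree <- eng$tree
  if (is.null(cols)) cols <- seq_len(ncol(geno))
  Lc <- length(cols)
  g <- model$grid$times_gen
  K <- model$grid$K
  n <- length(tree$parent)
  muc <- mu[cols]
  trans <- function(v0, v1, len) {
    ps <- 0.5 + 0.5 * exp(-2 * muc * len)
    list(ps * v0 + (1 - ps) * v1, ps * v1 + (1 - ps) * v0)
  }
  # upward partials
  up0 <- matrix(1, n, Lc); up1 <- matrix(1, n, Lc)
  for (v in seq_len(tree$n_leaf)) {
    a <- geno[tree$lineages[v], cols]
    up0[v, ] <- ifelse(is.na(a), 1, as.numeric(a == 0L))
    up1[v, ] <- ifelse(is.na(a), 1, as.numeric(a == 1L))
  }
  ch <- tree_children(tree)
  ordv <- order(tree$time)
  for (v in ordv) {
    if (length(ch[[v]]) != 2L) next
    a0 <- 1; a1 <- 1
    for (cc in ch[[v]]) {
      tv <- trans(up0[cc, ], up1[cc, ], g[tree$time[v]] - g[tree$time[cc]])
      a0 <- a0 * tv[[1]]; a1 <- a1 * tv[[2]]
    }
    up0[v, ] <- a0; up1[v, ] <- a1
  }
  # outside partials at the top of each branch (at the parent node),
  # including the ancestral-allele root prior
  dn0 <- matrix(0, n, Lc); dn1 <- matrix(0, n, Lc)
  root <- tree_root(tree)
  # node-level outside: O(v) = P(outside data | allele at node v)
  O0 <- matrix(0, n, Lc); O1 <- matrix(0, n, Lc)
  O0[root, ] <- 1; O1[root, ] <- 0
  for (v in rev(ordv)) {
    if (length(ch[[v]]) != 2L) next
    for (k in 1:2) {
      cc <- ch[[v]][k]; sib <- ch[[v]][3 - k]
      tv <- trans(up0[sib, ], up1[sib, ], g[tree$time[v]] - g[tree$time[sib]])
      dn0[cc, ] <- O0[v, ] * tv[[1]]
      dn1[cc, ] <- O1[v, ] * tv[[2]]
      tv2 <- trans(dn0[cc, ], dn1[cc, ], g[tree$time[v]] - g[tree$time[cc]])
      O0[cc, ] <- tv2[[1]]; O1[cc, ] <- tv2[[2]]
    }
  }
  # new-leaf partial
  lin <- model$lineages[model$lineages$lineage == eng$lineage, ]
  a <- geno[eng$lineage, cols]
  s0 <- ifelse(is.na(a), 1, as.numeric(a == 0L))
  s1 <- ifelse(is.na(a), 1, as.numeric(a == 1L))
  ga <- g[lin$age_idx]

  # emission rows are identical for states sharing (branch, time): the
  # population path affects transitions only. Compute unique pairs once.
  S <- length(eng$states$node)
  key <- paste0(eng$states$node, "_", eng$states$time)
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  un <- eng$states$node[uniq]; ut <- eng$states$time[uniq]
  new_cache <- list()
  E_u <- matrix(0, sum(uniq), Lc)
  for (s in seq_len(sum(uniq))) {
    v <- un[s]; j <- ut[s]
    low <- trans(up0[v, ], up1[v, ], g[j] - g[tree$time[v]])
    jc <- as.character(j)
    if (is.null(new_cache[[jc]]))
      new_cache[[jc]] <- trans(s0, s1, g[j] - ga)
    new <- new_cache[[jc]]
    if (v == root) {
      d0 <- 1; d1 <- 0    # prior sits at the new root
    } else {
      tv <- trans(dn0[v, ], dn1[v, ], g[tree$time[tree$parent[v]]] - g[j])
      d0 <- tv[[1]]; d1 <- tv[[2]]
    }
    E_u[s, ] <- d0 * low[[1]] * new[[1]] + d1 * low[[2]] * new[[2]]
  }
  E_u[map, , drop = FALSE]
}

#' Forward filtering with per-column scaling
#'
#' Reference implementation of the scaled forward recursion over dense
#' per-column transition matrices; used directly on small instances and as
#' the ground truth for the compiled fast path.
#'
#' @param pi Initial state distribution.
#' @param A Either a single transition matrix (time-homogeneous) or a list
#'   of `L - 1` matrices.
#' @param E States-by-columns emission likelihood matrix.
#' @return List with `alpha` (scaled forward table), `log_scale` and
#'   `loglik`.
#' @export
forward_filter <- function(pi, A, E) {
  S <- nrow(E); L <- ncol(E)
  alpha <- matrix(0, S, L)
  logs <- numeric(L)
  a <- pi * E[, 1]
  if (sum(a) <= 0) stop("zero likelihood at column 1", call. = FALSE)
  logs[1] <- log(sum(a)); alpha[, 1] <- a / sum(a)
  for (c_ in seq_len(L - 1L)) {
    Ac <- if (is.list(A)) A[[c_]] else A
    a <- as.numeric(crossprod(Ac, alpha[, c_])) * E[, c_ + 1L]
    if (sum(a) <= 0)
      stop("zero likelihood at column ", c_ + 1L, call. = FALSE)
    logs[c_ + 1L] <- log(sum(a)); alpha[, c_ + 1L] <- a / sum(a)
  }
  list(alpha = alpha, log_scale = logs, loglik = sum(logs))
}

#' Stochastic backward sampling from a forward table
#'
#' Draws one state path exactly proportional to its posterior probability,
#' by sampling the last column from the forward distribution and walking
#' backwards.
#'
#' @param ff Result of [forward_filter()].
#' @param A Transition matrix or list as in [forward_filter()].
#' @return Integer vector of sampled state indices per column.
#' @export
backward_sample <- function(ff, A) {
  alpha <- ff$alpha
  L <- ncol(alpha)
  out <- integer(L)
  out[L] <- sample.int(nrow(alpha), 1L, prob = alpha[, L])
  for (c_ in rev(seq_len(L - 1L))) {
    Ac <- if (is.list(A)) A[[c_]] else A
    w <- alpha[, c_] * Ac[, out[c_ + 1L]]
    out[c_] <- sample.int(nrow(alpha), 1L, prob = w)
  }
  out
}
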