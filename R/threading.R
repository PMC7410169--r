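# Orchestrates one threading operation: build the per-span HMM pieces,
# run forward filtering + stochastic backward sampling (compiled), and
# convert the sampled state sequence into thread() input.

sample_threading <- function(partial, model, data, lineage,
                             migration_enabled = TRUE,
                             max_one_migration = TRUE) {
  nspan <- length(partial$trees)
  engs <- vector("list", nspan)
  spans <- vector("list", nspan)
  r <- data$recomb_rate
  for (i in seq_len(nspan)) {
    eng <- span_engine(model, partial$trees[[i]], lineage,
                       migration_enabled = migration_enabled,
                       max_one_migration = max_one_migration)
    cols <- partial$starts[i]:partial$ends[i]
    E <- emission_matrix_eng(eng, model, data$geno, data$col$mu, cols)
    engs[[i]] <- eng
    spans[[i]] <- list(Rhat = eng$Rhat, E = E,
                       q = exp(-r * eng$ell),
                       w = as.numeric(data$col$nbases[cols]))
  }
  bmats <- vector("list", max(nspan - 1L, 0L))
  ids <- lapply(engs, function(e)
    paste(e$keys, e$states$time, e$states$path))
  if (nspan > 1L) for (i in seq_len(nspan - 1L)) {
    S1 <- length(ids[[i]]); S2 <- length(ids[[i + 1L]])
    B <- matrix(0, S1, S2)
    hit <- match(ids[[i]], ids[[i + 1L]])
    for (s in seq_len(S1)) {
      if (is.na(hit[s])) B[s, ] <- engs[[i + 1L]]$pi
      else B[s, hit[s]] <- 1
    }
    bmats[[i]] <- B
  }
  res <- ffbs_cpp(spans, engs[[1]]$pi, bmats)

  # collapse the sampled per-column states into runs and record
  # recombination times at within-span state changes
  L <- partial$n_col
  id_all <- character(L); key_all <- character(L)
  time_all <- integer(L); path_all <- integer(L)
  idx_all <- integer(L); span_all <- integer(L)
  for (i in seq_len(nspan)) {
    idx <- res$states[[i]]
    eng <- engs[[i]]
    cols <- partial$starts[i]:partial$ends[i]
    id_all[cols] <- ids[[i]][idx]
    key_all[cols] <- eng$keys[idx]
    time_all[cols] <- eng$states$time[idx]
    path_all[cols] <- eng$states$path[idx]
    idx_all[cols] <- idx
    span_all[cols] <- i
  }
  run_start <- c(1L, which(id_all[-1] != id_all[-L]) + 1L)
  run_end <- c(run_start[-1] - 1L, L)
  states <- tibble::tibble(
    start = run_start, end = run_end,
    target_key = key_all[run_start],
    coal_time = time_all[run_start],
    path = path_all[run_start])
  rec_col <- run_start[-1][span_all[run_start[-1]] ==
                             span_all[run_start[-1] - 1L]]
  recombs <- tibble::tibble(
    col = rec_col,
    rec_time = vapply(rec_col, function(cc)
      sample_recomb_time(engs[[span_all[cc]]], idx_all[cc - 1L],
                         idx_all[cc]), integer(1)))
  list(states = states, recombs = recombs, loglik = res$loglik)
}

# Sample the recombination grid level u for a transition i -> t, conditional
# on the re-coalescence target: weights lev[u] * exp(-cumA[p_t, u] -
# cumB[p_t, u - 1]) over u in [a_s, min(j_i, j_t, D) - 1].
sample_recomb_time <- function(eng, i, t) {
  p_t <- eng$pidx[t]
  Umax <- min(eng$states$time[i], eng$states$time[t],
              eng$D[eng$pidx[i], p_t]) - 1L
  us <- seq.int(eng$a_s, max(Umax, eng$a_s))
  cumB0 <- c(0, eng$cumB[p_t, ])
  w <- eng$lev[us] * exp(-eng$cumA[p_t, us] - cumB0[us])
  if (all(w <= 0)) return(us[1])
  us[sample.int(length(us), 1L, prob = w)]
}

# Thread a lineage into a partial ARG by sampling from the threading HMM.
thread_sample <- function(partial, model, data, lineage,
                          migration_enabled = TRUE) {
  s <- sample_threading(partial, model, data, lineage,
                        migration_enabled = migration_enabled)
  arg <- thread(partial, model, lineage, s$states, s$recombs)
  attr(arg, "loglik") <- s$loglik
  arg
}
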