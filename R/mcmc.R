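#' Initialize an ARG by sequential threading
#'
#' Lineages are threaded one at a time in input order with migrant states
#' disabled, giving a valid migration-free starting ARG for the chain.
#'
#' @param data An [arg_data()] object.
#' @param model A [demog_model()].
#' @return A valid [new_arg()] with zero migrant branches.
#' @export
initialize_arg <- function(data, model) {
  lins <- model$lineages$lineage
  stopifnot(all(lins %in% rownames(data$geno)))
  arg <- single_lineage_arg(model, lins[1], ncol(data$geno))
  for (ln in lins[-1])
    arg <- thread_sample(arg, model, data, ln, migration_enabled = FALSE)
  arg
}

# Randomize haplotype phase of unphased diploid individuals: at each
# heterozygous column the two alleles are assigned to the individual's two
# lineages with probability 1/2 each.
randomize_phase <- function(geno, model) {
  dip <- model$samples[model$samples$ploidy == 2L & !model$samples$phased, ]
  for (sid in dip$sample_id) {
    l1 <- paste0(sid, "_1"); l2 <- paste0(sid, "_2")
    het <- which(!is.na(geno[l1, ]) & !is.na(geno[l2, ]) &
                   geno[l1, ] != geno[l2, ])
    flip <- het[stats::runif(length(het)) < 0.5]
    tmp <- geno[l1, flip]
    geno[l1, flip] <- geno[l2, flip]
    geno[l2, flip] <- tmp
  }
  geno
}

#' Resample haplotype phase for one unphased diploid
#'
#' At each heterozygous column of the individual, the assignment of the two
#' alleles to the individual's two haploid lineages is redrawn by a Gibbs
#' step, proportional to the column likelihood of the current local tree
#' under each assignment. Homozygous and missing columns are unchanged, and
#' phased individuals are a no-op.
#'
#' @param arg The current [new_arg()].
#' @param model A [demog_model()].
#' @param data An [arg_data()] object holding the current genotype phase.
#' @param individual Sample id of the diploid.
#' @return The `arg_data` object with an updated genotype matrix (identical
#'   for phased or haploid individuals).
#' @export
resample_phase <- function(arg, model, data, individual) {
  data$geno <- resample_phase_cols(arg, model, data$geno, data$col$mu,
                                   individual)
  data
}

resample_phase_cols <- function(arg, model, geno, mu, individual) {
  row <- model$samples[model$samples$sample_id == individual, ]
  if (nrow(row) != 1L || row$ploidy != 2L || row$phased) return(geno)
  l1 <- paste0(individual, "_1"); l2 <- paste0(individual, "_2")
  het <- which(!is.na(geno[l1, ]) & !is.na(geno[l2, ]) &
                 geno[l1, ] != geno[l2, ])
  if (!length(het)) return(geno)
  span_of <- findInterval(het, arg$starts)
  swapped <- geno
  swapped[c(l1, l2), ] <- geno[c(l2, l1), ]
  for (sp in unique(span_of)) {
    cols <- het[span_of == sp]
    lik1 <- tree_column_likelihood(model, arg$trees[[sp]], geno, mu, cols)
    lik2 <- tree_column_likelihood(model, arg$trees[[sp]], swapped, mu, cols)
    pr <- lik2 / (lik1 + lik2)
    pr[!is.finite(pr)] <- 0.5
    do_swap <- cols[stats::runif(length(cols)) < pr]
    tmp <- geno[l1, do_swap]
    geno[l1, do_swap] <- geno[l2, do_swap]
    geno[l2, do_swap] <- tmp
  }
  geno
}

#' Run the ARG sampling chain
#'
#' A Gibbs-style MCMC over ARGs: each iteration removes and rethreads every
#' haploid lineage once (unthread/thread with the threading HMM), with
#' optional phase integration for unphased diploids. Migrant states are
#' disabled for the first `start_mig` iterations so the chain can establish
#' a sound tree structure before exploring migration. After `burnin`
#' iterations, every `thin`-th iteration is retained as a posterior sample.
#'
#' @param data An [arg_data()] object.
#' @param model A [demog_model()].
#' @param n_iter Total iterations (published-schedule default 2000).
#' @param burnin Iterations discarded before sampling (default 500).
#' @param thin Sampling interval after burnin (default 20).
#' @param start_mig Iterations with migration disabled at the start
#'   (default 100).
#' @param seed Random seed; identical inputs and seed give a byte-identical
#'   sample stream.
#' @param phase_integration Resample haplotype phase of unphased diploids
#'   during the sweep (default TRUE). Phase is randomized up front.
#' @param keep_args Keep the full sampled ARGs (memory-heavy); migrant
#'   tracts per band and lineage are always kept.
#' @param verbose Print progress.
#' @return An object of class `arg_chain`: list with `samples` (one element
#'   per retained iteration: `iter`, `tracts` tibble, optionally `arg`),
#'   `stats` (tibble: iteration, log-likelihood, migrant columns per band),
#'   `model`, `data`, `config`, and the final `arg` and genotype phase.
#' @export
run_chain <- function(data, model, n_iter = 2000, burnin = 500, thin = 20,
                      start_mig = 100, seed = 1, phase_integration = TRUE,
                      keep_args = FALSE, verbose = FALSE) {
  stopifnot(n_iter >= 1, burnin >= 0, thin >= 1, burnin <= n_iter)
  set.seed(seed)
  geno <- data$geno
  if (phase_integration) geno <- randomize_phase(geno, model)
  dat <- data
  dat$geno <- geno
  arg <- initialize_arg(dat, model)

  lins <- model$lineages
  bands <- model$bands$band
  samples <- list()
  stats <- list()
  for (iter in seq_len(n_iter)) {
    mig_on <- iter > start_mig
    for (k in seq_len(nrow(lins))) {
      ln <- lins$lineage[k]
      u <- unthread(arg, model, ln)
      arg <- thread_sample(u$partial, model, dat, ln,
                           migration_enabled = mig_on)
      if (phase_integration) {
        sid <- lins$sample_id[k]
        dat$geno <- resample_phase_cols(arg, model, dat$geno, dat$col$mu, sid)
      }
    }
    tracts <- chain_tracts(arg, model)
    mig_cols <- vapply(seq_along(bands), function(b) {
      tr <- tracts[tracts$band == bands[b], ]
      if (!nrow(tr)) 0L else sum(tr$end - tr$start + 1L)
    }, integer(1))
    stats[[iter]] <- tibble::tibble(
      iteration = iter,
      loglik = arg_loglik(arg, model, dat),
      !!!stats::setNames(as.list(mig_cols),
                         if (length(bands)) paste0("mig_", bands)
                         else character(0)))
    if (iter > burnin && (iter - burnin) %% thin == 0) {
      rec <- list(iter = iter, tracts = tracts)
      if (keep_args) rec$arg <- arg
      samples[[length(samples) + 1L]] <- rec
    }
    if (verbose && iter %% 10 == 0)
      message("iteration ", iter, " / ", n_iter)
  }
  structure(list(
    samples = samples,
    stats = dplyr::bind_rows(stats),
    model = model, data = dat,
    config = list(n_iter = n_iter, burnin = burnin, thin = thin,
                  start_mig = start_mig, seed = seed,
                  phase_integration = phase_integration),
    arg = arg
  ), class = "arg_chain")
}

# Migrant tracts for every (band, lineage) of the current ARG.
chain_tracts <- function(arg, model) {
  out <- list()
  for (b in seq_len(nrow(model$bands))) {
    for (ln in arg$lineages) {
      tr <- migrant_tracts(arg, model, b, ln)
      if (nrow(tr))
        out[[length(out) + 1L]] <- tibble::tibble(
          band = model$bands$band[b], lineage = ln,
          start = tr$start, end = tr$end)
    }
  }
  if (!length(out))
    return(tibble::tibble(band = character(), lineage = character(),
                          start = integer(), end = integer()))
  dplyr::bind_rows(out)
}

#' @export
print.arg_chain <- function(x, ...) {
  cat("<arg_chain>", x$config$n_iter, "iterations,",
      length(x$samples), "retained samples\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration chain statistics
#'
#' @param x An `arg_chain`.
#' @param ... Unused.
#' @return Tibble with iteration, log-likelihood and migrant column counts
#'   per band.
#' @export
tidy.arg_chain <- function(x, ...) x$stats

#' One-row chain summary
#'
#' @param x An `arg_chain`.
#' @param ... Unused.
#' @export
glance.arg_chain <- function(x, ...) {
  post <- x$stats[x$stats$iteration > x$config$burnin, ]
  tibble::tibble(
    n_iter = x$config$n_iter,
    burnin = x$config$burnin,
    n_samples = length(x$samples),
    mean_loglik = mean(post$loglik),
    seed = x$config$seed
  )
}
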