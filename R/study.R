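#' Run the sampler and call introgressed regions in one step
#'
#' Convenience wrapper around [run_chain()], [posterior_tracks()] and
#' [call_regions()]: runs the chain, then produces region calls for every
#' (migration band, diploid individual) pair.
#'
#' @inheritParams run_chain
#' @param threshold Posterior probability threshold for calls (default 0.5).
#' @param ... Passed to [run_chain()].
#' @return List with `chain` (the `arg_chain`), `calls` (tibble over all
#'   bands and diploid individuals) and `tracks` (named list of posterior
#'   tracks).
#' @export
introgression_scan <- function(data, model, threshold = 0.5, ...) {
  chain <- run_chain(data, model, ...)
  calls <- list(); tracks <- list()
  dips <- model$samples$sample_id[model$samples$ploidy == 2L]
  for (b in model$bands$band) for (ind in dips) {
    tr <- posterior_tracks(chain, b, ind)
    tracks[[paste(b, ind, sep = ".")]] <- tr
    calls[[length(calls) + 1L]] <- call_regions(tr, threshold = threshold)
  }
  list(chain = chain,
       calls = dplyr::bind_rows(calls),
       tracks = tracks)
}

#' One replicate of the simulation study
#'
#' Simulates a dataset with truth tracts under `sim_model`, degrades it
#' (random phase), and analyzes it with `infer_model`, returning calls and
#' truth in base-pair coordinates ready for [basewise_rates()].
#'
#' @param sim_model Model used to generate the data.
#' @param infer_model Model assumed by the sampler (defaults to
#'   `sim_model`).
#' @param admixture Pulse admixture truth (see [simulate_dataset()]).
#' @param window_bp Window length.
#' @param seed Seed for this replicate (drives simulation, degradation and
#'   the chain).
#' @param n_iter,burnin,thin,start_mig Chain schedule.
#' @param threshold Posterior call threshold.
#' @return List with `calls`, `truth`, `scan` and the `dataset`.
#' @export
study_replicate <- function(sim_model, admixture, window_bp, seed,
                            infer_model = sim_model,
                            n_iter = 36, burnin = 12, thin = 3,
                            start_mig = 6, threshold = 0.5) {
  sd <- simulate_dataset(sim_model, window_bp, admixture, seed = seed)
  sd <- degrade(sd, phase_randomize = TRUE, seed = seed + 1L)
  dat <- as_arg_data(sd)
  scan <- introgression_scan(dat, infer_model, threshold = threshold,
                             n_iter = n_iter, burnin = burnin, thin = thin,
                             start_mig = start_mig, seed = seed + 2L)
  list(calls = scan$calls, truth = sd$truth, scan = scan, dataset = sd)
}
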