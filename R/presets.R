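#' Hominin demographic model for deep-introgression analysis
#'
#' The population model used throughout the deep-introgression analyses:
#' modern humans (African), two Neanderthals and a Denisovan, a
#' "super-archaic" ghost population, and a haploid chimpanzee outgroup, on
#' the default 20-point time grid. Denisovans merge with Neanderthals at
#' 415 kya, archaics with humans at 575 kya, the super-archaic lineage at
#' `t_div`, and the outgroup at 6 Mya (all snapped to half time-points).
#' "Old migration" bands are placed at `t_mig`: Hum→Nea, Sup→Den and
#' Sup→Afr, plus two control bands (Sup→Nea, Hum→Den), all with prior rate
#' `mig_prior`.
#'
#' The African size is 23,700. Per-branch archaic size histories are not
#' part of the published model in usable form; this preset ships a
#' simplified three-epoch stand-in for each archaic branch (documented in
#' the methods vignette). The super-archaic size only matters for
#' simulation, never for inference (ghost population).
#'
#' @param t_mig Migration time in years (half time-point; 50/150/250/350 kya
#'   are natural choices; default 250 kya).
#' @param t_div Super-archaic divergence time in years (1 or 1.5 Mya).
#' @param n_afr Number of African diploid individuals (default 2).
#' @param n_nea Number of Neanderthal diploids (default 2: ages 115 and
#'   52 ky).
#' @param include_controls Include the Sup→Nea and Hum→Den control bands.
#' @param mig_prior Prior migration probability per band (default 0.01).
#' @param bands Which band set to include: `"old"` (default) or `"none"`.
#' @param grid Time grid (default [default_time_grid()]).
#' @return A [demog_model()] with a `growth` attribute unset.
#' @export
hominin_deep_model <- function(t_mig = 250e3, t_div = 1e6, n_afr = 2,
                               n_nea = 2, include_controls = TRUE,
                               mig_prior = 0.01, bands = c("old", "none"),
                               grid = default_time_grid()) {
  bands <- match.arg(bands)
  populations <- data.frame(
    name = c("Afr", "Nea", "Den", "Sup", "Chimp"),
    parent = c(NA, "Afr", "Nea", "Afr", "Afr"),
    div_time = c(NA, 575e3, 415e3, t_div, 6e6),
    ghost = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  sizes <- data.frame(
    population = c("Afr", "Afr",
                   "Nea", "Nea", "Nea",
                   "Den", "Den", "Den",
                   "Sup", "Chimp"),
    time = c(0, 575e3,
             0, 100e3, 300e3,
             0, 100e3, 300e3,
             0, 0),
    size = c(23700, 18500,
             1200, 2700, 3400,
             1500, 2500, 5000,
             13000, 30000)
  )
  # shared Neanderthal/Denisovan ancestor (415-575 kya) on the Nea branch
  sizes <- rbind(sizes,
                 data.frame(population = "Nea", time = 415e3, size = 3800))
  band_tbl <- NULL
  if (bands == "old") {
    band_tbl <- data.frame(
      source = c("Afr", "Sup", "Sup"),
      dest = c("Nea", "Den", "Afr"),
      time = t_mig, rate = mig_prior
    )
    if (include_controls)
      band_tbl <- rbind(band_tbl, data.frame(
        source = c("Sup", "Afr"), dest = c("Nea", "Den"),
        time = t_mig, rate = mig_prior))
  }
  samples <- data.frame(
    sample_id = c(if (n_afr > 0) paste0("Afr", seq_len(n_afr)),
                  if (n_nea >= 1) "NeaA", if (n_nea >= 2) "NeaV",
                  "Den1", "Chimp"),
    population = c(rep("Afr", n_afr), rep("Nea", min(n_nea, 2)),
                   "Den", "Chimp"),
    age = c(rep(0, n_afr), c(115e3, 52e3)[seq_len(min(n_nea, 2))],
            72e3, 0),
    ploidy = c(rep(2L, n_afr + min(n_nea, 2) + 1L), 1L),
    phased = FALSE
  )
  demog_model(populations, sizes, samples, band_tbl, grid = grid)
}

#' Pulse-admixture truth configuration for the deep-introgression study
#'
#' The three simulated migration events: Hum→Nea at 8%, Sup→Den at 4% and
#' Sup→Afr at 0.5%, all at `t_mig`.
#'
#' @param t_mig Migration time in years.
#' @param rates Named proportions (defaults 0.08 / 0.04 / 0.005).
#' @return Tibble usable as the `admixture` argument of
#'   [simulate_dataset()].
#' @export
deep_admixture <- function(t_mig = 250e3,
                           rates = c(hum_nea = 0.08, sup_den = 0.04,
                                     sup_afr = 0.005)) {
  tibble::tibble(
    source = c("Afr", "Sup", "Sup"),
    dest = c("Nea", "Den", "Afr"),
    time = t_mig,
    proportion = as.numeric(rates[c("hum_nea", "sup_den", "sup_afr")])
  )
}

#' Recent Neanderthal-into-human simulation preset
#'
#' The recent-introgression study design: African lineages plus Europeans
#' whose population split from Africans 100 kya with an initial size of
#' 2,100 and grew exponentially at rate 0.002 per generation from 42 kya to
#' a present size of 37,236; 2% Neanderthal→European admixture at 50 kya,
#' optionally with 5% human→Neanderthal admixture at 250 kya. Returns both
#' the simulation model (with the European population and growth) and the
#' inference model (all humans panmictic, a single Nea→Hum recent migration
#' band), plus the admixture truth table.
#'
#' @param n_afr_hap Number of haploid African lineages (full-study default
#'   86; scale down for desk-size runs).
#' @param n_eur Number of European diploid individuals (default 2, i.e. 4
#'   haploid lineages), phased.
#' @param include_hum_to_nea Also simulate the 5% Hum→Nea pulse at 250 kya.
#' @param mig_prior Prior migration rate for the inference band.
#' @param grid Time grid.
#' @return List with `sim_model`, `infer_model`, `admixture`.
#' @export
nea_to_hum_config <- function(n_afr_hap = 86, n_eur = 2,
                              include_hum_to_nea = FALSE,
                              mig_prior = 0.01,
                              grid = default_time_grid()) {
  arch_sizes <- data.frame(
    population = c("Nea", "Nea", "Nea", "Nea", "Chimp"),
    time = c(0, 100e3, 300e3, 415e3, 0),
    size = c(1200, 2700, 3400, 3800, 30000))
  sim_pops <- data.frame(
    name = c("Afr", "Eur", "Nea", "Chimp"),
    parent = c(NA, "Afr", "Afr", "Afr"),
    div_time = c(NA, 100e3, 575e3, 6e6),
    ghost = FALSE)
  sim_sizes <- rbind(
    data.frame(population = c("Afr", "Afr"), time = c(0, 575e3),
               size = c(23700, 18500)),
    data.frame(population = c("Eur", "Eur"), time = c(0, 42e3),
               size = c(37236, 2100)),
    arch_sizes)
  samples_sim <- data.frame(
    sample_id = c(paste0("AfrH", seq_len(n_afr_hap)),
                  paste0("Eur", seq_len(n_eur)), "NeaA", "NeaV", "Chimp"),
    population = c(rep("Afr", n_afr_hap), rep("Eur", n_eur),
                   "Nea", "Nea", "Chimp"),
    age = c(rep(0, n_afr_hap + n_eur), 115e3, 52e3, 0),
    ploidy = c(rep(1L, n_afr_hap), rep(2L, n_eur), 2L, 2L, 1L),
    phased = TRUE
  )
  sim_model <- demog_model(sim_pops, sim_sizes, samples_sim, NULL,
                           grid = grid, snap_times = FALSE)
  attr(sim_model, "growth") <- tibble::tibble(
    population = "Eur", rate = 0.002, end_time = 42e3)

  infer_pops <- data.frame(
    name = c("Afr", "Nea", "Chimp"),
    parent = c(NA, "Afr", "Afr"),
    div_time = c(NA, 575e3, 6e6),
    ghost = FALSE)
  infer_sizes <- rbind(
    data.frame(population = c("Afr", "Afr"), time = c(0, 575e3),
               size = c(23700, 18500)),
    arch_sizes)
  samples_inf <- samples_sim
  samples_inf$population[samples_inf$population == "Eur"] <- "Afr"
  infer_bands <- data.frame(source = "Nea", dest = "Afr", time = 50e3,
                            rate = mig_prior)
  if (include_hum_to_nea)
    infer_bands <- rbind(infer_bands,
                         data.frame(source = "Afr", dest = "Nea",
                                    time = 250e3, rate = mig_prior))
  infer_model <- demog_model(infer_pops, infer_sizes, samples_inf,
                             infer_bands, grid = grid)
  admixture <- tibble::tibble(
    source = "Nea", dest = "Eur", time = 50e3, proportion = 0.02)
  if (include_hum_to_nea)
    admixture <- dplyr::bind_rows(admixture, tibble::tibble(
      source = "Afr", dest = "Nea", time = 250e3, proportion = 0.05))
  list(sim_model = sim_model, infer_model = infer_model,
       admixture = admixture)
}
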