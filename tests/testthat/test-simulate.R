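# The coalescent simulator with truth tracts, and dataset degradation.

# Large recipient population and a young pulse: sampled lineages rarely
# coalesce before the pulse, so the truth-tract fraction estimates the pulse
# proportion with near-binomial error.
calib_model <- function() {
  demog_model(
    populations = data.frame(name = c("A", "B"), parent = c(NA, "A"),
                             div_time = c(NA, 600e3)),
    sizes = data.frame(population = c("A", "B"), size = c(20000, 20000)),
    samples = data.frame(sample_id = paste0("b", 1:8), population = "B",
                         ploidy = 1L),
    bands = data.frame(source = "A", dest = "B", time = 50e3, rate = 0.01),
    grid = time_grid(c(0, 100e3, 300e3, 500e3, 700e3, 900e3))
  )
}

test_that("truth-tract fraction estimates the pulse proportion", {
  m <- calib_model()
  adm <- tibble::tibble(source = "A", dest = "B", time = 50e3,
                        proportion = 0.25)
  tot <- 0; reps <- 8; L <- 100e3; nl <- 8
  for (s in seq_len(reps)) {
    sd <- simulate_dataset(m, L, adm, seed = 100 + s)
    tot <- tot + sum(sd$truth$end - sd$truth$start)
  }
  frac <- tot / (reps * L * nl)
  # block-correlated draws: allow 3 SE with a conservative effective count
  # of one draw per lineage per replicate
  se <- sqrt(0.25 * 0.75 / (reps * nl))
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("zero admixture gives no truth tracts and matches a no-pulse run", {
  m <- calib_model()
  adm0 <- tibble::tibble(source = "A", dest = "B", time = 50e3,
                         proportion = 0)
  sd0 <- simulate_dataset(m, 50e3, adm0, seed = 42)
  expect_equal(nrow(sd0$truth), 0L)
  sd_none <- simulate_dataset(m, 50e3, adm0[0, ], seed = 42)
  expect_equal(sd0$positions, sd_none$positions)
  expect_equal(sd0$alleles, sd_none$alleles)
})

test_that("pairwise diversity in a constant-size population matches 4 N mu", {
  m <- demog_model(
    populations = data.frame(name = "A", parent = NA, div_time = NA),
    sizes = data.frame(population = "A", size = 10000),
    samples = data.frame(sample_id = c("s1", "s2"), population = "A",
                         ploidy = 1L),
    grid = time_grid(c(0, 100e3, 1500e3))
  )
  mu <- 1.45e-8; L <- 300e3
  diffs <- 0; reps <- 4
  for (s in seq_len(reps)) {
    sd <- simulate_dataset(m, L, tibble::tibble()[0, ], mut_rate = mu,
                           seed = 200 + s)
    diffs <- diffs + sum(sd$alleles[1, ] != sd$alleles[2, ])
  }
  pi_hat <- diffs / (reps * L)
  expect_equal(pi_hat, 4 * 10000 * mu, tolerance = 0.25)
})

test_that("the deep-introgression preset has the published sampling design", {
  m <- hominin_deep_model()  # 5 unphased diploids + haploid outgroup
  expect_equal(nrow(m$samples), 6L)
  expect_equal(sum(m$samples$ploidy == 2L), 5L)
  expect_equal(nrow(m$lineages), 11L)
  expect_equal(sort(unique(m$samples$age)),
               sort(unique(c(0, 52e3, 72e3, 115e3))))
  sd <- simulate_dataset(m, 30e3, deep_admixture(), seed = 5)
  expect_equal(length(sd$lineages), 11L)
  expect_true(all(sd$truth$end <= 30e3))
  adm <- deep_admixture()
  expect_equal(adm$proportion, c(0.08, 0.04, 0.005))
})

test_that("degradation randomizes phase but preserves unordered genotypes", {
  m <- hominin_deep_model(n_afr = 1)
  sd <- simulate_dataset(m, 30e3, deep_admixture(), seed = 7)
  dg <- degrade(sd, phase_randomize = TRUE, seed = 3)
  for (sid in c("Afr1", "NeaA", "Den1")) {
    l1 <- paste0(sid, "_1"); l2 <- paste0(sid, "_2")
    for (i in seq_along(sd$positions))
      expect_setequal(unname(dg$alleles[c(l1, l2), i]),
                      unname(sd$alleles[c(l1, l2), i]))
  }
  # no masks + phased flag: identity
  m2 <- calib_model()
  sd2 <- simulate_dataset(m2, 20e3,
                          tibble::tibble(source = "A", dest = "B",
                                         time = 50e3, proportion = 0.1),
                          seed = 9)
  expect_equal(degrade(sd2, phase_randomize = TRUE, seed = 1)$alleles,
               sd2$alleles)  # all samples haploid: nothing to randomize
})

test_that("masks set the covered region to missing", {
  m <- calib_model()
  sd <- simulate_dataset(m, 20e3, tibble::tibble()[0, ], seed = 13)
  dg <- degrade(sd, phase_randomize = FALSE,
                masks = tibble::tibble(lineage = "b1", start = 0,
                                       end = 20e3))
  expect_true(all(is.na(dg$alleles["b1", ])))
  expect_true(all(!is.na(dg$alleles["b2", ])))
  dat <- as_arg_data(dg)
  expect_true(all(is.na(dat$geno["b1", ])))
  expect_error(degrade(sd, masks = tibble::tibble(lineage = "b1",
                                                  start = 0, end = 30e3)),
               "outside")
})

test_that("the recent Nea-to-human preset encodes the growth model", {
  cfg <- nea_to_hum_config(n_afr_hap = 4, n_eur = 1)
  expect_equal(attr(cfg$sim_model, "growth")$rate, 0.002)
  sz <- cfg$sim_model$sizes
  expect_equal(sz$size[sz$population == "Eur" & sz$time == 0], 37236)
  expect_equal(sz$size[sz$population == "Eur" & sz$time == 42e3], 2100)
  # without the optional pulse there is a single admixture event
  expect_equal(nrow(cfg$admixture), 1L)
  expect_equal(cfg$admixture$proportion, 0.02)
  expect_equal(cfg$admixture$time, 50e3)
  # the optional ancient human-to-Neanderthal pulse
  cfg2 <- nea_to_hum_config(n_afr_hap = 4, n_eur = 1,
                            include_hum_to_nea = TRUE)
  expect_equal(nrow(cfg2$admixture), 2L)
  expect_equal(cfg2$admixture$proportion[2], 0.05)
  expect_equal(cfg2$admixture$time[2], 250e3)
  # scaling down the sample sizes preserves event times and proportions
  big <- nea_to_hum_config()
  expect_equal(big$admixture, cfg$admixture)
  expect_equal(nrow(big$sim_model$samples), 86 + 2 + 2 + 1)
  # the inference model pools all humans into one population
  expect_false("Eur" %in% cfg$infer_model$pop_names)
  expect_equal(nrow(cfg$infer_model$bands), 1L)
  # a small simulated dataset runs end to end
  sd <- simulate_dataset(cfg$sim_model, 20e3, cfg$admixture, seed = 17)
  expect_equal(length(sd$lineages), 4 + 2 + 4 + 1)
})
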