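# The Gibbs chain: initialization, schedule arithmetic, determinism,
# migration gating, and phase integration.

chain_fixture <- function(...) {
  m <- toy_two_pop(samples = data.frame(
    sample_id = c("a1", "a2", "b1"), population = c("A", "A", "B"),
    ploidy = 1L))
  dat <- toy_data(m, window_bp = 1000, positions = c(55L, 333L, 800L))
  list(model = m, data = dat)
}

test_that("sequential initialization yields a valid, migration-free ARG", {
  fx <- chain_fixture()
  set.seed(13)
  arg <- initialize_arg(fx$data, fx$model)
  expect_true(validate_arg(arg, fx$model)$ok)
  for (tr in arg$trees)
    expect_equal(argthreader:::tree_migrant_count(fx$model, tr), 0L)
  # identical seeds give identical initial ARGs
  set.seed(13)
  arg2 <- initialize_arg(fx$data, fx$model)
  expect_equal(arg2, arg)
})

test_that("the sampling schedule retains the right iterations", {
  fx <- chain_fixture()
  ch <- run_chain(fx$data, fx$model, n_iter = 12, burnin = 4, thin = 2,
                  start_mig = 2, seed = 3, phase_integration = FALSE)
  expect_equal(length(ch$samples), 4L)  # iterations 6, 8, 10, 12
  expect_equal(vapply(ch$samples, `[[`, numeric(1), "iter"),
               c(6, 8, 10, 12))
  # the published schedule (2000 iterations, burn-in 500, thinning 20)
  # retains 75 samples under the same rule
  iters <- seq_len(2000)
  expect_equal(sum(iters > 500 & (iters - 500) %% 20 == 0), 75L)
  # n_iter == burnin leaves no samples
  ch0 <- run_chain(fx$data, fx$model, n_iter = 3, burnin = 3, thin = 1,
                   start_mig = 0, seed = 3, phase_integration = FALSE)
  expect_equal(length(ch0$samples), 0L)
})

test_that("migration stays disabled before start_mig and with start_mig
           beyond the chain length", {
  fx <- chain_fixture()
  ch <- run_chain(fx$data, fx$model, n_iter = 6, burnin = 1, thin = 1,
                  start_mig = 100, seed = 5, phase_integration = FALSE)
  for (s in ch$samples) expect_equal(nrow(s$tracts), 0L)
  expect_true(all(ch$stats$mig_A_to_B == 0))
})

test_that("every retained sample passes tree validation on every interval", {
  fx <- chain_fixture()
  ch <- run_chain(fx$data, fx$model, n_iter = 8, burnin = 2, thin = 2,
                  start_mig = 2, seed = 11, phase_integration = FALSE,
                  keep_args = TRUE)
  for (s in ch$samples)
    expect_true(validate_arg(s$arg, fx$model)$ok)
})

test_that("chains are byte-reproducible for identical seeds", {
  fx <- chain_fixture()
  ch1 <- run_chain(fx$data, fx$model, n_iter = 6, burnin = 2, thin = 1,
                   start_mig = 2, seed = 21)
  ch2 <- run_chain(fx$data, fx$model, n_iter = 6, burnin = 2, thin = 1,
                   start_mig = 2, seed = 21)
  expect_equal(ch1$samples, ch2$samples)
  expect_equal(ch1$stats, ch2$stats)
  expect_identical(serialize(ch1$arg, NULL), serialize(ch2$arg, NULL))
  ch3 <- run_chain(fx$data, fx$model, n_iter = 6, burnin = 2, thin = 1,
                   start_mig = 2, seed = 22)
  expect_false(identical(ch1$stats, ch3$stats))
})

test_that("with all data missing the chain samples migrant trees at the
           band-prior rate", {
  # start_mig = 0 and uniform emissions: the long-run fraction of sampled
  # trees containing a migrant branch must match the prior expectation of
  # the threading chain, computed exactly by enumeration on the same
  # two-lineage instance
  m <- toy_two_pop(rate = 0.1)
  dat <- toy_missing_data(m, n_col = 3L)
  pa <- find_path(m, 1L)
  tr <- local_tree(0L, 1L, pa, "a1")
  hmm <- dense_hmm(m, tr, "b1", dat)
  or <- enumerate_hmm(hmm$pi, hmm$A, hmm$E)
  mig_states <- !is.na(m$paths$half[hmm$eng$states$path])
  # P(any column migrant) over full state paths
  p_any_mig <- sum(or$weights[apply(
    matrix(mig_states[or$paths], nrow(or$paths)), 1L, any)])
  ch <- run_chain(dat, m, n_iter = 320, burnin = 20, thin = 1,
                  start_mig = 0, seed = 37, phase_integration = FALSE)
  frac <- mean(vapply(ch$samples, function(s) nrow(s$tracts) > 0,
                      logical(1)))
  # autocorrelated draws: allow 3 SE at a conservative effective size
  n_eff <- length(ch$samples) / 4
  se <- sqrt(p_any_mig * (1 - p_any_mig) / n_eff)
  expect_lt(abs(frac - p_any_mig), 3 * se)
})

test_that("phase resampling only touches heterozygous columns of unphased
           diploids", {
  m <- toy_two_pop(samples = data.frame(
    sample_id = c("a1", "b1"), population = c("A", "B"),
    ploidy = c(1L, 2L), phased = c(TRUE, FALSE)))
  lins <- m$lineages$lineage
  alleles <- matrix(c(0L, 1L, 1L,
                      1L, 0L, 0L,
                      1L, 1L, 0L), 3, 3, byrow = FALSE,
                    dimnames = list(lins, NULL))
  dat <- compress_sites(lins, c(100L, 300L, 500L), alleles, 700)
  set.seed(2)
  arg <- initialize_arg(dat, m)
  vcols <- which(dat$col$variant)
  hom <- vcols[dat$geno["b1_1", vcols] == dat$geno["b1_2", vcols]]
  set.seed(9)
  upd <- resample_phase(arg, m, dat, "b1")
  # homozygous columns unchanged; unordered genotype invariant everywhere
  expect_equal(upd$geno[, hom], dat$geno[, hom])
  for (cc in vcols)
    expect_setequal(unname(upd$geno[c("b1_1", "b1_2"), cc]),
                    unname(dat$geno[c("b1_1", "b1_2"), cc]))
  # phased individuals are a no-op
  expect_equal(resample_phase(arg, m, dat, "a1")$geno, dat$geno)
})

test_that("symmetric data yield a 50/50 long-run phase assignment", {
  m <- toy_two_pop(samples = data.frame(
    sample_id = c("a1", "b1"), population = c("A", "B"),
    ploidy = c(1L, 2L), phased = c(TRUE, FALSE)))
  lins <- m$lineages$lineage
  # b1 heterozygous at one site, a1 missing: the two assignments are
  # exchangeable, so the Gibbs flip should pick each with probability 1/2
  alleles <- matrix(c(NA_integer_, 0L, 1L), 3, 1,
                    dimnames = list(lins, NULL))
  dat <- compress_sites(lins, 350L, alleles, 700)
  set.seed(4)
  arg <- initialize_arg(dat, m)
  cc <- which(dat$col$variant)
  set.seed(31)
  n <- 2000
  ones <- 0
  cur <- dat
  for (k in seq_len(n)) {
    cur <- resample_phase(arg, m, cur, "b1")
    ones <- ones + (cur$geno["b1_1", cc] == 1L)
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(ones / n - 0.5), 3 * se)
})
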