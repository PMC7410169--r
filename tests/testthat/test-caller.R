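# Posterior tracks, region calls, coverage and frequency classification.

# A synthetic chain object with hand-specified migrant tracts per sample.
fake_chain <- function(tract_sets, model, n_col = 20L, width = 10L) {
  lins <- model$lineages$lineage
  geno <- matrix(0L, length(lins), n_col, dimnames = list(lins, NULL))
  col <- tibble::tibble(
    start_bp = seq(0L, by = width, length.out = n_col),
    end_bp = seq(width, by = width, length.out = n_col),
    nbases = width, variant = FALSE, mu = 1.45e-8 * width)
  structure(list(
    samples = lapply(seq_along(tract_sets), function(i)
      list(iter = i, tracts = tract_sets[[i]])),
    model = model,
    data = arg_data(geno, col, n_col * width),
    config = list(burnin = 0)
  ), class = "arg_chain")
}

dip_model <- function() {
  toy_two_pop(samples = data.frame(
    sample_id = c("a1", "b1"), population = c("A", "B"),
    ploidy = c(1L, 2L), phased = c(TRUE, FALSE)))
}

tr_row <- function(lineage, start, end, band = "A_to_B")
  tibble::tibble(band = band, lineage = lineage, start = start, end = end)

empty_tr <- function() tr_row(character(0), integer(0), integer(0))[0, ]

test_that("posterior fractions count het and hom lineages per sample", {
  m <- dip_model()
  # 75 samples: 30 with exactly one migrant lineage at columns 5-8, 15 with
  # both, 30 with none
  sets <- c(
    replicate(30, tr_row("b1_1", 5L, 8L), simplify = FALSE),
    replicate(15, dplyr::bind_rows(tr_row("b1_1", 5L, 8L),
                                   tr_row("b1_2", 5L, 8L)),
              simplify = FALSE),
    replicate(30, empty_tr(), simplify = FALSE))
  ch <- fake_chain(sets, m)
  track <- posterior_tracks(ch, "A_to_B", "b1")
  expect_equal(track$p_het[5], 0.4)
  expect_equal(track$p_hom[5], 0.2)
  expect_equal(track$p_any[5], 0.6)
  expect_equal(track$p_any[1], 0)
  # the identity holds everywhere by construction
  expect_equal(track$p_any, track$p_het + track$p_hom)
})

test_that("all samples homozygous gives p_hom = 1, p_het = 0", {
  m <- dip_model()
  sets <- replicate(10, dplyr::bind_rows(tr_row("b1_1", 3L, 6L),
                                         tr_row("b1_2", 3L, 6L)),
                    simplify = FALSE)
  track <- posterior_tracks(fake_chain(sets, m), "A_to_B", "b1")
  expect_equal(track$p_hom[4], 1)
  expect_equal(track$p_het[4], 0)
})

test_that("a chain with no migrant branches yields an all-zero track", {
  m <- dip_model()
  track <- posterior_tracks(fake_chain(replicate(5, empty_tr(),
                                                 simplify = FALSE), m),
                            "A_to_B", "b1")
  expect_true(all(track$p_any == 0))
  expect_error(posterior_tracks(fake_chain(list(empty_tr()), m),
                                "nope", "b1"), "band")
})

test_that("region calls are maximal supra-threshold runs in base pairs", {
  m <- dip_model()
  # columns 6..15 migrant in 9 of 10 samples (p = 0.9), compression 10
  sets <- c(replicate(9, tr_row("b1_1", 6L, 15L), simplify = FALSE),
            list(empty_tr()))
  track <- posterior_tracks(fake_chain(sets, m), "A_to_B", "b1")
  calls <- call_regions(track, threshold = 0.5)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 50L)
  expect_equal(calls$end, 150L)
  expect_equal(calls$bp, 100L)
  expect_equal(calls$zygosity, "het")
  expect_equal(calls$mean_posterior, 0.9)
  # all columns below threshold -> no calls
  expect_equal(nrow(call_regions(track, threshold = 0.95)), 0L)
})

test_that("a column at exactly the threshold is included", {
  m <- dip_model()
  sets <- c(replicate(5, tr_row("b1_1", 10L, 10L), simplify = FALSE),
            replicate(5, empty_tr(), simplify = FALSE))
  track <- posterior_tracks(fake_chain(sets, m), "A_to_B", "b1")
  expect_equal(track$p_any[10], 0.5)
  calls <- call_regions(track, threshold = 0.5)
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), c(90L, 100L))
})

test_that("region zygosity follows the base-pair majority", {
  m <- dip_model()
  # columns 3-10: hom in 6/10 samples; only 3-4 also het in the others
  sets <- c(replicate(6, dplyr::bind_rows(tr_row("b1_1", 3L, 10L),
                                          tr_row("b1_2", 3L, 10L)),
                      simplify = FALSE),
            replicate(4, tr_row("b1_1", 3L, 4L), simplify = FALSE))
  track <- posterior_tracks(fake_chain(sets, m), "A_to_B", "b1")
  calls <- call_regions(track, threshold = 0.5)
  expect_equal(calls$zygosity, "hom")
})

test_that("coverage combines het and hom as half plus full", {
  expect_equal(introgression_coverage(0.02 * 1e6, 0.01 * 1e6, 1e6), 0.02)
  expect_equal(introgression_coverage(0, 0, 1e6), 0)
  expect_equal(introgression_coverage(0, 1e6, 1e6), 1)
  expect_error(introgression_coverage(10, 10, 0), "undefined")
})

test_that("coverage grows as the threshold is lowered", {
  m <- dip_model()
  sets <- c(replicate(6, tr_row("b1_1", 3L, 10L), simplify = FALSE),
            replicate(3, tr_row("b1_1", 12L, 18L), simplify = FALSE),
            list(empty_tr()))
  track <- posterior_tracks(fake_chain(sets, m), "A_to_B", "b1")
  covs <- vapply(c(0.9, 0.6, 0.3, 0.1), function(th) {
    cl <- call_regions(track, threshold = th)
    introgression_coverage(sum(cl$bp[cl$zygosity == "het"]),
                           sum(cl$bp[cl$zygosity == "hom"]), 200)
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("thresholding drops short weak tracts, right-shifting called
           lengths relative to truth", {
  m <- dip_model()
  # two truth tracts: a long one sampled migrant in 8/10 ARGs, a short one
  # in only 4/10 (below threshold) - the ascertainment mechanism
  sets <- c(replicate(4, dplyr::bind_rows(tr_row("b1_1", 2L, 12L),
                                          tr_row("b1_1", 16L, 17L)),
                      simplify = FALSE),
            replicate(4, tr_row("b1_1", 2L, 12L), simplify = FALSE),
            replicate(2, empty_tr(), simplify = FALSE))
  track <- posterior_tracks(fake_chain(sets, m), "A_to_B", "b1")
  calls <- call_regions(track, threshold = 0.5)
  truth <- tibble::tibble(start = c(10, 150), end = c(120, 170))
  ld <- length_distribution(calls, truth)
  sm <- attr(ld, "summary")
  expect_gt(sm$mean_bp[sm$set == "called"],
            mean(truth$end - truth$start))
})

test_that("frequency classification labels joint zygosity across
           individuals", {
  calls <- tibble::tibble(
    start = c(0L, 0L, 500L), end = c(400L, 400L, 800L),
    band = "A_to_B",
    individual = c("x", "y", "x"),
    zygosity = c("hom", "hom", "het"),
    mean_posterior = 0.9, bp = c(400L, 400L, 300L))
  fc <- frequency_classify(calls, individuals = c("x", "y"))
  expect_equal(nrow(fc$regions), 2L)
  r1 <- fc$regions[fc$regions$start == 0, ]
  expect_equal(r1$x, "hom"); expect_equal(r1$y, "hom")
  r2 <- fc$regions[fc$regions$start == 500, ]
  expect_equal(r2$x, "het"); expect_equal(r2$y, "absent")
  # bp-weighted fractions match direct counting
  sp <- fc$spectrum
  expect_equal(sp$frac_bp[match(r1$category, sp$category)], 400 / 700)
  expect_equal(argthreader:::all_hom_fraction(fc, c("x", "y")), 400 / 700)
})
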