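# Basewise accuracy, ROC consistency, length distributions and
# frequency-spectrum dating.

test_that("basewise rates on a toy window match hand arithmetic", {
  truth <- tibble::tibble(band = "A_to_B", lineage = "x_1",
                          start = 0L, end = 100L)
  calls <- tibble::tibble(band = "A_to_B", individual = "x",
                          start = 50L, end = 150L)
  br <- basewise_rates(calls, truth, window_bp = 1000)
  expect_equal(br$rates$tp_rate, 0.5)
  # 50 called bp fall outside the truth tract, over 900 non-truth bp
  expect_equal(br$rates$fp_rate, 50 / 900)
  # calls identical to truth
  calls2 <- tibble::tibble(band = "A_to_B", individual = "x",
                           start = 0L, end = 100L)
  br2 <- basewise_rates(calls2, truth, window_bp = 1000)
  expect_equal(br2$rates$tp_rate, 1)
  expect_equal(br2$rates$fp_rate, 0)
  # disjoint calls
  calls3 <- tibble::tibble(band = "A_to_B", individual = "x",
                           start = 500L, end = 600L)
  expect_equal(basewise_rates(calls3, truth, 1000)$rates$tp_rate, 0)
})

test_that("true positives require the correct band and individual", {
  truth <- tibble::tibble(band = "A_to_B", lineage = "x_1",
                          start = 0L, end = 100L)
  # right interval, wrong individual
  calls <- tibble::tibble(band = "A_to_B", individual = "y",
                          start = 0L, end = 100L)
  br <- basewise_rates(calls, truth, 1000, individuals = c("x", "y"))
  expect_equal(br$rates$tp_rate[br$rates$individual == "x"], 0)
  # right individual, wrong band: tallied as a misclassification
  calls2 <- tibble::tibble(band = "B_to_A", individual = "x",
                           start = 0L, end = 100L)
  br2 <- basewise_rates(calls2, truth, 1000)
  expect_equal(br2$confusion$bp, 100)
  expect_equal(br2$confusion$called_band, "B_to_A")
  expect_equal(br2$confusion$truth_band, "A_to_B")
})

test_that("masked base pairs are excluded from the FP denominator", {
  truth <- tibble::tibble(band = "b", lineage = "x_1",
                          start = 0L, end = 100L)
  calls <- tibble::tibble(band = "b", individual = "x",
                          start = 50L, end = 150L)
  br <- basewise_rates(calls, truth, 1000,
                       masks = tibble::tibble(start = 800L, end = 1000L))
  expect_equal(br$scorable_bp, 800)
  expect_equal(br$rates$fp_rate, 50 / 700)
})

test_that("interval arithmetic agrees exactly with per-bp bitmaps", {
  set.seed(8)
  for (rep in 1:5) {
    mk <- function(n, band, who) {
      s <- sort(sample(0:900, n))
      tibble::tibble(band = band, lineage = paste0(who, "_1"),
                     individual = who,
                     start = s, end = s + sample(10:80, n, TRUE))
    }
    truth <- dplyr::bind_rows(mk(3, "b1", "x"), mk(2, "b2", "x"))
    calls <- dplyr::bind_rows(mk(3, "b1", "x"), mk(2, "b2", "x"))
    br <- basewise_rates(calls, truth, 1000)$rates
    bm <- bitmap_rates(calls, truth, 1000)
    j <- dplyr::inner_join(br, bm, by = c("band", "individual"))
    expect_equal(j$tp_bp.x, j$tp_bp.y)
    expect_equal(j$fp_bp.x, j$fp_bp.y)
  }
})

test_that("the ROC point at threshold 0.5 reproduces the basewise rates", {
  m <- toy_two_pop(samples = data.frame(
    sample_id = c("a1", "b1"), population = c("A", "B"),
    ploidy = c(1L, 2L), phased = FALSE))
  # reuse the caller fixture machinery via a direct track
  track <- tibble::tibble(
    col = 1:20,
    start_bp = seq(0L, 190L, by = 10L), end_bp = seq(10L, 200L, by = 10L),
    nbases = 10L,
    p_any = c(rep(0, 5), rep(0.8, 5), rep(0.3, 5), rep(0.6, 5)),
    p_het = 0, p_hom = 0)
  track$p_het <- track$p_any
  attr(track, "band") <- "A_to_B"; attr(track, "individual") <- "b1"
  truth_iv <- tibble::tibble(start = 50L, end = 120L)
  roc <- roc_curve(track, truth_iv)
  calls <- call_regions(track, threshold = 0.5)
  truth <- tibble::tibble(band = "A_to_B", lineage = "b1_1",
                          start = 50L, end = 120L)
  br <- basewise_rates(calls, truth, 200)
  at5 <- roc[roc$threshold == 0.5, ]
  expect_equal(at5$tp_bp, br$rates$tp_bp)
  expect_equal(at5$fp_bp, br$rates$fp_bp)
  # a perfect track passes through (fpr 0, tpr 1)
  perfect <- track
  perfect$p_any <- as.numeric(perfect$start_bp >= 50 & perfect$end_bp <= 120)
  roc_p <- roc_curve(perfect, truth_iv)
  expect_true(any(roc_p$fpr == 0 & roc_p$tpr == 1))
  # a constant track only yields the two trivial points
  const <- track; const$p_any <- 0.4
  roc_c <- roc_curve(const, truth_iv)
  expect_setequal(round(roc_c$tpr, 9), c(0, 1))
  expect_setequal(round(roc_c$fpr, 9), c(0, 1))
  # monotone in the threshold
  expect_true(all(diff(roc$tpr[order(roc$threshold)]) <= 1e-12))
})

test_that("length distributions bin calls and truth identically", {
  calls <- tibble::tibble(start = c(0, 100e3), end = c(75e3, 110e3))
  ld <- length_distribution(calls, nbins = 10)
  expect_equal(sum(ld$count), 2L)
  expect_equal(sum(ld$count[ld$bin_hi >= 75e3]), 1L)
  sm <- attr(ld, "summary")
  expect_equal(sm$mean_bp[sm$set == "called"],
               sm$total_bp[sm$set == "called"] / sm$n[sm$set == "called"])
  # empty call set
  ld0 <- length_distribution(tibble::tibble(start = numeric(0),
                                            end = numeric(0)))
  expect_equal(nrow(ld0), 0L)
  # joint binning with truth
  truth <- tibble::tibble(start = 0, end = 150e3)
  ld2 <- length_distribution(calls, truth, nbins = 5)
  expect_equal(unique(table(ld2$set)), 5L)
  expect_equal(max(ld2$bin_hi[ld2$set == "called"]),
               max(ld2$bin_hi[ld2$set == "truth"]))
})

test_that("dating accepts candidates whose spectra overlap the observed", {
  set.seed(5)
  mk_regions <- function(frac_all_hom, n = 400) {
    hom <- stats::runif(n) < frac_all_hom
    tibble::tibble(bp = rep(10e3, n),
                   category = ifelse(hom, "x:hom,y:hom", "x:het,y:absent"))
  }
  observed <- mk_regions(0.37)
  candidates <- list(`150` = mk_regions(0.10), `250` = mk_regions(0.38),
                     `350` = mk_regions(0.55))
  res <- date_migration(observed, candidates, n_boot = 200)
  expect_true(res$accepted[res$candidate == "250"])
  # spectra at 10% and 55% both reject an observed 37% with tight CIs
  expect_false(res$accepted[res$candidate == "150"])
  expect_false(res$accepted[res$candidate == "350"])
  # a candidate identical to the observed spectrum is accepted
  res2 <- date_migration(observed, list(same = observed), n_boot = 100)
  expect_true(res2$accepted)
  expect_error(date_migration(observed[0, ], candidates), "no observed")
})

test_that("bootstrap confidence intervals shrink with the region count", {
  set.seed(6)
  mk <- function(n) tibble::tibble(
    bp = rep(1e3, n),
    category = ifelse(stats::runif(n) < 0.4, "hom", "het"))
  width <- function(n) {
    r <- date_migration(mk(n), list(x = mk(n)), n_boot = 200)
    d <- attr(r, "observed")
    mean(d$hi - d$lo)
  }
  w_small <- width(50)
  w_big <- width(800)
  expect_lt(w_big, w_small / 2)  # roughly 1/sqrt(16) = 1/4 expected
})
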