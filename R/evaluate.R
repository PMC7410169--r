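# Basewise accuracy, ROC curves, length distributions, and
# frequency-spectrum dating of migration times.

ir <- function(start, end) {
  keep <- end > start
  IRanges::IRanges(start = start[keep] + 1L, end = end[keep])
}

ir_bp <- function(x) sum(IRanges::width(x))

#' Basewise true/false positive rates of introgression calls
#'
#' Rates are computed per base pair and per (band, individual): a true
#' positive requires the correct type of migration called in the correct
#' individual. An individual's truth is the union of its haploid lineages'
#' migrant tracts. The false-positive denominator excludes masked
#' (unscorable) base pairs. Calls of one band overlapping truth tracts of
#' another are additionally tallied as misclassifications.
#'
#' @param calls Tibble of calls (`band`, `individual`, `start`, `end`;
#'   0-based half-open bp).
#' @param truth Tibble of truth tracts (`band`, `lineage`, `start`, `end`).
#'   Lineage names `<individual>_1/_2` are mapped to their individual.
#' @param window_bp Window length (must match between calls and truth).
#' @param individuals Individuals to score (default: those in truth or
#'   calls).
#' @param bands Bands to score (default: union of calls and truth bands).
#' @param masks Optional tibble (`start`, `end`) of unscorable intervals.
#' @return List with `rates` (per band x individual tibble including
#'   `tp_rate`, `fp_rate`), `overall` (per band, lineage-averaged), and
#'   `confusion` (called band vs truth band bp).
#' @export
basewise_rates <- function(calls, truth, window_bp, individuals = NULL,
                           bands = NULL, masks = NULL) {
  truth <- tibble::as_tibble(truth)
  calls <- tibble::as_tibble(calls)
  if (nrow(truth) > 0 && max(truth$end) > window_bp ||
      nrow(calls) > 0 && max(calls$end) > window_bp)
    stop("calls/truth exceed the window", call. = FALSE)
  truth$individual <- sub("_[12]$", "", truth$lineage)
  if (is.null(individuals))
    individuals <- sort(unique(c(calls$individual, truth$individual)))
  if (is.null(bands))
    bands <- sort(unique(c(calls$band, truth$band)))
  scor <- ir(0L, as.integer(window_bp))
  if (!is.null(masks) && nrow(masks) > 0)
    scor <- IRanges::setdiff(scor, ir(masks$start, masks$end))
  scorable_bp <- ir_bp(scor)
  empty_rates <- tibble::tibble(
    band = character(), individual = character(), truth_bp = numeric(),
    called_bp = numeric(), tp_bp = numeric(), fp_bp = numeric(),
    tp_rate = numeric(), fp_rate = numeric())
  if (length(bands) == 0L || length(individuals) == 0L)
    return(list(rates = empty_rates,
                overall = empty_rates[, c("band", "truth_bp", "tp_bp",
                                          "fp_bp", "tp_rate", "fp_rate")],
                confusion = tibble::tibble(called_band = character(),
                                           truth_band = character(),
                                           individual = character(),
                                           bp = numeric()),
                scorable_bp = scorable_bp))

  rates <- list(); conf <- list()
  for (b in bands) for (ind in individuals) {
    tr <- truth[truth$band == b & truth$individual == ind, ]
    tr_ir <- IRanges::intersect(IRanges::reduce(ir(tr$start, tr$end)), scor)
    cl <- calls[calls$band == b & calls$individual == ind, ]
    cl_ir <- IRanges::intersect(IRanges::reduce(ir(cl$start, cl$end)), scor)
    tp <- ir_bp(IRanges::intersect(cl_ir, tr_ir))
    fp <- ir_bp(IRanges::setdiff(cl_ir, tr_ir))
    truth_bp <- ir_bp(tr_ir)
    nontruth_bp <- scorable_bp - truth_bp
    rates[[length(rates) + 1L]] <- tibble::tibble(
      band = b, individual = ind,
      truth_bp = truth_bp, called_bp = ir_bp(cl_ir),
      tp_bp = tp, fp_bp = fp,
      tp_rate = if (truth_bp > 0) tp / truth_bp else NA_real_,
      fp_rate = if (nontruth_bp > 0) fp / nontruth_bp else NA_real_)
    for (b2 in setdiff(bands, b)) {
      tr2 <- truth[truth$band == b2 & truth$individual == ind, ]
      tr2_ir <- IRanges::intersect(IRanges::reduce(ir(tr2$start, tr2$end)),
                                   scor)
      mis <- ir_bp(IRanges::intersect(cl_ir, tr2_ir))
      if (mis > 0)
        conf[[length(conf) + 1L]] <- tibble::tibble(
          called_band = b, truth_band = b2, individual = ind, bp = mis)
    }
  }
  rates <- dplyr::bind_rows(rates)
  overall <- rates %>%
    dplyr::group_by(.data$band) %>%
    dplyr::summarise(
      truth_bp = sum(.data$truth_bp), tp_bp = sum(.data$tp_bp),
      fp_bp = sum(.data$fp_bp),
      tp_rate = ifelse(sum(.data$truth_bp) > 0,
                       sum(.data$tp_bp) / sum(.data$truth_bp), NA_real_),
      fp_rate = sum(.data$fp_bp) /
        (length(individuals) * scorable_bp - sum(.data$truth_bp)),
      .groups = "drop")
  conf <- if (length(conf)) dplyr::bind_rows(conf)
          else tibble::tibble(called_band = character(),
                              truth_band = character(),
                              individual = character(), bp = numeric())
  list(rates = rates, overall = overall, confusion = conf,
       scorable_bp = scorable_bp)
}

#' Basewise ROC curve from a posterior track
#'
#' Sweeps the posterior probability threshold and reports base-pair-weighted
#' true/false positive rates against the truth tracts. The point at
#' threshold 0.5 reproduces [basewise_rates()] on the same track.
#'
#' @param track A [posterior_tracks()] tibble.
#' @param truth Tibble (`start`, `end`) of true introgressed intervals for
#'   the track's band and individual (bp, 0-based half-open).
#' @param thresholds Thresholds to evaluate (default: all observed posterior
#'   values plus 0 and 1).
#' @return Tibble with `threshold`, `tpr`, `fpr`, `tp_bp`, `fp_bp`.
#' @export
roc_curve <- function(track, truth, thresholds = NULL) {
  tr_ir <- IRanges::reduce(ir(truth$start, truth$end))
  col_ir <- ir(track$start_bp, track$end_bp)
  truth_bp_col <- numeric(nrow(track))
  hits <- IRanges::findOverlaps(col_ir, tr_ir)
  if (length(hits) > 0) {
    w <- IRanges::width(IRanges::pintersect(col_ir[S4Vectors::queryHits(hits)],
                                            tr_ir[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    truth_bp_col[as.integer(names(agg))] <- agg
  }
  non_bp_col <- track$nbases - truth_bp_col
  if (is.null(thresholds))
    thresholds <- sort(unique(c(0, 0.5, track$p_any, 1)))
  tot_truth <- sum(truth_bp_col); tot_non <- sum(non_bp_col)
  out <- lapply(thresholds, function(t) {
    called <- track$p_any >= t
    tibble::tibble(threshold = t,
                   tp_bp = sum(truth_bp_col[called]),
                   fp_bp = sum(non_bp_col[called]))
  })
  out <- dplyr::bind_rows(out)
  out$tpr <- if (tot_truth > 0) out$tp_bp / tot_truth else NA_real_
  out$fpr <- if (tot_non > 0) out$fp_bp / tot_non else NA_real_
  out[, c("threshold", "tpr", "fpr", "tp_bp", "fp_bp")]
}

#' Length distribution of called and true regions
#'
#' @param calls Tibble with `start`, `end` (called regions).
#' @param truth Optional tibble with `start`, `end` (true tracts), binned
#'   identically.
#' @param nbins Number of bins.
#' @return Tibble with `set`, `bin_lo`, `bin_hi`, `count`; summary
#'   statistics in attribute `"summary"`.
#' @export
length_distribution <- function(calls, truth = NULL, nbins = 20) {
  len_c <- calls$end - calls$start
  len_t <- if (!is.null(truth)) truth$end - truth$start else numeric(0)
  all_len <- c(len_c, len_t)
  if (!length(all_len)) {
    out <- tibble::tibble(set = character(), bin_lo = numeric(),
                          bin_hi = numeric(), count = integer())
    attr(out, "summary") <- tibble::tibble(set = character(), n = integer(),
                                           total_bp = numeric(),
                                           mean_bp = numeric())
    return(out)
  }
  breaks <- seq(0, max(all_len) * 1.0001, length.out = nbins + 1L)
  mk <- function(len, set) {
    ct <- tabulate(findInterval(len, breaks, rightmost.closed = TRUE),
                   nbins = nbins)
    tibble::tibble(set = set, bin_lo = breaks[-length(breaks)],
                   bin_hi = breaks[-1], count = ct)
  }
  out <- mk(len_c, "called")
  if (!is.null(truth)) out <- dplyr::bind_rows(out, mk(len_t, "truth"))
  sm <- function(len, set) tibble::tibble(
    set = set, n = length(len), total_bp = sum(len),
    mean_bp = if (length(len)) mean(len) else NA_real_)
  attr(out, "summary") <- dplyr::bind_rows(
    sm(len_c, "called"),
    if (!is.null(truth)) sm(len_t, "truth"))
  out
}

# bp-weighted category fractions of a region table (frequency_classify
# regions output or anything with bp + category).
category_fractions <- function(regions, categories = NULL) {
  if (is.null(categories)) categories <- sort(unique(regions$category))
  f <- vapply(categories, function(cat)
    sum(regions$bp[regions$category == cat]) / sum(regions$bp), numeric(1))
  tibble::tibble(category = categories, frac = f)
}

#' Date a migration by the frequency spectrum of introgressed regions
#'
#' Older migrations drift to higher frequency among the recipients, so the
#' joint-zygosity spectrum of ascertained regions carries a dating signal.
#' Bootstrap confidence intervals (resampling regions with replacement) are
#' computed for the observed spectrum and for caller-ascertained spectra
#' simulated under each candidate migration time; a candidate is accepted
#' when its intervals overlap the observed intervals in every category.
#'
#' @param observed Region table (`bp`, `category`), e.g.
#'   `frequency_classify()$regions`.
#' @param candidates Named list of simulated region tables, one per
#'   candidate migration time.
#' @param n_boot Bootstrap replicates (default 100).
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `candidate`, `accepted`, and a list-column `detail`
#'   of per-category intervals.
#' @export
date_migration <- function(observed, candidates, n_boot = 100, conf = 0.95) {
  if (nrow(observed) == 0L) stop("no observed regions", call. = FALSE)
  cats <- sort(unique(c(observed$category,
                        unlist(lapply(candidates, function(x) x$category)))))
  boot_ci <- function(regions) {
    fr <- replicate(n_boot, {
      idx <- sample.int(nrow(regions), replace = TRUE)
      category_fractions(regions[idx, ], cats)$frac
    })
    a <- (1 - conf) / 2
    tibble::tibble(category = cats,
                   frac = category_fractions(regions, cats)$frac,
                   lo = apply(fr, 1L, stats::quantile, probs = a),
                   hi = apply(fr, 1L, stats::quantile, probs = 1 - a))
  }
  obs_ci <- boot_ci(observed)
  out <- lapply(names(candidates), function(nm) {
    ci <- boot_ci(candidates[[nm]])
    overlap <- ci$lo <= obs_ci$hi & obs_ci$lo <= ci$hi
    tibble::tibble(candidate = nm, accepted = all(overlap),
                   detail = list(dplyr::bind_cols(
                     ci, obs_lo = obs_ci$lo, obs_hi = obs_ci$hi,
                     obs_frac = obs_ci$frac, overlap = overlap)))
  })
  res <- dplyr::bind_rows(out)
  attr(res, "observed") <- obs_ci
  res
}
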