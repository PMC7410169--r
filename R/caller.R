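#' Posterior introgression probabilities along the genome
#'
#' For one migration band and one individual, the fraction of retained ARG
#' samples in which one (`p_het`), both (`p_hom`), or at least one (`p_any`)
#' of the individual's haploid lineages follow the band at each column.
#' For haploid individuals only `p_any` is meaningful (`p_het` is the
#' single-lineage probability and `p_hom` is zero). `p_any = p_het + p_hom`
#' holds exactly by construction.
#'
#' @param chain An `arg_chain` from [run_chain()].
#' @param band Band label (`"source_to_dest"`).
#' @param individual Sample id.
#' @return Tibble with `col`, `start_bp`, `end_bp`, `nbases`, `p_any`,
#'   `p_het`, `p_hom` plus attributes `band` and `individual`.
#' @export
posterior_tracks <- function(chain, band, individual) {
  model <- chain$model
  if (!band %in% model$bands$band)
    stop("band not in model: ", band, call. = FALSE)
  row <- model$samples[model$samples$sample_id == individual, ]
  if (nrow(row) != 1L) stop("unknown individual: ", individual, call. = FALSE)
  if (length(chain$samples) == 0L)
    stop("chain has no retained samples", call. = FALSE)
  lns <- if (row$ploidy == 2L) paste0(individual, c("_1", "_2"))
         else individual
  L <- ncol(chain$data$geno)
  n_het <- numeric(L); n_hom <- numeric(L)
  for (s in chain$samples) {
    cnt <- integer(L)
    tr <- s$tracts[s$tracts$band == band & s$tracts$lineage %in% lns, ]
    if (nrow(tr) > 0L) for (i in seq_len(nrow(tr)))
      cnt[tr$start[i]:tr$end[i]] <- cnt[tr$start[i]:tr$end[i]] + 1L
    n_het <- n_het + (cnt == 1L)
    n_hom <- n_hom + (cnt >= 2L)
  }
  ns <- length(chain$samples)
  out <- tibble::tibble(
    col = seq_len(L),
    start_bp = chain$data$col$start_bp,
    end_bp = chain$data$col$end_bp,
    nbases = chain$data$col$nbases,
    p_het = n_het / ns,
    p_hom = n_hom / ns,
    p_any = (n_het + n_hom) / ns
  )
  attr(out, "band") <- band
  attr(out, "individual") <- individual
  attr(out, "ploidy") <- row$ploidy
  class(out) <- c("posterior_track", class(out))
  out
}

#' Threshold a posterior track into region calls
#'
#' Maximal runs of columns with `p_any >= threshold` become called regions
#' (0-based half-open base-pair intervals). A region's zygosity is `hom`
#' when columns with `p_hom >= p_het` hold the base-pair majority within the
#' run, else `het`. Adjacent runs separated by any sub-threshold column are
#' not merged (`merge_bp` can relax this).
#'
#' @param track A [posterior_tracks()] tibble.
#' @param threshold Posterior probability cutoff (default 0.5; columns at
#'   exactly the threshold are included).
#' @param merge_bp Merge adjacent calls separated by fewer than this many
#'   base pairs (default 0 = no merging).
#' @return Tibble of calls: `start`, `end`, `band`, `individual`,
#'   `zygosity`, `mean_posterior`, `bp`.
#' @export
call_regions <- function(track, threshold = 0.5, merge_bp = 0) {
  stopifnot(threshold > 0, threshold <= 1)
  hit <- track$p_any >= threshold
  runs <- rle(hit)
  hi <- cumsum(runs$lengths)
  lo <- hi - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- lo[k]:hi[k]
    bp_hom <- sum(track$nbases[idx][track$p_hom[idx] >= track$p_het[idx]])
    bp_tot <- sum(track$nbases[idx])
    out[[length(out) + 1L]] <- tibble::tibble(
      start = track$start_bp[lo[k]],
      end = track$end_bp[hi[k]],
      zygosity = if (bp_hom > bp_tot / 2) "hom" else "het",
      mean_posterior = sum(track$p_any[idx] * track$nbases[idx]) / bp_tot
    )
  }
  calls <- if (length(out)) dplyr::bind_rows(out)
           else tibble::tibble(start = integer(), end = integer(),
                               zygosity = character(),
                               mean_posterior = numeric())
  if (merge_bp > 0 && nrow(calls) > 1L) {
    merged <- calls[1, ]
    for (i in 2:nrow(calls)) {
      last <- nrow(merged)
      if (calls$start[i] - merged$end[last] < merge_bp) {
        w1 <- merged$end[last] - merged$start[last]
        w2 <- calls$end[i] - calls$start[i]
        merged$mean_posterior[last] <-
          (merged$mean_posterior[last] * w1 + calls$mean_posterior[i] * w2) /
          (w1 + w2)
        merged$end[last] <- calls$end[i]
      } else merged <- dplyr::bind_rows(merged, calls[i, ])
    }
    calls <- merged
  }
  calls$band <- attr(track, "band") %||% NA_character_
  calls$individual <- attr(track, "individual") %||% NA_character_
  calls$bp <- calls$end - calls$start
  calls[, c("start", "end", "band", "individual", "zygosity",
            "mean_posterior", "bp")]
}

#' Introgression coverage of an individual
#'
#' Total called introgression for a diploid individual, averaged across its
#' two haploid lineages: one-half times the heterozygous coverage plus the
#' homozygous coverage.
#'
#' @param het_bp Base pairs called heterozygous.
#' @param hom_bp Base pairs called homozygous.
#' @param callable_bp Total scorable base pairs.
#' @return Coverage fraction in `[0, 1]`.
#' @export
introgression_coverage <- function(het_bp, hom_bp, callable_bp) {
  if (any(callable_bp == 0))
    stop("undefined coverage: callable_bp is zero", call. = FALSE)
  stopifnot(all(het_bp + hom_bp <= callable_bp + 1e-9))
  (0.5 * het_bp + hom_bp) / callable_bp
}

#' Frequency spectrum of called regions across individuals
#'
#' Flattens calls for one band across the recipient individuals into
#' disjoint regions (the union of all calls) and labels each region with the
#' joint zygosity category (per-individual `hom`, `het` or absent, assigned
#' by base-pair majority of overlap). Regions in which every recipient
#' individual is homozygous are the "all-homozygous" class whose prevalence
#' dates the migration (for two diploid recipients this is the
#' doubly-homozygous fraction across all four lineages).
#'
#' @param calls Tibble of [call_regions()] rows (possibly several
#'   individuals, one band).
#' @param individuals Character vector of recipient individuals defining the
#'   category space (defaults to those present in `calls`).
#' @return List with `regions` (tibble: `start`, `end`, `bp`, one column per
#'   individual, `category`) and `spectrum` (tibble: `category`,
#'   `n_regions`, `bp`, `frac_bp`).
#' @export
frequency_classify <- function(calls, individuals = NULL) {
  if (is.null(individuals)) individuals <- unique(calls$individual)
  if (nrow(calls) == 0L)
    return(list(regions = tibble::tibble(), spectrum = tibble::tibble(
      category = character(), n_regions = integer(), bp = numeric(),
      frac_bp = numeric())))
  ir <- IRanges::reduce(IRanges::IRanges(calls$start + 1L, calls$end))
  regions <- tibble::tibble(start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir))
  for (ind in individuals) {
    sub <- calls[calls$individual == ind, ]
    status <- character(nrow(regions))
    for (i in seq_len(nrow(regions))) {
      ov_het <- 0; ov_hom <- 0
      if (nrow(sub) > 0L) {
        o <- pmin(regions$end[i], sub$end) - pmax(regions$start[i], sub$start)
        ov_het <- sum(o[o > 0 & sub$zygosity == "het"])
        ov_hom <- sum(o[o > 0 & sub$zygosity == "hom"])
      }
      len <- regions$end[i] - regions$start[i]
      status[i] <- if (ov_het + ov_hom < len / 2) "absent"
                   else if (ov_hom >= ov_het) "hom" else "het"
    }
    regions[[ind]] <- status
  }
  regions$bp <- regions$end - regions$start
  regions$category <- apply(
    regions[, individuals, drop = FALSE], 1L,
    function(z) paste(paste0(individuals, ":", z), collapse = ","))
  spectrum <- regions %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(n_regions = dplyr::n(), bp = sum(.data$bp),
                     .groups = "drop") %>%
    dplyr::mutate(frac_bp = .data$bp / sum(.data$bp))
  list(regions = regions, spectrum = spectrum)
}

# Fraction of flattened region bp in which all recipient individuals are
# homozygous ("doubly homozygous" for two diploid recipients).
all_hom_fraction <- function(fc, individuals) {
  if (!nrow(fc$regions)) return(NA_real_)
  all_hom <- apply(fc$regions[, individuals, drop = FALSE] == "hom", 1L, all)
  sum(fc$regions$bp[all_hom]) / sum(fc$regions$bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
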