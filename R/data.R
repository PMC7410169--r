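#' Compressed genotype data for the sampler
#'
#' The sampler works on "compressed columns": runs of invariant positions are
#' collapsed into single columns carrying a base count (their mutation rate
#' is scaled by the number of bases represented), while variant positions are
#' retained as their own columns. Alleles are polarized as 0 (ancestral) and
#' 1 (derived); NA marks missing data.
#'
#' @param geno Lineages-by-columns integer matrix of 0/1/NA with rownames
#'   equal to the haploid lineage names.
#' @param col Tibble describing the columns: `start_bp`, `end_bp` (0-based
#'   half-open), `nbases`, `variant`, `mu` (mutation rate per generation per
#'   column, compression-scaled).
#' @param window_bp Window length in base pairs.
#' @param recomb_rate Recombination rate per bp per generation assumed by
#'   the model.
#' @return An object of class `arg_data`.
#' @export
arg_data <- function(geno, col, window_bp, recomb_rate = 5e-9) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)),
            nrow(col) == ncol(geno))
  structure(list(geno = geno, col = tibble::as_tibble(col),
                 window_bp = as.numeric(window_bp),
                 recomb_rate = recomb_rate),
            class = "arg_data")
}

#' @export
print.arg_data <- function(x, ...) {
  cat("<arg_data>", nrow(x$geno), "lineages,", ncol(x$geno),
      "compressed columns over", format(x$window_bp, big.mark = ","),
      "bp (", sum(x$col$variant), "variant )\n")
  invisible(x)
}

# Mutation rate (per bp per generation) at a position, from a scalar or a
# map given as a data frame with start/end (0-based half-open) and rate.
rate_at <- function(rate, pos) {
  if (is.numeric(rate) && length(rate) == 1L) return(rep(rate, length(pos)))
  i <- findInterval(pos, rate$start)
  out <- rate$rate[pmax(i, 1L)]
  out[i < 1L] <- rate$rate[1]
  out
}

#' Build compressed sampler input from variant sites
#'
#' @param lineages Character vector of haploid lineage names (matrix row
#'   order).
#' @param positions 1-based base-pair positions of the variant sites.
#' @param alleles Lineages-by-sites matrix of 0/1/NA.
#' @param window_bp Window length.
#' @param compress Bases per invariant compressed column (default 10).
#' @param mut_rate Scalar rate per bp per generation, or a map (data frame
#'   with `start`, `end`, `rate`).
#' @param recomb_rate Recombination rate per bp per generation used by the
#'   threading model.
#' @param masks Optional data frame of missing-data intervals with columns
#'   `lineage` (or "all"), `start`, `end` (0-based half-open). An invariant
#'   column is set missing for a lineage when at least half of its bases are
#'   masked; a variant column when its position is masked.
#' @return An [arg_data()] object.
#' @export
compress_sites <- function(lineages, positions, alleles, window_bp,
                           compress = 10L, mut_rate = 1.45e-8,
                           recomb_rate = 5e-9, masks = NULL) {
  stopifnot(length(positions) == 0L || !is.unsorted(positions))
  if (length(positions) > 0L)
    stopifnot(min(positions) >= 1, max(positions) <= window_bp)
  # column layout: invariant blocks between variants, split to `compress` bp
  starts <- integer(0); ends <- integer(0); variant <- logical(0)
  cursor <- 0L
  add_invariant <- function(from, to) {
    # [from, to) 0-based
    if (to <= from) return(invisible())
    bs <- seq.int(from, to - 1L, by = compress)
    be <- pmin(bs + compress, to)
    starts <<- c(starts, bs); ends <<- c(ends, be)
    variant <<- c(variant, rep(FALSE, length(bs)))
  }
  for (p in positions) {
    add_invariant(cursor, p - 1L)
    starts <- c(starts, p - 1L); ends <- c(ends, p)
    variant <- c(variant, TRUE)
    cursor <- p
  }
  add_invariant(cursor, as.integer(window_bp))
  nb <- ends - starts
  centers <- (starts + ends) / 2
  mu <- rate_at(mut_rate, centers) * ifelse(variant, 1, nb)
  col <- tibble::tibble(start_bp = starts, end_bp = ends, nbases = nb,
                        variant = variant, mu = mu)
  geno <- matrix(0L, length(lineages), nrow(col),
                 dimnames = list(lineages, NULL))
  if (length(positions) > 0L)
    geno[, which(variant)] <- alleles
  if (!is.null(masks) && nrow(masks) > 0L) {
    for (i in seq_len(nrow(masks))) {
      tgt <- if (masks$lineage[i] == "all") lineages else masks$lineage[i]
      ov <- pmin(ends, masks$end[i]) - pmax(starts, masks$start[i])
      hit <- which(ov > 0 & (variant | ov >= nb / 2))
      geno[tgt, hit] <- NA_integer_
    }
  }
  arg_data(geno, col, window_bp, recomb_rate)
}

# Map column intervals (1-based inclusive) to bp intervals (0-based
# half-open).
cols_to_bp <- function(data, start_col, end_col) {
  tibble::tibble(start = data$col$start_bp[start_col],
                 end = data$col$end_bp[end_col])
}

# Full-data log-likelihood of an ARG (sum over spans and columns of the
# two-state pruning likelihood).
arg_loglik <- function(arg, model, data) {
  ll <- 0
  for (i in seq_along(arg$trees)) {
    cols <- arg$starts[i]:arg$ends[i]
    ll <- ll + sum(log(tree_column_likelihood(model, arg$trees[[i]],
                                              data$geno, data$col$mu, cols)))
  }
  ll
}
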