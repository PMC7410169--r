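#' Build a demographic model for ARG inference
#'
#' Defines the population tree, piecewise-constant population sizes,
#' migration bands and sampled genomes over a discrete [time_grid()]. The
#' population tree uses a "continuing parent" convention: each non-root
#' population names the population it merges into (backwards in time) and the
#' time of that merge; the parent population simply continues above the merge.
#' Divergence and migration times are snapped to the nearest half time-point.
#'
#' Migration bands are stated forwards in time (`source` is the origin of
#' migrants, `dest` the recipient). Traced backwards, a lineage sitting in
#' `dest` at the band's half time-point follows the migrant path into
#' `source` with prior probability `rate`.
#'
#' @param populations Data frame with columns `name`, `parent` (NA for the
#'   single root), `div_time` (years; NA for the root) and optionally `ghost`
#'   (logical; unsampled population with no within-population coalescence).
#' @param sizes Data frame with columns `population`, `size` (diploid
#'   effective size) and optionally `time` (start of the epoch in years,
#'   default 0; epochs extend backwards to the next older entry). Ghost
#'   populations may be omitted.
#' @param samples Data frame with columns `sample_id`, `population`, and
#'   optionally `age` (years, default 0), `ploidy` (1 or 2, default 2) and
#'   `phased` (default FALSE for diploids).
#' @param bands Optional data frame with columns `source`, `dest`, `time`
#'   (years) and `rate` (prior migration probability per lineage, in (0,1)).
#' @param grid A [time_grid()]; defaults to [default_time_grid()].
#' @param generation_time Years per generation, used to convert the grid to
#'   coalescent time units.
#' @param snap_times Snap divergence and band times to half time-points
#'   (default TRUE, required for inference). Set FALSE only for
#'   simulation-only models whose event times should be honored exactly.
#' @return An object of class `demog_model`.
#' @examples
#' m <- demog_model(
#'   populations = data.frame(name = c("A", "B"), parent = c(NA, "A"),
#'                            div_time = c(NA, 600e3)),
#'   sizes = data.frame(population = c("A", "B"), size = c(10000, 2000)),
#'   samples = data.frame(sample_id = c("a1", "b1"),
#'                        population = c("A", "B")),
#'   bands = data.frame(source = "A", dest = "B", time = 250e3, rate = 0.01)
#' )
#' @export
demog_model <- function(populations, sizes, samples, bands = NULL,
                        grid = default_time_grid(),
                        generation_time = grid$generation_time,
                        snap_times = TRUE) {
  stopifnot(inherits(grid, "time_grid"))
  pops <- tibble::as_tibble(populations)
  if (!"ghost" %in% names(pops)) pops$ghost <- FALSE
  pops$ghost <- ifelse(is.na(pops$ghost), FALSE, pops$ghost)
  if (anyDuplicated(pops$name)) stop("duplicate population names", call. = FALSE)
  n_root <- sum(is.na(pops$parent))
  if (n_root != 1L) stop("exactly one root population required", call. = FALSE)
  if (!all(stats::na.omit(pops$parent) %in% pops$name))
    stop("unknown parent population", call. = FALSE)

  K <- grid$K
  pop_names <- pops$name
  npop <- nrow(pops)
  pidx <- function(x) {
    i <- match(x, pop_names)
    if (anyNA(i) && !all(is.na(x))) stop("unknown population: ",
      paste(x[is.na(i) & !is.na(x)], collapse = ", "), call. = FALSE)
    i
  }

  nonroot <- !is.na(pops$parent)
  if (snap_times) {
    pops$div_time[nonroot] <- snap_to_half_time(grid, pops$div_time[nonroot])
    pops$div_time[!nonroot] <- NA_real_
    pops$div_half <- match(pops$div_time, grid$half)
  } else {
    pops$div_time[!nonroot] <- NA_real_
    pops$div_half <- findInterval(pops$div_time * (1 - 1e-12), grid$half) + 1L
    pops$div_half <- pmin(pops$div_half, grid$K - 1L)
  }

  # child must merge strictly below its parent's own merge
  for (i in seq_len(npop)) {
    if (is.na(pops$parent[i])) next
    pj <- pidx(pops$parent[i])
    if (!is.na(pops$div_half[pj]) && pops$div_half[i] >= pops$div_half[pj])
      stop("population ", pops$name[i],
           " must diverge below its parent's own merge", call. = FALSE)
  }

  # resident population (index) of each population at each grid time
  resident <- matrix(0L, npop, K)
  for (p in seq_len(npop)) {
    cur <- p
    for (j in seq_len(K)) {
      while (!is.na(pops$div_half[cur]) && pops$div_half[cur] + 1L <= j)
        cur <- pidx(pops$parent[cur])
      resident[p, j] <- cur
    }
  }
  if (length(unique(resident[, K])) != 1L)
    stop("model must coalesce to a single population by the oldest time",
         call. = FALSE)

  # piecewise-constant sizes -> size at each grid time
  sz <- tibble::as_tibble(sizes)
  if (!"time" %in% names(sz)) sz$time <- 0
  sz$time[is.na(sz$time)] <- 0
  if (any(sz$size <= 0, na.rm = TRUE))
    stop("population sizes must be positive", call. = FALSE)
  N <- matrix(NA_real_, npop, K)
  for (p in seq_len(npop)) {
    rows <- sz[pidx(sz$population) == p, , drop = FALSE]
    if (nrow(rows) == 0) {
      if (!pops$ghost[p])
        stop("no size given for non-ghost population ", pop_names[p],
             call. = FALSE)
      next
    }
    rows <- rows[order(rows$time), , drop = FALSE]
    if (rows$time[1] > 0) rows$time[1] <- 0
    idx <- findInterval(grid$times, rows$time)
    N[p, ] <- rows$size[pmax(idx, 1L)]
  }

  # migration bands
  if (is.null(bands) || nrow(tibble::as_tibble(bands)) == 0) {
    bands <- tibble::tibble(source = character(), dest = character(),
                            time = numeric(), rate = numeric(),
                            half = integer(), band = character())
  } else {
    bands <- tibble::as_tibble(bands)
    if (any(bands$rate <= 0 | bands$rate >= 1))
      stop("band prior rates must lie strictly in (0, 1)", call. = FALSE)
    if (snap_times) {
      bands$time <- snap_to_half_time(grid, bands$time)
      bands$half <- match(bands$time, grid$half)
    } else {
      bands$half <- pmin(findInterval(bands$time * (1 - 1e-12), grid$half) + 1L,
                         grid$K - 1L)
    }
    bands$band <- paste0(bands$source, "_to_", bands$dest)
    for (b in seq_len(nrow(bands))) {
      s <- pidx(bands$source[b]); d <- pidx(bands$dest[b])
      m <- bands$half[b]
      if (resident[d, m] != d)
        stop("band ", bands$band[b], ": dest does not exist at ",
             bands$time[b], " years", call. = FALSE)
      if (resident[s, m + 1L] != s)
        stop("band ", bands$band[b], ": source does not exist above ",
             bands$time[b], " years", call. = FALSE)
      if (resident[s, m + 1L] == resident[d, m + 1L])
        stop("band ", bands$band[b],
             ": time must lie strictly below the source/dest divergence",
             call. = FALSE)
    }
  }

  # samples and haploid lineages
  smp <- tibble::as_tibble(samples)
  if (!"age" %in% names(smp)) smp$age <- 0
  if (!"ploidy" %in% names(smp)) smp$ploidy <- 2L
  if (!"phased" %in% names(smp)) smp$phased <- smp$ploidy == 1L
  smp$phased <- smp$phased | smp$ploidy == 1L
  if (anyDuplicated(smp$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (any(smp$age < 0)) stop("sample ages must be non-negative", call. = FALSE)
  if (any(pops$ghost[pidx(smp$population)]))
    stop("samples cannot belong to a ghost population", call. = FALSE)
  smp$age_idx <- grid_time_index(grid, smp$age)

  lineages <- do.call(rbind, lapply(seq_len(nrow(smp)), function(i) {
    n <- smp$ploidy[i]
    tibble::tibble(
      lineage = if (n == 1L) smp$sample_id[i]
                else paste0(smp$sample_id[i], "_", seq_len(n)),
      sample_id = smp$sample_id[i],
      population = smp$population[i],
      pop = pidx(smp$population[i]),
      age_idx = smp$age_idx[i]
    )
  }))

  model <- structure(
    list(grid = grid, generation_time = generation_time,
         pops = pops, pop_names = pop_names, npop = npop,
         resident = resident, N = N, sizes = sz, bands = bands,
         samples = smp, lineages = lineages),
    class = "demog_model"
  )
  model$paths <- build_path_table(model, max_migrations = 1L)
  model
}

#' @export
print.demog_model <- function(x, ...) {
  cat("<demog_model> ", x$npop, " populations (",
      sum(x$pops$ghost), " ghost), ", nrow(x$bands), " migration bands, ",
      nrow(x$samples), " samples (", nrow(x$lineages),
      " haploid lineages), K = ", x$grid$K, "\n", sep = "")
  invisible(x)
}

# Enumerate population paths from a starting population upward. Returns a
# list of rows: pops (integer K-vector of population index at each grid
# time), band / half (crossing; NA if resident), n_mig.
enumerate_paths_int <- function(model, start_pop, max_migrations = 1L) {
  K <- model$grid$K
  bands <- model$bands
  div_half <- model$pops$div_half
  parent_idx <- match(model$pops$parent, model$pop_names)
  out <- list()
  walk <- function(j, cur, pops_so_far, crossings) {
    if (j == K) {
      out[[length(out) + 1L]] <<- list(
        pops = c(pops_so_far, cur),
        band = if (length(crossings)) crossings[[1]][1] else NA_integer_,
        half = if (length(crossings)) crossings[[1]][2] else NA_integer_,
        crossings = crossings,
        n_mig = length(crossings))
      return(invisible())
    }
    # choices at half time-point j (between grid times j and j+1)
    resident_next <- if (!is.na(div_half[cur]) && div_half[cur] == j)
      parent_idx[cur] else cur
    walk(j + 1L, resident_next, c(pops_so_far, cur), crossings)
    if (length(crossings) < max_migrations && nrow(bands) > 0) {
      appl <- which(bands$half == j & match(bands$dest, model$pop_names) == cur)
      for (b in appl) {
        src <- match(bands$source[b], model$pop_names)
        walk(j + 1L, src, c(pops_so_far, cur),
             c(crossings, list(c(b, j))))
      }
    }
  }
  walk(1L, start_pop, integer(0), list())
  out
}

# Global path table over all populations (anchor = population the path
# starts in at the present end of the branch using it).
build_path_table <- function(model, max_migrations = 1L) {
  rows <- list()
  for (p in seq_len(model$npop)) {
    if (model$pops$ghost[p]) {
      # ghost populations are never anchors; keep resident row for lookups
      paths <- enumerate_paths_int(model, p, 0L)
    } else {
      paths <- enumerate_paths_int(model, p, max_migrations)
    }
    for (pa in paths)
      rows[[length(rows) + 1L]] <- c(list(anchor = p), pa)
  }
  list(
    anchor = vapply(rows, `[[`, integer(1), "anchor"),
    mat = do.call(rbind, lapply(rows, `[[`, "pops")),
    band = vapply(rows, `[[`, integer(1), "band"),
    half = vapply(rows, `[[`, integer(1), "half"),
    n_mig = vapply(rows, `[[`, integer(1), "n_mig")
  )
}

# Path id for an anchored path with a given (single) crossing, or resident.
find_path <- function(model, anchor, band = NA_integer_, half = NA_integer_) {
  pt <- model$paths
  hit <- which(pt$anchor == anchor &
                 (if (is.na(band)) is.na(pt$band)
                  else !is.na(pt$band) & pt$band == band & pt$half == half))
  if (length(hit) != 1L)
    stop("no unique path for anchor ", model$pop_names[anchor],
         if (!is.na(band)) paste0(" crossing band ", band, " at half ", half),
         call. = FALSE)
  hit
}

# Population (index) of path `pid` at grid time index `j`.
path_pop <- function(model, pid, j) model$paths$mat[pid, j]

# Does path pid cross a band within half indices [a, b-1] (branch spanning
# grid indices [a, b])?
path_crosses <- function(model, pid, a, b, band = NULL) {
  h <- model$paths$half[pid]
  if (is.na(h)) return(FALSE)
  ok <- h >= a && h < b
  if (!is.null(band)) ok <- ok && model$paths$band[pid] == band
  ok
}

#' Enumerate population paths for a lineage
#'
#' Lists the population paths available to a lineage sampled in
#' `population`: the resident path following the divergence tree, plus one
#' path per migration band the lineage can cross (up to `max_migrations`
#' crossings in total).
#'
#' @param model A [demog_model()].
#' @param population Population name the lineage is sampled in.
#' @param age Sampling age in years (default 0); bands below the sampling
#'   age cannot be crossed.
#' @param max_migrations Maximum number of band crossings per path.
#' @return A tibble with one row per path: `path_id` (row in the model's
#'   path table when `max_migrations = 1`, otherwise sequential),
#'   `n_migrations`, `band`, `migration_time`, and a list-column `pops`
#'   of population names at each grid time.
#' @export
enumerate_paths <- function(model, population, age = 0, max_migrations = 1L) {
  stopifnot(inherits(model, "demog_model"))
  p <- match(population, model$pop_names)
  if (is.na(p)) stop("unknown population: ", population, call. = FALSE)
  if (model$pops$ghost[p]) stop("cannot sample a lineage in a ghost population",
                                call. = FALSE)
  age_idx <- grid_time_index(model$grid, age)
  if (max_migrations == 1L) {
    pt <- model$paths
    ids <- which(pt$anchor == p & (is.na(pt$half) | pt$half >= age_idx))
    return(tibble::tibble(
      path_id = ids,
      n_migrations = pt$n_mig[ids],
      band = ifelse(is.na(pt$band[ids]), NA_character_,
                    model$bands$band[pt$band[ids]]),
      migration_time = ifelse(is.na(pt$half[ids]), NA_real_,
                              model$grid$half[pt$half[ids]]),
      pops = lapply(ids, function(i) model$pop_names[pt$mat[i, ]])
    ))
  }
  paths <- enumerate_paths_int(model, p, as.integer(max_migrations))
  keep <- vapply(paths, function(pa)
    all(vapply(pa$crossings, function(cr) cr[2] >= age_idx, logical(1))),
    logical(1))
  paths <- paths[keep]
  tibble::tibble(
    path_id = seq_along(paths),
    n_migrations = vapply(paths, `[[`, integer(1), "n_mig"),
    band = vapply(paths, function(pa)
      if (is.na(pa$band)) NA_character_ else model$bands$band[pa$band],
      character(1)),
    migration_time = vapply(paths, function(pa)
      if (is.na(pa$half)) NA_real_ else model$grid$half[pa$half], numeric(1)),
    pops = lapply(paths, function(pa) model$pop_names[pa$pops])
  )
}

#' Scale all population sizes by a factor
#'
#' Multiplies every population size by `factor`, leaving times unchanged.
#' Used, for example, to approximate X-chromosome demography by scaling
#' autosomal sizes by 0.75.
#'
#' @param model A [demog_model()].
#' @param factor Positive scaling factor.
#' @return A new `demog_model`.
#' @export
scale_model <- function(model, factor) {
  stopifnot(inherits(model, "demog_model"))
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  model$N <- model$N * factor
  model$sizes$size <- model$sizes$size * factor
  model
}

# Effective size (diploid) of population q at coalescence time index j.
pop_size_at <- function(model, q, j) model$N[q, j]
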