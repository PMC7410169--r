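#' Simulate a dataset with ground-truth migrant tracts
#'
#' Simulates the structured coalescent with recombination under the model's
#' divergence and size history, with pulse admixture events at the given
#' times and proportions and with the model's sampling ages, then drops
#' binary mutations. The engine is msprime, driven through a bundled python
#' script. Ground truth is recorded per haploid lineage: an interval is
#' migrant for a band exactly when the lineage's ancestor just above the
#' pulse time sits in the source population (extracted via census nodes).
#'
#' @param model A [demog_model()] (all populations, including ghosts, need
#'   sizes for simulation).
#' @param length_bp Window length in base pairs.
#' @param admixture Data frame of pulse events: `source`, `dest`, `time`
#'   (years), `proportion` in (0,1). Defaults to the model's migration bands
#'   with zero pulses removed — pass explicitly in normal use.
#' @param recomb_rate Scalar rate per bp per generation or a map (data frame
#'   `start`, `end`, `rate`).
#' @param mut_rate Scalar or map, as `recomb_rate`.
#' @param seed Integer random seed.
#' @param python Python interpreter with msprime available.
#' @return An object of class `sim_dataset`: haploid genotypes at variant
#'   positions, truth tracts (bp, 0-based half-open), and the generating
#'   configuration.
#' @export
simulate_dataset <- function(model, length_bp, admixture,
                             recomb_rate = 5e-9, mut_rate = 1.45e-8,
                             seed = 1,
                             python = getOption("argthreader.python",
                                                "python")) {
  stopifnot(inherits(model, "demog_model"), length_bp > 0)
  admixture <- tibble::as_tibble(admixture)
  if (nrow(admixture) > 0) {
    if (any(admixture$proportion < 0 | admixture$proportion >= 1))
      stop("admixture proportions must lie in [0, 1)", call. = FALSE)
    admixture <- admixture[admixture$proportion > 0, , drop = FALSE]
  } else {
    admixture <- tibble::tibble(source = character(), dest = character(),
                                time = numeric(), proportion = numeric())
  }
  gt <- model$generation_time
  pidx <- function(x) match(x, model$pop_names)

  pops_cfg <- lapply(seq_len(model$npop), function(p) {
    rows <- model$sizes[pidx(model$sizes$population) == p, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("population ", model$pop_names[p],
           " needs a size for simulation", call. = FALSE)
    rows <- rows[order(rows$time), ]
    cfg <- list(name = model$pop_names[p],
                size_epochs = lapply(seq_len(nrow(rows)), function(i)
                  list(time_gen = rows$time[i] / gt, size = rows$size[i])))
    gr <- attr(model, "growth")
    if (!is.null(gr) && model$pop_names[p] %in% gr$population) {
      g <- gr[gr$population == model$pop_names[p], ]
      cfg$growth <- list(rate = g$rate, end_time_gen = g$end_time / gt)
    }
    cfg
  })
  merges <- model$pops[!is.na(model$pops$parent), ]
  merges_cfg <- lapply(seq_len(nrow(merges)), function(i)
    list(time_gen = merges$div_time[i] / gt,
         child = merges$name[i], parent = merges$parent[i]))

  pulses_cfg <- lapply(seq_len(nrow(admixture)), function(i) {
    m <- half_index(model$grid, admixture$time[i])
    d <- pidx(admixture$dest[i])
    recip <- model$lineages$lineage[
      model$resident[model$lineages$pop, m] == d &
        model$lineages$age_idx <= m]
    list(time_gen = snap_to_half_time(model$grid, admixture$time[i]) / gt,
         source = admixture$source[i], dest = admixture$dest[i],
         proportion = admixture$proportion[i],
         band = paste0(admixture$source[i], "_to_", admixture$dest[i]),
         recipients = as.list(recip))
  })

  rate_cfg <- function(rate) {
    if (is.numeric(rate) && length(rate) == 1L) return(list(rate = rate))
    list(map = list(start = as.list(rate$start), rate = as.list(rate$rate)))
  }
  cfg <- list(
    seed = as.integer(seed %% 2147483646L + 1L),
    length_bp = length_bp,
    generation_time = gt,
    recomb = rate_cfg(recomb_rate),
    mut = rate_cfg(mut_rate),
    populations = pops_cfg,
    merges = merges_cfg,
    pulses = pulses_cfg,
    # exact sampling ages are honored in simulation; inference snaps them
    # to the nearest grid time
    samples = lapply(seq_len(nrow(model$lineages)), function(i) {
      sid <- model$lineages$sample_id[i]
      age <- model$samples$age[model$samples$sample_id == sid]
      list(lineage = model$lineages$lineage[i],
           population = model$lineages$population[i],
           time_gen = age / gt)
    })
  )
  cfg_path <- tempfile(fileext = ".json")
  out_path <- tempfile(fileext = ".json")
  on.exit(unlink(c(cfg_path, out_path)), add = TRUE)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "simulate_dataset.py",
                        package = "argthreader")
  status <- system2(python, c(shQuote(script), shQuote(cfg_path),
                              shQuote(out_path)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_path))
    stop("simulation failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  res <- jsonlite::read_json(out_path, simplifyVector = TRUE)

  lineages <- res$lineages
  n_sites <- length(res$positions)
  alleles <- if (n_sites > 0) {
    m <- matrix(as.integer(res$alleles_flat), nrow = length(lineages))
    rownames(m) <- lineages
    m
  } else matrix(integer(0), length(lineages), 0,
                dimnames = list(lineages, NULL))
  truth <- if (length(res$tracts) && NROW(res$tracts) > 0)
    tibble::as_tibble(res$tracts)
  else tibble::tibble(band = character(), lineage = character(),
                      start = numeric(), end = numeric())
  structure(list(
    lineages = lineages,
    positions = as.integer(res$positions),
    alleles = alleles,
    truth = truth,
    window_bp = length_bp,
    model = model,
    admixture = admixture,
    seed = seed,
    masks = NULL,
    num_trees = res$num_trees
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", length(x$lineages), "haploid lineages,",
      length(x$positions), "variant sites over",
      format(x$window_bp, big.mark = ","), "bp;",
      nrow(x$truth), "truth tracts\n")
  invisible(x)
}

#' Degrade a simulated dataset with phase randomization and masks
#'
#' Within each unphased diploid individual, the two alleles at every
#' heterozygous site are swapped with probability 1/2; the unordered
#' genotype per site is invariant. Mask intervals set the covered region to
#' missing for the given lineages (or `"all"`).
#'
#' @param dataset A [simulate_dataset()] result.
#' @param phase_randomize Randomize phase of unphased diploids.
#' @param masks Data frame with `lineage`, `start`, `end` (bp, 0-based
#'   half-open).
#' @param seed Random seed for the phase randomization.
#' @return The modified `sim_dataset`.
#' @export
degrade <- function(dataset, phase_randomize = TRUE, masks = NULL,
                    seed = 1) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!is.null(masks) && nrow(masks) > 0 &&
      (any(masks$start < 0) || any(masks$end > dataset$window_bp)))
    stop("masks outside the window", call. = FALSE)
  set.seed(seed)
  if (phase_randomize && ncol(dataset$alleles) > 0) {
    smp <- dataset$model$samples
    for (sid in smp$sample_id[smp$ploidy == 2L & !smp$phased]) {
      l1 <- paste0(sid, "_1"); l2 <- paste0(sid, "_2")
      het <- which(!is.na(dataset$alleles[l1, ]) &
                     !is.na(dataset$alleles[l2, ]) &
                     dataset$alleles[l1, ] != dataset$alleles[l2, ])
      flip <- het[stats::runif(length(het)) < 0.5]
      tmp <- dataset$alleles[l1, flip]
      dataset$alleles[l1, flip] <- dataset$alleles[l2, flip]
      dataset$alleles[l2, flip] <- tmp
    }
  }
  if (!is.null(masks) && nrow(masks) > 0) {
    masks <- tibble::as_tibble(masks)
    for (i in seq_len(nrow(masks))) {
      tgt <- if (masks$lineage[i] == "all") dataset$lineages
             else masks$lineage[i]
      hit <- which(dataset$positions > masks$start[i] &
                     dataset$positions <= masks$end[i])
      if (length(hit)) dataset$alleles[tgt, hit] <- NA_integer_
    }
    dataset$masks <- dplyr::bind_rows(dataset$masks, masks)
  }
  dataset
}

#' Convert a simulated dataset to sampler input
#'
#' @param dataset A [simulate_dataset()] (possibly [degrade()]d) result.
#' @param compress Bases per invariant compressed column.
#' @param mut_rate,recomb_rate Rates assumed by the inference model
#'   (defaults match the simulation defaults).
#' @return An [arg_data()] object.
#' @export
as_arg_data <- function(dataset, compress = 10L, mut_rate = 1.45e-8,
                        recomb_rate = 5e-9) {
  compress_sites(dataset$lineages, dataset$positions, dataset$alleles,
                 dataset$window_bp, compress = compress,
                 mut_rate = mut_rate, recomb_rate = recomb_rate,
                 masks = dataset$masks)
}
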