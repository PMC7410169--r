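# Shared fixtures: small demographic models and datasets built in code.

# Two populations A (large) and B (small), one band A->B at 250 ky, coarse
# 6-point grid. Lineage b* can be resident or migrant.
toy_two_pop <- function(rate = 0.01, samples = NULL, bands = TRUE) {
  if (is.null(samples))
    samples <- data.frame(sample_id = c("a1", "b1"),
                          population = c("A", "B"), ploidy = 1L)
  demog_model(
    populations = data.frame(name = c("A", "B"), parent = c(NA, "A"),
                             div_time = c(NA, 600e3)),
    sizes = data.frame(population = c("A", "B"), size = c(10000, 2000)),
    samples = samples,
    bands = if (bands) data.frame(source = "A", dest = "B", time = 250e3,
                                  rate = rate) else NULL,
    grid = time_grid(c(0, 100e3, 300e3, 500e3, 700e3, 900e3))
  )
}

# Single panmictic population (threading reduces to branch x time).
toy_one_pop <- function(n = 3) {
  demog_model(
    populations = data.frame(name = "A", parent = NA, div_time = NA),
    sizes = data.frame(population = "A", size = 10000),
    samples = data.frame(sample_id = paste0("s", seq_len(n)),
                         population = "A", ploidy = 1L),
    grid = time_grid(c(0, 100e3, 300e3, 500e3, 700e3, 900e3))
  )
}

# Three-population toy with a ghost source, mirroring the hominin setup at
# a smaller grid: Hum (large), Rec (small recipient), ghost Sup.
toy_ghost <- function(rate = 0.01) {
  demog_model(
    populations = data.frame(name = c("Hum", "Rec", "Sup"),
                             parent = c(NA, "Hum", "Hum"),
                             div_time = c(NA, 600e3, 900e3),
                             ghost = c(FALSE, FALSE, TRUE)),
    sizes = data.frame(population = c("Hum", "Rec", "Sup"),
                       size = c(15000, 2000, 10000)),
    samples = data.frame(sample_id = c("h1", "r1"),
                         population = c("Hum", "Rec"), ploidy = 1L),
    bands = data.frame(source = "Sup", dest = "Rec", time = 250e3,
                       rate = rate),
    grid = time_grid(c(0, 100e3, 300e3, 500e3, 700e3, 900e3, 1100e3))
  )
}

# Small dataset over a toy model: a few variant columns.
toy_data <- function(model, window_bp = 500, positions = c(55L, 201L, 333L),
                     alleles = NULL) {
  lins <- model$lineages$lineage
  if (is.null(alleles)) {
    set.seed(99)
    alleles <- matrix(sample(0:1, length(lins) * length(positions),
                             replace = TRUE),
                      length(lins), length(positions))
  }
  rownames(alleles) <- lins
  compress_sites(lins, positions, alleles, window_bp)
}

# All-missing dataset (uniform emissions): posterior equals the prior.
toy_missing_data <- function(model, n_col = 20L, width = 10L) {
  lins <- model$lineages$lineage
  geno <- matrix(NA_integer_, length(lins), n_col,
                 dimnames = list(lins, NULL))
  col <- tibble::tibble(
    start_bp = seq(0L, by = width, length.out = n_col),
    end_bp = seq(width, by = width, length.out = n_col),
    nbases = width, variant = FALSE, mu = 1.45e-8 * width)
  arg_data(geno, col, n_col * width)
}
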