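# ARG editing: unthread/thread round trips, SPR handling, migrant tracts.

# A small chain-produced ARG over the two-population toy.
make_toy_arg <- function(seed = 7, n_iter = 6) {
  m <- toy_two_pop(samples = data.frame(
    sample_id = c("a1", "a2", "b1"), population = c("A", "A", "B"),
    ploidy = 1L))
  dat <- toy_data(m, window_bp = 2000,
                  positions = c(55L, 201L, 333L, 777L, 1500L))
  set.seed(seed)
  arg <- initialize_arg(dat, m)
  for (it in seq_len(n_iter)) for (ln in m$lineages$lineage) {
    u <- unthread(arg, m, ln)
    arg <- argthreader:::thread_sample(u$partial, m, dat, ln,
                                       migration_enabled = TRUE)
  }
  list(model = m, data = dat, arg = arg)
}

tree_at <- function(arg, col) arg$trees[[findInterval(col, arg$starts)]]

test_that("unthread/thread are mutually inverse", {
  x <- make_toy_arg()
  for (ln in c("a1", "b1")) {
    u <- unthread(x$arg, x$model, ln)
    back <- thread(u$partial, x$model, ln, u$record)
    expect_true(validate_arg(back, x$model)$ok)
    for (col in seq_len(x$arg$n_col)) {
      expect_true(argthreader:::trees_equal(tree_at(x$arg, col),
                                            tree_at(back, col)))
    }
    # and unthreading again restores the partial ARG exactly
    u2 <- unthread(back, x$model, ln)
    expect_equal(length(u2$partial$trees), length(u$partial$trees))
    for (col in seq_len(x$arg$n_col))
      expect_true(argthreader:::trees_equal(tree_at(u2$partial, col),
                                            tree_at(u$partial, col)))
  }
})

test_that("tree spans tile the window and all trees validate", {
  x <- make_toy_arg()
  expect_equal(x$arg$starts[1], 1L)
  expect_equal(x$arg$ends[length(x$arg$ends)], x$arg$n_col)
  if (length(x$arg$starts) > 1)
    expect_equal(x$arg$starts[-1], x$arg$ends[-length(x$arg$ends)] + 1L)
  expect_true(validate_arg(x$arg, x$model)$ok)
})

test_that("SPRs on the removed branch are absorbed by unthreading", {
  x <- make_toy_arg(seed = 21, n_iter = 8)
  n_spans <- length(x$arg$trees)
  u <- unthread(x$arg, x$model, "b1")
  # spans can only merge, never split
  expect_lte(length(u$partial$trees), n_spans)
  # every partial tree has n-1 leaves
  for (tr in u$partial$trees) expect_equal(tr$n_leaf, 2L)
})

test_that("unthreading down to a single lineage is degenerate but valid", {
  m <- toy_two_pop()
  dat <- toy_data(m, window_bp = 400, positions = c(10L, 200L))
  set.seed(3)
  arg <- initialize_arg(dat, m)
  u <- unthread(arg, m, "b1")
  expect_equal(length(u$partial$trees), 1L)  # no SPRs can survive
  expect_equal(u$partial$trees[[1]]$n_leaf, 1L)
  expect_error(unthread(u$partial, m, "a1"), "only lineage")
})

test_that("migrant tracts are maximal intervals of band-following ancestry", {
  m <- toy_two_pop()
  dat <- toy_data(m, window_bp = 1000, positions = c(100L, 500L))
  pa <- find_path(m, 1L)
  pb <- find_path(m, 2L)
  pmig <- find_path(m, 2L, band = 1L, half = 2L)
  resident <- local_tree(c(3L, 3L, 0L), c(1L, 1L, 5L), c(pa, pb, pa),
                         c("a1", "b1"))
  migrant <- local_tree(c(3L, 3L, 0L), c(1L, 1L, 3L), c(pa, pmig, pa),
                        c("a1", "b1"))
  # no migrant branches anywhere -> empty
  arg0 <- new_arg(list(resident), 1L, ncol(dat$geno), list(),
                  ncol(dat$geno), c("a1", "b1"))
  expect_equal(nrow(migrant_tracts(arg0, m, "A_to_B", "b1")), 0L)
  # migrant in the middle span only
  L <- ncol(dat$geno)
  arg1 <- new_arg(list(resident, migrant, resident),
                  c(1L, 21L, 61L), c(20L, 60L, L),
                  vector("list", 2), L, c("a1", "b1"))
  tr <- migrant_tracts(arg1, m, "A_to_B", "b1")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, 21L)
  expect_equal(tr$end, 60L)
  # the non-migrant lineage has no tracts
  expect_equal(nrow(migrant_tracts(arg1, m, "A_to_B", "a1")), 0L)
  expect_error(migrant_tracts(arg1, m, "nope", "b1"), "band")
})

test_that("tracts of uninvolved lineages survive a round trip", {
  x <- make_toy_arg(seed = 5, n_iter = 8)
  before <- migrant_tracts(x$arg, x$model, "A_to_B", "b1")
  u <- unthread(x$arg, x$model, "a2")
  back <- thread(u$partial, x$model, "a2", u$record)
  after <- migrant_tracts(back, x$model, "A_to_B", "b1")
  expect_equal(after, before)
})

test_that("constant threading state adds no SPRs", {
  m <- toy_two_pop()
  dat <- toy_data(m, window_bp = 300, positions = c(50L, 150L))
  set.seed(1)
  arg <- initialize_arg(dat, m)
  u <- unthread(arg, m, "b1")
  st <- u$record[1, ]
  st$start <- 1L; st$end <- arg$n_col
  back <- thread(u$partial, m, "b1", st)
  expect_equal(length(back$trees), length(u$partial$trees))
  expect_true(validate_arg(back, m)$ok)
})
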