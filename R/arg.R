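#' Ancestral recombination graphs as tiled local trees
#'
#' An `arg` is an ordered list of local trees whose spans tile the window of
#' compressed columns, together with the SPR (subtree-prune-regraft) events
#' relating adjacent trees. Spans are stored as 1-based column intervals
#' `[starts[i], ends[i]]`; converting to base pairs goes through the data's
#' column map.
#'
#' @param trees List of [local_tree()] objects.
#' @param starts,ends Integer vectors of first/last column per span.
#' @param sprs List (length `length(trees) - 1`) of SPR records or NULL
#'   where the event is not explicitly represented.
#' @param n_col Total number of columns in the window.
#' @param lineages Character vector of haploid lineage names.
#' @return An object of class `arg`.
#' @export
new_arg <- function(trees, starts, ends, sprs, n_col, lineages) {
  stopifnot(length(trees) == length(starts), length(starts) == length(ends))
  structure(list(trees = trees, starts = as.integer(starts),
                 ends = as.integer(ends), sprs = sprs,
                 n_col = as.integer(n_col), lineages = lineages),
            class = "arg")
}

#' @export
print.arg <- function(x, ...) {
  cat("<arg>", length(x$lineages), "lineages,", length(x$trees),
      "local trees over", x$n_col, "columns\n")
  invisible(x)
}

# Trivial ARG holding a single lineage (used to seed sequential threading).
single_lineage_arg <- function(model, lineage, n_col) {
  row <- model$lineages[model$lineages$lineage == lineage, ]
  tr <- local_tree(parent = 0L, time = row$age_idx,
                   path = find_path(model, row$pop),
                   lineages = lineage)
  new_arg(list(tr), 1L, n_col, list(), n_col, lineage)
}

trees_equal <- function(a, b) {
  identical(a$parent, b$parent) && identical(a$time, b$time) &&
    identical(a$path, b$path) && identical(a$lineages, b$lineages)
}

#' Remove one haploid lineage from every local tree of an ARG
#'
#' The "unthreading" half of the sampler's core move. The leaf and its
#' parent node are removed from every local tree; spans whose trees become
#' identical after removal (because the intervening recombination lived on
#' the removed branch) are merged. The returned record holds, per remaining
#' span, the original coalescence target (as a branch key of the partial
#' tree), coalescence time and population path of the removed branch, which
#' is enough to reconstruct the original ARG exactly via [thread()].
#'
#' @param arg An [new_arg()] object.
#' @param model The [demog_model()].
#' @param lineage Name of the haploid lineage to remove.
#' @return List with `partial` (the n-1 lineage ARG) and `record` (tibble
#'   with columns `start`, `end`, `target_key`, `coal_time`, `path`).
#' @export
unthread <- function(arg, model, lineage) {
  if (!lineage %in% arg$lineages)
    stop("unknown lineage: ", lineage, call. = FALSE)
  det <- lapply(arg$trees, detach_leaf, model = model, lineage = lineage)
  trees <- lapply(det, `[[`, "tree")
  recs <- lapply(det, `[[`, "record")
  starts <- arg$starts; ends <- arg$ends
  keep_tree <- list(); keep_start <- integer(); keep_end <- integer()
  for (i in seq_along(trees)) {
    if (length(keep_tree) > 0 &&
        trees_equal(keep_tree[[length(keep_tree)]], trees[[i]])) {
      keep_end[length(keep_end)] <- ends[i]
    } else {
      keep_tree[[length(keep_tree) + 1L]] <- trees[[i]]
      keep_start <- c(keep_start, starts[i])
      keep_end <- c(keep_end, ends[i])
    }
  }
  partial <- new_arg(keep_tree, keep_start, keep_end,
                     vector("list", max(length(keep_tree) - 1L, 0L)),
                     arg$n_col, setdiff(arg$lineages, lineage))
  record <- tibble::tibble(
    start = starts, end = ends,
    target_key = vapply(recs, `[[`, character(1), "target_key"),
    coal_time = vapply(recs, `[[`, integer(1), "coal_time"),
    path = vapply(recs, `[[`, integer(1), "path"))
  list(partial = partial, record = record)
}

#' Thread a lineage back into a partial ARG
#'
#' The inverse of [unthread()]: given per-column coalescence states for the
#' new branch (constant within runs, changing only at recombination
#' positions or at recombinations of the fixed ARG), attaches the lineage to
#' every local tree and records the implied SPR events.
#'
#' @param partial The n-1 lineage ARG.
#' @param model The [demog_model()].
#' @param lineage Name of the lineage being threaded.
#' @param states Tibble with columns `start`, `end` (column spans),
#'   `target_key` (branch key in the partial tree; the root's key selects
#'   the root's upward continuation), `coal_time` (grid index) and `path`
#'   (global path id). Spans must tile the window.
#' @param recombs Optional tibble with columns `col` and `rec_time` giving
#'   the recombination time on the new branch at each state change within a
#'   fixed-tree span (used for the SPR records).
#' @return A full [new_arg()] with `length(partial$lineages) + 1` lineages.
#' @export
thread <- function(partial, model, lineage, states, recombs = NULL) {
  row <- model$lineages[model$lineages$lineage == lineage, ]
  if (nrow(row) != 1L) stop("unknown lineage: ", lineage, call. = FALSE)
  states <- tibble::as_tibble(states)
  if (states$start[1] != 1L || states$end[nrow(states)] != partial$n_col ||
      (nrow(states) > 1 && any(states$start[-1] != states$end[-nrow(states)] + 1L)))
    stop("inconsistent state sequence: spans must tile the window",
         call. = FALSE)
  # split at the union of partial-tree boundaries and state boundaries
  cuts <- sort(unique(c(partial$starts, states$start)))
  seg_start <- cuts
  seg_end <- c(cuts[-1] - 1L, partial$n_col)
  tree_of <- findInterval(seg_start, partial$starts)
  state_of <- findInterval(seg_start, states$start)
  trees <- vector("list", length(seg_start))
  sprs <- vector("list", max(length(seg_start) - 1L, 0L))
  for (i in seq_along(seg_start)) {
    ptree <- partial$trees[[tree_of[i]]]
    st <- states[state_of[i], ]
    keys <- tree_keys(ptree)
    tgt <- match(st$target_key, keys)
    if (is.na(tgt))
      stop("inconsistent state sequence: no branch with key ",
           st$target_key, " at column ", seg_start[i], call. = FALSE)
    trees[[i]] <- attach_leaf(model, ptree, lineage, row$age_idx,
                              tgt, st$coal_time, st$path)
    if (i > 1L) {
      same_fixed <- tree_of[i] == tree_of[i - 1L]
      same_state <- state_of[i] == state_of[i - 1L]
      if (same_fixed && !same_state) {
        rt <- NA_integer_
        if (!is.null(recombs)) {
          hit <- which(recombs$col == seg_start[i])
          if (length(hit)) rt <- recombs$rec_time[hit[1]]
        }
        sprs[[i - 1L]] <- list(pos = seg_start[i], rec_key = lineage,
                               rec_time = rt,
                               coal_key = st$target_key,
                               coal_time = st$coal_time,
                               coal_path = st$path)
      }  # fixed-ARG boundaries keep a NULL (inherited) record
    }
  }
  new_arg(trees, seg_start, seg_end, sprs, partial$n_col,
          c(partial$lineages, lineage))
}

#' Migrant tracts of a lineage in a sampled ARG
#'
#' Maximal column intervals over which the lineage's ancestral branch at the
#' band's half time-point follows the migration band, i.e. the lineage is
#' introgressed at that genomic position.
#'
#' @param arg A sampled [new_arg()].
#' @param model The [demog_model()].
#' @param band Band label (`"source_to_dest"`) or band index.
#' @param lineage Haploid lineage name.
#' @return Tibble with columns `start`, `end` (1-based inclusive column
#'   intervals).
#' @export
migrant_tracts <- function(arg, model, band, lineage) {
  b <- if (is.character(band)) match(band, model$bands$band) else band
  if (is.na(b) || b < 1L || b > nrow(model$bands))
    stop("band not in model: ", band, call. = FALSE)
  m <- model$bands$half[b]
  K <- model$grid$K
  flag <- logical(length(arg$trees))
  for (i in seq_along(arg$trees)) {
    tr <- arg$trees[[i]]
    v <- match(lineage, tr$lineages)
    if (is.na(v)) stop("unknown lineage: ", lineage, call. = FALSE)
    # ancestral branch of the lineage spanning half time-point m
    while (tr$parent[v] != 0L && tr$time[tr$parent[v]] <= m)
      v <- tr$parent[v]
    hi <- if (tr$parent[v] == 0L) K else tr$time[tr$parent[v]]
    pid <- tr$path[v]
    flag[i] <- !is.na(model$paths$half[pid]) &&
      model$paths$half[pid] == m && model$paths$band[pid] == b &&
      tr$time[v] <= m && m < hi
  }
  runs <- rle(flag)
  pos <- cumsum(c(1L, runs$lengths))
  hit <- which(runs$values)
  tibble::tibble(start = arg$starts[pos[hit]],
                 end = arg$ends[pos[hit + 1L] - 1L])
}

# Validate every local tree of an ARG; returns TRUE or the first violation.
validate_arg <- function(arg, model, max_one_migration = TRUE) {
  if (arg$starts[1] != 1L || arg$ends[length(arg$ends)] != arg$n_col ||
      (length(arg$starts) > 1 &&
       any(arg$starts[-1] != arg$ends[-length(arg$ends)] + 1L)))
    return(list(ok = FALSE, violations = tibble::tibble(
      type = "tiling", message = "tree spans do not tile the window")))
  for (i in seq_along(arg$trees)) {
    v <- validate_tree(arg$trees[[i]], model, max_one_migration)
    if (!v$ok) return(v)
  }
  list(ok = TRUE,
       violations = tibble::tibble(type = character(), message = character()))
}
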