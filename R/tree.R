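#' Local genealogical trees with population-path-labeled branches
#'
#' A local tree is the coalescent genealogy of the sampled haploid lineages
#' over one non-recombining interval. Nodes `1..n` are the leaves (in the
#' order of `lineages`); internal nodes follow. Each node `v` carries the
#' grid-time index `time[v]` and the population path `path[v]` of the branch
#' above it (for the root, the path of its upward continuation, onto which a
#' rethreaded lineage may still coalesce).
#'
#' @param parent Integer vector of parent node ids (0 for the root).
#' @param time Integer vector of grid time indices (1-based).
#' @param path Integer vector of global path ids (rows of the model's path
#'   table).
#' @param lineages Character vector of haploid lineage names for the leaves.
#' @return An object of class `local_tree`.
#' @export
local_tree <- function(parent, time, path, lineages) {
  stopifnot(length(parent) == length(time), length(time) == length(path))
  structure(list(parent = as.integer(parent), time = as.integer(time),
                 path = as.integer(path), lineages = lineages,
                 n_leaf = length(lineages)),
            class = "local_tree")
}

#' @export
print.local_tree <- function(x, ...) {
  cat("<local_tree>", x$n_leaf, "leaves, root at time index",
      x$time[tree_root(x)], "\n")
  invisible(x)
}

tree_root <- function(tree) which(tree$parent == 0L)

# children list per node
tree_children <- function(tree) {
  ch <- vector("list", length(tree$parent))
  for (v in seq_along(tree$parent)) {
    p <- tree$parent[v]
    if (p > 0L) ch[[p]] <- c(ch[[p]], v)
  }
  ch
}

# Descendant-leaf key per node: sorted leaf names, comma-separated. Used as a
# stable branch identity across tree edits (node ids are renumbered).
# Cached on the tree (invalidated by the edit functions, which rebuild it).
tree_keys <- function(tree) {
  if (!is.null(tree$keys)) return(tree$keys)
  tree_keys_compute(tree)
}

tree_keys_compute <- function(tree) {
  n <- length(tree$parent)
  sets <- vector("list", n)
  for (v in seq_len(tree$n_leaf)) sets[[v]] <- tree$lineages[v]
  ord <- order(tree$time[seq_len(n)])  # children always younger than parents
  for (v in ord) {
    p <- tree$parent[v]
    if (p > 0L) sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
}

# Deterministic renumbering: leaves sorted by lineage name; internal nodes
# sorted by (time, smallest descendant leaf index). Guarantees byte-identical
# serializations for a given seed regardless of threading order.
canonical_tree <- function(tree) {
  n <- length(tree$parent)
  nl <- tree$n_leaf
  perm <- order(tree$lineages)
  if (!identical(perm, seq_len(nl))) {
    map <- integer(n)
    map[perm] <- seq_len(nl)
    if (n > nl) map[(nl + 1L):n] <- (nl + 1L):n
    out <- tree
    out$parent[map] <- ifelse(tree$parent == 0L, 0L, map[pmax(tree$parent, 1L)])
    out$time[map] <- tree$time
    out$path[map] <- tree$path
    out$lineages <- tree$lineages[perm]
    tree <- out
  }
  if (n == nl) return(tree)
  minleaf <- rep(NA_integer_, n)
  minleaf[seq_len(nl)] <- seq_len(nl)
  ord_t <- order(tree$time)
  for (v in ord_t) {
    p <- tree$parent[v]
    if (p > 0L)
      minleaf[p] <- min(minleaf[p], minleaf[v], na.rm = TRUE)
  }
  internals <- (nl + 1L):n
  neworder <- internals[order(tree$time[internals], minleaf[internals])]
  map <- integer(n)
  map[seq_len(nl)] <- seq_len(nl)
  map[neworder] <- (nl + 1L):n
  out <- tree
  out$parent[map] <- ifelse(tree$parent == 0L, 0L, map[pmax(tree$parent, 1L)])
  out$time[map] <- tree$time
  out$path[map] <- tree$path
  out
}

# Population index of the branch above node v at grid time index j.
branch_pop <- function(model, tree, v, j) model$paths$mat[tree$path[v], j]

# Canonical path id: smallest global path row whose populations match the
# branch's true population history over its span (root branches match up to
# the top of the grid so the upward continuation is well defined).
canonical_path <- function(model, pops_vec, a, b) {
  mat <- model$paths$mat
  idx <- seq_len(nrow(mat))
  sub <- mat[, a:b, drop = FALSE]
  target <- pops_vec[a:b]
  hit <- idx[colSums(t(sub) != target) == 0L]
  if (!length(hit))
    stop("no population path matches the required history", call. = FALSE)
  min(hit)
}

canonicalize_tree_paths <- function(model, tree) {
  K <- model$grid$K
  for (v in seq_along(tree$parent)) {
    p <- tree$parent[v]
    a <- tree$time[v]
    b <- if (p == 0L) K else tree$time[p]
    tree$path[v] <- canonical_path(model, model$paths$mat[tree$path[v], ], a, b)
  }
  tree
}

# Fast count of migrant branches (no allocation); see tree_migrant_nodes.
tree_migrant_count <- function(model, tree) {
  K <- model$grid$K
  half <- model$paths$half[tree$path]
  hi <- ifelse(tree$parent == 0L, K, tree$time[pmax(tree$parent, 1L)])
  sum(!is.na(half) & tree$time <= half & half < hi)
}

# Migrant branches: nodes whose branch crosses a migration band within its
# own span (crossing at half index h requires t_child <= h < t_parent; the
# root's continuation spans up to the top of the grid).
tree_migrant_nodes <- function(model, tree) {
  K <- model$grid$K
  pt <- model$paths
  out <- list()
  for (v in seq_along(tree$parent)) {
    h <- pt$half[tree$path[v]]
    if (is.na(h)) next
    hi <- if (tree$parent[v] == 0L) K else tree$time[tree$parent[v]]
    if (tree$time[v] <= h && h < hi)
      out[[length(out) + 1L]] <- c(node = v, band = pt$band[tree$path[v]],
                                   half = h)
  }
  if (!length(out))
    return(tibble::tibble(node = integer(), band = integer(),
                          half = integer()))
  tibble::as_tibble(do.call(rbind, out))
}

#' Validate a local tree against a demographic model
#'
#' Checks binary coalescent topology, leaf sampling ages, population
#' co-location of coalescing branches (coalescence requires both branches and
#' the parent's path to occupy the same population at the coalescence time),
#' absence of coalescence inside ghost populations, and (optionally) that at
#' most one branch in the tree crosses any migration band.
#'
#' @param tree A [local_tree()].
#' @param model A [demog_model()].
#' @param max_one_migration Enforce the default at-most-one-migration-per-
#'   location constraint.
#' @return A list with `ok` (logical) and `violations` (tibble of `type`,
#'   `message`). Never silently passes: every failed check is reported.
#' @export
validate_tree <- function(tree, model, max_one_migration = TRUE) {
  viol <- list()
  bad <- function(type, msg)
    viol[[length(viol) + 1L]] <<- tibble::tibble(type = type, message = msg)
  n <- length(tree$parent)
  nl <- tree$n_leaf
  K <- model$grid$K

  if (sum(tree$parent == 0L) != 1L) bad("topology", "tree must have one root")
  if (nl >= 2L && n != 2L * nl - 1L)
    bad("topology", "tree is not a binary coalescent tree")
  ch <- tree_children(tree)
  for (v in (if (n > nl) (nl + 1L):n else integer(0))) {
    if (length(ch[[v]]) != 2L) bad("topology", paste("node", v, "not binary"))
  }
  for (v in seq_len(n)) {
    p <- tree$parent[v]
    if (p > 0L) {
      ok_time <- tree$time[p] > tree$time[v] ||
        (tree$time[p] == K && tree$time[v] == K)
      if (!ok_time)
        bad("times", paste("branch above node", v,
                           "has non-positive duration"))
    }
  }

  lin <- model$lineages
  for (v in seq_len(nl)) {
    row <- lin[lin$lineage == tree$lineages[v], ]
    if (nrow(row) != 1L) { bad("leaves", paste("unknown lineage",
                                               tree$lineages[v])); next }
    if (tree$time[v] != row$age_idx)
      bad("leaves", paste("leaf", tree$lineages[v], "has wrong sampling age"))
    if (model$paths$mat[tree$path[v], row$age_idx] != row$pop)
      bad("leaves", paste("leaf", tree$lineages[v],
                          "path does not start in its population"))
  }

  for (w in seq_len(n)) {
    if (length(ch[[w]]) != 2L) next
    j <- tree$time[w]
    p1 <- branch_pop(model, tree, ch[[w]][1], j)
    p2 <- branch_pop(model, tree, ch[[w]][2], j)
    pw <- branch_pop(model, tree, w, j)
    if (p1 != p2 || p1 != pw)
      bad("colocation", paste("coalescence at node", w,
                              "joins branches in different populations"))
    else if (model$pops$ghost[p1])
      bad("ghost", paste("coalescence at node", w,
                         "inside ghost population",
                         model$pop_names[p1]))
  }

  if (max_one_migration) {
    mig <- tree_migrant_nodes(model, tree)
    if (nrow(mig) > 1L)
      bad("migration", paste(nrow(mig),
                             "branches cross a migration band (max 1)"))
  }

  if (length(viol))
    list(ok = FALSE, violations = do.call(rbind, viol))
  else
    list(ok = TRUE,
         violations = tibble::tibble(type = character(), message = character()))
}

# Attach a new leaf onto a partial tree. `target` is the node id whose branch
# receives the coalescence (0 = the root's upward continuation), `j` the
# coalescence time index, `path_id` the new branch's population path.
attach_leaf <- function(model, tree, lineage, age_idx, target, j, path_id) {
  n <- length(tree$parent)
  nl <- tree$n_leaf
  # old node v -> new id: leaves keep 1..nl, internals shift by 1 to make
  # room for the new leaf at nl+1; new internal node w appended last
  map <- c(seq_len(nl), if (n > nl) (nl + 2L):(n + 1L) else integer(0))
  leaf_id <- nl + 1L
  w <- n + 2L
  parent <- integer(n + 2L)
  time <- integer(n + 2L)
  path <- integer(n + 2L)
  parent[map] <- ifelse(tree$parent == 0L, 0L, map[pmax(tree$parent, 1L)])
  time[map] <- tree$time
  path[map] <- tree$path
  time[leaf_id] <- age_idx
  path[leaf_id] <- path_id
  parent[leaf_id] <- w
  time[w] <- j
  if (target == 0L) {
    root <- map[tree_root(tree)]
    parent[root] <- w
    parent[w] <- 0L
    path[w] <- path[root]
  } else {
    tgt <- map[target]
    parent[w] <- parent[tgt]
    parent[tgt] <- w
    path[w] <- path[tgt]
  }
  out <- local_tree(parent, time, path, c(tree$lineages, lineage))
  out <- canonical_tree(out)
  out <- canonicalize_tree_paths(model, out)
  out$keys <- tree_keys_compute(out)
  out
}

# Remove a leaf (by name) and its parent; returns list(tree, record) where
# record holds what is needed to re-attach: target branch key in the partial
# tree, coalescence time and the removed branch's path id.
detach_leaf <- function(model, tree, lineage) {
  v <- match(lineage, tree$lineages)
  if (is.na(v)) stop("unknown lineage: ", lineage, call. = FALSE)
  n <- length(tree$parent)
  K <- model$grid$K
  if (tree$n_leaf == 1L)
    stop("cannot remove the only lineage", call. = FALSE)
  w <- tree$parent[v]
  ch <- tree_children(tree)
  sib <- setdiff(ch[[w]], v)
  gp <- tree$parent[w]
  keys <- tree_keys(tree)
  record <- list(
    target_key = keys[sib],
    coal_time = tree$time[w],
    path = tree$path[v]
  )
  # splice the sibling branch through the removed node: the merged branch
  # follows the sibling's population history below the coalescence time and
  # the removed node's branch history above it
  new_parent <- tree$parent
  new_path <- tree$path
  new_parent[sib] <- gp
  pops <- model$paths$mat[tree$path[sib], ]
  pops[tree$time[w]:K] <- model$paths$mat[tree$path[w], tree$time[w]:K]
  t_hi <- if (gp == 0L) K else tree$time[gp]
  new_path[sib] <- canonical_path(model, pops, tree$time[sib], t_hi)
  keep <- setdiff(seq_len(n), c(v, w))
  map <- integer(n); map[keep] <- seq_along(keep)
  out <- local_tree(
    parent = ifelse(new_parent[keep] == 0L, 0L, map[pmax(new_parent[keep], 1L)]),
    time = tree$time[keep],
    path = new_path[keep],
    lineages = tree$lineages[-v]
  )
  out <- canonical_tree(out)
  out <- canonicalize_tree_paths(model, out)
  out$keys <- tree_keys_compute(out)
  list(tree = out, record = record)
}

# Column-likelihood of a full tree by two-state pruning (used for phase
# integration and chain statistics). `geno` is the lineages x columns matrix
# of 0/1/NA; `mu` the per-column rate; returns the per-column likelihood.
tree_column_likelihood <- function(model, tree, geno, mu, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(geno))
  Lc <- length(cols)
  n <- length(tree$parent)
  g <- model$grid$times_gen
  up0 <- matrix(1, n, Lc); up1 <- matrix(1, n, Lc)
  for (v in seq_len(tree$n_leaf)) {
    a <- geno[tree$lineages[v], cols]
    up0[v, ] <- ifelse(is.na(a), 1, as.numeric(a == 0L))
    up1[v, ] <- ifelse(is.na(a), 1, as.numeric(a == 1L))
  }
  ch <- tree_children(tree)
  for (v in order(tree$time)) {
    if (length(ch[[v]]) != 2L) next
    a0 <- rep(1, Lc); a1 <- rep(1, Lc)
    for (c_ in ch[[v]]) {
      len <- g[tree$time[v]] - g[tree$time[c_]]
      ps <- 0.5 + 0.5 * exp(-2 * mu[cols] * len)
      a0 <- a0 * (ps * up0[c_, ] + (1 - ps) * up1[c_, ])
      a1 <- a1 * (ps * up1[c_, ] + (1 - ps) * up0[c_, ])
    }
    up0[v, ] <- a0; up1[v, ] <- a1
  }
  up0[tree_root(tree), ]  # ancestral-allele root prior
}
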