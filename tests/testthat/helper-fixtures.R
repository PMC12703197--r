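# shared builders and independent oracles used across the test files

make_profile <- function(a, b, level = "amino_acid", site = 1L) {
  structure(list(set_a = sort(unique(a)), set_b = sort(unique(b)),
                 level = level, site = site, scannable = TRUE),
            class = "site_profile_pair")
}

aln_from_rows <- function(rows, level = "amino_acid") {
  mat <- do.call(rbind, strsplit(unlist(rows), ""))
  rownames(mat) <- names(rows)
  multiple_alignment(mat, level)
}

# column matrix -> alignment (one character per cell)
aln_from_matrix <- function(mat, level = "amino_acid") {
  multiple_alignment(mat, level)
}

random_labeled_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  read_newick(tr)
}

# independent brute-force mutually-exclusive-site scanner: set intersection
# per column, no optimisations, no run filter
brute_force_exclusive_sites <- function(states, group_a, group_b, sentinel) {
  which(vapply(seq_len(ncol(states)), function(s) {
    a <- states[group_a, s]; b <- states[group_b, s]
    if (any(grepl(sentinel, c(a, b), fixed = TRUE))) return(FALSE)
    length(intersect(unique(a), unique(b))) == 0L
  }, logical(1)))
}

# exhaustive parsimony oracle: enumerate every assignment of states to the
# internal nodes, score unit-cost changes over all edges, and collect the
# states each node attains in at least one minimum-cost assignment
exhaustive_parsimony_sets <- function(tree, leaf_states, alphabet) {
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1L]))
  K <- length(alphabet)
  grids <- rep(list(seq_len(K)), length(internal))
  combos <- as.matrix(expand.grid(grids))
  cost <- apply(combos, 1L, function(row) {
    st <- character(max(tree$edge))
    st[internal] <- alphabet[row]
    st[seq_len(ntip)] <- leaf_states[tree$tip.label]
    sum(vapply(seq_len(nrow(tree$edge)), function(e) {
      p <- st[tree$edge[e, 1L]]; c <- st[tree$edge[e, 2L]]
      if (leaf_missing(c)) 0L else as.integer(p != c)
    }, integer(1)))
  })
  best <- combos[cost == min(cost), , drop = FALSE]
  sets <- lapply(seq_along(internal), function(i)
    sort(alphabet[unique(best[, i])]))
  names(sets) <- as.character(internal)
  sets
}

leaf_missing <- function(s) s %in% c("X", "N")

# independent path-class walker: climbs each target leaf to its apex, then
# enumerates every node state along the parent-to-leaf paths via
# ape::nodepath, and applies the simple/complex definition directly
walker_path_class <- function(tr, targets, st) {
  ntip <- length(tr$tip.label)
  state_of <- function(v)
    if (v <= ntip) unname(st$leaf_states[tr$tip.label[v]])
    else unname(st$map_state[as.character(v)])
  parent <- rep(NA_integer_, max(tr$edge))
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  tipset <- function(v)
    if (v <= ntip) tr$tip.label[v] else ape::extract.clade(tr, v)$tip.label
  apexes <- unique(vapply(match(targets, tr$tip.label), function(tp) {
    v <- tp
    while (!is.na(parent[v]) && all(tipset(parent[v]) %in% targets))
      v <- parent[v]
    v
  }, integer(1)))
  info <- lapply(apexes, function(a) {
    pa <- parent[a]
    leaves <- intersect(tipset(a), targets)
    nodes <- unique(unlist(lapply(match(leaves, tr$tip.label), function(tp)
      setdiff(ape::nodepath(tr, from = pa, to = tp), c(pa, tp)))))
    list(parent_state = state_of(pa),
         derived = unique(unname(st$leaf_states[leaves])),
         inner_states = vapply(nodes, state_of, character(1)))
  })
  parents <- vapply(info, `[[`, character(1), "parent_state")
  if (anyNA(parents) ||
      any(vapply(info, function(x) anyNA(x$inner_states), logical(1))))
    return("unresolved")
  simple <- length(unique(parents)) == 1L &&
    all(vapply(info, function(x)
      length(x$derived) == 1L && all(x$inner_states == x$derived) &&
        parents[1L] != x$derived, logical(1)))
  if (simple) "simple" else "complex"
}

expect_same_set <- function(a, b) expect_setequal(a, b)
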