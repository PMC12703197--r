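#' Independent lineages of a chosen species set on a tree
#'
#' Partitions a set of chosen leaves into its maximal chosen-only clades: a
#' lineage is a maximal set of chosen species whose spanning subtree contains
#' no unchosen leaf. Each lineage's *apex* is the highest node all of whose
#' leaf descendants are chosen (for a single species with unchosen relatives,
#' the leaf itself; unary chains extend the apex upward). The branch entering
#' the apex is the lineage's origin branch.
#'
#' @param tree a rooted `phylo` tree.
#' @param chosen character vector of chosen leaf labels.
#' @return list of lineages, each `list(species, apex)`, in order of first
#'   chosen species.
#' @export
chosen_lineages <- function(tree, chosen) {
  idx <- match(chosen, tree$tip.label)
  if (anyNA(idx)) stop("unknown leaf label(s): ",
                       paste(chosen[is.na(idx)], collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  ord <- node_preorder(tree)
  ch <- tree_children(tree)
  n_below <- integer(nnode)
  n_chosen <- integer(nnode)
  for (v in rev(ord)) {
    if (v <= ntip) {
      n_below[v] <- 1L
      n_chosen[v] <- as.integer(v %in% idx)
    } else {
      n_below[v] <- sum(n_below[ch[[v]]])
      n_chosen[v] <- sum(n_chosen[ch[[v]]])
    }
  }
  pure <- n_below == n_chosen & n_chosen > 0L
  par <- tree_parents(tree)
  apex <- which(pure & (is.na(par[seq_len(nnode)]) | !pure[pmax(par, 1L)]))
  lin <- lapply(apex, function(a)
    list(species = sort(node_tips(tree, a)), apex = a))
  ord1 <- order(vapply(lin, function(l) min(match(l$species, chosen)),
                       numeric(1)))
  lin[ord1]
}

#' Species combination on a tree
#'
#' Wraps a k-species subset with its partition into independent lineages
#' (see [chosen_lineages()]).
#'
#' @param tree a rooted `phylo` tree.
#' @param species character vector of k distinct leaf labels.
#' @return an object of class `species_combination`: list with `species`
#'   (sorted), `lineages` (list of character vectors), `apexes` (node ids),
#'   `m` (lineage count).
#' @export
species_combination <- function(tree, species) {
  species <- sort(unique(as.character(species)))
  lin <- chosen_lineages(tree, species)
  structure(list(species = species,
                 lineages = lapply(lin, `[[`, "species"),
                 apexes = vapply(lin, `[[`, integer(1), "apex"),
                 m = length(lin)),
            class = "species_combination")
}

#' @export
print.species_combination <- function(x, ...) {
  cat(sprintf("species_combination: k=%d, m=%d lineage(s)\n",
              length(x$species), x$m))
  for (i in seq_along(x$lineages))
    cat(sprintf("  lineage %d: %s\n", i, paste(x$lineages[[i]], collapse = ",")))
  invisible(x)
}

#' Enumerate k-species combinations from independent lineages
#'
#' Enumerates subsets of k leaves in deterministic lexicographic order (over
#' sorted leaf labels). With `m = NULL` every subset qualifies; with `m` set,
#' only subsets whose chosen species fall into exactly `m` independent
#' lineages (maximal chosen-only clades), each with an origin branch (apex
#' below the root), are kept — for `m >= 2` the subset's global MRCA is then
#' automatically a strict ancestor of every lineage apex.
#'
#' With `count_only = TRUE` and `m = NULL` the subsets are streamed and
#' counted without materialisation (compiled enumeration), which handles
#' counts in the tens of millions in seconds.
#'
#' @param tree a rooted `phylo` tree.
#' @param k species per combination.
#' @param m required lineage count, or `NULL` for no constraint.
#' @param count_only return only the number of combinations.
#' @param max_materialize safety cap on the number of subsets examined when
#'   materialising (default 2e6).
#' @return list of [species_combination()] objects, or a count.
#' @export
enumerate_combinations <- function(tree, k, m = NULL, count_only = FALSE,
                                   max_materialize = 2e6) {
  tree <- validate_tree(tree)
  n <- length(tree$tip.label)
  if (k > n) stop("k exceeds the number of leaves")
  if (count_only && is.null(m))
    return(stream_ksubset_count(n, k))
  if (choose(n, k) > max_materialize)
    stop("C(", n, ",", k, ") subsets exceed max_materialize; ",
         "use count_only = TRUE or raise the cap")
  labels <- sort(tree$tip.label)
  sets <- utils::combn(labels, k, simplify = FALSE)
  combos <- lapply(sets, function(s) species_combination(tree, s))
  if (!is.null(m)) {
    root <- tree_root(tree)
    keep <- vapply(combos, function(cb)
      cb$m == m && !any(cb$apexes == root), logical(1))
    combos <- combos[keep]
  }
  if (count_only) length(combos) else combos
}

#' Filter combinations to the core-control template
#'
#' Keeps combinations whose lineages comprise exactly two lineages resident
#' in two *different* focal clades plus exactly one lineage disjoint from all
#' focal clades (the template behind core-control species sets: two of the
#' three trait clades plus one non-trait clade).
#'
#' @param combos list of `species_combination` objects.
#' @param focal_clades named list of (>= 3) disjoint leaf-label sets defining
#'   the focal clades.
#' @return the kept subset of `combos`.
#' @export
filter_core_controls <- function(combos, focal_clades) {
  stopifnot(is.list(focal_clades), length(focal_clades) >= 2L)
  all_f <- unlist(focal_clades)
  if (anyDuplicated(all_f)) stop("focal clade definitions overlap")
  keep <- vapply(combos, function(cb) {
    if (cb$m != 3L) return(FALSE)
    home <- vapply(cb$lineages, function(sp) {
      inside <- vapply(focal_clades, function(f) all(sp %in% f), logical(1))
      if (any(inside)) which(inside)[1L]
      else if (!any(sp %in% all_f)) 0L   # disjoint from all focal clades
      else -1L                           # straddles a focal boundary
    }, integer(1))
    if (any(home < 0L)) return(FALSE)
    focal_homes <- home[home > 0L]
    length(focal_homes) == 2L && length(unique(focal_homes)) == 2L &&
      sum(home == 0L) == 1L
  }, logical(1))
  combos[keep]
}

#' Phylogenetic branch features of a species combination
#'
#' Computes the four branch features used to model background convergence:
#'
#' * `POB` — product of the origin-branch lengths over the combination's `m`
#'   lineages (the branch entering each lineage apex);
#' * `PTB` — product of the `k` terminal branch lengths;
#' * `DTB` — sum over species of the path length from the tree-wide MRCA to
#'   the leaf;
#' * `DTN` — sum over species of the path length from the tree-wide MRCA to
#'   the leaf's most recent ancestral node (its parent), so that
#'   `DTB - DTN` equals the summed terminal branch lengths.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param combo a `species_combination` (or character vector of leaf labels).
#' @return an object of class `phylo_features`: list with `POB`, `PTB`,
#'   `DTB`, `DTN`, `m`, `k`.
#' @export
compute_phylo_features <- function(tree, combo) {
  tree <- validate_tree(tree)
  if (!inherits(combo, "species_combination"))
    combo <- species_combination(tree, combo)
  root <- tree_root(tree)
  if (any(combo$apexes == root))
    stop("lineage apex at the tree root has no origin branch")
  bl <- tree_branch_in(tree)
  origin <- bl[combo$apexes]
  if (any(origin == 0))
    warning("zero-length origin branch; POB is 0")
  tips <- match(combo$species, tree$tip.label)
  depth <- tree_root_depths(tree)
  gmrca <- mrca_node(tree, tree$tip.label)   # MRCA of all leaves
  par <- tree_parents(tree)
  structure(list(POB = prod(origin),
                 PTB = prod(bl[tips]),
                 DTB = sum(depth[tips] - depth[gmrca]),
                 DTN = sum(depth[par[tips]] - depth[gmrca]),
                 m = combo$m, k = length(combo$species)),
            class = "phylo_features")
}

#' @export
print.phylo_features <- function(x, ...) {
  cat(sprintf("phylo_features (k=%d, m=%d): POB=%g PTB=%g DTB=%g DTN=%g\n",
              x$k, x$m, x$POB, x$PTB, x$DTB, x$DTN))
  invisible(x)
}

#' Feature table over many combinations
#'
#' @param tree a rooted `phylo` tree.
#' @param combos list of `species_combination` objects.
#' @return data frame with columns `combo_id`, `species`, `m`, `POB`, `PTB`,
#'   `DTB`, `DTN`.
#' @export
phylo_features_table <- function(tree, combos) {
  rows <- lapply(seq_along(combos), function(i) {
    f <- compute_phylo_features(tree, combos[[i]])
    data.frame(combo_id = i,
               species = paste(combos[[i]]$species, collapse = ","),
               m = f$m, POB = f$POB, PTB = f$PTB, DTB = f$DTB, DTN = f$DTN,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
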