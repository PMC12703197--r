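#' Ancestral state reconstruction at one alignment site
#'
#' Reconstructs states at the internal nodes of a fixed rooted tree for one
#' site (column) of an alignment, in one of two modes:
#'
#' * `"parsimony"`: unit-cost (Fitch/Sankoff) parsimony. For every internal
#'   node the full set of states attained by at least one maximum-parsimony
#'   assignment is computed exactly by an up-down dynamic program; the
#'   posterior is uniform over that set.
#' * `"ml"`: marginal maximum-likelihood posteriors under a K-state
#'   equal-rates, time-reversible substitution model with uniform equilibrium
#'   frequencies over the states observed in the column, computed by the
#'   pruning recursion followed by an outside pass.
#'
#' The alphabet is the set of states observed at the site, with the gap `-`
#' as a full state; ambiguity sentinels (`X`, or any state containing `N`)
#' are treated as missing data. Branch lengths are in expected substitutions
#' per site. A tree of total length zero in `"ml"` mode degenerates (all
#' transition matrices are the identity) and falls back to parsimony with a
#' warning. MAP states are reported as `NA` when tied, never broken
#' arbitrarily.
#'
#' @param tree a rooted `phylo` tree whose leaves are alignment rows.
#' @param aln a `multiple_alignment` containing every leaf of `tree`.
#' @param site 1-based site index (codon index for `level = "codon"`).
#' @param mode `"parsimony"` or `"ml"`.
#' @param level state level, as in [site_profiles()]; defaults to the
#'   alignment's own level.
#' @return an object of class `ancestral_state_map`: list with `site`,
#'   `mode`, `alphabet`, `posterior` (internal-node x state matrix, rows
#'   named by ape node id), `map_state` (named character, `NA` on ties),
#'   `leaf_states` (named character vector of observed leaf states).
#' @export
reconstruct_marginal_states <- function(tree, aln, site,
                                        mode = c("ml", "parsimony"),
                                        level = NULL) {
  mode <- match.arg(mode)
  tree <- validate_tree(tree)
  if (!all(tree$tip.label %in% alignment_species(aln)))
    stop("tree leaves missing from alignment: ",
         paste(setdiff(tree$tip.label, alignment_species(aln)), collapse = ", "))
  level <- level %||% alignment_level(aln)
  states <- site_states(aln, site, level)[tree$tip.label]
  missing_state <- if (level == "amino_acid") function(s) grepl("X", s, fixed = TRUE)
                   else function(s) grepl("N", s, fixed = TRUE)
  obs <- states[!missing_state(states)]
  alphabet <- sort(unique(unname(obs)))
  if (!length(alphabet)) stop("column has no unambiguous states (unresolvable)")
  if (all(alphabet == "-") || all(alphabet == "---"))
    stop("all-gap column is unresolvable")

  if (mode == "ml" && sum(tree$edge.length) == 0) {
    warning("zero-length tree in ml mode; falling back to parsimony")
    mode <- "parsimony"
  }
  post <- if (mode == "parsimony")
    parsimony_posteriors(tree, states, alphabet, missing_state)
  else
    ml_posteriors(tree, states, alphabet, missing_state)

  map <- apply(post, 1L, function(p) {
    top <- which(p > max(p) - 1e-12)
    if (length(top) == 1L) colnames(post)[top] else NA_character_
  })
  structure(list(site = site, mode = mode, alphabet = alphabet,
                 posterior = post, map_state = map, leaf_states = states),
            class = "ancestral_state_map")
}

#' @export
print.ancestral_state_map <- function(x, ...) {
  cat(sprintf("ancestral_state_map: site %d, mode %s, %d internal nodes, alphabet {%s}\n",
              x$site, x$mode, nrow(x$posterior),
              paste(x$alphabet, collapse = ",")))
  invisible(x)
}

# exact per-node optimal-state sets under unit-cost parsimony (up-down DP);
# posterior uniform over the optimal set
parsimony_posteriors <- function(tree, states, alphabet, missing_state) {
  K <- length(alphabet)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  ch <- tree_children(tree)
  ord <- node_preorder(tree)
  INF <- .Machine$double.xmax / 4

  up <- matrix(0, nnode, K)       # min cost of subtree given node state
  m <- matrix(0, nnode, K)        # per-child message given parent state
  for (v in rev(ord)) {
    if (v <= ntip) {
      s <- states[tree$tip.label[v]]
      up[v, ] <- if (missing_state(s)) 0 else ifelse(alphabet == s, 0, INF)
    } else {
      for (c in ch[[v]]) {
        best <- min(up[c, ])
        m[c, ] <- pmin(up[c, ] + 1, best + 1)       # parent != child costs 1
        m[c, ] <- pmin(m[c, ], up[c, ])             # parent == child
        up[v, ] <- up[v, ] + m[c, ]
      }
    }
  }
  root <- tree_root(tree)
  down <- matrix(0, nnode, K)     # min cost of rest of tree given node state
  for (v in ord) {
    if (v <= ntip || is.null(ch[[v]])) next
    for (c in ch[[v]]) {
      other <- up[v, ] - m[c, ]   # siblings' contribution given v's state
      base <- down[v, ] + other
      down[c, ] <- pmin(min(base) + 1, base)        # change vs keep on edge
    }
  }
  tot <- up + down
  gmin <- min(tot[root, ])
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  post <- matrix(0, length(internal), K,
                 dimnames = list(as.character(internal), alphabet))
  for (i in seq_along(internal)) {
    opt <- tot[internal[i], ] <= gmin + 1e-9
    post[i, ] <- opt / sum(opt)
  }
  post
}

# transition matrix of the K-state equal-rates model, branch length t in
# expected substitutions per site
equal_rates_P <- function(K, t) {
  if (K == 1L) return(matrix(1, 1, 1))
  e <- exp(-K * t / (K - 1))
  P <- matrix((1 - e) / K, K, K)
  diag(P) <- 1 / K + (K - 1) * e / K
  P
}

ml_posteriors <- function(tree, states, alphabet, missing_state) {
  K <- length(alphabet)
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  ch <- tree_children(tree)
  bl <- tree_branch_in(tree)
  ord <- node_preorder(tree)
  root <- tree_root(tree)

  L <- matrix(1, nnode, K)        # conditional likelihood of data below node
  for (v in rev(ord)) {
    if (v <= ntip) {
      s <- states[tree$tip.label[v]]
      if (!missing_state(s)) L[v, ] <- as.numeric(alphabet == s)
    } else {
      for (c in ch[[v]]) {
        P <- equal_rates_P(K, bl[c])
        L[v, ] <- L[v, ] * as.vector(P %*% L[c, ])
      }
      if (max(L[v, ]) > 0) L[v, ] <- L[v, ] / max(L[v, ])  # rescale
    }
  }
  O <- matrix(0, nnode, K)        # outside: prior x likelihood of rest
  O[root, ] <- 1 / K
  for (v in ord) {
    if (v <= ntip || is.null(ch[[v]])) next
    for (c in ch[[v]]) {
      sib <- rep(1, K)
      for (b in setdiff(ch[[v]], c)) {
        P <- equal_rates_P(K, bl[b])
        sib <- sib * as.vector(P %*% L[b, ])
      }
      P <- equal_rates_P(K, bl[c])
      O[c, ] <- as.vector(t(P) %*% (O[v, ] * sib))
      if (max(O[c, ]) > 0) O[c, ] <- O[c, ] / max(O[c, ])
    }
  }
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  post <- L[internal, , drop = FALSE] * O[internal, , drop = FALSE]
  post <- post / rowSums(post)
  dimnames(post) <- list(as.character(internal), alphabet)
  post
}

#' Binary presence/absence encoding of an alignment
#'
#' Encodes every cell as 0 (gap) or 1 (any residue), preserving column order
#' and retaining all-gap columns, so indel histories can be reconstructed as
#' binary characters alongside the substitution history.
#'
#' @param aln a `multiple_alignment`.
#' @return integer matrix of 0/1 with the alignment's dimnames.
#' @export
encode_indels_binary <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"))
  out <- matrix(1L, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  out[unclass(aln) == "-"] <- 0L
  out
}

#' Classify the evolutionary path of a target-group variant
#'
#' Given ancestral reconstructions at a variant site, labels the variant's
#' history across the target clades as `"simple"` (parallel: every clade's
#' origin branch changes directly from one shared ancestral state to the
#' clade's derived state, with no differing intermediate states inside any
#' clade) or `"complex"` (convergence or divergence via intermediates).
#' Unresolved MAP states (posterior ties) on any needed node give
#' `"unresolved"`.
#'
#' Target clades are the maximal chosen-only lineages of `part$group_a` on
#' the tree (see [enumerate_combinations()] for the lineage rule); the origin
#' branch of a clade is the branch entering its apex node.
#'
#' @param tree a rooted `phylo` tree.
#' @param part a `species_partition`; all of `group_a` must be tree leaves.
#' @param states an `ancestral_state_map` for the site (from
#'   [reconstruct_marginal_states()]).
#' @param derived_profile optional `site_profile_pair` for the site; used
#'   only for bookkeeping in the returned object.
#' @return an object of class `evolutionary_path`: list with `clades` (data
#'   frame: clade, species, apex_node, parent_node, parent_state,
#'   derived_state, direct) and `path_class`.
#' @export
classify_path <- function(tree, part, states, derived_profile = NULL) {
  stopifnot(inherits(states, "ancestral_state_map"))
  tree <- validate_tree(tree)
  if (!all(part$group_a %in% tree$tip.label))
    stop("target species missing from tree")
  lin <- chosen_lineages(tree, part$group_a)
  par <- tree_parents(tree)
  ntip <- length(tree$tip.label)
  node_state <- function(v) {
    if (v <= ntip) states$leaf_states[tree$tip.label[v]]
    else states$map_state[as.character(v)]
  }

  rows <- lapply(seq_along(lin), function(i) {
    apex <- lin[[i]]$apex
    parent <- par[apex]
    if (is.na(parent)) stop("target lineage apex is the tree root; no origin branch")
    leaves <- lin[[i]]$species
    leaf_states <- states$leaf_states[leaves]
    derived <- if (length(unique(leaf_states)) == 1L)
      unname(leaf_states[1L]) else NA_character_
    inner <- setdiff(descendant_nodes(tree, apex), match(leaves, tree$tip.label))
    inner_states <- vapply(c(apex, inner), node_state, character(1))
    data.frame(clade = i, species = paste(leaves, collapse = ","),
               apex_node = apex, parent_node = parent,
               parent_state = unname(node_state(parent)),
               derived_state = derived,
               direct = !is.na(derived) && !anyNA(inner_states) &&
                 all(inner_states == derived),
               stringsAsFactors = FALSE)
  })
  clades <- do.call(rbind, rows)

  path_class <- if (anyNA(clades$parent_state) ||
                    any(vapply(seq_along(lin), function(i) {
                      apex <- lin[[i]]$apex
                      inner <- setdiff(descendant_nodes(tree, apex),
                                       match(lin[[i]]$species, tree$tip.label))
                      anyNA(vapply(c(apex, inner), node_state, character(1)))
                    }, logical(1))))
    "unresolved"
  else if (length(unique(clades$parent_state)) == 1L &&
           all(clades$direct) &&
           all(clades$parent_state != clades$derived_state))
    "simple"
  else
    "complex"

  structure(list(clades = clades, path_class = path_class,
                 profile = derived_profile),
            class = "evolutionary_path")
}

#' @export
print.evolutionary_path <- function(x, ...) {
  cat(sprintf("evolutionary_path: %s (%d target clade(s))\n",
              x$path_class, nrow(x$clades)))
  for (i in seq_len(nrow(x$clades)))
    cat(sprintf("  clade %d [%s]: %s -> %s\n", i, x$clades$species[i],
                x$clades$parent_state[i], x$clades$derived_state[i]))
  invisible(x)
}

# all internal nodes strictly below a node (excluding leaves and the node)
descendant_nodes <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- ch[[node]]
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v > ntip) {
      out <- c(out, v)
      stack <- c(stack, ch[[v]])
    }
  }
  out
}

#' Read RAxML marginal ancestral state output
#'
#' Parses the `marginalAncestralStates` file RAxML writes with `-f A` (lines
#' of `nodeLabel<TAB or space>sequence`) so externally computed
#' reconstructions can be compared with the in-package ones. Because such
#' runs drop columns that are all-gap in every species, `keep_mask` (logical,
#' one per original column, `TRUE` = retained) re-inserts dropped columns as
#' gaps to restore the original coordinates.
#'
#' @param path path to a `marginalAncestralStates` file.
#' @param keep_mask optional logical vector over original columns.
#' @return named character vector of per-node state sequences (original
#'   coordinates if `keep_mask` given).
#' @export
read_raxml_ancestral <- function(path, keep_mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(trimws(lines), "\\s+")
  seqs <- stats::setNames(vapply(f, `[[`, character(1), 2L),
                          vapply(f, `[[`, character(1), 1L))
  if (!is.null(keep_mask)) {
    if (any(nchar(seqs) != sum(keep_mask)))
      stop("sequence length does not match keep_mask")
    seqs <- vapply(seqs, function(s) {
      out <- rep("-", length(keep_mask))
      out[keep_mask] <- strsplit(s, "")[[1]]
      paste(out, collapse = "")
    }, character(1))
  }
  seqs
}
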