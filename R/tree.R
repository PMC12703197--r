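#' Read a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the toolkit relies on: a rooted tree, unique leaf labels, and
#' non-negative branch lengths. Missing branch lengths default to 0 with a
#' warning.
#'
#' @param path path to a Newick file (or a `phylo` object, passed through the
#'   same checks).
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- if (inherits(path, "phylo")) path else {
    if (!file.exists(path)) stop("file not found: ", path)
    out <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("Newick parse error: ",
                                             conditionMessage(e)))
    if (is.null(out)) stop("Newick parse error in ", path)
    out
  }
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  # a basal multifurcation (e.g. a star tree) is treated as rooted at its
  # root node; every phylo object has exactly one such node
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

# --- small internal tree helpers (ape numbering: tips 1..n, root n+1) -------

tree_root <- function(tr) length(tr$tip.label) + 1L

# parent[node] = parent node id, NA at root
tree_parents <- function(tr) {
  par <- rep(NA_integer_, max(tr$edge))
  par[tr$edge[, 2L]] <- tr$edge[, 1L]
  par
}

# incoming branch length per node, NA at root
tree_branch_in <- function(tr) {
  bl <- rep(NA_real_, max(tr$edge))
  bl[tr$edge[, 2L]] <- tr$edge.length
  bl
}

# children list per node
tree_children <- function(tr) {
  ch <- vector("list", max(tr$edge))
  for (i in seq_len(nrow(tr$edge)))
    ch[[tr$edge[i, 1L]]] <- c(ch[[tr$edge[i, 1L]]], tr$edge[i, 2L])
  ch
}

# distance from root to every node
tree_root_depths <- function(tr) {
  par <- tree_parents(tr)
  bl <- tree_branch_in(tr)
  ord <- node_preorder(tr)
  d <- rep(NA_real_, max(tr$edge))
  d[tree_root(tr)] <- 0
  for (v in ord[-1L]) d[v] <- d[par[v]] + bl[v]
  d
}

# preorder (root first) over all nodes
node_preorder <- function(tr) {
  ch <- tree_children(tr)
  out <- integer(0)
  stack <- tree_root(tr)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    if (!is.null(ch[[v]])) stack <- c(stack, rev(ch[[v]]))
  }
  out
}

# MRCA node of a set of tip labels (the tip itself for a singleton)
mrca_node <- function(tr, tips) {
  idx <- match(tips, tr$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s): ",
                       paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tr, idx)
}

# tip labels descending from a node
node_tips <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(tr$tip.label[node])
  ch <- tree_children(tr)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, tr$tip.label[v]) else stack <- c(stack, ch[[v]])
  }
  out
}
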