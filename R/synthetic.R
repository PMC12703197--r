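#' Simulation configuration for tree-consistent alignments
#'
#' Describes a synthetic alignment: background sites evolve down a fixed
#' rooted tree under an equal-rates (Jukes-Cantor-style) substitution
#' process from a random root sequence; selected sites are then overwritten
#' ("planted") so that a chosen target group carries prescribed group-A
#' states and every other species carries prescribed group-B states,
#' realising a requested mutually exclusive variant type with known truth.
#'
#' A plant is a list with elements `site` (1-based, in the level's
#' coordinates), `a_species` (target taxa), `a_states`, `b_states` (for
#' `level = "codon"`, codon triplets), `type` (expected 1-4), and optionally
#' `expected_synonymy` / `expected_source` for codon plants. The generator
#' validates that the requested type matches the state-set cardinalities
#' (e.g. Type 1 needs exactly one A state and one B state) and that the
#' state sets are disjoint.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param n_sites number of sites (codons for `level = "codon"`).
#' @param level `"amino_acid"` or `"codon"`.
#' @param rate multiplier applied to branch lengths before simulation
#'   (0 gives an invariant background).
#' @param plants list of plant specifications (see Details).
#' @param indel_prob per-leaf, per-site probability of gapping a
#'   non-planted site (default 0).
#' @param seed integer seed making the output fully reproducible.
#' @param allow_adjacent permit plants at adjacent sites (used to exercise
#'   the continuous-run filter; otherwise adjacency is a configuration
#'   error).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_sites, level = c("amino_acid", "codon"),
                              rate = 1, plants = list(), indel_prob = 0,
                              seed = 1L, allow_adjacent = FALSE) {
  level <- match.arg(level)
  tree <- validate_tree(tree)
  sites <- vapply(plants, `[[`, numeric(1), "site")
  if (anyDuplicated(sites)) stop("planted sites must be distinct")
  if (any(sites < 1 | sites > n_sites)) stop("planted site out of range")
  if (!allow_adjacent && length(sites) > 1L &&
      min(diff(sort(sites))) <= 1L)
    stop("plants at adjacent sites; set allow_adjacent = TRUE if intended")
  for (p in plants) validate_plant(p, tree, level)
  structure(list(tree = tree, n_sites = n_sites, level = level, rate = rate,
                 plants = plants, indel_prob = indel_prob, seed = seed,
                 allow_adjacent = allow_adjacent),
            class = "simulation_config")
}

validate_plant <- function(p, tree, level) {
  need <- c("site", "a_species", "a_states", "b_states")
  if (!all(need %in% names(p))) stop("plant missing field(s): ",
                                     paste(setdiff(need, names(p)), collapse = ", "))
  if (!all(p$a_species %in% tree$tip.label))
    stop("plant target species not in tree")
  a <- unique(p$a_states); b <- unique(p$b_states)
  if (length(intersect(a, b)))
    stop("plant state sets must be disjoint")
  n_b_species <- length(tree$tip.label) - length(p$a_species)
  if (length(a) > length(p$a_species) || length(b) > n_b_species)
    stop("more planted states than species to carry them")
  if (level == "codon" && any(nchar(c(a, b)) != 3L))
    stop("codon plants need 3-letter states")
  if (!is.null(p$type)) {
    implied <- if (length(a) == 1L) {
      if (length(b) == 1L) 1L else 2L
    } else if (length(b) == 1L) 3L else 4L
    if (p$type != implied)
      stop("plant at site ", p$site, " requests Type ", p$type,
           " but its state sets imply Type ", implied)
  }
  invisible(p)
}

#' Simulate an alignment with planted exclusive variants
#'
#' Runs the background substitution process described in
#' [simulation_config()], overwrites the planted sites, and returns the
#' alignment together with a truth table recording every plant. The same
#' seed reproduces the alignment exactly.
#'
#' @param config a `simulation_config`.
#' @return list with `alignment` (a `multiple_alignment`; nucleotide level
#'   for codon simulations) and `truth` (data frame: site, level, type,
#'   con_div, a_states, b_states, synonymy, nt_source, filtered — `filtered`
#'   marks plants expected to be removed by the continuous-run filter).
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tr <- config$tree
  alphabet <- if (config$level == "amino_acid")
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] else c("A", "C", "G", "T")
  n_col <- if (config$level == "amino_acid") config$n_sites
           else 3L * config$n_sites
  K <- length(alphabet)

  # background: equal-rates process down the tree from a uniform root sequence
  nnode <- max(tr$edge)
  ord <- node_preorder(tr)
  par <- tree_parents(tr)
  bl <- tree_branch_in(tr) * config$rate
  seqs <- matrix(NA_character_, nnode, n_col)
  seqs[tree_root(tr), ] <- sample(alphabet, n_col, replace = TRUE)
  for (v in ord[-1L]) {
    t_v <- bl[v]
    p_change <- if (t_v <= 0) 0 else (K - 1) / K * (1 - exp(-K * t_v / (K - 1)))
    parent_seq <- seqs[par[v], ]
    change <- stats::runif(n_col) < p_change
    out <- parent_seq
    if (any(change)) {
      shift <- sample.int(K - 1L, sum(change), replace = TRUE)
      out[change] <- alphabet[((match(parent_seq[change], alphabet) - 1L +
                                  shift) %% K) + 1L]
    }
    seqs[v, ] <- out
  }
  ntip <- length(tr$tip.label)
  mat <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(mat) <- tr$tip.label

  planted_cols <- integer(0)
  for (p in config$plants) {
    cols <- if (config$level == "codon")
      (3L * p$site - 2L):(3L * p$site) else p$site
    planted_cols <- c(planted_cols, cols,
                      if (config$level == "amino_acid") c(p$site - 1L, p$site + 1L)
                      else c(cols - 3L, cols + 3L))
  }

  # indels only away from plants and their immediate neighbours
  if (config$indel_prob > 0) {
    free <- setdiff(seq_len(n_col), planted_cols)
    gap <- matrix(stats::runif(ntip * length(free)) < config$indel_prob,
                  ntip, length(free))
    if (config$level == "codon") {       # gap whole codons to keep frame clean
      codon_of <- (free - 1L) %/% 3L     # 0-based codon index per free column
      for (i in seq_len(ntip)) {
        gc <- unique(codon_of[gap[i, ]])
        gcols <- intersect(as.vector(vapply(gc, function(g)
          3L * g + 1:3, integer(3))), free)
        mat[i, gcols] <- "-"
      }
    } else {
      for (i in seq_len(ntip)) mat[i, free[gap[i, ]]] <- "-"
    }
  }

  truth <- list()
  sites <- vapply(config$plants, `[[`, numeric(1), "site")
  for (p in config$plants) {
    a <- unique(p$a_states); b <- unique(p$b_states)
    b_species <- setdiff(tr$tip.label, p$a_species)
    a_assign <- rep_len(a, length(p$a_species))
    b_assign <- rep_len(b, length(b_species))
    cols <- if (config$level == "codon")
      (3L * p$site - 2L):(3L * p$site) else p$site
    put <- function(species, states) {
      for (i in seq_along(species)) {
        mat[species[i], cols] <<- strsplit(states[i], "")[[1]]
      }
    }
    put(p$a_species, a_assign)
    put(b_species, b_assign)
    type <- if (length(a) == 1L) { if (length(b) == 1L) 1L else 2L }
            else { if (length(b) == 1L) 3L else 4L }
    truth[[length(truth) + 1L]] <- data.frame(
      site = p$site,
      level = if (config$level == "codon") "codon" else "amino_acid",
      type = type, con_div = label_con_div(type),
      a_states = paste(sort(a), collapse = ","),
      b_states = paste(sort(b), collapse = ","),
      synonymy = p$expected_synonymy %||% NA_character_,
      nt_source = p$expected_source %||% NA_character_,
      filtered = any(abs(sites - p$site) == 1L),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
  else data.frame(site = integer(0), level = character(0), type = integer(0),
                  con_div = character(0), a_states = character(0),
                  b_states = character(0), synonymy = character(0),
                  nt_source = character(0), filtered = logical(0))

  aln <- multiple_alignment(mat, if (config$level == "amino_acid")
    "amino_acid" else "nucleotide")
  list(alignment = aln, truth = truth[order(truth$site), , drop = FALSE])
}

#' Write a standard fixture suite to a directory
#'
#' Generates a reproducible set of small test inputs: toy trees (4, 8, and
#' 12 leaves), an amino-acid alignment with plants of all four variant
#' types, a codon alignment with plants exercising every nucleotide-source
#' class (ConSNV / DivSNV / CNENV) and both synonymy classes, an
#' adjacent-plant alignment for the continuous-run filter, a two-block MAF
#' file with a minus-strand row, and truth tables as TSV. All randomness
#' derives from `seed`; the same seed writes byte-identical files.
#'
#' @param out_dir writable output directory (created if absent).
#' @param seed integer seed.
#' @return named character vector of the written paths, invisibly.
#' @export
generate_fixture_suite <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  trees <- fixture_trees()
  paths <- c(tree4 = file.path(out_dir, "tree4.nwk"),
             tree8 = file.path(out_dir, "tree8.nwk"),
             tree12 = file.path(out_dir, "tree12.nwk"),
             aa = file.path(out_dir, "aa_plants.faa"),
             aa_truth = file.path(out_dir, "aa_plants_truth.tsv"),
             codon = file.path(out_dir, "codon_plants.fna"),
             codon_truth = file.path(out_dir, "codon_plants_truth.tsv"),
             adjacent = file.path(out_dir, "aa_adjacent.faa"),
             adjacent_truth = file.path(out_dir, "aa_adjacent_truth.tsv"),
             maf = file.path(out_dir, "blocks.maf"))
  ape::write.tree(trees$t4, paths["tree4"])
  ape::write.tree(trees$t8, paths["tree8"])
  ape::write.tree(trees$t12, paths["tree12"])

  aa <- simulate_alignment(fixture_aa_config(trees$t12, seed))
  write_fasta_alignment(aa$alignment, paths["aa"])
  write_truth(aa$truth, paths["aa_truth"])

  cod <- simulate_alignment(fixture_codon_config(trees$t8, seed + 1L))
  write_fasta_alignment(cod$alignment, paths["codon"])
  write_truth(cod$truth, paths["codon_truth"])

  adj <- simulate_alignment(fixture_adjacent_config(trees$t8, seed + 2L))
  write_fasta_alignment(adj$alignment, paths["adjacent"])
  write_truth(adj$truth, paths["adjacent_truth"])

  writeLines(fixture_maf_lines(), paths["maf"])
  invisible(paths)
}

write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# three nested toy trees; the 12-leaf tree has two deep target clades plus a
# separated single-species lineage, mirroring a polyphyletic trait group
fixture_trees <- function() {
  list(
    t4 = read_newick(ape::read.tree(
      text = "((A:0.1,B:0.12):0.05,(C:0.08,D:0.11):0.07);")),
    t8 = read_newick(ape::read.tree(
      text = "(((s1:0.05,s2:0.06):0.04,(s3:0.07,s4:0.05):0.03):0.02,((s5:0.06,s6:0.04):0.05,(s7:0.08,s8:0.05):0.04):0.03);")),
    t12 = read_newick(ape::read.tree(
      text = paste0("(((v1:0.04,v2:0.05):0.03,(b1:0.06,b2:0.04):0.02):0.02,",
                    "(((v3:0.05,v4:0.04):0.03,b3:0.07):0.02,",
                    "((v5:0.06,b4:0.05):0.03,(b5:0.04,b6:0.05):0.02):0.02):0.02);"))))
}

# all four types planted on an invariant background (rate 0) so recovery is
# exactly the planted set
fixture_aa_config <- function(tree, seed) {
  a <- c("v1", "v2", "v3", "v4", "v5")
  simulation_config(
    tree, n_sites = 40L, level = "amino_acid", rate = 0, seed = seed,
    plants = list(
      list(site = 5L, a_species = a, a_states = "N", b_states = "H", type = 1L),
      list(site = 12L, a_species = a, a_states = "V",
           b_states = c("I", "-"), type = 2L),
      list(site = 20L, a_species = a, a_states = c("S", "T"),
           b_states = "G", type = 3L),
      list(site = 30L, a_species = a, a_states = c("Q", "V", "L"),
           b_states = c("A", "I"), type = 4L)))
}

fixture_codon_config <- function(tree, seed) {
  a <- c("s1", "s2", "s5")
  simulation_config(
    tree, n_sites = 30L, level = "codon", rate = 0, seed = seed,
    plants = list(
      list(site = 3L, a_species = a, a_states = "AAT",
           b_states = c("CAT", "CAC"), type = 2L,
           expected_synonymy = "nonsynonymous", expected_source = "ConSNV"),
      list(site = 8L, a_species = a, a_states = c("AAA", "GAA"),
           b_states = "CAA", type = 3L,
           expected_synonymy = "nonsynonymous", expected_source = "DivSNV"),
      list(site = 14L, a_species = a, a_states = c("TCA", "AGT"),
           b_states = "ACT", type = 3L,
           expected_synonymy = "nonsynonymous", expected_source = "CNENV"),
      list(site = 20L, a_species = a, a_states = "CTT",
           b_states = "CTC", type = 1L,
           expected_synonymy = "synonymous", expected_source = "ConSNV"),
      list(site = 26L, a_species = a, a_states = c("TTA", "CTG"),
           b_states = c("CTC", "TTG"), type = 4L,
           expected_synonymy = "synonymous", expected_source = "CNENV")))
}

fixture_adjacent_config <- function(tree, seed) {
  a <- c("s1", "s2")
  simulation_config(
    tree, n_sites = 20L, level = "amino_acid", rate = 0, seed = seed,
    allow_adjacent = TRUE,
    plants = list(
      list(site = 9L, a_species = a, a_states = "W", b_states = "R", type = 1L),
      list(site = 10L, a_species = a, a_states = "K", b_states = "E", type = 1L),
      list(site = 15L, a_species = a, a_states = "F", b_states = "Y", type = 1L)))
}

# two adjacent blocks on the same reference plus a minus-strand query row
fixture_maf_lines <- function() {
  c("##maf version=1",
    "a score=100.0",
    "s ref.chr1 100 6 + 1000 AATG-GA",
    "s sp1.chr5  40 7 + 500  CATGCGA",
    "s sp2.chr2 210 6 - 800  AAT-CGA",
    "",
    "a score=80.0",
    "s ref.chr1 106 4 + 1000 TTAC",
    "s sp1.chr5  47 4 + 500  TTGC")
}
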