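test_that("invariant and small columns reconstruct as expected", {
  tr <- read_newick(ape::read.tree(text = "(A:0.05,B:0.05);"))
  aln <- aln_from_rows(list(A = "A", B = "A"))
  r <- reconstruct_marginal_states(tr, aln, 1, mode = "ml")
  expect_equal(unname(r$map_state), "A")
  expect_gt(r$posterior[1, "A"], 0.99)

  # 3-leaf star, states A,A,C, equal branch lengths: root is A, and the
  # posterior matches a hand evaluation of the pruning recursion for the
  # 2-state equal-rates model
  star <- read_newick(ape::read.tree(text = "(A:1,B:1,C:1);"))
  aln3 <- aln_from_rows(list(A = "A", B = "A", C = "C"))
  r3 <- reconstruct_marginal_states(star, aln3, 1, mode = "ml")
  expect_equal(unname(r3$map_state), "A")
  p_same <- 1 / 2 + exp(-2) / 2          # K = 2, t = 1
  p_diff <- 1 / 2 - exp(-2) / 2
  lik_A <- p_same * p_same * p_diff
  lik_C <- p_diff * p_diff * p_same
  expect_equal(unname(r3$posterior[1, "A"]), lik_A / (lik_A + lik_C),
               tolerance = 1e-12)

  expect_error(reconstruct_marginal_states(
    star, aln_from_rows(list(A = "-", B = "-", C = "-")), 1), "unresolvable")
})

test_that("parsimony mode equals an exhaustive minimum-cost enumeration", {
  tr <- read_newick(ape::read.tree(
    text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);"))
  set.seed(21)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:100) {
    states <- sample(alphabet, 4, replace = TRUE)
    names(states) <- c("A", "B", "C", "D")
    aln <- aln_from_matrix(matrix(states, 4, 1,
                                  dimnames = list(names(states), NULL)),
                           "nucleotide")
    r <- reconstruct_marginal_states(tr, aln, 1, mode = "parsimony")
    obs_alpha <- sort(unique(unname(states)))
    want <- exhaustive_parsimony_sets(tr, states, obs_alpha)
    for (node in rownames(r$posterior)) {
      got_set <- colnames(r$posterior)[r$posterior[node, ] > 0]
      expect_equal(sort(got_set), want[[node]])
    }
  }
})

test_that("parsimony agrees with an independent Fitch implementation", {
  skip_if_not_installed("phangorn")
  tr <- read_newick(ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);"))
  set.seed(33)
  for (i in 1:40) {
    states <- stats::setNames(sample(c("A", "C", "G", "T"), 6, TRUE),
                              tr$tip.label)
    aln <- aln_from_matrix(matrix(states, 6, 1,
                                  dimnames = list(names(states), NULL)),
                           "nucleotide")
    r <- reconstruct_marginal_states(tr, aln, 1, mode = "parsimony")
    pd <- phangorn::phyDat(t(t(states)), type = "DNA")
    anc <- phangorn::ancestral.pars(tr, pd, type = "MPR")
    lv <- toupper(attr(anc, "levels"))
    for (node in rownames(r$posterior)) {
      got <- sort(colnames(r$posterior)[r$posterior[node, ] > 0])
      ref <- sort(lv[anc[[as.integer(node)]][1, ] > 0])
      expect_equal(got, ref)
    }
  }
})

test_that("short-branch likelihood reconstruction converges to parsimony", {
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = "A", B = "A", C = "C", D = "A")
  aln <- aln_from_matrix(matrix(states, 4, 1,
                                dimnames = list(names(states), NULL)),
                         "nucleotide")
  trs <- tr0; trs$edge.length <- rep(1e-4, nrow(tr0$edge))
  rml <- reconstruct_marginal_states(read_newick(trs), aln, 1, mode = "ml")
  rp <- reconstruct_marginal_states(read_newick(tr0), aln, 1,
                                    mode = "parsimony")
  # Fitch is unambiguous here (A everywhere): the ML MAP matches it
  expect_equal(rml$map_state, rp$map_state)
  expect_true(all(rml$map_state == "A"))

  trz <- tr0; trz$edge.length <- rep(0, nrow(tr0$edge))
  expect_warning(rz <- reconstruct_marginal_states(read_newick(trz), aln, 1,
                                                   mode = "ml"),
                 "falling back to parsimony")
  expect_equal(rz$mode, "parsimony")
})

test_that("posteriors normalise and ties are reported as unresolved", {
  tr <- read_newick(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  states <- c(A = "A", B = "C", C = "A", D = "C")   # fully symmetric
  aln <- aln_from_matrix(matrix(states, 4, 1,
                                dimnames = list(names(states), NULL)),
                         "nucleotide")
  for (mode in c("ml", "parsimony")) {
    r <- reconstruct_marginal_states(tr, aln, 1, mode = mode)
    expect_equal(unname(rowSums(r$posterior)), rep(1, nrow(r$posterior)),
                 tolerance = 1e-12)
    expect_true(is.na(r$map_state[as.character(convarfinder:::tree_root(tr))]))
  }
})

test_that("indel binary encoding preserves shape and all-gap columns", {
  aln <- aln_from_rows(list(s1 = "A-T", s2 = "--T", s3 = "-CT"),
                       "nucleotide")
  enc <- encode_indels_binary(aln)
  expect_equal(dim(enc), dim(aln))
  expect_equal(unname(enc["s1", ]), c(1L, 0L, 1L))
  all_gap <- aln_from_rows(list(s1 = "A-", s2 = "C-"), "nucleotide")
  enc2 <- encode_indels_binary(all_gap)
  expect_equal(unname(enc2[, 2]), c(0L, 0L))
})

test_that("path classification separates simple parallel from complex histories", {
  # two target clades {t1,t2} and {t3,t4} far apart in a 10-leaf background
  txt <- paste0("(((t1:.1,t2:.1):.1,(o1:.1,o2:.1):.1):.1,",
                "(((t3:.1,t4:.1):.1,o3:.1):.1,((o4:.1,o5:.1):.1,o6:.1):.1):.1);")
  tr <- read_newick(ape::read.tree(text = txt))
  part <- species_partition(c("t1", "t2", "t3", "t4"),
                            setdiff(tr$tip.label, c("t1", "t2", "t3", "t4")))

  col_simple <- c(t1 = "N", t2 = "N", t3 = "N", t4 = "N",
                  o1 = "H", o2 = "H", o3 = "H", o4 = "H", o5 = "H", o6 = "H")
  aln <- aln_from_matrix(matrix(col_simple, 10, 1,
                                dimnames = list(names(col_simple), NULL)))
  st <- reconstruct_marginal_states(tr, aln, 1, mode = "ml")
  p <- classify_path(tr, part, st)
  expect_equal(p$path_class, "simple")
  expect_equal(unique(p$clades$parent_state), "H")

  # differing ancestral context around one clade makes the path complex:
  # o3, sister to clade {t3,t4}, carries Y so that parent states differ
  col_cplx <- col_simple
  col_cplx[c("o3")] <- "Y"
  col_cplx[c("o4", "o5", "o6")] <- "Y"
  aln2 <- aln_from_matrix(matrix(col_cplx, 10, 1,
                                 dimnames = list(names(col_cplx), NULL)))
  st2 <- reconstruct_marginal_states(tr, aln2, 1, mode = "ml")
  p2 <- classify_path(tr, part, st2)
  expect_equal(p2$path_class, "complex")

  # clade order does not affect the classification
  part_rev <- species_partition(c("t3", "t4", "t1", "t2"), part$group_b)
  expect_equal(classify_path(tr, part_rev, st)$path_class, "simple")
})

test_that("path classification matches a brute-force root-to-leaf walker", {
  txt <- paste0("(((t1:.1,t2:.1):.1,(o1:.1,o2:.1):.1):.1,",
                "((t3:.1,o3:.1):.1,o4:.1):.1);")
  tr <- read_newick(ape::read.tree(text = txt))
  targets <- c("t1", "t2", "t3")
  part <- species_partition(targets, setdiff(tr$tip.label, targets))
  n_leaf <- length(tr$tip.label)
  bg <- setdiff(tr$tip.label, targets)
  set.seed(77)
  for (i in 1:60) {
    col <- stats::setNames(rep("N", n_leaf), tr$tip.label)
    col[bg] <- sample(c("H", "Y"), length(bg), TRUE)
    aln <- aln_from_matrix(matrix(col, n_leaf, 1,
                                  dimnames = list(names(col), NULL)))
    st <- reconstruct_marginal_states(tr, aln, 1, mode = "ml")
    got <- classify_path(tr, part, st)$path_class
    want <- walker_path_class(tr, targets, st)
    expect_equal(got, want)
  }
})
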