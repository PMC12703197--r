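test_that("lineages are maximal chosen-only clades", {
  tr <- read_newick(ape::read.tree(
    text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1);"))
  # A,B form one lineage; D alone is a lineage although E is its sister
  cb <- species_combination(tr, c("A", "B", "D"))
  expect_equal(cb$m, 2L)
  expect_setequal(vapply(cb$lineages, paste, character(1), collapse = ","),
                  c("A,B", "D"))
  # choosing a whole cherry merges it into one lineage
  cb2 <- species_combination(tr, c("D", "E"))
  expect_equal(cb2$m, 1L)
})

test_that("enumeration respects the lineage-count constraint", {
  tr <- read_newick(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  all_pairs <- enumerate_combinations(tr, 2)
  expect_length(all_pairs, choose(4, 2))
  cross <- enumerate_combinations(tr, 2, m = 2)
  expect_setequal(vapply(cross, function(x) paste(x$species, collapse = ""),
                         character(1)),
                  c("AC", "AD", "BC", "BD"))  # {A,B} and {C,D} are single clades

  # on a star tree every subset splits into k singleton lineages
  star <- read_newick(ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);"))
  expect_length(enumerate_combinations(star, 3, m = 3), choose(5, 3))
  expect_length(enumerate_combinations(star, 3, m = 2), 0L)

  expect_error(enumerate_combinations(tr, 9), "exceeds")
})

test_that("unconstrained enumeration counts match the binomial coefficient", {
  for (n in c(5, 12, 20)) {
    tr <- random_labeled_tree(n, seed = n)
    for (k in c(2, min(4, n))) {
      expect_equal(enumerate_combinations(tr, k, count_only = TRUE),
                   choose(n, k))
    }
  }
})

test_that("constrained enumeration equals a brute-force clade test", {
  skip_if_not_installed("phangorn")
  for (seed in c(3, 9)) {
    tr <- random_labeled_tree(12, seed = seed)
    root <- length(tr$tip.label) + 1L
    # independent oracle: for each subset, climb each chosen leaf to its
    # highest ancestor whose tips are all chosen; count distinct apexes
    oracle_m <- function(sp) {
      tips <- match(sp, tr$tip.label)
      anc <- phangorn::Ancestors(tr, tips, "all")
      if (length(tips) == 1L) anc <- list(anc)
      apexes <- vapply(seq_along(tips), function(i) {
        v <- tips[i]
        for (a in anc[[i]]) {
          below <- tr$tip.label[phangorn::Descendants(tr, a, "tips")[[1]]]
          if (all(below %in% sp)) v <- a else break
        }
        v
      }, integer(1))
      unique(apexes)
    }
    for (k in 2:4) for (m in 2:min(3, k)) {
      got <- enumerate_combinations(tr, k, m = m)
      got_keys <- vapply(got, function(x)
        paste(x$species, collapse = ","), character(1))
      subsets <- utils::combn(sort(tr$tip.label), k, simplify = FALSE)
      want_keys <- vapply(Filter(function(sp) {
        ap <- oracle_m(sp)
        length(ap) == m && !any(ap == root)
      }, subsets), paste, character(1), collapse = ",")
      expect_setequal(got_keys, want_keys)
    }
  }
})

test_that("core-control filtering keeps exactly 2 focal clades plus 1 outside clade", {
  txt <- paste0("(((f1:1,f2:1):1,(g1:1,g2:1):1):1,",
                "(((h1:1,h2:1):1,(x1:1,x2:1):1):1,((x3:1,x4:1):1,(x5:1,x6:1):1):1):1);")
  tr <- read_newick(ape::read.tree(text = txt))
  focal <- list(F = c("f1", "f2"), G = c("g1", "g2"), H = c("h1", "h2"))
  combos <- enumerate_combinations(tr, 4, m = 3)
  kept <- filter_core_controls(combos, focal)
  # every kept combination follows the 2-focal + 1-background template
  for (cb in kept) {
    homes <- vapply(cb$lineages, function(sp) {
      inside <- vapply(focal, function(f) all(sp %in% f), logical(1))
      if (any(inside)) names(focal)[which(inside)[1]] else "out"
    }, character(1))
    expect_equal(sum(homes != "out"), 2L)
    expect_equal(length(unique(homes[homes != "out"])), 2L)
    expect_equal(sum(homes == "out"), 1L)
  }
  # template match equals an exhaustive check over all enumerated combos
  oracle_keep <- Filter(function(cb) {
    homes <- vapply(cb$lineages, function(sp) {
      inside <- vapply(focal, function(f) all(sp %in% f), logical(1))
      if (any(inside)) names(focal)[which(inside)[1]]
      else if (!any(sp %in% unlist(focal))) "out" else "straddle"
    }, character(1))
    sum(homes %in% names(focal)) == 2L &&
      length(unique(homes[homes %in% names(focal)])) == 2L &&
      sum(homes == "out") == 1L && !any(homes == "straddle")
  }, combos)
  expect_equal(vapply(kept, function(x) paste(x$species, collapse = ","),
                      character(1)),
               vapply(oracle_keep, function(x) paste(x$species, collapse = ","),
                      character(1)))
  # a combination using all three focal clades is rejected
  all3 <- species_combination(tr, c("f1", "f2", "g1", "h1"))
  expect_length(filter_core_controls(list(all3), focal), 0L)
  expect_error(filter_core_controls(kept, list(A = "f1", B = "f1")),
               "overlap")
})

test_that("phylogenetic features follow their definitions on a hand-computed tree", {
  tr <- read_newick(ape::read.tree(text = "((A:1,B:2):3,(C:4):5);"))
  f <- compute_phylo_features(tr, c("A", "C"))
  # origin branches: leaf A (length 1) and the chosen-only chain above C (5)
  expect_equal(f$POB, 1 * 5)
  expect_equal(f$PTB, 1 * 4)
  expect_equal(f$DTB, (3 + 1) + (5 + 4))
  expect_equal(f$DTN, 3 + 5)
  expect_equal(f$m, 2L)

  # single-lineage combination: POB is that lineage's origin branch
  f1 <- compute_phylo_features(tr, c("A", "B"))
  expect_equal(f1$m, 1L)
  expect_equal(f1$POB, 3)
  expect_equal(f1$PTB, 1 * 2)

  tr0 <- read_newick(ape::read.tree(text = "((A:0,B:2):3,C:4);"))
  expect_warning(fz <- compute_phylo_features(tr0, c("A", "C")), "zero-length")
  expect_equal(fz$POB, 0)
})

test_that("feature identities hold across enumerated combinations", {
  tr <- random_labeled_tree(10, seed = 4)
  combos <- enumerate_combinations(tr, 3, m = NULL)
  combos <- Filter(function(cb)
    !any(cb$apexes == convarfinder:::tree_root(tr)), combos)
  bl <- convarfinder:::tree_branch_in(tr)
  for (cb in combos) {
    f <- compute_phylo_features(tr, cb)
    term <- sum(bl[match(cb$species, tr$tip.label)])
    expect_equal(f$DTB - f$DTN, term, tolerance = 1e-12)
  }
  # features are invariant to species ordering
  f_a <- compute_phylo_features(tr, c("t01", "t05", "t09"))
  f_b <- compute_phylo_features(tr, c("t09", "t01", "t05"))
  expect_equal(f_a, f_b)
})

test_that("branch-length scaling acts as a power law on the features", {
  tr <- random_labeled_tree(8, seed = 12)
  cb <- enumerate_combinations(tr, 3, m = 2)[[1]]
  f1 <- compute_phylo_features(tr, cb)
  c_scale <- 2.5
  tr2 <- tr; tr2$edge.length <- tr$edge.length * c_scale
  f2 <- compute_phylo_features(read_newick(tr2), cb)
  expect_equal(f2$POB, f1$POB * c_scale^f1$m)
  expect_equal(f2$PTB, f1$PTB * c_scale^f1$k)
  expect_equal(f2$DTB, f1$DTB * c_scale)
  expect_equal(f2$DTN, f1$DTN * c_scale)
})
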