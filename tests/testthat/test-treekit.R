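test_that("read_newick parses tips and depths of simple trees", {
  tr <- read_newick("(A:1,B:1);")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(unname(root_to_tip(tr)), c(1, 1))

  tr2 <- read_newick("((A:1,B:1):1,C:2);")
  d <- root_to_tip(tr2)
  expect_equal(unname(d[c("A", "B", "C")]), c(2, 2, 2))
  expect_equal(oracle_mrca_depth(tr2, match("A", tr2$tip.label), match("B", tr2$tip.label)), 1)
})

test_that("read_newick rejects malformed input", {
  expect_error(read_newick("(A:1,A:2);"), "duplicate tip")
  expect_error(read_newick("((A:1,B:1):1,C:2;"), "unbalanced")
  expect_error(read_newick("(A:1,B:1)"), "';'")
  expect_error(read_newick("(A:1,B:-1);"), "negative branch length.*B")
})

test_that("missing branch lengths default to 1 with a warning, or error in strict mode", {
  expect_warning(tr <- read_newick("(A,(B,C));"), "defaulting")
  expect_equal(tr$edge.length, rep(1, nrow(tr$edge)))
  expect_error(read_newick("(A,(B,C));", strict = TRUE), "strict")
})

test_that("tip labels are normalized and matched after normalization", {
  tr <- read_newick("('Sphenodon punctatus':1,Gallus_gallus:1);")
  expect_true("Sphenodon_punctatus" %in% tr$tip.label)
  expect_equal(normalize_labels("  Homo   sapiens "), "Homo_sapiens")
})

test_that("write_newick round-trips labels and branch lengths", {
  set.seed(42)
  tr <- ape::rtree(20)
  tr$edge.length <- tr$edge.length * exp(rnorm(length(tr$edge.length)))
  back <- read_newick(write_newick(tr))
  expect_setequal(back$tip.label, tr$tip.label)
  d0 <- root_to_tip(tr)
  d1 <- root_to_tip(back)
  expect_equal(d1[names(d0)], d0, tolerance = 1e-9)
})

test_that("prune_to_taxa preserves patristic distances", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(oracle_patristic_named(pr, "A", "C"), 4)

  # identity case
  same <- prune_to_taxa(tr, tr$tip.label)
  expect_setequal(same$tip.label, tr$tip.label)
  expect_equal(root_to_tip(same)[tr$tip.label], root_to_tip(tr)[tr$tip.label])

  # random subset of a 50-tip tree: all pairwise distances conserved
  big <- simulate_pure_birth_tree(50, seed = 11)
  set.seed(12)
  keep <- sample(big$tip.label, 10)
  small <- prune_to_taxa(big, keep)
  for (a in keep) {
    for (b in setdiff(keep, a)) {
      expect_equal(
        oracle_patristic_named(small, a, b),
        oracle_patristic_named(big, a, b),
        tolerance = 1e-10
      )
    }
  }
  expect_error(prune_to_taxa(tr, c("A", "Z")), "absent.*Z")
})

test_that("phylo_vcv matches definition on known trees", {
  V <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(
    unclass(V)[c("A", "B", "C"), c("A", "B", "C")],
    matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
    ),
    ignore_attr = TRUE
  )
  star <- phylo_vcv(read_newick("(A:1,B:1,C:1);"))
  expect_equal(unclass(star), diag(3), ignore_attr = TRUE)
  expect_equal(attr(V, "model_tag"), "BM")
})

test_that("phylo_vcv agrees with the brute-force MRCA oracle on a simulated tree", {
  tr <- simulate_pure_birth_tree(20, seed = 5)
  V <- unclass(phylo_vcv(tr))
  expect_equal(V, oracle_vcv(tr)[rownames(V), colnames(V)], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("phylo_vcv rejects degenerate zero-depth tips", {
  tr <- read_newick("(A:0,B:1);")
  expect_error(phylo_vcv(tr), "zero distance")
})

test_that("is_ultrametric distinguishes tip-depth spreads", {
  expect_true(is_ultrametric(read_newick("(A:1,B:1);")))
  expect_false(is_ultrametric(read_newick("(A:1,B:2);")))
  expect_true(is_ultrametric(read_newick("((A:1,B:1):1,C:2);")))
})

test_that("build_composite merges clades with unit branch lengths", {
  subs <- list(
    Squamata = read_newick("(s1:3,s2:3);"),
    Testudines = read_newick("(t1:1,t2:1);"),
    Crocodilia = read_newick("(c1:9,c2:9);")
  )
  comp <- build_composite(subtrees = subs)
  expect_setequal(comp$tip.label, c("s1", "s2", "t1", "t2", "c1", "c2"))
  expect_equal(comp$edge.length, rep(1, nrow(comp$edge)))

  # single-clade case: backbone leaf replaced by the subtree itself
  single <- build_composite("(Squamata);", subs["Squamata"])
  expect_setequal(single$tip.label, c("s1", "s2"))
  expect_equal(single$edge.length, rep(1, nrow(single$edge)))

  expect_error(
    build_composite(subtrees = subs[c("Squamata", "Testudines")]),
    "no matching subtree"
  )
  subs_bad <- subs
  subs_bad$Testudines <- read_newick("(s1:1,x:1);")
  expect_error(build_composite(subtrees = subs_bad), "more than one subtree")
})

test_that("composite diagonal variances equal node depth in edges", {
  set.seed(21)
  subs <- list(
    Squamata = ape::rtree(10),
    Testudines = ape::rtree(5),
    Crocodilia = ape::rtree(3)
  )
  for (nm in names(subs)) {
    subs[[nm]]$tip.label <- paste0(nm, "_", subs[[nm]]$tip.label)
  }
  comp <- build_composite(subtrees = subs)
  V <- unclass(phylo_vcv(comp))
  depths <- tree_summary(comp)
  expect_equal(
    diag(V)[depths$tip], setNames(as.numeric(depths$depth_edges), depths$tip)
  )
  # equal-depth ultrametricity arithmetic: unit-branch composite is
  # ultrametric iff all tips sit at the same edge depth
  expect_equal(
    is_ultrametric(comp),
    length(unique(depths$depth_edges)) == 1
  )
})

test_that("tree_summary reports root-to-tip distance and edge depth", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  ts <- tree_summary(tr)
  expect_equal(ts$root_to_tip[match(c("A", "C"), ts$tip)], c(2, 2))
  expect_equal(ts$depth_edges[match(c("A", "C"), ts$tip)], c(2L, 1L))
})
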