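test_that("reading minimal trees gives correct ages and ultrametric flags", {
  tr <- newick_tree("(A:1,B:1):0;")
  expect_equal(length(tr$tip.label), 2)
  expect_equal(unname(attr(tr, "node_age")[1:2]), c(0, 0))
  expect_equal(attr(tr, "height"), 1)

  tr2 <- newick_tree("((A:1,B:1):1,C:2):0;")
  expect_true(attr(tr2, "ultrametric"))

  tr3 <- newick_tree("((A:1,B:1):1,C:1):0;")
  expect_false(attr(tr3, "ultrametric"))
})

test_that("malformed and invalid trees are rejected with clear errors", {
  tf <- tempfile()
  writeLines("((A:1,B:1", tf)
  expect_error(read_tree(tf), "parse")
  writeLines("((A:1,A:1):1,C:2);", tf)
  expect_error(read_tree(tf), "duplicate")
  writeLines("((A,B),C);", tf)
  expect_error(read_tree(tf), "branch lengths")
})

test_that("NEXUS trees read equivalently to Newick", {
  nwk <- newick_tree("((A:1,B:1):1,C:2):0;")
  tf <- tempfile(fileext = ".nex")
  ape::write.nexus(nwk, file = tf)
  nex <- read_tree(tf, format = "nexus")
  expect_equal(sort(nex$tip.label), sort(nwk$tip.label))
  expect_equal(attr(nex, "height"), attr(nwk, "height"))
})

test_that("tree round-trip preserves topology and branch lengths", {
  set.seed(11)
  for (i in 1:5) {
    tr <- sim_tree(sample(5:40, 1), root_age = 90, seed = i)
    tf <- tempfile(fileext = ".nwk")
    write_tree(tr, tf)
    back <- read_tree(tf)
    expect_true(ape::all.equal.phylo(back, tr, use.edge.length = TRUE,
                                     tolerance = 1e-9))
  }
})

test_that("polytomies are preserved", {
  tr <- newick_tree("(A:1,B:1,C:1,D:1);")
  expect_equal(tr$Nnode, 1)
  expect_equal(length(tr$tip.label), 4)
})

test_that("align_tree_and_traits intersects, passes through, and errors", {
  tr <- newick_tree("((A:1,B:1):1,C:2):0;")
  td2 <- trait_dataset(c(A = "x", C = "y"), c("x", "y"))
  al <- align_tree_and_traits(tr, td2, policy = "intersect")
  expect_setequal(al$tree$tip.label, c("A", "C"))
  # pruning preserves path lengths: A keeps depth 2
  expect_equal(attr(al$tree, "height"), 2)
  expect_equal(max(ape::node.depth.edgelength(al$tree)), 2)

  td3 <- trait_dataset(c(A = "x", B = "y", C = "x"), c("x", "y"))
  al2 <- align_tree_and_traits(tr, td3)
  expect_equal(al2$tree$edge.length, tr$edge.length)

  tdz <- trait_dataset(c(Z = "x", W = "y"), c("x", "y"))
  expect_error(align_tree_and_traits(tr, tdz), "no species shared")
  expect_error(align_tree_and_traits(tr, td2, policy = "error"), "differ")
})

test_that("lambda transform matches the hand-computed example", {
  tr <- newick_tree("((A:1,B:1):1,C:2):0;")
  t1 <- lambda_transform(tr, 1)
  expect_equal(t1$edge.length, tr$edge.length)

  t0 <- lambda_transform(tr, 0)
  po <- ape::reorder.phylo(t0, "postorder")
  ntip <- 3
  internal <- po$edge[, 2] > ntip
  expect_equal(po$edge.length[internal], 0)
  expect_equal(unname(ape::node.depth.edgelength(t0)[1:3]), c(2, 2, 2))

  t5 <- lambda_transform(tr, 0.5)
  po5 <- ape::reorder.phylo(t5, "postorder")
  lens <- stats::setNames(po5$edge.length, po5$edge[, 2])
  expect_equal(unname(lens[as.character(match(c("A", "B", "C"),
                                              t5$tip.label))]),
               c(1.5, 1.5, 2))
  expect_equal(unname(lens[as.character(5)]), 0.5)
})

test_that("lambda transform preserves depths, is monotone, rejects bad input", {
  set.seed(21)
  tr <- sim_tree(30, 90, seed = 3)
  d0 <- ape::node.depth.edgelength(tr)[1:30]
  prev_internal <- -Inf
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    tl <- lambda_transform(tr, lam)
    expect_equal(ape::node.depth.edgelength(tl)[1:30], d0,
                 tolerance = 1e-9)
    internal_total <- sum(tl$edge.length[tl$edge[, 2] > 30])
    expect_gte(internal_total, prev_internal)
    prev_internal <- internal_total
  }
  # agreement with the reference implementation in phytools
  tl <- lambda_transform(tr, 0.37)
  ref <- phytools:::lambdaTree(tr, 0.37)
  expect_equal(tl$edge.length, ref$edge.length, tolerance = 1e-8)

  nonultra <- newick_tree("((A:1,B:1):1,C:1):0;")
  expect_error(lambda_transform(nonultra, 0.5), "ultrametric")
  expect_error(lambda_transform(tr, 1.5), "lambda")
})
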