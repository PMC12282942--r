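test_that("dummy-root consensus keeps agreements and writes D at conflicts", {
  expect_equal(makeDummyRoot(c("AGC", "CGC")), "DGC")
  expect_equal(makeDummyRoot(c("AAA", "AAA")), "AAA")
  expect_equal(makeDummyRoot(c("AGT", "CGA")), "DGD")
  expect_error(makeDummyRoot(c("AG", "CGC")), "length")
  expect_error(makeDummyRoot("AGC"), "two")
})

test_that("root selection prefers lowest SHM, then unswitched isotype, then a dummy", {
  n1 <- mkNode("1", "AAA", shm = 0.01)
  n2 <- mkNode("2", "CCC", shm = 0.05)
  n3 <- mkNode("3", "GGG", shm = 0.02)
  sel <- selectRoot(list(n1, n2, n3))
  expect_false(sel$is_dummy)
  expect_equal(sel$root$node_name, "1")

  tieM <- mkNode("m", "AGC", shm = 0, iso = "IgM")
  tieG <- mkNode("g", "CGC", shm = 0, iso = "IgG")
  sel2 <- selectRoot(list(tieG, tieM))
  expect_false(sel2$is_dummy)
  expect_equal(sel2$root$node_name, "m")

  g1 <- mkNode("g1", "AGC", muts = mut(1, "A"), shm = 0.1)
  g2 <- mkNode("g2", "CGC", muts = mut(1, "C"), shm = 0.1)
  sel3 <- selectRoot(list(g1, g2))
  expect_true(sel3$is_dummy)
  expect_equal(sel3$root$clonotype_seq, "DGC")
  expect_equal(sel3$root$shm_rate, 0.1)
  expect_length(sel3$root$cdr_mutations, 0)  # intersection of disjoint sets
  expect_equal(sel3$root$size, 0)

  expect_error(selectRoot(list()), "zero")
})

test_that("inheritance requires identical (region, position, base) triples", {
  m1 <- "cdrh3|3|T"; m2 <- "cdrh1|0|G"
  expect_true(inheritsMutations(character(0), m1))
  expect_true(inheritsMutations(m1, c(m1, m2)))
  expect_false(inheritsMutations(m1, c("cdrh3|3|A", m2)))
})

test_that("edge weights are Levenshtein over parent length, D mismatching all bases", {
  expect_equal(edgeWeight("ACGT", "ACGT"), 0)
  expect_equal(edgeWeight("ACGT", "ACTT"), 0.25)
  expect_equal(edgeWeight("AAAA", "AAAAA"), 0.25)  # one insertion
  expect_equal(edgeWeight("DGC", "AGC"), 1 / 3)
  expect_error(edgeWeight("", "A"), "empty")
})

test_that("a strict mutation chain is recovered exactly as a path", {
  nodes <- chainNodes()
  tree <- buildTree(nodes)
  e <- treeEdges(tree)
  expect_equal(rootName(tree), "1")
  expect_equal(e[order(e$child), c("parent", "child")],
               data.frame(parent = c("1", "2", "3"),
                          child = c("2", "3", "4")),
               ignore_attr = TRUE)
  expect_false(any(e$fallback))
  # brute-force oracle: the generating parent is the unique minimum-distance
  # inheritance-valid lower-SHM candidate for every node
  for (i in 2:4) {
    child <- nodes[[i]]
    cand <- Filter(function(n) n$shm_rate < child$shm_rate &&
                     all(n$cdr_mutations %in% child$cdr_mutations),
                   nodes[-i])
    d <- vapply(cand, function(n)
      levOracle(n$clonotype_seq, child$clonotype_seq), numeric(1))
    expect_equal(sum(d == min(d)), 1)
    expect_equal(cand[[which.min(d)]]$node_name, as.character(i - 1))
  }
})

test_that("disjoint single-mutation progeny form a star on the germline root", {
  germ <- "ACGTACGTAC"
  nodes <- list(
    mkNode("1", germ, character(0), 0),
    mkNode("2", applyMut(germ, mut(1, "C")), mut(1, "C"), 0.1),
    mkNode("3", applyMut(germ, mut(5, "G")), mut(5, "G"), 0.1),
    mkNode("4", applyMut(germ, mut(9, "T")), mut(9, "T"), 0.1))
  tree <- buildTree(nodes)
  e <- treeEdges(tree)
  expect_setequal(e$parent, "1")
  expect_setequal(e$child, c("2", "3", "4"))
  expect_false(any(e$fallback))
  # no non-root node is a valid parent of another (disjoint mutation sets)
  for (i in 2:4) for (j in 2:4) {
    if (i == j) next
    expect_false(inheritsMutations(nodes[[i]]$cdr_mutations,
                                   nodes[[j]]$cdr_mutations))
  }
})

test_that("a single node gives a tree of one node, no edges, depth zero", {
  tree <- buildTree(list(mkNode("1", "ACGT", character(0), 0)))
  expect_length(treeNodes(tree), 1)
  expect_equal(nrow(treeEdges(tree)), 0)
  expect_equal(treeDepth(tree), 0)
})

test_that("a node inheriting from no placed node attaches to the root as a flagged fallback", {
  germ <- "ACGTACGTAC"
  nodes <- list(
    mkNode("1", applyMut(germ, mut(1, "C")), mut(1, "C"), 0.1, iso = "IgM"),
    mkNode("2", applyMut(germ, mut(5, "G")), mut(5, "G"), 0.1))
  tree <- buildTree(nodes)
  e <- treeEdges(tree)
  expect_equal(nrow(e), 1)
  expect_equal(e$parent, "1")   # IgM wins the root tie
  expect_true(e$fallback)       # root's mutation is not in the child's set
  expect_error(validObject(tree), NA)
})

test_that("trees are deterministic under node-order shuffling", {
  set.seed(11)
  for (rep in 1:5) {
    sim <- simulateTree(L = 60, N = 25, lambdaC = 2, lambdaM = 2,
                        seed = 100 + rep)
    nodes <- simToCloneNodes(sim)
    t1 <- buildTree(nodes)
    t2 <- buildTree(nodes[sample(length(nodes))])
    e1 <- treeEdges(t1); e2 <- treeEdges(t2)
    expect_equal(e1[order(e1$child), ], e2[order(e2$child), ],
                 ignore_attr = TRUE)
  }
})

test_that("built trees always satisfy SHM ordering and non-fallback inheritance", {
  set.seed(5)
  for (rep in 1:20) {
    sim <- simulateTree(L = 80, N = 20, lambdaC = 3, lambdaM = 1,
                        seed = 500 + rep)
    tree <- buildTree(simToCloneNodes(sim))
    shm <- vapply(treeNodes(tree), function(n) n$shm_rate, numeric(1))
    e <- treeEdges(tree)
    expect_true(all(shm[e$child] >= shm[e$parent]))
    for (i in seq_len(nrow(e))) {
      if (e$fallback[i]) next
      expect_true(inheritsMutations(
        treeNodes(tree)[[e$parent[i]]]$cdr_mutations,
        treeNodes(tree)[[e$child[i]]]$cdr_mutations))
    }
    expect_error(validObject(tree), NA)
  }
})
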