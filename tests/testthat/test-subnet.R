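nonRecoverableFixture <- function() {
  # the root's two children fan into two reticulations that reconverge on
  # a single vertex carrying all leaves, so the lowest stable ancestor of
  # the full leaf set sits strictly below the root
  phyloNetwork(cbind(
    tail = c("r", "r", "a", "a", "b", "b", "v", "w", "u", "u", "m", "m"),
    head = c("a", "b", "v", "w", "v", "w", "u", "u", "c", "m", "d", "e")),
    leafLabels = c(c = "c", d = "d", e = "e"))
}

test_that("lsa matches the path-enumeration oracle on all fixtures", {
  fixtures <- c(fixtureNetworks(), list(nonRecoverable = nonRecoverableFixture()))
  for (nm in names(fixtures)) {
    net <- fixtures[[nm]]
    tx <- taxa(net)
    subsets <- unlist(lapply(seq_along(tx), function(s)
      utils::combn(tx, s, simplify = FALSE)), recursive = FALSE)
    for (y in subsets)
      expect_identical(lsa(net, y), oracleLsa(net, y),
                       label = paste0("lsa(", nm, ", {",
                                      paste(y, collapse = ","), "})"))
  }
  # and on random networks
  for (seed in 1:6) {
    net <- randomNetwork(4, 2, seed = seed)
    for (y in utils::combn(taxa(net), 2, simplify = FALSE))
      expect_identical(lsa(net, y), oracleLsa(net, y))
  }
})

test_that("lsa handles the stated special cases", {
  tr <- readENewick("((a,b),c);")
  expect_identical(lsa(tr, taxa(tr)), networkRoot(tr))
  # single leaf in a tree: the parent vertex
  expect_identical(lsa(tr, "c"), networkRoot(tr))
  a <- arcs(tr)
  cherry <- unname(a[a[, 2L] == names(leafLabels(tr))[leafLabels(tr) == "a"], 1L])
  expect_identical(lsa(tr, "a"), cherry)
  expect_error(lsa(tr, character(0)), "nonempty")
  expect_error(lsa(tr, "zz"), "unknown")
})

test_that("recoverability is the root condition on lsa", {
  expect_true(isRecoverable(buildN(1, 3)))
  expect_true(isRecoverable(buildN(2, 5)))
  expect_true(isRecoverable(buildH(1, 3)))
  expect_true(isRecoverable(buildH(2, 4)))
  expect_false(isRecoverable(nonRecoverableFixture()))
})

test_that("suppression removes exactly the degenerate structure", {
  # chain root -> v -> leaf inside a 4-vertex DAG collapses
  g <- rootedDAG(cbind(tail = c("r", "v", "r"), head = c("v", "l1", "l2")),
                 leafLabels = c(l1 = "a", l2 = "b"))
  s <- suppressDegenerate(g)
  expect_setequal(vertexIds(s), c("r", "l1", "l2"))
  # the even-class DAG has no degenerate vertices: fixpoint is immediate
  for (n in 3:5) {
    d2 <- buildD(2, n)
    s2 <- suppressDegenerate(d2)
    expect_identical(sort(vertexIds(s2)), sort(vertexIds(d2)))
    expect_identical(nrow(arcs(s2)), nrow(arcs(d2)))
  }
  # the odd-class DAG loses exactly its weight-1 sequence vertices, each
  # replaced by a root-to-y arc
  d1 <- buildD(1, 3)
  n1 <- suppressDegenerate(d1)
  expect_setequal(setdiff(vertexIds(d1), vertexIds(n1)),
                  c("100", "010", "001"))
  a <- arcs(n1)
  for (j in 1:3)
    expect_true(any(a[, 1L] == "rho" & a[, 2L] == paste0("y", j)))
})

test_that("suppression is confluent under randomized orders", {
  for (seed in 1:100) {
    g <- degenerateFixture(seed, nLeaves = 3 + seed %% 3,
                           nRet = seed %% 3, nSubdiv = 2 + seed %% 4)
    ref <- suppressDegenerate(g)
    set.seed(seed * 7L)
    alt <- suppressDegenerate(g, order = "random")
    expect_true(verdict(areEquivalent(ref, alt)),
                label = paste("confluence seed", seed))
  }
})

test_that("restriction obeys its fixed points and collapses", {
  # full-leaf-set restriction of a recoverable network returns it
  for (net in list(buildN(1, 3), buildN(2, 4), buildH(1, 3))) {
    expect_true(verdict(areEquivalent(restrictNetwork(net, taxa(net)), net)))
  }
  # for a non-recoverable network it returns the subnet below lsa(X)
  nr <- nonRecoverableFixture()
  below <- restrictNetwork(nr, taxa(nr))
  expect_false(verdict(areEquivalent(below, nr)))
  expect_true(isRecoverable(below))
  expect_identical(sort(taxa(below)), sort(taxa(nr)))
  # single-leaf restriction is the two-vertex network
  for (net in list(buildN(1, 3), buildH(2, 4), randomNetwork(5, 2, seed = 3))) {
    for (x in taxa(net)[1:2]) {
      r <- restrictNetwork(net, x)
      expect_length(vertexIds(r), 2)
      expect_identical(taxa(r), x)
    }
  }
  # every restriction is valid and recoverable
  for (seed in 4:6) {
    net <- randomNetwork(5, 2, seed = seed)
    for (y in utils::combn(taxa(net), 3, simplify = FALSE)) {
      r <- restrictNetwork(net, y)
      expect_length(validateNetwork(r, strict = TRUE), 0)
      expect_true(isRecoverable(r))
      expect_identical(sort(taxa(r)), sort(y))
    }
  }
})

test_that("trinets enumerate all 3-subsets and reduce to triplets on trees", {
  net <- buildH(1, 4)
  tn <- trinets(net)
  expect_length(tn, choose(4, 3))
  expect_setequal(names(tn), apply(utils::combn(taxa(net), 3), 2,
                                   paste, collapse = "|"))
  # trinets of a tree are its triplet trees (cross-checked against ape)
  tr <- readENewick("(((a,b),c),d);")
  tn <- trinets(tr)
  for (k in names(tn)) {
    expect_identical(networkLevel(tn[[k]]), 0L)
    expect_length(vertexIds(tn[[k]]), 5)  # rooted binary triplet
  }
  apeTriplet <- function(full, keep) {
    ph <- ape::read.tree(text = full)
    ape::write.tree(ape::keep.tip(ph, keep))
  }
  mine <- tn[["a|b|d"]]
  ref <- readENewick(apeTriplet("(((a,b),c),d);", c("a", "b", "d")))
  expect_true(verdict(areEquivalent(mine, ref)))
  expect_error(trinets(readENewick("(a);")), "3 leaves")
})
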