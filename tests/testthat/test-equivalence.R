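test_that("canonical form ignores vertex identifiers", {
  for (seed in 1:10) {
    net <- randomNetwork(4, seed %% 3, seed = seed)
    copy <- shuffledCopy(net, seed + 500)
    expect_identical(canonicalForm(net), canonicalForm(copy))
    expect_identical(canonicalForm(net, respectLabels = FALSE),
                     canonicalForm(copy, respectLabels = FALSE))
  }
})

test_that("canonical-form equality matches the exhaustive-bijection oracle", {
  # pairs: equivalent copies, genuinely different networks, and
  # label-swapped variants; internal vertex counts stay small enough for
  # the factorial oracle
  pairs <- list()
  for (seed in 1:9) {
    a <- randomNetwork(3, seed %% 2, seed = seed)
    pairs[[length(pairs) + 1L]] <- list(a, shuffledCopy(a, seed + 50))
    b <- randomNetwork(3, seed %% 2, seed = seed + 200)
    pairs[[length(pairs) + 1L]] <- list(a, b)
    sw <- relabelTaxa(shuffledCopy(a, seed + 70),
                      c(t1 = "t2", t2 = "t1"))
    pairs[[length(pairs) + 1L]] <- list(a, sw)
  }
  nChecked <- 0L
  for (p in pairs) {
    mine <- identical(canonicalForm(p[[1]]), canonicalForm(p[[2]]))
    expect_identical(mine, oracleEquivalent(p[[1]], p[[2]]))
    expect_identical(mine, igraphEquivalent(p[[1]], p[[2]]))
    nChecked <- nChecked + 1L
  }
  expect_gte(nChecked, 27)
})

test_that("areEquivalent returns checked witnesses and sharp certificates", {
  n1 <- buildN(1, 3); n2 <- buildN(2, 3)
  w <- areEquivalent(n1, n1)
  expect_true(verdict(w))
  expect_identical(unname(witnessMapping(w)[vertexIds(n1)]), vertexIds(n1))
  # a shuffled copy: mapping must verify arc-by-arc
  cp <- shuffledCopy(n1, 11)
  w <- areEquivalent(n1, cp)
  expect_true(verdict(w))
  m <- witnessMapping(w)
  a1 <- arcs(n1)
  mapped <- sort(paste(m[a1[, 1]], m[a1[, 2]]))
  expect_identical(mapped, sort(paste(arcs(cp)[, 1], arcs(cp)[, 2])))
  # the two variants differ: exactly one of them has a child of the root
  # with outdegree n (the all-ones sequence), caught by a cheap invariant
  w <- areEquivalent(n1, n2)
  expect_false(verdict(w))
  expect_true(nzchar(certificate(w)))
  expect_false(verdict(areEquivalent(buildH(1, 3), buildH(2, 3))))
  # different taxon sets
  w <- areEquivalent(readENewick("((a,b),c);"), readENewick("((a,b),d);"))
  expect_false(verdict(w))
  expect_match(certificate(w), "label sets")
})

test_that("isomorphism ignores labels; equivalence implies isomorphism", {
  a <- randomNetwork(4, 1, seed = 31)
  b <- relabelTaxa(shuffledCopy(a, 32), c(t1 = "t3", t3 = "t1"))
  expect_true(areIsomorphic(a, b))
  # whether the label swap is visible depends on where the labels sit;
  # the exhaustive oracle is the referee
  expect_identical(verdict(areEquivalent(a, b)), oracleEquivalent(a, b))
  expect_false(areIsomorphic(buildN(1, 3), buildN(2, 3)))
  for (seed in 33:38) {
    x <- randomNetwork(4, seed %% 3, seed = seed)
    y <- shuffledCopy(x, seed + 10)
    expect_true(verdict(areEquivalent(x, y)))
    expect_true(areIsomorphic(x, y))
  }
})

test_that("equivalence is an equivalence relation on fixtures", {
  nets <- list(buildN(1, 3), shuffledCopy(buildN(1, 3), 1),
               shuffledCopy(buildN(1, 3), 2), buildN(2, 3),
               buildH(1, 3), shuffledCopy(buildH(1, 3), 3))
  for (i in seq_along(nets)) {
    expect_true(verdict(areEquivalent(nets[[i]], nets[[i]])))  # reflexive
    for (j in seq_along(nets)) {
      vij <- verdict(areEquivalent(nets[[i]], nets[[j]]))
      expect_identical(vij, verdict(areEquivalent(nets[[j]], nets[[i]])))
      for (k in seq_along(nets)) {
        if (vij && verdict(areEquivalent(nets[[j]], nets[[k]])))
          expect_true(verdict(areEquivalent(nets[[i]], nets[[k]])))
      }
    }
  }
})

test_that("network-equivalence separates the 4-leaf trees with a certificate", {
  a <- readENewick("((a,b),(c,d));")
  b <- readENewick("(((a,b),c),d);")
  w <- areNetworkEquivalent(a, b)
  expect_false(verdict(w))
  expect_match(certificate(w), "\\{a,c,d\\}")
  # the named subset really distinguishes them
  ra <- restrictNetwork(a, c("a", "c", "d"))
  rb <- restrictNetwork(b, c("a", "c", "d"))
  expect_false(verdict(areEquivalent(ra, rb)))
  expect_error(areNetworkEquivalent(a, readENewick("((a,b),(c,e));")),
               "taxon set")
})

test_that("equivalent networks are network-equivalent (sanity of Lemma 1)", {
  for (seed in 41:60) {
    a <- randomNetwork(4, seed %% 3, seed = seed)
    b <- shuffledCopy(a, seed + 300)
    expect_true(verdict(areEquivalent(a, b)))
    expect_true(verdict(areNetworkEquivalent(a, b)),
                label = paste("lemma seed", seed))
  }
})

test_that("maximal-only mode agrees with the full check on these fixtures", {
  expect_true(verdict(areNetworkEquivalent(buildN(1, 3), buildN(2, 3),
                                           maximalOnly = TRUE)))
  expect_false(verdict(areNetworkEquivalent(
    readENewick("((a,b),(c,d));"), readENewick("(((a,b),c),d);"),
    maximalOnly = TRUE)))
})
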