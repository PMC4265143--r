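test_that("the layered DAG has the defining vertex and arc structure", {
  for (i in 1:2) for (n in 3:4) {
    d <- buildD(i, n)
    cls <- parityClasses(n)[[i]]
    expect_setequal(vertexIds(d),
                    c("rho", cls, paste0("y", 1:n), paste0("x", 1:n)))
    a <- arcs(d)
    # root star over the parity class
    expect_setequal(a[a[, 1] == "rho", 2], cls)
    # sequence-to-middle arcs follow the letters
    for (u in cls)
      expect_setequal(a[a[, 1] == u, 2], paste0("y", bitSupport(u)))
    # every y feeds exactly its leaf
    for (j in 1:n)
      expect_identical(unname(a[a[, 1] == paste0("y", j), 2]),
                       paste0("x", j))
  }
  # root children at n=4 match the enumerated classes
  expect_setequal(arcs(buildD(1, 4))[arcs(buildD(1, 4))[, 1] == "rho", 2],
                  c("1110", "1101", "1000", "1011",
                    "0100", "0111", "0010", "0001"))
  expect_setequal(arcs(buildD(2, 4))[arcs(buildD(2, 4))[, 1] == "rho", 2],
                  c("1111", "1100", "1010", "1001", "0110", "0101", "0011"))
  # the all-zero sequence never appears
  expect_false(zeroSeq(4) %in% vertexIds(buildD(2, 4)))
  expect_error(buildD(1, 2), "at least 3")
  expect_error(buildD(3, 4), "variant")
})

test_that("middle-layer indegrees equal 2^(n-2)", {
  for (i in 1:2) for (n in 3:6) {
    ind <- indegrees(buildD(i, n))
    expect_true(all(ind[paste0("y", 1:n)] == 2^(n - 2)),
                label = sprintf("variant %d, n=%d", i, n))
  }
})

test_that("the trie is the binary prefix tree", {
  p3 <- buildTrie(3)
  expect_length(vertexIds(p3), 15)
  expect_setequal(taxa(p3), allBitSequences(3))
  expect_true(isBinaryNetwork(p3))
  expect_identical(networkLevel(p3), 0L)
  # every internal vertex t:w has children t:w0 and t:w1
  a <- arcs(p3)
  for (v in setdiff(vertexIds(p3), names(leafLabels(p3)))) {
    w <- sub("^t:", "", v)
    expect_setequal(a[a[, 1] == v, 2], paste0("t:", w, c("0", "1")))
  }
  p1 <- buildTrie(1)
  expect_setequal(taxa(p1), c("0", "1"))
  expect_length(vertexIds(p1), 3)
})

test_that("caterpillars realize exactly the suffix clusters", {
  ct <- buildCaterpillar(c(1, 2, 3, 5, 7))
  expect_setequal(taxa(ct), c("1", "2", "3", "5", "7"))
  expect_true(isBinaryNetwork(ct))
  # clusters below non-leaf vertices are the suffixes
  a <- arcs(ct)
  lab <- leafLabels(ct)
  clusterOf <- function(v) {
    ix <- c(v); acc <- character(0)
    while (length(ix)) {
      u <- ix[[length(ix)]]; ix <- ix[-length(ix)]
      ch <- a[a[, 1] == u, 2]
      if (!length(ch)) acc <- c(acc, lab[[u]]) else ix <- c(ix, ch)
    }
    sort(acc)
  }
  internal <- setdiff(vertexIds(ct), names(lab))
  got <- lapply(internal, clusterOf)
  want <- lapply(1:4, function(j) sort(as.character(c(1, 2, 3, 5, 7)[j:5])))
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
  # k = 1 and the cherry
  single <- buildCaterpillar(7)
  expect_identical(taxa(single), "7")
  expect_length(vertexIds(single), 2)
  cherry <- buildCaterpillar(c(2, 9))
  expect_length(vertexIds(cherry), 3)
  expect_error(buildCaterpillar(c(3, 1)), "increasing")
  expect_error(buildCaterpillar(c(1, 1, 2)), "increasing")
})

test_that("staged rewrites stay rooted on the same leaves, then go binary", {
  for (i in 1:2) {
    stages <- lapply(c("D1", "D2", "D3", "H"), function(s) buildH(i, 3, s))
    for (s in stages) {
      expect_length(validateNetwork(s, strict = FALSE), 0)
      expect_setequal(taxa(s), paste0("x", 1:3))
    }
    h <- stages[[4]]
    expect_true(isBinaryNetwork(h))
    expect_true(isRecoverable(h))
    expect_length(validateNetwork(h, strict = TRUE), 0)
  }
  # interior vertices of distinct reversed copies are disjoint by tagging
  d2 <- buildH(1, 4, "D2")
  tags <- grep("^R[0-9]+:", vertexIds(d2), value = TRUE)
  expect_identical(anyDuplicated(sub("^R([0-9]+):.*", "\\1", tags)) > 0,
                   TRUE)  # several copies exist ...
  expect_identical(anyDuplicated(tags), 0L)  # ... but never share a vertex
})

test_that("stage D2 against an independently hand-built n=3 instance", {
  # Following the three rewrite steps literally for variant 1, n=3:
  # odd class {001,010,100,111}; the trie restriction keeps root "",
  # inner vertices for prefixes with two odd extensions; each y_j gathers
  # B_{3,j} = two sequences through one reversed cherry.
  d2 <- buildH(1, 3, "D2")
  # counts derived by hand: sequences 4, trie interior {root,"1x"-branch} 3,
  # y 3, x 3; arcs: trie 6, reversed cherries 3*2=6... plus y->x 3
  ind <- indegrees(d2); outd <- outdegrees(d2)
  expect_identical(sum(outd == 0L), 3L)                  # leaves x1..x3
  expect_setequal(names(ind)[ind >= 2L], paste0("y", 1:3))
  expect_true(all(ind[paste0("y", 1:3)] == 2L))
  # each sequence vertex has one parent in the trie part and one child
  # per support element
  for (w in parityClasses(3)$odd) {
    expect_identical(unname(ind[w]), 1L)
    expect_identical(unname(outd[w]), bitWeight(w))
  }
})

test_that("the headline pair properties hold at small n", {
  # nonbinary family
  rep1 <- verifyNonbinaryPair(3, 5)
  expect_true(rep1$pass)
  expect_identical(vapply(rep1$entries, `[[`, integer(1), "subsetsChecked"),
                   c(6L, 14L, 30L))
  # binary family
  rep2 <- verifyBinaryPair(3, 4)
  expect_true(rep2$pass)
  expect_true(all(vapply(rep2$entries,
                         function(e) e$checks$binary, logical(1))))
  expect_error(verifyBinaryPair(3, 6), "force")
  expect_error(verifyNonbinaryPair(3, 8), "force")
})

test_that("the flip map induces the explicit witness on leaf-drop subnets", {
  # dropping leaf x_k: the map fixing everything except flipping letter k
  # on the sequence vertices carries variant 1 onto variant 2
  for (n in 3:4) {
    n1 <- buildN(1, n); n2 <- buildN(2, n)
    for (k in 1:n) {
      xk <- setdiff(paste0("x", 1:n), paste0("x", k))
      r1 <- restrictNetwork(n1, xk)
      r2 <- restrictNetwork(n2, xk)
      chi <- vapply(vertexIds(r1), function(v) {
        if (grepl("^[01]+$", v)) flipBit(k, v) else v
      }, character(1))
      a1 <- arcs(r1)
      mapped <- sort(paste(chi[a1[, 1]], chi[a1[, 2]]))
      expect_identical(mapped, sort(paste(arcs(r2)[, 1], arcs(r2)[, 2])),
                       label = sprintf("flip witness n=%d k=%d", n, k))
      # and the generic checker agrees
      expect_true(verdict(areEquivalent(r1, r2)))
    }
  }
})
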