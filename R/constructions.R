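## Builders for the two counterexample families.
##
## Family 1 (nonbinary): the DAG D_i places the odd- (i = 1) or even-
## weight (i = 2) length-n bit sequences between a root and a layer of
## internal vertices y_1..y_n, with an arc from sequence u to y_j exactly
## when letter j of u is 1; suppressing degenerate vertices yields the
## network N_i.  Family 2 (binary): three staged rewrites of D_i — the
## root star becomes a restriction of the prefix trie, each y_j star
## becomes an arc-reversed trie restriction, each remaining high-degree
## sequence vertex becomes a caterpillar — and suppression yields the
## binary network H_i.  For every n >= 3 the two members of each pair are
## not equivalent yet induce equivalent subnets on every proper leaf
## subset.

.checkRecipe <- function(variant, n, taxonNames) {
  if (!(variant %in% c(1L, 2L))) stop("variant must be 1 or 2", call. = FALSE)
  if (n < 3L) stop("n must be at least 3", call. = FALSE)
  stopifnot(length(taxonNames) == n, !anyDuplicated(taxonNames))
}

#' Build the layered DAG D_i
#'
#' Vertices: a root, the chosen parity class of length-\code{n} bit
#' sequences, internal vertices \code{y_1..y_n}, and leaves
#' \code{x_1..x_n}.  Arcs: root to every sequence; sequence \code{u} to
#' \code{y_j} exactly when letter \code{j} of \code{u} is 1; \code{y_j}
#' to \code{x_j}.  Every \code{y_j} has indegree \code{2^(n-2)}.  For
#' variant 1 the weight-1 sequences are degenerate (indegree 1, outdegree
#' 1), so \code{D_1} is a \code{RootedDAG} but not yet a network.
#'
#' @param variant 1 (odd-weight class) or 2 (even-weight class, all-zero
#'   sequence excluded).
#' @param n Number of taxa, at least 3.
#' @param taxonNames Leaf labels (default \code{x1..xn}).
#' @return A \code{RootedDAG} with leaf set \code{taxonNames}.
#' @export
buildD <- function(variant, n, taxonNames = paste0("x", seq_len(n))) {
  .checkRecipe(variant, n, taxonNames)
  cls <- parityClasses(n)[[variant]]
  ys <- paste0("y", seq_len(n))
  xs <- paste0("x", seq_len(n))
  tails <- rep("rho", length(cls))
  heads <- cls
  for (u in cls) for (j in bitSupport(u)) {
    tails <- c(tails, u); heads <- c(heads, ys[[j]])
  }
  tails <- c(tails, ys); heads <- c(heads, xs)
  rootedDAG(cbind(tail = tails, head = heads),
            leafLabels = structure(taxonNames, names = xs))
}

#' Build the nonbinary network N_i
#'
#' Suppresses the degenerate vertices of \code{\link{buildD}}.  The
#' result is a valid, recoverable network; for every \code{n >= 3} the
#' pair \code{buildN(1, n)}, \code{buildN(2, n)} is not equivalent but is
#' network-equivalent.
#'
#' @inheritParams buildD
#' @return A \code{PhyloNetwork}.
#' @examples
#' n1 <- buildN(1, 3)
#' n2 <- buildN(2, 3)
#' verdict(areEquivalent(n1, n2))         # FALSE
#' verdict(areNetworkEquivalent(n1, n2))  # TRUE
#' @export
buildN <- function(variant, n, taxonNames = paste0("x", seq_len(n))) {
  suppressDegenerate(buildD(variant, n, taxonNames))
}

#' Build the prefix trie on length-n bit sequences
#'
#' The rooted binary tree whose vertices are all bit sequences of length
#' at most \code{n}, with an arc from \code{w} to \code{w'} exactly when
#' \code{w} is the maximal precursor of \code{w'} in that pool (i.e.
#' \code{w'} minus its last letter).  The root is the empty sequence and
#' the leaves are the \code{2^n} length-\code{n} sequences, each labeled
#' by its own sequence.
#'
#' @param n Sequence length, \code{n >= 1}.
#' @return A \code{PhyloNetwork} that is a binary tree.
#' @export
buildTrie <- function(n) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  pool <- allBitSequencesUpTo(n)
  tails <- character(0); heads <- character(0)
  for (w in pool) {
    mp <- maximalPrecursor(w, pool)
    if (!is.null(mp)) {
      tails <- c(tails, paste0("t:", mp))
      heads <- c(heads, paste0("t:", w))
    }
  }
  leaves <- allBitSequences(n)
  phyloNetwork(cbind(tail = tails, head = heads),
               leafLabels = structure(leaves, names = paste0("t:", leaves)))
}

#' Build a rooted caterpillar tree
#'
#' For an increasing set \code{a_1 < ... < a_k} of positive integers,
#' the caterpillar is the unique binary tree (single-leaf tree for
#' \code{k = 1}) whose non-leaf clusters are exactly the suffixes
#' \code{{a_j, ..., a_k}} for \code{1 <= j < k}: \code{a_1} hangs off the
#' root and \code{a_{k-1}, a_k} form the bottom cherry.  Leaves are
#' labeled by the integers as strings.
#'
#' @param a Strictly increasing vector of positive integers.
#' @return A \code{PhyloNetwork} that is a tree on \code{length(a)}
#'   leaves.
#' @export
buildCaterpillar <- function(a) {
  if (length(a) == 0L || any(diff(a) <= 0L) || any(a < 1L))
    stop("a must be a strictly increasing vector of positive integers",
         call. = FALSE)
  k <- length(a)
  leafId <- paste0("cl", a)
  if (k == 1L) {
    return(.newDAG(c("c1", leafId), cbind(tail = "c1", head = leafId), "c1",
                   structure(as.character(a), names = leafId),
                   "PhyloNetwork"))
  }
  tails <- character(0); heads <- character(0)
  for (j in seq_len(k - 1L)) {
    spine <- paste0("c", j)
    tails <- c(tails, spine); heads <- c(heads, leafId[[j]])
    nxt <- if (j < k - 1L) paste0("c", j + 1L) else leafId[[k]]
    tails <- c(tails, spine); heads <- c(heads, nxt)
  }
  phyloNetwork(cbind(tail = tails, head = heads),
               leafLabels = structure(as.character(a), names = leafId))
}

## Reverse all arcs of a tree (restriction of the trie), renaming: former
## leaves map to their labels (the sequence vertices of the host DAG),
## the former root maps to `sinkId`, interior vertices get `tagPrefix`.
.reverseToSink <- function(tree, sinkId, tagPrefix) {
  lab <- tree@leafLabels
  rename <- function(v) {
    if (v %in% names(lab)) return(lab[[v]])
    if (v == tree@root) return(sinkId)
    paste0(tagPrefix, v)
  }
  m <- vapply(tree@vertices, rename, character(1L))
  cbind(tail = unname(m[tree@arcs[, 2L]]),
        head = unname(m[tree@arcs[, 1L]]))
}

#' Build the binary family: stages D1-D3 and the network H_i
#'
#' Starting from \code{\link{buildD}}, three rewrites produce a binary
#' object with the same subnet behavior:
#' \describe{
#'   \item{\code{"D1"}}{the star under the root is replaced by the
#'     restriction of the prefix trie to the chosen parity class;}
#'   \item{\code{"D2"}}{each star into \code{y_j} is replaced by a
#'     fresh-vertex copy of the arc-reversed trie restricted to the class
#'     members whose letter \code{j} is 1, with sink \code{y_j};}
#'   \item{\code{"D3"}}{each sequence vertex with support larger than 2 is
#'     replaced by a caterpillar on its support whose leaf for position
#'     \code{t} is the child leading to \code{y_t};}
#'   \item{\code{"H"}}{degenerate vertices of the \code{"D3"} stage are
#'     suppressed, giving the valid, binary, recoverable network
#'     \code{H_i}.}
#' }
#' Interior vertices of distinct reversed-tree copies never coincide.
#'
#' @inheritParams buildD
#' @param stage One of \code{"H"} (default), \code{"D1"}, \code{"D2"},
#'   \code{"D3"}.
#' @return A \code{PhyloNetwork} for stage \code{"H"}; a \code{RootedDAG}
#'   for the intermediate stages.
#' @examples
#' h1 <- buildH(1, 3)
#' isBinaryNetwork(h1)  # TRUE
#' @export
buildH <- function(variant, n, stage = c("H", "D1", "D2", "D3"),
                   taxonNames = paste0("x", seq_len(n))) {
  stage <- match.arg(stage)
  .checkRecipe(variant, n, taxonNames)
  cls <- parityClasses(n)[[variant]]
  ys <- paste0("y", seq_len(n))
  xs <- paste0("x", seq_len(n))
  trie <- buildTrie(n)

  ## Stage D1: root star -> trie restricted to the parity class.  The
  ## restriction's leaves are labeled by the sequences; rename each leaf
  ## vertex to the sequence itself so the arcs into y_j reattach.
  tr <- restrictNetwork(trie, cls)
  lab <- tr@leafLabels
  ren <- function(v) if (v %in% names(lab)) lab[[v]] else v
  topArcs <- cbind(tail = vapply(tr@arcs[, 1L], ren, character(1L)),
                   head = vapply(tr@arcs[, 2L], ren, character(1L)))
  midArcs <- NULL
  for (u in cls) for (j in bitSupport(u))
    midArcs <- rbind(midArcs, c(u, ys[[j]]))
  botArcs <- cbind(ys, xs)
  d1 <- rootedDAG(rbind(topArcs, midArcs, botArcs),
                  leafLabels = structure(taxonNames, names = xs))
  if (stage == "D1") return(d1)

  ## Stage D2: star into each y_j -> reversed trie restriction with sink
  ## y_j; interior vertices are tagged per copy so copies stay disjoint.
  arcsNow <- d1@arcs
  for (j in seq_len(n)) {
    bij <- cls[vapply(cls, function(w) bitAt(w, j) == 1L, logical(1L))]
    rj <- restrictNetwork(trie, bij)
    drop <- arcsNow[, 2L] == ys[[j]]
    arcsNow <- rbind(arcsNow[!drop, , drop = FALSE],
                     .reverseToSink(rj, ys[[j]], paste0("R", j, ":")))
  }
  d2 <- rootedDAG(arcsNow, leafLabels = structure(taxonNames, names = xs))
  if (stage == "D2") return(d2)

  ## Stage D3: each sequence vertex with |support| > 2 -> caterpillar on
  ## its support; the leaf slot for position t takes the child of w that
  ## reaches y_t (a reachability query in the current stage).
  ix <- .graphIndex(d2)
  arcsNow <- d2@arcs
  for (w in cls) {
    supp <- bitSupport(w)
    if (length(supp) <= 2L) next
    wi <- match(w, ix$v)
    children <- ix$v[ix$out[[wi]]]
    childFor <- character(0)
    for (ch in children) {
      reach <- .reachableFrom(ix, match(ch, ix$v))
      t <- supp[vapply(supp, function(t) reach[[match(ys[[t]], ix$v)]],
                       logical(1L))]
      if (length(t) != 1L)
        stop("internal error: child of ", w, " reaches ", length(t),
             " middle-layer sinks", call. = FALSE)
      childFor[[as.character(t)]] <- ch
    }
    drop <- arcsNow[, 1L] == w
    arcsNow <- arcsNow[!drop, , drop = FALSE]
    ## caterpillar spine rooted at w itself
    k <- length(supp)
    spine <- c(w, if (k > 2L) paste0("C", w, ":", seq_len(k - 2L)))
    newArcs <- NULL
    for (jj in seq_len(k - 1L)) {
      newArcs <- rbind(newArcs,
                       c(spine[[jj]], childFor[[as.character(supp[[jj]])]]))
      nxt <- if (jj < k - 1L) spine[[jj + 1L]]
             else childFor[[as.character(supp[[k]])]]
      newArcs <- rbind(newArcs, c(spine[[jj]], nxt))
    }
    arcsNow <- rbind(arcsNow, newArcs)
  }
  d3 <- rootedDAG(arcsNow, leafLabels = structure(taxonNames, names = xs))
  if (stage == "D3") return(d3)

  suppressDegenerate(d3)
}
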