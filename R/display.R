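## Displayed trees and triplets.
##
## A displayed tree arises from a switching: keep exactly one in-arc per
## reticulation vertex, delete the rest, clean up vertices that lost
## their root path or all their descendants, and suppress to a valid tree
## on the full leaf set.  Switchings are enumerated exhaustively (the
## counterexample families at n <= 4 stay below 4096 switchings per
## network), and distinct results are collected by canonical form.

## Canonical key of a rooted tree given integer arcs: sorted nested
## parentheses over leaf labels.  Iso-invariant for trees and cheap.
.treeKeyInt <- function(nV, tails, heads, root, labelOf) {
  kids <- vector("list", nV)
  for (a in seq_along(tails))
    kids[[tails[[a]]]] <- c(kids[[tails[[a]]]], heads[[a]])
  rec <- function(v) {
    if (is.null(kids[[v]])) return(labelOf[[v]])
    paste0("(", paste(sort(vapply(kids[[v]], rec, character(1L))),
                      collapse = ","), ")")
  }
  rec(root)
}

.treeKey <- function(tree) {
  v <- tree@vertices
  labelOf <- character(length(v))
  labelOf[match(names(tree@leafLabels), v)] <- unname(tree@leafLabels)
  .treeKeyInt(length(v), match(tree@arcs[, 1L], v), match(tree@arcs[, 2L], v),
              match(tree@root, v), labelOf)
}

.makeTreeSet <- function(trees, keys) {
  o <- order(keys)
  new("TreeSet", trees = trees[o], keys = keys[o])
}

#' TreeSet accessors and comparison
#'
#' \code{treeSetMembers} returns the member trees as a list (sorted by
#' canonical key); \code{treeSetKeys} the keys; \code{treeSetEqual} tests
#' whether two collections hold exactly the same trees up to equivalence.
#'
#' @param x,a,b \code{TreeSet} objects.
#' @return See above.
#' @export
treeSetMembers <- function(x) { stopifnot(is(x, "TreeSet")); x@trees }

#' @rdname treeSetMembers
#' @export
treeSetKeys <- function(x) { stopifnot(is(x, "TreeSet")); x@keys }

#' @rdname treeSetMembers
#' @export
treeSetEqual <- function(a, b) {
  stopifnot(is(a, "TreeSet"), is(b, "TreeSet"))
  identical(a@keys, b@keys)
}

#' @rdname treeSetMembers
#' @param object The collection to print.
#' @keywords internal
#' @export
setMethod("show", "TreeSet", function(object) {
  cat(sprintf("TreeSet of %d tree(s)\n", length(object@trees)))
  for (k in utils::head(object@keys, 8L)) cat(" ", k, "\n")
  if (length(object@keys) > 8L) cat("  ...\n")
  invisible(object)
})

#' @rdname treeSetMembers
#' @export
setMethod("length", "TreeSet", function(x) length(x@trees))

#' Enumerate the trees displayed by a network
#'
#' For every choice of exactly one in-arc per reticulation vertex, the
#' unchosen in-arcs are deleted, vertices cut off from the root (or left
#' with no descendants) are removed, and the result is suppressed to a
#' valid tree on the full leaf set.  Distinct trees are collected.  The
#' number of switchings is the product of the reticulation indegrees, so
#' the output has at most that many members (and at most \code{2^r} for a
#' binary network with \code{r} reticulations).
#'
#' @param net A valid \code{PhyloNetwork}.
#' @return A \code{\linkS4class{TreeSet}}.
#' @export
displayedTrees <- function(net) {
  stopifnot(is(net, "RootedDAG"))
  v <- net@vertices
  nV <- length(v)
  tails0 <- match(net@arcs[, 1L], v)
  heads0 <- match(net@arcs[, 2L], v)
  root <- match(net@root, v)
  leaf <- v %in% names(net@leafLabels)
  labelOf <- character(nV)
  labelOf[match(names(net@leafLabels), v)] <- unname(net@leafLabels)

  indeg <- tabulate(heads0, nV)
  hybrids <- which(indeg >= 2L)
  inArcsOf <- lapply(hybrids, function(hv) which(heads0 == hv))
  radix <- lengths(inArcsOf)

  seen <- new.env(parent = emptyenv())
  trees <- list(); keys <- character(0)
  record <- function(tails, heads, rt) {
    key <- .treeKeyInt(nV, tails, heads, rt, labelOf)
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    arcs <- cbind(tail = v[tails], head = v[heads])
    alive <- unique(c(tails, heads))
    lab <- net@leafLabels
    tr <- .newDAG(v[alive], arcs, v[rt],
                  lab[names(lab) %in% v[alive]], "PhyloNetwork")
    trees[[length(trees) + 1L]] <<- tr
    keys <<- c(keys, key)
  }

  choice <- rep(1L, length(hybrids))
  repeat {
    dropArc <- logical(length(tails0))
    for (i in seq_along(hybrids)) {
      ia <- inArcsOf[[i]]
      dropArc[ia[-choice[[i]]]] <- TRUE
    }
    tails <- tails0[!dropArc]; heads <- heads0[!dropArc]
    ## cleanup: keep vertices reachable from the root that still lead to
    ## a leaf; iterate because each removal can expose the other defect
    repeat {
      keepV <- logical(nV)
      keepV[unique(c(tails, heads, root))] <- TRUE
      ## reachability from root over current arcs
      reach <- logical(nV); stack <- root; reach[root] <- TRUE
      while (length(stack)) {
        u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        for (w in heads[tails == u]) if (!reach[[w]]) {
          reach[[w]] <- TRUE; stack <- c(stack, w)
        }
      }
      outdeg <- tabulate(tails, nV)
      dead <- keepV & (!reach | (outdeg == 0L & !leaf))
      if (!any(dead)) break
      keepA <- !(tails %in% which(dead)) & !(heads %in% which(dead))
      tails <- tails[keepA]; heads <- heads[keepA]
    }
    sup <- .suppressInt(nV, tails, heads, root, leaf)
    record(sup$tails, sup$heads, sup$root)
    ## next switching (mixed-radix counter)
    if (!length(hybrids)) break
    i <- 1L
    while (i <= length(choice)) {
      choice[[i]] <- choice[[i]] + 1L
      if (choice[[i]] <= radix[[i]]) break
      choice[[i]] <- 1L
      i <- i + 1L
    }
    if (i > length(choice)) break
  }
  .makeTreeSet(trees, keys)
}

#' Triplet trees of a network
#'
#' The 3-leaf restrictions of the displayed trees, deduplicated by
#' canonical form.
#'
#' @param net A valid \code{PhyloNetwork} with at least 3 leaves.
#' @return A \code{\linkS4class{TreeSet}} of 3-leaf trees.
#' @export
tripletTrees <- function(net) {
  tx <- taxa(net)
  if (length(tx) < 3L) stop("triplets need at least 3 leaves", call. = FALSE)
  disp <- displayedTrees(net)
  combos <- utils::combn(tx, 3L)
  seen <- new.env(parent = emptyenv())
  trees <- list(); keys <- character(0)
  for (tr in disp@trees) {
    for (i in seq_len(ncol(combos))) {
      trip <- restrictNetwork(tr, combos[, i])
      key <- .treeKey(trip)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        trees[[length(trees) + 1L]] <- trip
        keys <- c(keys, key)
      }
    }
  }
  .makeTreeSet(trees, keys)
}
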