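## Induced subnets: degenerate-vertex suppression, lowest stable
## ancestors, restriction N|Y, recoverability, trinets.
##
## Suppression runs on an integer arc representation; the character-level
## objects are rebuilt only at the boundary.  Degenerate chains are
## contracted in batches (deterministic, topological effect); a
## one-at-a-time randomized order is kept for confluence checking.

## ---- integer-level suppression -------------------------------------------

## tails/heads: integer arc vectors over vertices 1..nV; leaf: logical.
## Returns list(tails, heads, root, alive).  Leaves are never suppressed.
.suppressInt <- function(nV, tails, heads, root, leaf) {
  alive <- logical(nV)
  alive[unique(c(tails, heads, root))] <- TRUE
  repeat {
    ## merge parallel arcs
    key <- (tails - 1) * nV + heads
    dup <- duplicated(key)
    if (any(dup)) { tails <- tails[!dup]; heads <- heads[!dup] }
    outdeg <- tabulate(tails, nV)
    indeg <- tabulate(heads, nV)
    nAlive <- sum(alive)
    if (nAlive < 3L) break
    ## promote past any outdegree-1 root
    changed <- FALSE
    while (alive[root] && outdeg[root] == 1L && sum(alive) >= 3L) {
      child <- heads[tails == root][1L]
      if (leaf[child])
        stop("internal error: outdegree-1 root above a leaf in a ",
             "graph of 3+ vertices (disconnected input?)", call. = FALSE)
      keep <- tails != root
      tails <- tails[keep]; heads <- heads[keep]
      alive[root] <- FALSE
      root <- child
      outdeg <- tabulate(tails, nV); indeg <- tabulate(heads, nV)
      changed <- TRUE
    }
    ## contract chains of indegree-1 / outdegree-1 vertices
    degen <- alive & !leaf & indeg == 1L & outdeg == 1L
    if (!any(degen)) { if (!changed) break else next }
    childOf <- integer(nV)
    childOf[tails[degen[tails]]] <- heads[degen[tails]]
    newT <- integer(0); newH <- integer(0)
    for (a in seq_along(tails)) {
      u <- tails[a]
      if (degen[u]) next  # arc leaves a suppressed vertex; folded below
      h <- heads[a]
      while (degen[h]) h <- childOf[h]
      newT <- c(newT, u); newH <- c(newH, h)
    }
    alive[degen] <- FALSE
    tails <- newT; heads <- newH
  }
  list(tails = tails, heads = heads, root = root, alive = alive)
}

## Randomized one-at-a-time suppression (confluence checking).
.suppressIntRandom <- function(nV, tails, heads, root, leaf) {
  alive <- logical(nV)
  alive[unique(c(tails, heads, root))] <- TRUE
  repeat {
    key <- (tails - 1) * nV + heads
    dup <- duplicated(key)
    if (any(dup)) { tails <- tails[!dup]; heads <- heads[!dup] }
    if (sum(alive) < 3L) break
    outdeg <- tabulate(tails, nV)
    indeg <- tabulate(heads, nV)
    degen <- which(alive & !leaf & outdeg == 1L & indeg <= 1L)
    if (!length(degen)) break
    v <- if (length(degen) == 1L) degen else sample(degen, 1L)
    w <- heads[tails == v][1L]
    if (indeg[v] == 0L) {           # outdegree-1 root
      if (leaf[w])
        stop("internal error: outdegree-1 root above a leaf", call. = FALSE)
      keep <- tails != v
      tails <- tails[keep]; heads <- heads[keep]
      root <- w
    } else {
      u <- tails[heads == v][1L]
      keep <- tails != v & heads != v
      tails <- c(tails[keep], u); heads <- c(heads[keep], w)
    }
    alive[v] <- FALSE
  }
  list(tails = tails, heads = heads, root = root, alive = alive)
}

#' Suppress degenerate vertices
#'
#' Iterates to a fixpoint: every degenerate vertex (outdegree 1, indegree
#' at most 1, in a graph of at least 3 vertices) is removed — an interior
#' one by splicing its in-arc onto its out-arc, an outdegree-1 root by
#' promoting its child — and parallel arcs arising along the way are
#' merged to single arcs.  The result satisfies the strict network
#' invariants.  The fixpoint does not depend on the processing order;
#' \code{order = "random"} exercises an arbitrary one-at-a-time order
#' (using the current RNG state) for exactly that confluence property.
#'
#' @param g A \code{RootedDAG} (a \code{PhyloNetwork} passes through
#'   unchanged up to class).
#' @param order \code{"batch"} (deterministic chain contraction, default)
#'   or \code{"random"}.
#' @return A \code{PhyloNetwork} on the same leaves.
#' @export
suppressDegenerate <- function(g, order = c("batch", "random")) {
  stopifnot(is(g, "RootedDAG"))
  order <- match.arg(order)
  v <- g@vertices
  nV <- length(v)
  tails <- match(g@arcs[, 1L], v)
  heads <- match(g@arcs[, 2L], v)
  leaf <- v %in% names(g@leafLabels)
  root <- match(g@root, v)
  res <- if (order == "batch")
    .suppressInt(nV, tails, heads, root, leaf)
  else
    .suppressIntRandom(nV, tails, heads, root, leaf)
  arcs <- cbind(tail = v[res$tails], head = v[res$heads])
  keepLab <- g@leafLabels[names(g@leafLabels) %in% v[res$alive]]
  out <- .newDAG(v[res$alive], arcs, v[res$root], keepLab, "PhyloNetwork")
  bad <- validateNetwork(out, strict = TRUE)
  if (length(bad))
    stop("suppression did not reach a valid network: ",
         paste(bad, collapse = "; "), call. = FALSE)
  out
}

## ---- lowest stable ancestor ----------------------------------------------

## Dominator sets via a single topological-order dataflow pass:
## Dom(root) = {root}; Dom(v) = {v} + intersection of Dom over parents.
## Returns an nV x nV logical matrix D with D[v, u] = TRUE iff u dominates v.
.dominators <- function(ix) {
  nV <- length(ix$v)
  topo <- .topoOrder(ix)
  if (is.null(topo)) stop("cyclic graph", call. = FALSE)
  D <- matrix(FALSE, nV, nV)
  for (u in topo) {
    ps <- ix$inn[[u]]
    if (length(ps) == 0L) {
      D[u, u] <- TRUE
    } else {
      row <- D[ps[[1L]], ]
      for (p in ps[-1L]) row <- row & D[p, ]
      row[u] <- TRUE
      D[u, ] <- row
    }
  }
  D
}

.resolveTaxa <- function(net, taxaSubset) {
  if (length(taxaSubset) == 0L)
    stop("the leaf subset must be nonempty", call. = FALSE)
  lab <- net@leafLabels
  hit <- match(taxaSubset, lab)
  if (anyNA(hit))
    stop("unknown taxa: ", paste(taxaSubset[is.na(hit)], collapse = ", "),
         call. = FALSE)
  names(lab)[hit]
}

#' Lowest stable ancestor of a leaf subset
#'
#' The lowest stable ancestor of a nonempty leaf subset \code{Y} is the
#' non-leaf vertex that lies on every directed path from the root to every
#' member of \code{Y}, such that no vertex below it has the same property.
#' It always exists and is unique.  Computed via dominator analysis: the
#' common dominators of \code{Y} form a chain from the root, and the
#' answer is its lowest non-leaf element.
#'
#' @param net A valid \code{PhyloNetwork} (any \code{RootedDAG} with a
#'   single root is accepted).
#' @param taxaSubset Nonempty character vector of taxon labels.
#' @return The identifier of the lowest stable ancestor vertex.
#' @export
lsa <- function(net, taxaSubset) {
  stopifnot(is(net, "RootedDAG"))
  targets <- .resolveTaxa(net, taxaSubset)
  ix <- .graphIndex(net)
  D <- .dominators(ix)
  ti <- match(targets, ix$v)
  common <- D[ti[[1L]], ]
  for (t in ti[-1L]) common <- common & D[t, ]
  common[match(names(net@leafLabels), ix$v)] <- FALSE  # w is never a leaf
  cand <- which(common)
  if (!length(cand))
    stop("internal error: no stable ancestor found", call. = FALSE)
  ## the candidates form a chain under domination; the lowest one has all
  ## other candidates among its own dominators
  for (u in cand) if (all(D[u, cand])) return(ix$v[[u]])
  stop("internal error: stable ancestors do not form a chain", call. = FALSE)
}

#' Is the network recoverable?
#'
#' A network is recoverable when the lowest stable ancestor of its full
#' leaf set is the root — exactly the networks fixed by restriction to
#' their own leaf set.
#'
#' @param net A valid \code{PhyloNetwork}.
#' @return Logical.
#' @export
isRecoverable <- function(net) {
  identical(lsa(net, unname(net@leafLabels)), net@root)
}

#' Induced subnet on a leaf subset
#'
#' The subnet \code{N|Y}: delete every vertex (with its incident arcs)
#' that does not lie on a directed path from the lowest stable ancestor of
#' \code{Y} to some member of \code{Y}, then suppress degenerate vertices
#' and merge parallel arcs until a valid network on \code{Y} remains.  The
#' result is always recoverable.
#'
#' @inheritParams lsa
#' @return A \code{PhyloNetwork} with taxon set \code{taxaSubset}.
#' @export
restrictNetwork <- function(net, taxaSubset) {
  stopifnot(is(net, "RootedDAG"))
  targets <- .resolveTaxa(net, taxaSubset)
  top <- lsa(net, taxaSubset)
  ix <- .graphIndex(net)
  ti <- match(targets, ix$v)
  keep <- .reachableFrom(ix, match(top, ix$v)) & .coReachable(ix, ti)
  kv <- ix$v[keep]
  a <- net@arcs
  a <- a[a[, 1L] %in% kv & a[, 2L] %in% kv, , drop = FALSE]
  lab <- net@leafLabels[names(net@leafLabels) %in% targets]
  if (length(kv) == 1L) {           # single leaf with lsa == its parent? never: lsa is non-leaf
    stop("internal error: restriction collapsed to one vertex", call. = FALSE)
  }
  sub <- .newDAG(kv, a, top, lab, "RootedDAG")
  suppressDegenerate(sub)
}

#' All trinets of a network
#'
#' The trinet on a 3-element leaf subset is the induced subnet on those
#' three taxa.  Every 3-subset of the leaf set is enumerated.
#'
#' @param net A valid \code{PhyloNetwork} with at least 3 leaves.
#' @return Named list of \code{PhyloNetwork} objects, one per 3-subset,
#'   keyed by the sorted taxa joined with \code{"|"}.
#' @export
trinets <- function(net) {
  tx <- taxa(net)
  if (length(tx) < 3L)
    stop("trinets need at least 3 leaves", call. = FALSE)
  combos <- utils::combn(tx, 3L)
  out <- vector("list", ncol(combos))
  nm <- character(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    y <- combos[, i]
    out[[i]] <- restrictNetwork(net, y)
    nm[[i]] <- paste(y, collapse = "|")
  }
  names(out) <- nm
  out
}
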