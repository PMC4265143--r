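## Core network model: constructors, accessors, validation, degree
## predicates, and the level statistic.
##
## Internally all algorithms run on an integer-indexed view of the arc
## matrix (.graphIndex) so hot paths avoid repeated string matching.

.newDAG <- function(vertices, arcs, root, leafLabels,
                    class = "RootedDAG") {
  new(class, vertices = vertices, arcs = arcs, root = root,
      leafLabels = leafLabels)
}

.emptyArcs <- function() {
  matrix(character(0), ncol = 2L, dimnames = list(NULL, c("tail", "head")))
}

.asArcMatrix <- function(arcs) {
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.null(arcs) || length(arcs) == 0L) return(.emptyArcs())
  if (!is.matrix(arcs) || ncol(arcs) != 2L)
    stop("arcs must be a two-column matrix of (tail, head) pairs",
         call. = FALSE)
  storage.mode(arcs) <- "character"
  dimnames(arcs) <- list(NULL, c("tail", "head"))
  arcs
}

## Integer-indexed adjacency view: out/inn are lists of integer child /
## parent vectors (with multiplicity, for multisets of arcs).
.graphIndex <- function(g) {
  v <- g@vertices
  nV <- length(v)
  t <- match(g@arcs[, 1L], v)
  h <- match(g@arcs[, 2L], v)
  out <- vector("list", nV)
  inn <- vector("list", nV)
  for (i in seq_len(nV)) { out[[i]] <- integer(0); inn[[i]] <- integer(0) }
  if (length(t)) {
    out <- unname(split(h, factor(t, levels = seq_len(nV))))
    inn <- unname(split(t, factor(h, levels = seq_len(nV))))
  }
  list(v = v, out = out, inn = inn,
       outdeg = lengths(out), indeg = lengths(inn),
       root = match(g@root, v))
}

## Kahn topological order over an index; NULL if the graph has a cycle.
.topoOrder <- function(ix) {
  n <- length(ix$v)
  indeg <- ix$indeg
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, u)
    for (w in ix$out[[u]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) NULL else order
}

.reachableFrom <- function(ix, start) {
  seen <- logical(length(ix$v))
  stack <- start
  seen[start] <- TRUE
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (w in ix$out[[u]]) if (!seen[[w]]) { seen[[w]] <- TRUE; stack <- c(stack, w) }
  }
  seen
}

.coReachable <- function(ix, targets) {
  seen <- logical(length(ix$v))
  stack <- targets
  seen[targets] <- TRUE
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (w in ix$inn[[u]]) if (!seen[[w]]) { seen[[w]] <- TRUE; stack <- c(stack, w) }
  }
  seen
}

#' Construct a rooted DAG
#'
#' Builds a \code{\linkS4class{RootedDAG}} from an arc list, inferring the
#' vertex set, the root (the unique indegree-0 vertex) and, when
#' \code{leafLabels} is omitted, labeling every outdegree-0 vertex by its
#' own identifier.  Parallel arcs are permitted.  Structural defects
#' (cycles, several roots, unreachable vertices) are errors here; use
#' \code{\link{validateNetwork}} to obtain a report instead.
#'
#' @param arcs Two-column matrix (or data frame) of (tail, head) vertex
#'   identifier pairs.
#' @param leafLabels Optional named character vector mapping outdegree-0
#'   vertex identifiers to taxon labels.
#' @param isolated Optional character vector of additional vertices with
#'   no incident arcs (rarely needed).
#' @return A validated \code{RootedDAG}.
#' @examples
#' g <- rootedDAG(rbind(c("r", "a"), c("r", "b")))
#' @export
rootedDAG <- function(arcs, leafLabels = NULL, isolated = character(0)) {
  arcs <- .asArcMatrix(arcs)
  vertices <- unique(c(arcs[, 1L], arcs[, 2L], isolated))
  dag <- .finishDAG(vertices, arcs, leafLabels, "RootedDAG")
  bad <- validateNetwork(dag, strict = FALSE)
  if (length(bad))
    stop("invalid rooted DAG: ", paste(bad, collapse = "; "), call. = FALSE)
  dag
}

#' Construct a phylogenetic network
#'
#' Like \code{\link{rootedDAG}} but enforces the full network invariants:
#' no parallel arcs, no degenerate vertices, root outdegree at least 2
#' (unless the network has exactly two vertices).
#'
#' @inheritParams rootedDAG
#' @return A validated \code{PhyloNetwork}.
#' @export
phyloNetwork <- function(arcs, leafLabels = NULL) {
  arcs <- .asArcMatrix(arcs)
  vertices <- unique(c(arcs[, 1L], arcs[, 2L]))
  net <- .finishDAG(vertices, arcs, leafLabels, "PhyloNetwork")
  bad <- validateNetwork(net, strict = TRUE)
  if (length(bad))
    stop("invalid phylogenetic network: ", paste(bad, collapse = "; "),
         call. = FALSE)
  net
}

.finishDAG <- function(vertices, arcs, leafLabels, class) {
  if (length(vertices) == 0L)
    stop("a rooted DAG needs at least one arc", call. = FALSE)
  outdeg <- table(factor(arcs[, 1L], levels = vertices))
  indeg <- table(factor(arcs[, 2L], levels = vertices))
  roots <- vertices[indeg == 0L]
  root <- if (length(roots) == 1L) roots else vertices[[1L]]
  leaves <- vertices[outdeg == 0L]
  if (is.null(leafLabels)) {
    leafLabels <- structure(leaves, names = leaves)
  } else {
    leafLabels <- leafLabels[names(leafLabels) %in% vertices]
  }
  .newDAG(vertices, arcs, root, leafLabels, class)
}

#' Promote a rooted DAG to a phylogenetic network
#'
#' Checks the strict network invariants on an existing \code{RootedDAG}
#' and rebrands it; fails if any are violated (it does not repair — see
#' \code{\link{suppressDegenerate}} for that).
#'
#' @param dag A \code{RootedDAG}.
#' @return A \code{PhyloNetwork} with identical vertices and arcs.
#' @export
asPhyloNetwork <- function(dag) {
  stopifnot(is(dag, "RootedDAG"))
  bad <- validateNetwork(dag, strict = TRUE)
  if (length(bad))
    stop("not a valid phylogenetic network: ", paste(bad, collapse = "; "),
         call. = FALSE)
  .newDAG(dag@vertices, dag@arcs, dag@root, dag@leafLabels, "PhyloNetwork")
}

#' Accessors for rooted DAGs and networks
#'
#' \code{vertexIds} returns the vertex identifiers, \code{arcs} the
#' (tail, head) arc matrix, \code{networkRoot} the root identifier,
#' \code{leafLabels} the vertex-to-taxon map, and \code{taxa} the sorted
#' taxon labels.
#'
#' @param x A \code{RootedDAG} or \code{PhyloNetwork}.
#' @return See above.
#' @name accessors
#' @aliases vertexIds arcs networkRoot leafLabels taxa
NULL

#' @rdname accessors
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))
#' @rdname accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))
#' @rdname accessors
#' @export
setGeneric("networkRoot", function(x) standardGeneric("networkRoot"))
#' @rdname accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))
#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
setMethod("vertexIds", "RootedDAG", function(x) x@vertices)
#' @rdname accessors
setMethod("arcs", "RootedDAG", function(x) x@arcs)
#' @rdname accessors
setMethod("networkRoot", "RootedDAG", function(x) x@root)
#' @rdname accessors
setMethod("leafLabels", "RootedDAG", function(x) x@leafLabels)
#' @rdname accessors
setMethod("taxa", "RootedDAG", function(x) sort(unname(x@leafLabels)))

#' Vertex degrees
#'
#' In- and outdegrees of every vertex, as named integer vectors.
#'
#' @param x A \code{RootedDAG} or \code{PhyloNetwork}.
#' @return Named integer vector over all vertices.
#' @export
indegrees <- function(x) {
  d <- table(factor(x@arcs[, 2L], levels = x@vertices))
  structure(as.integer(d), names = x@vertices)
}

#' @rdname indegrees
#' @export
outdegrees <- function(x) {
  d <- table(factor(x@arcs[, 1L], levels = x@vertices))
  structure(as.integer(d), names = x@vertices)
}

#' Show a network summary
#'
#' @param object The object.
#' @keywords internal
#' @export
setMethod("show", "RootedDAG", function(object) {
  kind <- if (is(object, "PhyloNetwork")) "PhyloNetwork" else "RootedDAG"
  ret <- sum(indegrees(object) >= 2L)
  cat(sprintf("%s: %d vertices, %d arcs, %d reticulation(s)\n",
              kind, length(object@vertices), nrow(object@arcs), ret))
  cat("  root:", object@root, "\n")
  tx <- taxa(object)
  cat(sprintf("  taxa (%d): %s\n", length(tx),
              paste(utils::head(tx, 10L), collapse = ", ")))
  invisible(object)
})

#' Validate a rooted DAG or network
#'
#' Checks the structural invariants and returns a report of every
#' violation found (an empty character vector means the object is valid);
#' nothing is thrown.  With \code{strict = TRUE} the phylogenetic-network
#' invariants are demanded on top of the DAG ones: no parallel arcs, no
#' degenerate vertices (outdegree 1 with indegree at most 1, in a graph of
#' at least 3 vertices), and root outdegree at least 2 unless the network
#' has exactly two vertices.
#'
#' @param g A \code{RootedDAG} (or \code{PhyloNetwork}).
#' @param strict Demand the network invariants as well.
#' @return Character vector of violation messages; empty iff valid.
#' @export
validateNetwork <- function(g, strict = FALSE) {
  stopifnot(is(g, "RootedDAG"))
  msg <- character(0)
  v <- g@vertices
  ix <- .graphIndex(g)
  if (is.null(.topoOrder(ix)))
    msg <- c(msg, "graph contains a directed cycle")
  nroots <- sum(ix$indeg == 0L)
  if (nroots != 1L)
    msg <- c(msg, sprintf("expected exactly one indegree-0 vertex, found %d",
                          nroots))
  else if (v[ix$indeg == 0L] != g@root)
    msg <- c(msg, "root slot does not name the indegree-0 vertex")
  if (!is.na(ix$root) && !is.null(.topoOrder(ix))) {
    if (!all(.reachableFrom(ix, ix$root)))
      msg <- c(msg, "not every vertex is reachable from the root")
  }
  leaves <- v[ix$outdeg == 0L]
  lab <- g@leafLabels
  if (!setequal(names(lab), leaves))
    msg <- c(msg, "leaf labels must cover exactly the outdegree-0 vertices")
  if (anyDuplicated(lab))
    msg <- c(msg, "leaf labels must be injective")
  if (strict) {
    if (anyDuplicated(paste(g@arcs[, 1L], g@arcs[, 2L], sep = "\r")))
      msg <- c(msg, "parallel arcs present")
    if (length(v) >= 3L) {
      degen <- v[ix$outdeg == 1L & ix$indeg <= 1L]
      if (length(degen))
        msg <- c(msg, paste0("degenerate vertices present: ",
                             paste(sort(degen), collapse = ", ")))
    }
    if (length(v) > 2L && !is.na(ix$root) && ix$outdeg[[ix$root]] < 2L)
      msg <- c(msg, "root outdegree must be at least 2")
  }
  msg
}

#' Is the network binary?
#'
#' A network is binary when its root has outdegree 2 and every interior
#' vertex (neither root nor leaf) has indegree plus outdegree equal to 3.
#' The two-vertex network is not binary (root outdegree 1).
#'
#' @param net A valid \code{PhyloNetwork}.
#' @return Logical.
#' @export
isBinaryNetwork <- function(net) {
  stopifnot(is(net, "RootedDAG"))
  indeg <- indegrees(net); outdeg <- outdegrees(net)
  if (outdeg[[net@root]] != 2L) return(FALSE)
  interior <- setdiff(net@vertices, c(net@root, names(net@leafLabels)))
  all(indeg[interior] + outdeg[interior] == 3L)
}

#' Level of a network
#'
#' The level is the maximum, over the biconnected components of the
#' underlying undirected graph, of the number of reticulation vertices
#' (directed indegree at least 2) contained in the component.  Every tree
#' has level 0.
#'
#' @param net A valid \code{PhyloNetwork}.
#' @return Nonnegative integer.
#' @export
networkLevel <- function(net) {
  stopifnot(is(net, "RootedDAG"))
  indeg <- indegrees(net)
  hybrids <- names(indeg)[indeg >= 2L]
  if (length(hybrids) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(net@arcs, directed = FALSE)
  comps <- igraph::biconnected_components(g)$components
  best <- 0L
  for (comp in comps) {
    k <- sum(names(comp) %in% hybrids)
    if (k > best) best <- k
  }
  best
}

#' Relabel taxa
#'
#' Replaces taxon labels by new ones, keeping the topology untouched.
#'
#' @param net A \code{RootedDAG} or \code{PhyloNetwork}.
#' @param map Named character vector from old taxon labels to new ones;
#'   labels absent from the map are kept.
#' @return Object of the same class with relabeled leaves.
#' @export
relabelTaxa <- function(net, map) {
  stopifnot(is(net, "RootedDAG"))
  lab <- net@leafLabels
  hit <- lab %in% names(map)
  lab[hit] <- map[lab[hit]]
  if (anyDuplicated(lab)) stop("relabeling must stay injective", call. = FALSE)
  .newDAG(net@vertices, net@arcs, net@root, lab, class(net))
}
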