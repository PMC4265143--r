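#' @import methods
NULL

#' Rooted directed acyclic graphs with labeled leaves
#'
#' \code{RootedDAG} is the working container for rooted, connected DAGs
#' whose outdegree-0 vertices carry taxon labels.  It may hold parallel
#' arcs (the arc slot is a multiset) and degenerate vertices — vertices of
#' outdegree 1 and indegree at most 1 — both of which arise transiently
#' during suppression and in the staged constructions.
#'
#' \code{PhyloNetwork} extends \code{RootedDAG} with the constraints of a
#' rooted phylogenetic network: the arcs form a set (no parallel arcs),
#' there are no degenerate vertices, and the root has outdegree at least 2
#' unless the network is the trivial two-vertex root-plus-leaf network.
#'
#' Vertex identifiers are opaque strings; no operation relies on their
#' content.  Use \code{\link{rootedDAG}} and \code{\link{phyloNetwork}} to
#' build validated objects, and the accessors \code{\link{vertexIds}},
#' \code{\link{arcs}}, \code{\link{networkRoot}}, \code{\link{leafLabels}},
#' \code{\link{taxa}} rather than slots.
#'
#' @slot vertices Character vector of distinct vertex identifiers.
#' @slot arcs Two-column character matrix of (tail, head) pairs.
#' @slot root Identifier of the unique indegree-0 vertex.
#' @slot leafLabels Named character vector mapping each outdegree-0 vertex
#'   identifier to its taxon label (injective).
#'
#' @aliases PhyloNetwork-class RootedDAG-class
#' @name RootedDAG-class
#' @exportClass RootedDAG
setClass("RootedDAG",
  representation(vertices = "character", arcs = "matrix",
                 root = "character", leafLabels = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!is.character(object@arcs) || ncol(object@arcs) != 2L)
      msg <- c(msg, "arcs must be a two-column character matrix")
    if (length(object@root) != 1L)
      msg <- c(msg, "root must be a single vertex identifier")
    if (anyDuplicated(object@vertices))
      msg <- c(msg, "vertex identifiers must be distinct")
    if (length(msg)) msg else TRUE
  })

#' @name RootedDAG-class
#' @exportClass PhyloNetwork
setClass("PhyloNetwork", contains = "RootedDAG")

#' Outcome of an equivalence test, with proof
#'
#' Carries the verdict of \code{\link{areEquivalent}} or
#' \code{\link{areNetworkEquivalent}} together with evidence: a verified
#' vertex bijection when the verdict is positive, or a human-readable
#' certificate (a distinguishing structural invariant, or the leaf subset
#' on which induced subnets differ) when it is negative.
#'
#' @slot verdict Logical.
#' @slot mapping Named character vector (names: vertices of the first
#'   network; values: vertices of the second); empty unless verdict is
#'   \code{TRUE} and a single-network bijection applies.
#' @slot certificate Character description of the failure; empty when the
#'   verdict is \code{TRUE}.
#'
#' @name EquivalenceWitness-class
#' @exportClass EquivalenceWitness
setClass("EquivalenceWitness",
  representation(verdict = "logical", mapping = "character",
                 certificate = "character"))

#' A duplicate-free collection of rooted trees keyed by canonical form
#'
#' Holds rooted phylogenetic trees on a common leaf set (displayed trees,
#' triplet trees) with duplicates collapsed: two members never share a
#' canonical form.  Compare collections with \code{\link{treeSetEqual}}.
#'
#' @slot trees List of \code{PhyloNetwork} tree objects.
#' @slot keys Character vector of canonical-form keys, parallel to
#'   \code{trees}, strictly sorted.
#'
#' @name TreeSet-class
#' @exportClass TreeSet
setClass("TreeSet",
  representation(trees = "list", keys = "character"),
  validity = function(object) {
    if (length(object@trees) != length(object@keys))
      return("trees and keys must have equal length")
    if (anyDuplicated(object@keys))
      return("keys must be distinct (duplicates collapsed on construction)")
    TRUE
  })
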