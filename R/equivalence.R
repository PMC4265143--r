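## Equivalence (leaf-label-preserving isomorphism), plain digraph
## isomorphism, canonical forms, and network-equivalence over all proper
## leaf subsets.
##
## The decision procedure is a canonical form computed by iterative color
## refinement seeded with leaf labels, with individualization-refinement
## backtracking when color classes remain ambiguous (reticulation
## symmetry).  General DAG isomorphism has no known polynomial algorithm;
## instances here are tiny and the test suite guards the procedure with an
## exhaustive-bijection oracle and igraph's VF2.

## Refine an integer coloring to the coarsest stable refinement under
## (own color, multiset of child colors, multiset of parent colors).
.refineColors <- function(ix, colors) {
  repeat {
    sig <- character(length(colors))
    for (v in seq_along(colors)) {
      ch <- colors[ix$out[[v]]]
      pa <- colors[ix$inn[[v]]]
      sig[[v]] <- paste(colors[[v]],
                        paste(sort(ch), collapse = ","),
                        paste(sort(pa), collapse = ","), sep = "|")
    }
    newc <- match(sig, sort(unique(sig)))
    if (length(unique(newc)) == length(unique(colors))) return(newc)
    colors <- newc
  }
}

.initialColors <- function(net, ix, respectLabels) {
  colors <- rep(1L, length(ix$v))
  if (respectLabels) {
    lab <- net@leafLabels
    li <- match(names(lab), ix$v)
    colors[li] <- 1L + match(lab, sort(unname(lab)))
  } else {
    colors[match(names(net@leafLabels), ix$v)] <- 2L
  }
  colors
}

## Serialize a discrete (all-singleton) coloring into a canonical string.
.serializeColoring <- function(net, ix, colors, respectLabels) {
  rank <- match(seq_along(colors), order(colors))
  arcsStr <- paste(rank[match(net@arcs[, 1L], ix$v)],
                   rank[match(net@arcs[, 2L], ix$v)], sep = ">")
  leafStr <- if (respectLabels) {
    li <- match(names(net@leafLabels), ix$v)
    sort(paste0(rank[li], "=", unname(net@leafLabels)))
  } else {
    sort(as.character(rank[match(names(net@leafLabels), ix$v)]))
  }
  paste0("V", length(colors), ";A", nrow(net@arcs), ";",
         paste(sort(arcsStr), collapse = " "), ";L:",
         paste(leafStr, collapse = " "))
}

## Individualization-refinement: returns list(key, order) where order is
## the canonical vertex ordering (indices into ix$v).
.canonSearch <- function(net, ix, colors, respectLabels) {
  colors <- .refineColors(ix, colors)
  tab <- table(colors)
  if (all(tab == 1L)) {
    key <- .serializeColoring(net, ix, colors, respectLabels)
    return(list(key = key, order = order(colors)))
  }
  ## first ambiguous cell (smallest color value): isomorphism-invariant
  target <- as.integer(names(tab)[tab > 1L][1L])
  cell <- which(colors == target)
  best <- NULL
  newColor <- max(colors) + 1L
  for (v in cell) {
    branch <- colors
    branch[[v]] <- newColor
    res <- .canonSearch(net, ix, branch, respectLabels)
    if (is.null(best) || res$key < best$key) best <- res
  }
  best
}

.canonical <- function(net, respectLabels = TRUE) {
  ix <- .graphIndex(net)
  .canonSearch(net, ix, .initialColors(net, ix, respectLabels),
               respectLabels)
}

#' Canonical form of a network
#'
#' Computes a character string such that two valid networks on the same
#' taxon set are equivalent (isomorphic by a bijection fixing every leaf
#' label) if and only if their canonical forms are identical.  The string
#' does not depend on vertex identifiers.
#'
#' @param net A valid \code{PhyloNetwork} (or \code{RootedDAG}).
#' @param respectLabels If \code{FALSE}, leaf labels are erased (leaves
#'   stay distinguishable as a class) and the string decides plain digraph
#'   isomorphism instead.
#' @return A character string.
#' @export
canonicalForm <- function(net, respectLabels = TRUE) {
  stopifnot(is(net, "RootedDAG"))
  .canonical(net, respectLabels)$key
}

.witness <- function(verdict, mapping = character(0),
                     certificate = character(0)) {
  new("EquivalenceWitness", verdict = verdict, mapping = mapping,
      certificate = certificate)
}

#' @rdname verdict
#' @param object The witness to print.
#' @keywords internal
#' @export
setMethod("show", "EquivalenceWitness", function(object) {
  cat("EquivalenceWitness: verdict", object@verdict, "\n")
  if (length(object@certificate))
    cat("  certificate:", object@certificate, "\n")
  if (length(object@mapping))
    cat("  mapping over", length(object@mapping), "vertices\n")
  invisible(object)
})

#' Witness accessors
#'
#' @param w An \code{EquivalenceWitness}.
#' @return \code{verdict}: logical; \code{witnessMapping}: named character
#'   vertex bijection (empty when none applies); \code{certificate}:
#'   failure description (empty on success).
#' @export
verdict <- function(w) w@verdict
#' @rdname verdict
#' @export
witnessMapping <- function(w) w@mapping
#' @rdname verdict
#' @export
certificate <- function(w) w@certificate

## Verify that a candidate vertex bijection maps a onto b exactly.
.verifyMapping <- function(a, b, mapping) {
  if (length(mapping) != length(a@vertices)) return(FALSE)
  if (!setequal(unname(mapping), b@vertices)) return(FALSE)
  mapped <- cbind(unname(mapping[a@arcs[, 1L]]),
                  unname(mapping[a@arcs[, 2L]]))
  keyA <- sort(paste(mapped[, 1L], mapped[, 2L], sep = "\r"))
  keyB <- sort(paste(b@arcs[, 1L], b@arcs[, 2L], sep = "\r"))
  if (!identical(keyA, keyB)) return(FALSE)
  la <- a@leafLabels
  lb <- b@leafLabels
  all(unname(lb[unname(mapping[names(la)])]) == unname(la))
}

.cheapCertificate <- function(a, b) {
  if (!setequal(unname(a@leafLabels), unname(b@leafLabels)))
    return("label sets differ")
  if (length(a@vertices) != length(b@vertices))
    return(sprintf("vertex counts differ (%d vs %d)",
                   length(a@vertices), length(b@vertices)))
  if (nrow(a@arcs) != nrow(b@arcs))
    return(sprintf("arc counts differ (%d vs %d)",
                   nrow(a@arcs), nrow(b@arcs)))
  degA <- sort(paste(indegrees(a), outdegrees(a)))
  degB <- sort(paste(indegrees(b), outdegrees(b)))
  if (!identical(degA, degB))
    return("degree multisets differ")
  NULL
}

#' Are two networks equivalent?
#'
#' Two networks on the same taxon set are equivalent when there is a
#' digraph isomorphism between them mapping every leaf to itself (i.e.
#' preserving taxon labels).  On success the returned witness carries an
#' explicit vertex bijection, re-verified by direct arc comparison; on
#' failure it carries a distinguishing certificate (a cheap structural
#' invariant where one suffices).
#'
#' @param a,b Valid \code{PhyloNetwork} objects.
#' @return An \code{\linkS4class{EquivalenceWitness}}.
#' @export
areEquivalent <- function(a, b) {
  stopifnot(is(a, "RootedDAG"), is(b, "RootedDAG"))
  cert <- .cheapCertificate(a, b)
  if (!is.null(cert)) return(.witness(FALSE, certificate = cert))
  ca <- .canonical(a, TRUE)
  cb <- .canonical(b, TRUE)
  if (!identical(ca$key, cb$key))
    return(.witness(FALSE, certificate = "no label-preserving isomorphism"))
  mapping <- structure(b@vertices[cb$order], names = a@vertices[ca$order])
  if (!.verifyMapping(a, b, mapping))
    stop("internal error: canonical orders produced an invalid witness",
         call. = FALSE)
  .witness(TRUE, mapping = mapping)
}

#' Are two networks isomorphic as digraphs?
#'
#' Plain digraph isomorphism: leaf labels are erased (leaves remain
#' distinguishable as outdegree-0 vertices).  Networks equivalent under
#' \code{\link{areEquivalent}} are always isomorphic; the converse can
#' fail when labels sit below non-symmetric vertices.
#'
#' @inheritParams areEquivalent
#' @return Logical.
#' @export
areIsomorphic <- function(a, b) {
  stopifnot(is(a, "RootedDAG"), is(b, "RootedDAG"))
  if (length(a@vertices) != length(b@vertices)) return(FALSE)
  if (nrow(a@arcs) != nrow(b@arcs)) return(FALSE)
  identical(canonicalForm(a, respectLabels = FALSE),
            canonicalForm(b, respectLabels = FALSE))
}

#' Are two networks network-equivalent?
#'
#' Two networks on the same taxon set X are network-equivalent when for
#' every nonempty proper subset Y of X the induced subnets N|Y agree (are
#' equivalent).  All \code{2^|X| - 2} subsets are enumerated, by
#' decreasing size and lexicographically within a size; on failure the
#' certificate names the first failing subset.  With
#' \code{maximalOnly = TRUE} only the \code{|X|} subsets of size
#' \code{|X| - 1} are checked — a fast heuristic, not the full relation.
#'
#' @inheritParams areEquivalent
#' @param maximalOnly Check only the maximal proper subsets (heuristic).
#' @return An \code{\linkS4class{EquivalenceWitness}} (no single vertex
#'   bijection applies; the mapping slot stays empty on success).
#' @export
areNetworkEquivalent <- function(a, b, maximalOnly = FALSE) {
  stopifnot(is(a, "RootedDAG"), is(b, "RootedDAG"))
  ta <- taxa(a); tb <- taxa(b)
  if (!identical(ta, tb))
    stop("networks must share one taxon set", call. = FALSE)
  if (length(ta) < 2L)
    stop("network-equivalence needs at least 2 taxa", call. = FALSE)
  sizes <- if (maximalOnly) length(ta) - 1L else seq(length(ta) - 1L, 1L)
  for (s in sizes) {
    combos <- utils::combn(ta, s)
    for (i in seq_len(ncol(combos))) {
      y <- combos[, i]
      w <- areEquivalent(restrictNetwork(a, y), restrictNetwork(b, y))
      if (!w@verdict)
        return(.witness(FALSE, certificate = paste0(
          "subnets differ on {", paste(y, collapse = ","), "}: ",
          w@certificate)))
    }
  }
  .witness(TRUE)
}
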