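## Extended Newick (eNewick) input/output and DOT export.
##
## Dialect (fixed, documented): hybrid vertices are written label#H<k>
## with the same #H tag identifying the same vertex across occurrences;
## exactly one occurrence carries the children.  Internal vertex labels
## are omitted on output (accepted and dropped on input); no branch
## lengths (the constructions are purely topological).  A two-vertex
## network with leaf a is written "(a);".

## ---- parser ---------------------------------------------------------------

#' Read a network from eNewick text
#'
#' Parses extended Newick: hybrid tags (\code{#H1}, \code{x#H2}, ...) with
#' the same identifier are merged into a single vertex.  The merged graph
#' must satisfy the strict network invariants; violations are reported as
#' an error.
#'
#' @param text A single eNewick string (terminating \code{";"} optional),
#'   or a connection/file path via \code{file}.
#' @param file Optional path read with \code{readLines} (overrides
#'   \code{text}).
#' @return A valid \code{PhyloNetwork}.
#' @examples
#' readENewick("((a,b),c);")
#' readENewick("((a,(x)#H1),(#H1,b));")
#' @export
readENewick <- function(text, file = NULL) {
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  if (nchar(s) == 0L) stop("empty eNewick input", call. = FALSE)
  pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  nodes <- list()   # each: list(name, tag, children = integer ids)
  addNode <- function(name, tag, children) {
    nodes[[length(nodes) + 1L]] <<- list(name = name, tag = tag,
                                         children = children)
    length(nodes)
  }
  readLabel <- function() {
    start <- pos
    while (pos <= n && !(substr(s, pos, pos) %in% c("(", ")", ",", ";")))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parseSubtree <- function() {
    children <- integer(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parseSubtree())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("parse error at position ", pos, " of eNewick input",
             call. = FALSE)
      }
    }
    lab <- readLabel()
    if (length(children) == 0L && nchar(lab) == 0L)
      stop("parse error: empty leaf label at position ", pos, call. = FALSE)
    tag <- ""
    name <- lab
    if (grepl("#", lab, fixed = TRUE)) {
      parts <- strsplit(lab, "#", fixed = TRUE)[[1L]]
      name <- parts[[1L]]
      tag <- paste(parts[-1L], collapse = "#")
    }
    addNode(name, tag, children)
  }
  top <- parseSubtree()
  if (pos <= n) stop("trailing characters at position ", pos, call. = FALSE)

  ## assign vertex ids, merging hybrid tags
  tags <- vapply(nodes, `[[`, character(1L), "tag")
  ids <- character(length(nodes))
  for (i in seq_along(nodes)) {
    ids[[i]] <- if (nzchar(tags[[i]])) paste0("#", tags[[i]])
                else sprintf(".n%d", i)
  }
  arcs <- .emptyArcs()
  for (i in seq_along(nodes))
    for (ch in nodes[[i]]$children)
      arcs <- rbind(arcs, c(ids[[i]], ids[[ch]]))
  vertices <- unique(ids)
  outdeg <- table(factor(arcs[, 1L], levels = vertices))
  leaves <- vertices[outdeg == 0L]
  nm <- vapply(nodes, `[[`, character(1L), "name")
  leafLabels <- character(0)
  for (lf in leaves) {
    cand <- unique(nm[ids == lf & nzchar(nm)])
    if (length(cand) == 0L)
      stop("unlabeled leaf in eNewick input", call. = FALSE)
    if (length(cand) > 1L)
      stop("conflicting labels for one hybrid leaf: ",
           paste(cand, collapse = ", "), call. = FALSE)
    leafLabels[lf] <- cand
  }
  net <- .finishDAG(vertices, arcs, leafLabels, "PhyloNetwork")
  bad <- validateNetwork(net, strict = TRUE)
  if (length(bad))
    stop("eNewick input is not a valid network: ",
         paste(bad, collapse = "; "), call. = FALSE)
  net
}

## ---- writer ----------------------------------------------------------------

## Structure key of the sub-DAG below each vertex, used to order children
## deterministically: leaf label for leaves, sorted children keys wrapped
## in parentheses otherwise.  Identifier-independent.
.subtreeKeys <- function(net, ix) {
  topo <- .topoOrder(ix)
  keys <- character(length(ix$v))
  lab <- net@leafLabels
  for (u in rev(topo)) {
    v <- ix$v[[u]]
    if (ix$outdeg[[u]] == 0L) {
      keys[[u]] <- lab[[v]]
    } else {
      keys[[u]] <- paste0("(", paste(sort(keys[ix$out[[u]]]), collapse = ","),
                          ")")
    }
  }
  keys
}

#' Write a network as eNewick
#'
#' Deterministic serialization: the children of every vertex are emitted
#' in the order of the structure keys of the sub-DAGs below them (ties
#' keep input order; tied children are structurally interchangeable), and
#' every reticulation vertex is written once in full and referenced by its
#' \code{#H} tag elsewhere.  Serializing the same object twice yields
#' identical bytes.
#'
#' @param net A valid \code{PhyloNetwork} (or \code{RootedDAG}).
#' @return A single eNewick string ending in \code{";"}.
#' @export
writeENewick <- function(net) {
  stopifnot(is(net, "RootedDAG"))
  ix <- .graphIndex(net)
  keys <- .subtreeKeys(net, ix)
  hybrid <- ix$indeg >= 2L
  tagOf <- integer(length(ix$v))   # 0 = unnumbered
  nextTag <- 0L
  lab <- net@leafLabels
  emit <- function(u) {
    if (hybrid[[u]]) {
      if (tagOf[[u]] > 0L)
        return(paste0("#H", tagOf[[u]]))
      nextTag <<- nextTag + 1L
      tagOf[[u]] <<- nextTag
      body <- if (ix$outdeg[[u]] == 0L) lab[[ix$v[[u]]]] else {
        ch <- ix$out[[u]][order(keys[ix$out[[u]]])]
        paste0("(", paste(vapply(ch, emit, character(1L)), collapse = ","), ")")
      }
      return(paste0(body, "#H", tagOf[[u]]))
    }
    if (ix$outdeg[[u]] == 0L) return(lab[[ix$v[[u]]]])
    ch <- ix$out[[u]][order(keys[ix$out[[u]]])]
    paste0("(", paste(vapply(ch, emit, character(1L)), collapse = ","), ")")
  }
  paste0(emit(ix$root), ";")
}

#' Export a network in DOT format
#'
#' One vertex per line, arcs as \code{tail -> head}; leaves are boxed and
#' labeled with their taxa.  For visual inspection with Graphviz.
#'
#' @param net A \code{RootedDAG} or \code{PhyloNetwork}.
#' @param file Optional path; when \code{NULL} the DOT text is returned.
#' @return The DOT text, invisibly when written to a file.
#' @export
writeDOT <- function(net, file = NULL) {
  stopifnot(is(net, "RootedDAG"))
  lab <- net@leafLabels
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph network {",
             "  rankdir=TB;")
  for (v in net@vertices) {
    if (v %in% names(lab))
      lines <- c(lines, sprintf("  %s [shape=box,label=%s];", q(v), q(lab[[v]])))
    else
      lines <- c(lines, sprintf("  %s [shape=point];", q(v)))
  }
  for (i in seq_len(nrow(net@arcs)))
    lines <- c(lines, sprintf("  %s -> %s;", q(net@arcs[i, 1L]),
                              q(net@arcs[i, 2L])))
  lines <- c(lines, "}")
  text <- paste(lines, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file)
  invisible(text)
}
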