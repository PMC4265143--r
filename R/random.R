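## Seeded random-network fixture generator.
##
## Grows a random binary tree by repeated arc subdivision, then adds
## reticulations by subdividing two arcs and joining the new vertices,
## rejecting draws that would create a directed cycle.  By construction
## the result is binary, free of degenerate vertices and parallel arcs,
## and recoverable (the root keeps both original children, and every tree
## path survives).

#' Generate a random binary network
#'
#' Deterministic given the seed.  The RNG state of the session is left
#' untouched.
#'
#' @param nLeaves Number of leaves, at least 1 (at least 2 when
#'   reticulations are requested).
#' @param nReticulations Number of indegree-2 vertices to insert.
#' @param seed Integer seed; required, so fixtures are reproducible.
#' @param taxonNames Leaf labels (default \code{t1..tk}).
#' @return A valid, recoverable, binary \code{PhyloNetwork}.
#' @examples
#' randomNetwork(4, 2, seed = 1)
#' @export
randomNetwork <- function(nLeaves, nReticulations, seed,
                          taxonNames = paste0("t", seq_len(nLeaves))) {
  if (nLeaves < 1L) stop("nLeaves must be at least 1", call. = FALSE)
  if (nReticulations < 0L) stop("nReticulations must be nonnegative",
                                call. = FALSE)
  if (nLeaves == 1L && nReticulations > 0L)
    stop("reticulations need at least 2 leaves", call. = FALSE)
  stopifnot(length(taxonNames) == nLeaves, !anyDuplicated(taxonNames))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)

  nextId <- 0L
  fresh <- function(prefix) {
    nextId <<- nextId + 1L
    paste0(prefix, nextId)
  }
  if (nLeaves == 1L) {
    net <- .newDAG(c("r", "L1"), cbind(tail = "r", head = "L1"), "r",
                   structure(taxonNames, names = "L1"), "PhyloNetwork")
    return(net)
  }
  ## random binary tree by arc subdivision
  tails <- c("r", "r")
  heads <- c("L1", "L2")
  for (k in 3:max(3L, nLeaves)) {
    if (k > nLeaves) break
    a <- sample.int(length(tails), 1L)
    mid <- fresh("v")
    leafId <- paste0("L", k)
    tails <- c(tails[-a], tails[a], mid, mid)
    heads <- c(heads[-a], mid, heads[a], leafId)
  }
  ## reticulations by double subdivision
  canReach <- function(from, to) {
    ## DFS on current arc list
    stack <- from
    seen <- from
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (w in heads[tails == u]) if (!(w %in% seen)) {
        if (w == to) return(TRUE)
        seen <- c(seen, w); stack <- c(stack, w)
      }
    }
    from == to
  }
  added <- 0L
  attempts <- 0L
  while (added < nReticulations) {
    attempts <- attempts + 1L
    if (attempts > 1000L * (nReticulations + 1L))
      stop("infeasible leaf/reticulation combination", call. = FALSE)
    pick <- sample.int(length(tails), 2L)
    e1 <- pick[[1L]]; e2 <- pick[[2L]]
    ## new arc a -> b with a on e1 and b on e2; acyclic iff no path from
    ## the head of e2 back to the tail of e1
    if (canReach(heads[e2], tails[e1])) next
    a <- fresh("s"); b <- fresh("h")
    u1 <- tails[e1]; v1 <- heads[e1]
    u2 <- tails[e2]; v2 <- heads[e2]
    keep <- setdiff(seq_along(tails), c(e1, e2))
    tails <- c(tails[keep], u1, a, u2, b, a)
    heads <- c(heads[keep], a, v1, b, v2, b)
    added <- added + 1L
  }
  leafIds <- paste0("L", seq_len(nLeaves))
  net <- .newDAG(unique(c(tails, heads)), cbind(tail = tails, head = heads),
                 "r", structure(taxonNames, names = leafIds), "PhyloNetwork")
  bad <- validateNetwork(net, strict = TRUE)
  if (length(bad))
    stop("internal error: generator produced an invalid network: ",
         paste(bad, collapse = "; "), call. = FALSE)
  net
}
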