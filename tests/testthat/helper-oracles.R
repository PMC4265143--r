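# Independent oracles and fixture builders used across the suite.
# The oracles deliberately use different algorithms (exhaustive path
# enumeration, exhaustive bijection search, igraph VF2) from the package
# implementations they guard.

# Lowest stable ancestor by brute force: enumerate every root-to-target
# directed path, intersect their vertex sets, return the unique lowest
# (non-leaf) element.  Exponential; fixtures stay small.
oracleLsa <- function(net, taxaSubset) {
  a <- arcs(net)
  lab <- leafLabels(net)
  targets <- names(lab)[match(taxaSubset, lab)]
  childrenOf <- function(v) a[a[, 1L] == v, 2L]
  pathsTo <- function(target) {
    acc <- list()
    walk <- function(v, path) {
      path <- c(path, v)
      if (v == target) { acc[[length(acc) + 1L]] <<- path; return() }
      for (w in childrenOf(v)) walk(w, path)
    }
    walk(networkRoot(net), character(0))
    acc
  }
  common <- NULL
  for (t in targets)
    for (p in pathsTo(t))
      common <- if (is.null(common)) p else intersect(common, p)
  common <- setdiff(common, names(lab))
  reachSet <- function(v) {
    seen <- character(0); stack <- v
    while (length(stack)) {
      u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (w in childrenOf(u)) if (!(w %in% seen)) {
        seen <- c(seen, w); stack <- c(stack, w)
      }
    }
    seen
  }
  for (u in common)
    if (!any(common %in% reachSet(u))) return(u)
  stop("oracle: no lowest element found")
}

# All permutations of a vector (n! rows; callers keep n small).
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in allPerms(v[-i]))
      out[[length(out) + 1L]] <- c(v[[i]], rest)
  out
}

# Exhaustive-bijection equivalence oracle: leaves are pinned by label,
# every bijection of the non-leaf vertices is tried.
oracleEquivalent <- function(a, b) {
  la <- leafLabels(a); lb <- leafLabels(b)
  if (!setequal(unname(la), unname(lb))) return(FALSE)
  intA <- setdiff(vertexIds(a), names(la))
  intB <- setdiff(vertexIds(b), names(lb))
  if (length(intA) != length(intB)) return(FALSE)
  if (nrow(arcs(a)) != nrow(arcs(b))) return(FALSE)
  arcKey <- function(m) sort(paste(m[, 1L], m[, 2L], sep = "\r"))
  keyB <- arcKey(arcs(b))
  leafMap <- structure(names(lb)[match(unname(la), unname(lb))],
                       names = names(la))
  aa <- arcs(a)
  for (perm in allPerms(intB)) {
    map <- c(leafMap, structure(perm, names = intA))
    if (identical(arcKey(cbind(unname(map[aa[, 1L]]),
                               unname(map[aa[, 2L]]))), keyB))
      return(TRUE)
  }
  FALSE
}

# igraph VF2 oracle for label-preserving isomorphism.
igraphEquivalent <- function(a, b) {
  la <- leafLabels(a); lb <- leafLabels(b)
  if (!setequal(unname(la), unname(lb))) return(FALSE)
  pal <- sort(unname(la))
  colorOf <- function(net) {
    lab <- leafLabels(net)
    v <- vertexIds(net)
    col <- integer(length(v))
    li <- match(names(lab), v)
    col[li] <- match(unname(lab), pal)
    col
  }
  ga <- igraph::graph_from_edgelist(arcs(a), directed = TRUE)
  gb <- igraph::graph_from_edgelist(arcs(b), directed = TRUE)
  ca <- colorOf(a)[match(igraph::V(ga)$name, vertexIds(a))]
  cb <- colorOf(b)[match(igraph::V(gb)$name, vertexIds(b))]
  igraph::is_isomorphic_to(ga, gb, method = "vf2",
                           vertex.color1 = ca, vertex.color2 = cb)
}

# An equivalent copy with renamed internal vertices and shuffled arc rows.
shuffledCopy <- function(net, seed) {
  set.seed(seed)
  lab <- leafLabels(net)
  v <- vertexIds(net)
  internal <- setdiff(v, names(lab))
  map <- structure(v, names = v)
  map[internal] <- paste0("z", sample(length(internal)))
  a <- arcs(net)
  a2 <- cbind(tail = unname(map[a[, 1L]]), head = unname(map[a[, 2L]]))
  a2 <- a2[sample(nrow(a2)), , drop = FALSE]
  cls <- class(net)
  new(cls, vertices = unname(map[v])[sample(length(v))], arcs = a2,
      root = unname(map[[networkRoot(net)]]), leafLabels = structure(
        unname(lab), names = unname(map[names(lab)])))
}

# A RootedDAG with degenerate chains: subdivide random arcs of a random
# binary network.
degenerateFixture <- function(seed, nLeaves = 4, nRet = 1, nSubdiv = 4) {
  net <- randomNetwork(nLeaves, nRet, seed = seed)
  set.seed(seed + 1000L)
  a <- arcs(net)
  for (k in seq_len(nSubdiv)) {
    i <- sample.int(nrow(a), 1L)
    mid <- paste0("d", k)
    a <- rbind(a[-i, , drop = FALSE],
               c(a[i, 1L], mid), c(mid, a[i, 2L]))
  }
  rootedDAG(a, leafLabels = leafLabels(net))
}

# Small named fixture networks (all at most 12 vertices).
fixtureNetworks <- function() {
  list(
    triplet = readENewick("((a,b),c);"),
    fourTreeBalanced = readENewick("((a,b),(c,d));"),
    fourTreeCaterpillar = readENewick("(((a,b),c),d);"),
    oneRet = readENewick("((a,(x)#H1),(#H1,b));"),
    twoVertex = readENewick("(a);"),
    funnel = readENewick("(((a,b),(c,(d)#H1)),#H1);")
  )
}
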