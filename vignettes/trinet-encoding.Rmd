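---
title: "Why subnets do not encode rooted phylogenetic networks: models, constructions, and verification"
author: "trinetlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why subnets do not encode rooted phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trinetlab)
```

## The scientific question

Rooted phylogenetic networks extend evolutionary trees to reticulate
histories: they are rooted directed acyclic graphs whose leaves are
bijectively labeled by taxa and whose indegree-≥2 vertices (reticulations)
model events such as hybridization and recombination.  Many practical
reconstruction methods assemble a large network from small inferred
building blocks — triplets, clusters, trees, or their network analogue,
the *trinet* (the induced subnetwork on three leaves).  For trees this
strategy is sound because a rooted binary tree is determined by its
triplets.  The question this package addresses computationally is whether
the analogous statement holds for networks: **is a rooted phylogenetic
network determined by the subnetworks it induces on proper subsets of its
leaves?**

The answer is no.  The package constructs, for every leaf count $n \ge 3$,
two pairs of witnesses:

* a **nonbinary pair** $N_1, N_2$, and
* a **binary pair** $H_1, H_2$,

such that within each pair the two networks are *not* equivalent, yet
induce *equivalent* subnets on every nonempty proper leaf subset — in
particular they have identical trinet sets — and (for the binary pair)
also display identical sets of evolutionary trees.  Everything needed to
state and machine-check these claims (induced subnets, equivalence
testing, displayed trees) is implemented here, and the claims are verified
exhaustively at small $n$.

## The model

**Networks.** A digraph is *valid* here when it is acyclic, has a unique
indegree-0 vertex (the root) from which every vertex is reachable, and has
its outdegree-0 vertices injectively labeled by taxa.  A *phylogenetic
network* additionally has no parallel arcs, no *degenerate* vertices
(outdegree 1 with indegree ≤ 1, in a graph of ≥ 3 vertices), and root
outdegree ≥ 2 unless it is the trivial two-vertex network.  The class
`RootedDAG` carries the relaxed object (parallel arcs and degenerate
vertices arise transiently); `PhyloNetwork` carries the strict one.  A
vertex is an ancestor of itself, by convention.

**Induced subnets.** For a nonempty leaf subset $Y$, the *lowest stable
ancestor* $\mathrm{lsa}(Y)$ is the lowest non-leaf vertex lying on every
root-to-$y$ path for every $y \in Y$.  The subnet $N|Y$ deletes every
vertex not on a path from $\mathrm{lsa}(Y)$ to $Y$, then repeatedly
suppresses degenerate vertices and merges parallel arcs.  $N|X = N$
exactly for *recoverable* networks ($\mathrm{lsa}(X) = \rho$), and every
subnet is itself recoverable.

**Equivalence.** Two networks on the same taxa are *equivalent* when a
digraph isomorphism between them fixes every leaf label, and
*network-equivalent* when their subnets on every nonempty proper leaf
subset are equivalent.  Equivalence always implies network-equivalence;
the constructions show the converse fails.

## The two constructions

Both are fueled by a small calculus on binary sequences (strings over
{0,1}, 1-based indexing).  Write $B_n^1$ and $B_n^2$ for the odd- and
even-weight length-$n$ sequences, with the all-zero sequence $0_n$
excluded from both, so $|B_n^1| = 2^{n-1}$ and $|B_n^2| = 2^{n-1}-1$.

**Nonbinary pair.** The layered DAG $D_i$ ($i = 1,2$) has a root over the
class $B_n^i$, a middle layer $y_1..y_n$, and leaves $x_1..x_n$, with an
arc from sequence $u$ to $y_j$ exactly when letter $j$ of $u$ is 1; each
$y_j$ has indegree $2^{n-2}$.  Suppressing degenerate vertices (for
$i = 1$, the weight-1 sequences) gives $N_i$.  The pair is inequivalent
for a degree reason: exactly one of the two classes contains the all-ones
sequence, so exactly one network has a child of the root with outdegree
$n$.  Deleting one leaf $x_k$, however, makes the classes
interchangeable: flipping letter $k$ is a bijection from
$B_n^1 \setminus \{w_k\}$ onto $B_n^2$ (where $w_k$ is the unit sequence
at $k$), and extending it by the identity on all other vertices is an
explicit equivalence between the subnets.  The package checks both the
explicit flip witness and, independently, the generic equivalence test on
every one of the $2^n - 2$ proper subsets.

**Binary pair.** Three local rewrites turn $D_i$ into a binary network
with the same behavior: (1) the root star is replaced by the restriction
of the binary prefix trie $P_n$ (vertices: all sequences of length ≤ $n$;
arcs: maximal-precursor pairs, i.e. drop-last-letter) to $B_n^i$; (2)
each star into $y_j$ is replaced by a fresh-vertex copy of the
arc-reversed trie restricted to the class members whose letter $j$ is 1,
with sink $y_j$; (3) each remaining sequence vertex with more than two
children is replaced by the caterpillar tree on its support, its leaf for
position $t$ wired to the child leading to $y_t$.  Suppression then gives
the binary, recoverable network $H_i$.  Every stage is exposed
(`buildH(i, n, stage = "D1" | "D2" | "D3" | "H")`) for inspection.

```{r headline}
n1 <- buildN(1, 3); n2 <- buildN(2, 3)
verdict(areEquivalent(n1, n2))
verdict(areNetworkEquivalent(n1, n2))
h1 <- buildH(1, 4); h2 <- buildH(2, 4)
c(binary = isBinaryNetwork(h1), distinct = !verdict(areEquivalent(h1, h2)),
  netEq = verdict(areNetworkEquivalent(h1, h2)),
  sameTrees = treeSetEqual(displayedTrees(h1), displayedTrees(h2)))
```

The *level* of these binary networks — the maximum reticulation count in a
biconnected component — is $(2^{n-2}-1)\,n$ (3 at $n=3$, 12 at $n=4$), so
the counterexamples are highly reticulate relative to their leaf number;
low-level networks (level ≤ 2, tree-child) are known to be encoded by
their trinets, and the constructions do not contradict that.

## Algorithmic and design choices

**Lowest stable ancestor.**  Computed from dominator sets: processing
vertices in topological order, $\mathrm{Dom}(v) = \{v\} \cup
\bigcap_{p \in \mathrm{parents}(v)} \mathrm{Dom}(p)$.  The common
dominators of the target leaves form a chain; the answer is its lowest
non-leaf element.  A single dataflow pass suffices on a DAG, and an
exponential path-enumeration oracle validates the implementation on all
small fixtures in the test suite.

**Suppression.**  Degenerate chains are contracted in batches, parallel
arcs merged as they arise, iterating to a fixpoint; an outdegree-1 root is
deleted and its child promoted (in a connected input of ≥ 3 vertices that
child is never a leaf).  The fixpoint is order-independent; the suite
checks confluence against a one-at-a-time randomized order
(`suppressDegenerate(g, order = "random")`) on 100+ random instances.

**Equivalence decision.**  A canonical form: iterative color refinement
seeded with leaf labels (internal vertices start uniform), refining on the
multisets of child and parent colors; when color classes remain ambiguous
— reticulation symmetry — individualization-refinement branches over the
first ambiguous class and keeps the lexicographically least serialization.
Two networks are equivalent iff their canonical strings match, and the
canonical orders yield an explicit vertex bijection which is re-verified
arc-by-arc before being returned (the witness is checked, never trusted).
General DAG isomorphism has no known polynomial algorithm; instances here
are tiny, and the suite referees the procedure against an
exhaustive-bijection search and igraph's VF2.  Plain digraph isomorphism
(`areIsomorphic`) is the same machinery with labels erased.

**Network-equivalence.**  All $2^{|X|}-2$ nonempty proper subsets are
enumerated (decreasing size, lexicographic within a size), not only the
maximal ones, because composing restrictions is not part of the subnet
contract; `maximalOnly = TRUE` exists as a labeled heuristic.  Singletons
and pairs are checked too even though subnets on them are nearly always
equal — fidelity over speed at these sizes.  On failure the first failing
subset is named in the certificate, reproducible via the `compare` CLI
command.

**Displayed trees.**  A switching keeps exactly one in-arc per
reticulation; vertices cut off from the root, or left without
descendants, are removed, and the remainder is suppressed.  This
switching-based definition is the standard one in the displayed-tree
literature and is adopted here as a convention; with a single root and
reachability cleanup no leaf is ever lost.  Switchings are enumerated
exhaustively — at $n = 4$ the binary pair has $2^{12} = 4096$ switchings
per network, enumerated in seconds on integer-indexed arc arrays — since
exact set equality, not sampling, is the claim being checked.

**eNewick dialect.**  Hybrid vertices are written `label#Hk`, one
occurrence in full, others by reference; internal labels omitted; no
branch lengths (the constructions are topological).  Children are ordered
by the structure key of the sub-DAG below them, so serialization is
byte-deterministic for a given object.  The dialect is this package's
choice (the constructions themselves never prescribe one) and round-trips
to equivalence on every construction and random fixture.

**Maximal precursors.**  In the pool of all sequences of length ≤ $n$,
every sequence shorter than $n$ is the maximal precursor of exactly its
two one-letter extensions, and length-$n$ sequences are precursors of
nothing; `maximalPrecursor` returns the longest proper prefix present in
the pool, which is the unique consistent reading of that definition.

**Random generator.**  `randomNetwork(nLeaves, nReticulations, seed)`
grows a random binary tree by arc subdivision, then repeatedly subdivides
two arcs and joins the new vertices, rejecting draws that would close a
directed cycle.  The result is always valid, binary and recoverable, and
identical seeds give identical networks.  Defaults in the test suite use
3–7 leaves and 0–3 reticulations: large enough to exercise reticulation
symmetry and restriction nontrivially, small enough for the factorial
oracles to referee every verdict.

## What the verification does and does not show

The claims hold as theorems for every $n \ge 3$; machine verification is
necessarily truncated.  The suite and the acceptance script check the
nonbinary pair at $n = 3..5$ (6, 14, 30 proper subsets), the binary pair
at $n = 3..4$, displayed-tree equality at $n = 3..4$, and the level
formula at $n = 3..4$; the `verify` CLI command records the bounds it ran
in its report and refuses larger $n$ without `--force` (the cost is
doubly exponential: $2^n$ subsets over networks with $\Theta(2^n)$
vertices).  Synthetic fixtures are binary, seed-stable and of desk scale;
they do not emulate features of real reticulate data such as branch
lengths, sampling noise, or level-bounded structure, so passing tests
certify the combinatorial claims and the correctness of the operations,
not anything about inference on empirical data.

## Known limitations

* Equivalence testing is worst-case exponential (individualization);
  fine for the families built here, not intended for hundreds of
  reticulations.
* `areNetworkEquivalent` enumerates all proper subsets; beyond roughly
  $|X| = 12$ this is impractical by design.
* Displayed-tree enumeration is exhaustive over switchings; softwired
  cluster semantics and tree-containment queries are out of scope.
* Unrooted and data-display (split) networks are out of scope throughout.
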