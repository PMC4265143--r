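# trinetlab

Subnets, trinets, and equivalence of rooted phylogenetic networks — with
constructions showing that induced subnetworks do **not** encode networks.

## The problem

Rooted phylogenetic networks generalize evolutionary trees to reticulate
histories: rooted DAGs whose leaves carry taxon labels and whose
indegree-≥2 vertices model hybridization or recombination.  Network
reconstruction methods often assemble a network from small building
blocks — triplets, clusters, trees, or *trinets* (the induced
subnetworks on three leaves).  For trees this is sound: a rooted binary
tree is determined by its triplets.  For networks it is not, and this
package makes that failure concrete and machine-checkable.

For every taxon count *n* ≥ 3 it constructs two pairs of networks on
*X* = {x₁,…,xₙ}:

* a **nonbinary pair** N₁, N₂ built from the odd- and even-weight binary
  sequences of length *n*, and
* a **binary pair** H₁, H₂ obtained from the first pair by three local
  rewrites (prefix-trie restriction, arc-reversed trie copies,
  caterpillar expansion) followed by suppression of degenerate vertices,

such that within each pair the networks are **not equivalent** (no
isomorphism fixing the leaves) yet **network-equivalent**: for every
nonempty proper subset *Y* ⊂ *X* the induced subnets N|Y — formed by
cutting at the lowest stable ancestor lsa(Y) and suppressing degenerate
vertices — are equivalent.  In particular both members induce identical
trinet sets, and the binary pair also displays identical sets of
evolutionary trees.  So even complete knowledge of all proper induced
subnetworks (plus all displayed trees) cannot determine the network.

The package is audience-directed at phylogenetics researchers and method
developers: it provides the underlying machinery (induced subnets via
lowest stable ancestors, canonical forms and equivalence witnesses,
displayed-tree enumeration, eNewick I/O, a seeded random-network
generator) as reusable S4 infrastructure, alongside the constructions and
a verification driver.

## Worked example

```r
library(trinetlab)

n1 <- buildN(1, 4)   # odd-weight variant, 4 taxa
n2 <- buildN(2, 4)   # even-weight variant
n1
#> PhyloNetwork: 13 vertices, 24 arcs, 4 reticulation(s)
#>   root: rho
#>   taxa (4): x1, x2, x3, x4

areEquivalent(n1, n2)
#> EquivalenceWitness: verdict FALSE
#>   certificate: vertex counts differ (13 vs 16)

areNetworkEquivalent(n1, n2)   # all 2^4 - 2 = 14 proper subsets agree
#> EquivalenceWitness: verdict TRUE
```

The two networks are distinguishable as whole objects (here already by a
vertex count; at equal counts a degree certificate or the canonical form
decides), yet every proper restriction is pairwise equivalent — the
building blocks are identical.  The binary pair behaves the same way and
is maximally reticulate for its size:

```r
h1 <- buildH(1, 4); h2 <- buildH(2, 4)
networkLevel(h1)               # (2^(n-2) - 1) * n at n = 4
#> [1] 12
treeSetEqual(displayedTrees(h1), displayedTrees(h2))
#> [1] TRUE
displayedTrees(h1)
#> TreeSet of 15 tree(s)
#>   (((x1,x2),x3),x4)
#>   (((x1,x2),x4),x3)
#>   ...
```

Both networks display all 15 rooted binary tree shapes on four taxa —
identical tree sets, identical trinets, different networks.  Networks can
be serialized and exchanged in extended Newick:

```r
writeENewick(buildH(1, 3))
#> "(((((x2)#H1,(x3)#H2),(x1)#H3),#H3),(#H1,#H2));"
```

## Command-line interface

`exec/trinetlab` exposes the same operations from a shell:

```sh
exec/trinetlab construct --family binary --variant 1 --n 4 --out h1.nwk
exec/trinetlab compare --mode trinets h1.nwk h2.nwk     # exit 0: all equal
exec/trinetlab verify --family both --n-min 3 --n-max 4 # JSON report
exec/trinetlab random --leaves 6 --reticulations 2 --seed 7
```

Exit codes: 0 success/equivalent, 1 verified difference, 2 input error.

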