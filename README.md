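# rtcnspace

Tools for comparing **ranked tree-child networks (RTCNs)** — rooted
phylogenetic networks whose speciation and hybridization events are ordered
in time — and their edge-weighted counterparts, **equidistant tree-child
networks (ETCNs)**.

Phylogenetic inference under reticulate evolution (hybridization, lateral
gene transfer) produces networks rather than trees, and downstream analyses
need principled ways to measure how different two such networks are.  For
ranked *trees* there is a mature toolkit (ranked nearest-neighbor
interchange distances, the ultrametric tree space); this package implements
the generalization of that toolkit to tree-child networks, for
methodologists who want exact, brute-force-verifiable reference
implementations at desk scale.

## The encoding

Everything rests on a combinatorial encoding.  A binary RTCN on a taxon set
*X* (|X| = n) is equivalent to a *maximal chain* of cluster systems

    {{x} : x ∈ X} = C₁ ⊢ C₂ ⊢ … ⊢ Cₙ = {X}

where each step is either a **join** (a branching event),

    C' = (C − {A, B}) ∪ {A ∪ B},

or a **reticulation** (a hybridization event; B is the hybrid cluster),

    C' = (C − {A, B, C}) ∪ {A ∪ B, B ∪ C}.

The i-th system lists the clusters visible at time level i, and the chain
determines the network uniquely because every cluster in a chain system
contains a *private* taxon found in no other cluster of that system.

On top of the encoding the package provides:

* **Discrete distances** between binary RTCNs: a ranked Robinson–Foulds
  analogue (symmetric difference of the chains as system sets) and the
  exact rNNI\* distance (shortest sequence of single-position chain
  replacements), computed by breadth-first search, plus the constructive
  transformation of any network chain into a ranked-tree chain
  (`detangle_to_tree()`).
* **The graded poset 𝔗(X)** of all chain-realizable cluster systems,
  with membership, comparability, grading `n − |C|`, and exhaustive chain
  enumeration for small n.
* **General (non-maximal) chains** and their canonical non-binary ranked
  networks, via the three-phase frontier construction.
* **The CAT(0) orthant space 𝔖(X) of ETCNs**: points are sparse
  non-negative maps from cluster systems to rank differences whose support
  forms a chain; the geodesic distance is computed exactly by successive
  path-space refinement with min-cut splitting, where two coordinate axes
  are compatible exactly when their systems are comparable in the poset.
* **Serialization**: a canonical JSON interchange format for chains,
  networks and points, and extended-Newick export for networks.
* **Simulation**: seeded random chains and random ETCN points, and the
  bundled worked examples (`worked_examples()`).

## Worked example

```r
library(rtcnspace)
fx <- worked_examples()

# a maximal chain on {a,b,c,d} with one reticulation step
fx$net4_chain
#> Chain on 4 taxa (a,b,c,d), length 4:
#>   [1] {a}{b}{c}{d}
#>   [2] {a,b}{c}{d}
#>   [3] {a,b,c}{c,d}
#>   [4] {a,b,c,d}

net <- decode_binary(fx$net4_chain)
to_enewick(net)
#> [1] "(((a[r=1],b[r=1])[r=2],(c[r=1])#H1[r=3])[r=3],(#H1[r=3],d[r=1])[r=3])[r=4];"
```

The decoded network has one hybrid vertex (`#H1`, above taxon `c`) created
at rank 3; `encode(net)` returns the chain unchanged.

```r
# two ranked trees on five taxa, one rNNI apart
pr <- fx$tree_pair5
rf_distance(pr[[1]], pr[[2]])
#> [1] 2
bfs_distance(pr[[1]], pr[[2]], "star")$distance
#> [1] 1
```

The chains differ in exactly one system, so the symmetric-difference
distance is 2 and the move distance is 1.

```r
# an ETCN: a weighted network point with rank differences 1.3, 2.0, 1.9, 0.8
p <- fx$etcn_point5
pn <- point_to_network(p)          # equidistant weighted network
p2 <- point_from_network(pn$network, pn$weights)
p2$values[["{a,b}{b,c}{d}{e}"]]
#> [1] 2
geodesic_distance(p, make_point(caterpillar_chain(letters[1:5]), rep(1, 4)))$distance
#> [1] 4.554119
```

Every root-to-leaf path in `pn$network` sums to 1.3 + 2.0 + 1.9 + 0.8 = 6,
and the round trip recovers every rank difference, e.g. 2.0 at the system
`{{a,b},{b,c},{d},{e}}`.

A command-line wrapper is installed as `exec/rtcn`
(`rtcn --help` lists the subcommands: encode, decode, build, validate,
simulate, dist-rf, dist-rnni, dist-geodesic, enumerate, fixtures).

## Scope

Exact algorithms at desk scale: poset queries and BFS distances are
exponential in the worst case (the complexity of the rNNI\* distance is an
open problem) and are capped by default at n = 6 for enumeration and
move-graph search.  Fréchet means, tangent PCA and confidence sets on the
orthant space are out of scope, as are unranked tree-child networks and
parsing third-party extended Newick.
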