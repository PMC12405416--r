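---
title: "Chains, moves and geodesics for ranked tree-child networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chains, moves and geodesics for ranked tree-child networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtcnspace)
```

## The model

A binary ranked tree-child network (RTCN) on a taxon set $X$ with
$n = |X| \ge 2$ is a rooted binary DAG with leaves labeled by $X$ in which
(i) every interior vertex has at least one child that is a tree vertex
(in-degree $\le 1$), and (ii) vertices carry ranks in $\{1, \dots, n\}$
that never increase along arcs, with equality across an arc exactly when
the head is a hybrid vertex.  The ranks order the speciation and
hybridization events along a time line, which is what distinguishes these
networks from plain tree-child networks and what makes them the natural
network analogue of ranked genealogies.

`rtcnspace` never manipulates such networks directly as its primary data
structure.  Instead it works with their *chain encoding*: a binary RTCN is
equivalent to a maximal chain of cluster systems
$\{\{x\}\} = \mathcal{C}_1 \vdash \dots \vdash \mathcal{C}_n = \{X\}$,
where each step replaces either two clusters by their union (a *join*,
mirroring a branching) or three clusters $A, B, C$ by the two unions
$A \cup B$ and $B \cup C$ (a *reticulation*, with $B$ the hybrid cluster).
The $i$-th system is exactly the set of hard-wired clusters visible at
rank level $i$ of the network.  Decoding is unambiguous because every
cluster of a chain system contains a *private* taxon appearing in no other
cluster of that system; `decode_binary()` uses those private taxa to
identify the participating frontier vertices at each step, and `encode()`
reads the systems back off the arcs spanning each rank level.  The
round-trip identity is tested exhaustively for all 108 chains at
$n = 4$ and on random chains at $n \in \{5,6,7\}$.

One consequence of the private-taxon property worth recording: a single
chain step can never admit both a join and a reticulation decomposition.
A reticulation whose net effect removed two clusters and added one would
need either $B \subseteq A$ (leaving $B$ without a private taxon) or a
collision between a created union and a surviving cluster (which the
operations reject).  The validator still reports a `"both"` tag
defensively, but on chain systems the step tags are well defined, and the
package relies on this when counting reticulation steps.

Operations whose set unions would collapse more than one cluster per step
(e.g. $A \cup B$ coinciding with a remaining cluster) are rejected with a
"cluster collision" error: such applications cannot occur inside chains,
where system sizes decrease by exactly one, and silently accepting them
would break the size grading.

## The poset and its queries

$\mathfrak{T}(X)$ is the set of all cluster systems occurring in some
maximal chain, ordered by co-occurrence: $\mathcal{C} \preceq \mathcal{C}'$
when some maximal chain contains both, in that order.  The poset is bounded
by the singleton partition and $\{X\}$ and graded by $n - |\mathcal{C}|$.

No polynomial-time membership characterization is assumed; `is_member()`
and `precedes()` are decided by breadth-first search over the successor
relation, which doubles as an unimpeachable oracle at the problem sizes the
package targets.  Three observations make the search fast enough for the
worked examples (up to $n = 8$):

* every cluster of a system below a target $\mathcal{T}$ in a chain is
  contained in some cluster of $\mathcal{T}$, so candidate moves that
  create a cluster fitting inside no target cluster are pruned;
* both step types only ever combine clusters fitting inside *overlapping*
  target clusters, so the search factorizes over the connected components
  of the target's cluster-overlap graph, and a component whose target is a
  single cluster is always reachable by repeated joins;
* systems are hashed by a canonical string key (clusters as sorted label
  vectors, systems sorted by minimum label, size, then lexicographically),
  and all reachability and comparability answers are memoized for the
  session.

Internally the search runs on integer bitmasks (one bit per taxon), which
caps supported taxon sets at 30 labels — far beyond the sizes at which
exhaustive search is meaningful anyway.  The partial-order axioms,
gradedness, boundedness and the flag property (pairwise comparable systems
sort into a chain by grade) are tested exhaustively over all members at
$n = 4$; the flag property is what later justifies treating pairwise
compatibility as joint compatibility in the orthant space.

Enumeration of maximal chains is exact and lexicographic, with
$\prod_{k=3}^{n}\bigl(\binom{k}{2} + 3\binom{k}{3}\bigr)$ chains at size
$n$ (108 at $n = 4$, 4320 at $n = 5$); the default cap of $n \le 6$ keeps
accidental calls from materializing the ~400k chains at $n = 6$, and a
streaming callback avoids storing them when enumeration at the cap is
really wanted.

## General chains and non-binary networks

Dropping intermediate systems gives general chains
($2 \le t \le n$ pairwise distinct systems, consecutive ones comparable).
`build_network()` realizes each chain as its canonical ranked tree-child
network by the three-phase frontier construction: at step $i$, frontier
vertices whose clusters have equal $H$-sets
($H(A) = \{B \in \mathcal{C}_i : A \subseteq B\}$) are identified, each
frontier vertex with a singleton $H$-set contained in a larger one sends an
arc into the latter's vertex (creating hybrids), and a stem is added above
every frontier vertex of out-degree $\ge 2$.  For maximal chains this
reproduces `decode_binary()` exactly (tested by graph isomorphism on
canonical vertex signatures), and `encode(build_network(chain))` is the
identity on every chain the suite generates.

A design point inherited from the construction: a non-maximal chain is
represented by *one* canonical network.  Other ranked tree-child networks
can represent the same chain (already at $n = 4$, for the chain through
$\{\{a,b,c\},\{b,c,d\}\}$); those alternatives are deliberately out of
scope, since without a canonical representative the chain no longer
determines the network.  For that example chain the construction merges
the two frontier vertices of $\{b\}$ and $\{c\}$ (equal $H$-sets) into a
single hybrid vertex with in-degree and out-degree two — one hybrid, not
two, which is also what the hybrid-count test asserts.

## Moves and discrete distances

An rNNI\* move replaces exactly one interior system of a maximal chain by
another system sandwiched between its neighbors; restricted to ranked-tree
(partition-only) chains this is the classical ranked nearest-neighbor
interchange.  `rf_distance()` is the symmetric difference of two chains as
system sets — a ranked analogue of Robinson–Foulds that is a metric,
even-valued and bounded by $2(n-2)$ (endpoints always coincide).

`bfs_distance()` computes exact move distances by breadth-first search
over the move graph, with memoized neighborhoods.  Exactness matters more
than speed here: the complexity of the rNNI\* distance is open, so search
is the only safe reference; the default cap $n \le 6$ bounds the state
space (the set of all maximal chains).  Connectivity of the move graph is
verified exhaustively at $n = 3$ (6 chains) and $n = 4$ (108 chains), and
on ranked-tree pairs at $n = 4$ the network-move distance never exceeds
the tree-move distance (whether the two are always equal is open;
the suite counts strict cases rather than asserting either way).

`detangle_to_tree()` is the constructive half of connectivity: while a
reticulation step remains, take the last one, restrict the tail of the
chain to one private representative per cluster (ties broken by smallest
label), walk the restricted ranked tree to a caterpillar pairing the two
representatives of the reticulation's unions (inner walk found by
tree-move BFS — correct if exponential in the worst case; a polynomial
rNNI router could be swapped in here), lift each restricted move back, and
finally replace the reticulated position by the corresponding join.  Each
round removes exactly one reticulation step; the output is a valid move
sequence and upper-bounds the BFS distance, both tested over all 108
chains at $n = 4$.

## The orthant space of equidistant networks

An equidistant tree-child network is an RTCN with non-negative arc weights
under which all root-to-leaf paths have equal length and equally ranked
vertices sit at equal depth.  Such a weighting is the same thing as a
non-negative *rank difference* per chain position, so a weighted network
is a point $\omega$ mapping cluster systems to non-negative reals whose
support (plus the two endpoints) forms a chain.  `point_to_network()` and
`point_from_network()` implement the two directions, the latter validating
path-independence of depths, equal leaf depth and rank consistency at
tolerance $10^{-9}$ before reading the rank differences off the depth
levels.  Zero coordinates are genuine boundary points: skipped systems
produce the (possibly non-binary) canonical network of the support chain,
and the all-zero origin is valid.

Each maximal chain spans a Euclidean orthant with one axis per
non-terminal system; orthants glue along shared axes, and because the
underlying poset makes pairwise-comparable sets into chains, the complex
is a CAT(0) orthant space: geodesics exist and are unique.
`geodesic_distance()` computes them exactly:

* axes supported by both points contribute a plain Euclidean term (each is
  comparable with everything in either support chain);
* the exclusive supports $A$ and $B$ are organized into an ordered pair of
  partitions $(A_1,\dots,A_k;\,B_1,\dots,B_k)$ such that (i) every system
  in an earlier $B$-block is comparable with every system in a later
  $A$-block and (ii) the norm ratios $\lVert A_i\rVert/\lVert B_i\rVert$
  are nondecreasing; the squared path length is then
  $\sum_i (\lVert A_i\rVert + \lVert B_i\rVert)^2$;
* starting from the single-block cone path, a block is split whenever the
  bipartite incomparability graph between its sides admits a vertex cover
  of weight $< 1$ under the squared normalized coordinate weights; the
  exact cover comes from a max-flow/min-cut computation (via igraph), and
  the two pieces re-enter the queue in place.

Condition (ii) is essential and easy to overlook: the length formula above
is attained by an actual path only when the ratios are ordered, so the
geodesic is the minimum over partitions satisfying *both* conditions.  The
test suite checks the refinement against a brute-force enumeration of all
valid partition pairs (both conditions verified directly) on random point
pairs with exclusive supports of size $\le 4$, along with the metric
axioms on sampled triples, the sandwich between the independent-coordinate
lower bound and the cone-path upper bound, and the degenerate case of
nested supports (plain Euclidean distance).

Axes comparable with the entire opposite support need no special-casing:
an empty minimum cover splits a block into an $(\,\emptyset, B\,)$ and an
$(A, \emptyset\,)$ piece, which reproduces the product-space (Euclidean)
behaviour such shared directions must have.

`geodesic_point()` evaluates the unique geodesic at an arc-length
fraction: shared axes interpolate linearly, and within block $i$ the $p$
coordinates shrink by $((1-s)\lVert A_i\rVert - s\lVert B_i\rVert)_+ /
\lVert A_i\rVert$ while the $q$ coordinates grow symmetrically, so each
block bends once and the support always stays inside the union of the two
supports.  Between ultrametric-tree points (partition-only supports) every
intermediate point is again an ultrametric tree, so the restriction of the
distance to tree points is the ultrametric tree-space distance; the suite
checks partition-only supports along sampled geodesics.

Numeric policy: coordinates are doubles; ratio ordering, cover-weight
comparisons and support thresholds all use a fixed tolerance of $10^{-9}$;
coordinates at or below the tolerance are treated as absent from the
support.

## Random generators and what they do (not) show

`random_maximal_chain(n, p_ret)` replays the generative process: at each
step with $k \ge 3$ frontier clusters it reticulates with probability
`p_ret` (uniform over the $3\binom{k}{3}$ middle/outer choices) and joins
otherwise (uniform over the $\binom{k}{2}$ pairs); with two clusters the
final join is forced.  The draw order (step type, then witness) is fixed,
so a seed fully determines the output.  This is *not* the uniform
distribution over binary RTCNs — uniform sampling is available only by
exhaustive enumeration at small $n$ — and `p_ret` defaults to 0.25 as a
moderate reticulation load; the calibration test checks the realized
reticulation fraction against `p_ret` within three standard errors.
`random_point()` layers position dropping (probability `p_skip`, endpoints
kept) and exponential rank differences (mean `rate`, default 1 — the
natural scale-free choice for non-negative branch-length-like quantities)
on top.

The generated objects exercise every validator and theorem the package
implements, but they emulate combinatorial structure only: there is no
sequence-level noise, no inference error, and no model of how reticulation
probability varies along a time line, so green tests certify the algebra
and the geometry, not the behaviour of any estimator on real data.

## Problem sizes and limits

The suite works exhaustively at $n \le 4$ (108 chains; all poset members;
all ranked-tree pairs), by random sampling at $n \in \{5,6,7\}$ (encode /
decode round trips, generator validity), and at $n = 8$ only for the
worked poset-chain example.  These sizes were chosen so that every check
rests either on full enumeration or on an independent brute-force oracle.
Known limitations: poset queries and BFS distances are exponential in the
worst case (raise the caps explicitly at your own risk); taxon sets are
limited to 30 labels by the bitmask representation; extended Newick is
export-only; and non-binary networks other than the canonical
representative of a chain are not constructed.
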