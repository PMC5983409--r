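---
title: "Synthesis interactomes: recursion, essentiality and the minimal cell core"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesis interactomes: recursion, essentiality and the minimal cell core}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicore)
```

## The model

`sicore` works with a deliberately spartan model of cellular biosynthesis.
During the window of the cell cycle between division and the initiation of
DNA replication (the B period), the synthesis of every internally produced
cell element is abstracted as a *commutative binary operator*

$$\langle s_{ia}, s_{ib} \rangle \Rightarrow s_i,$$

read as: when the two operands bind, the product $s_i$ appears instantly.
Higher-order assemblies are nested pairs, so binary operators lose no
generality.  A **synthesis interactome** (SI) is a table with one such row
per internally synthesized element.  The model ignores concentrations,
kinetics, energy and compartments on purpose: what remains is exactly the
dependency structure of synthesis, and that structure alone already decides
which elements are essential.

The table induces a partition of the element universe $S$:

* $S_i$ — the products (internal elements), one per row;
* $S_e = S \setminus S_i$ — external elements, for which the table carries
  no synthesis information;
* $G \subseteq S_e$ — genomic elements, an *annotation* only.  The genome
  is static during the B period, so G members behave algorithmically like
  any other external element; the package accordingly forbids a G-annotated
  name from appearing as a product (reported as `genome_as_product`).
  This is a design choice: nothing in the calculus would break if it were
  allowed, but a "synthesized genome" row would contradict the B-period
  reading of the model, so we flag it rather than silently accept it.

Well-formedness asks that all products be distinct (the SI is
non-redundant) and that all *unordered* operand pairs be distinct
(commutativity makes $\langle b,c\rangle$ and $\langle c,b\rangle$ the same
operator; two rows sharing them would map one operator to two products).
`validate_si()` reports every violation with row numbers.  Two useful
closure properties follow: row order never matters, and any non-empty
subset of rows is again well-formed — deleting rows models *loss of
knowledge* about synthesis, which is central to the robustness discussion
below.

## From condensed to expanded formulas

Each row is a *condensed* formula.  Expansion substitutes, simultaneously,
every internal-element leaf by that element's own operator:

```{r}
toy <- toy_si()
toy
format_expression(expand_to_level(toy, "a", 2))
```

Three behaviours occur:

1. **Closed formulas.** If some level's operands are all external, the
   expansion has reached a fixed point, a closed formula $E^*(x)$ built
   from externals only (`closed_expanded_formula()`).
2. **Open formulas.** Otherwise the tree grows forever.  The growth is
   linear for elements that merely sit downstream of a cycle and
   exponential inside cycles, which is why `expand_to_level()` carries a
   `size_cap` (default $10^6$ leaves — large enough for any level a human
   would inspect, small enough to fail fast instead of exhausting memory).
3. **Operand-set convergence.** Even when trees grow without bound, the
   *set* of distinct operands seen up to level $r$,
   $O^*_r(x) = \bigcup_{j \le r} O_j(E_j(x))$, is monotone and bounded by
   $S$, so it converges in fewer than $|S|$ levels.  The limit $O^*(x)$ is
   the complete operand set: everything needed, at any depth, to make $x$.
   `complete_operand_set()` iterates the level sets directly (the leaf set
   of level $r+1$ is the external part of level $r$ plus the operands of
   its internal members), so it never builds a tree and needs no cap.

Whether a closed formula exists is decided *before* any tree is grown: it
exists iff the sub-digraph induced by $x$ and its ancestors is acyclic.
This avoids guessing an expansion bound heuristically.

On symbol counting (`symbol_count()`): the package defines the `"tokens"`
convention — every name, bracket and comma counts one, so a tree with $n$
leaves has $4n-3$ tokens — and a `"leaves"` convention.  For the worked
example's element `i` the token count grows as $5 + 8r$, a regression
guard on the substitution engine.  Other counting conventions exist in the
literature that match neither of these; we pin only our own.

## Recursion and the two essentiality rules

An internal element $x$ is **recursive** when $x \in O^*(x)$: it is
needed, at some depth, for its own synthesis.  Such an element cannot be
synthesized de novo in its own absence — the RNA polymerase is the
canonical biological case ("to make polymerase you need polymerase") —
and is therefore *essential*.  Two rules define the essential set:

* **Recursion rule:** every recursive internal element is essential
  (`essential_internal()`).
* **Propagation rule:** every member of $O^*(e)$ of an essential $e$ is
  essential, internal, external or genomic
  (`essential_set()`: $E = \bigcup_{e\ \mathrm{recursive}} O^*(e)$).

$E$ may be empty (no recursion anywhere — e.g. a secondary-metabolite
pathway) or all of $S$.  A third, experimental notion — essentiality of
the genome-*replication* machinery — is out of algorithmic reach: its
failure only manifests in the next generation, so the report carries a
fixed note instead of a classification.

`minimal_si()` applies the reduction that motivates the whole exercise:
keep exactly the rows whose product is essential.  The surviving table is
well-formed and classifying it again reproduces the same essential set
(idempotence, covered by tests).

### The fixpoint and a subtlety worth knowing about

`fixpoint_operand_sets()` computes all $O^*(x)$ at once: start each set at
the row's own operands and repeatedly merge into it the current sets of
its internal members, until nothing changes.  Termination needs no
safeguard — sets only grow and are bounded by $S$ — and the result
provably equals the level-wise union (both compute reverse transitive
closure over the operand-to-product relation).

Elements are marked *frozen* the moment they are first seen inside their
own set; `frozen_order` reports this detection order.  A tempting
optimization is to stop merging a frozen element's set into its consumers
(its recursion is already established).  The package deliberately does
**not** do this: a set can be frozen while still incomplete, and a
consumer that stops listening at that moment ends up short.  A minimal
example: with rows `a <- <b,x>`, `b <- <a,y>`, `c <- <a,z>`, the pair
`a`/`b` freezes before `c` has seen `y` through `b`; an early-stopping
merge would report $O^*(c)$ without `y`, while the true ancestor set
contains it.  Merging through frozen members costs nothing (termination is
monotonicity's job, not freezing's) and keeps the fixpoint exact.  The
regression test for precisely this topology lives in the essentiality
test file.

## The graph view as an independent oracle

The same table defines a directed graph: nodes are elements, and each row
contributes operand-to-product edges.  The correspondence that makes this
useful:

* $O^*(x)$ = the **ancestor set** of $x$ (all nodes with a directed path
  to $x$), with $x$ itself included exactly when a closed walk passes
  through it;
* $x$ recursive $\iff$ $x$ lies on a **directed closed walk** (a strongly
  connected component of size $\ge 2$, or a self-loop);
* a closed formula exists $\iff$ the ancestry of $x$ is acyclic.

`build_synthesis_digraph()` computes recursion and essentiality purely
graph-side (SCCs and reverse reachability via igraph), so the two routes
share no code and cross-validate each other — the agreement is asserted on
all fixtures and on 200 generated interactomes in the test suite.
`cycle_for_element()` returns one explicit witness walk, the shortest one
with lexicographic tie-breaking over the successors of $x$; published walk
listings need not be shortest, so tests assert exact equality only where
the shortest walk is forced (e.g. `o → pol → t.o → o`) and otherwise
validate the returned walk edge-by-edge.

Representation choices: a repeated operand ($\langle f,f\rangle$) is
stored as one edge with `multiplicity = 2` — reachability and cycle
semantics are unaffected and simple-graph exports stay clean; the
in-degree law then reads "incoming multiplicities of an internal node sum
to 2".  A row whose product equals an operand becomes a self-loop, making
SCC-based cycle detection uniform.  The undirected *binding* graph (one
edge per row between the two operands) is exposed for completeness and
export.

## The random generator

`random_si()` exists to make the central equivalences testable on ground
truth that is *provable, not just observed*.  Planted cycles use minimal
wiring — each cycle member's row takes the previous member as one operand
and an external element as the other — so every planted member is
recursive by construction.  All remaining internal elements draw operands
only from earlier-indexed non-cycle internals and externals, which makes
them acyclic by construction and keeps them from feeding the planted
cycles.  Consequently the recursive set of a generated SI is exactly the
union of its planted cycles, and any disagreement in a property test is a
bug, not noise.

Defaults and conventions: names are `iNNN`/`eNNN`/`gNNN` (internal /
external / genomic) for stable sorting and readable diffs; at least one
external element is required (cycle rows need external partners); the
same seed yields a byte-identical table, and the caller's RNG stream is
restored afterwards.  The generator emulates *dependency topology only* —
it makes no attempt at realistic degree distributions, modularity, or
biochemical plausibility.  Passing property tests therefore certify the
algorithms, not the biological fidelity of any particular interactome:
conclusions about a real organism are only as good as the curated SI fed
in, and real interactomes are chronically incomplete — deleting knowledge
(rows) can only hide recursion, never invent it, as the partial
polymerase fixture shows (12 recursive elements → 0 after removing the
four transcription rows).

Problem sizes: the property suites sweep 200 seeded configurations with
2–10 internal and 1–6 external elements and cycles of length 1–4.  These
sizes exercise every code path (self-loops, multi-cycles, pure DAGs,
genomic annotations) while keeping the whole suite fast; the algorithms
are polynomial ($O(|S|)$ fixpoint rounds over sets bounded by $|S|$), so
nothing qualitatively new appears at larger sizes.

## Worked example

```{r}
pol <- pol_si()
report <- essential_set(pol)
report
g <- build_synthesis_digraph(pol)
cycle_for_element(g, "o")
si_size(minimal_si(pol))       # every row survives: pol is all core
essential_internal(partial_pol_si())  # knowledge deleted: nothing provably essential
```

The interactome-size estimator `estimate_min_operators()` is the model's
back-of-envelope projection: an integrated interactome (polymerase +
ribosome + streptomycin synthesis) shows roughly three binary operators
per gene, so a complete SI for a genome of $N_G$ genes is estimated at
$\hat N_{bo} = 3 N_G$ operators.  It is a linear extrapolation from a
single data point and almost surely an underestimate for large genomes;
it is exposed because it is part of the model's account of itself, not
because it is a serious predictor.

## Known limitations

* Redundant synthesis routes (two operators yielding the same product) and
  stochastic operator outcomes are outside the model; condition (ii)
  enforces non-redundancy, which is also why the calculus is deliberately
  non-robust to row deletion.
* Essentiality is always *relative to the information in the table*: an
  element classified non-essential may simply be under-described (the
  partial polymerase fixture is the canonical illustration).
* The genome-replication machinery cannot be classified by these rules at
  all; the report says so rather than guessing.
* `as.data.frame()` on a report needs the originating SI to enumerate
  external elements; the report alone does not retain them.
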