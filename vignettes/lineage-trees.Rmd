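---
title: "SHM-ordered inheritance trees: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SHM-ordered inheritance trees: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmtree)
```

## The model

`shmtree` treats affinity maturation as a constrained optimization walk.
B cells in a germinal centre accumulate somatic hypermutations (SHM) under
continuous selection against a fixed antigen. Two consequences shape the
tree model:

1. **Monotone divergence.** Selection survivors are progressively more
   mutated, so along any ancestral line the SHM rate (mutated fraction of
   the V region relative to the inferred germline) should not decrease.
2. **Mutation inheritance.** Reversions are unlikely over the days-long
   timescale, and observed CDR mutations in sampled cells are treated as
   advantageous; a child should carry every CDR mutation of its parent.

A lineage tree here is a rooted directed tree over unique clonotypes in
one clonal lineage such that every edge satisfies child SHM ≥ parent SHM,
and, on every non-fallback edge, parent CDR mutations ⊆ child CDR
mutations. Mutation identity is the triple (CDR region, 0-based position
within the gapped CDR slice of the alignment, observed base): a different
base at the same position is a *different* mutation event, so subset
semantics are exact. Unlike binary phylogenies, internal nodes are sampled
clonotypes — appropriate for data in which ancestors and descendants
co-occur.

## The algorithm

For each lineage:

1. Collapse members into clonotype nodes (unique V-region nucleotide
   sequence, or unique concatenated-CDR sequence). A node's SHM rate is
   the mean over its members; member SHM is always computed on the
   V-region alignment, combined across heavy/light chains by the chosen
   method.
2. Select the root: the node with the lowest SHM rate. On ties, a single
   unswitched (IgM/IgD) candidate wins; if ties remain, a **dummy root**
   is formed — the positionwise consensus of the tied sequences with `D`
   at disagreeing positions (`AGC` + `CGC` → `DGC`), SHM rate equal to
   the tied minimum, and mutation set the intersection of the tied sets
   (so every tied candidate remains a valid child). `D` mismatches every
   base in all distance computations.
3. Process the remaining nodes in ascending SHM order (ties broken by
   sequence, for determinism). Each node attaches to the already-placed
   candidate with the smallest *unnormalized* Levenshtein distance among
   those whose mutation set it inherits. The root is permanently a
   candidate (the universal-root fallback): a node inheriting from no
   placed node still attaches — to the root — and the edge is flagged
   `fallback`, keeping the tree connected while leaving the inheritance
   invariant testable. Distance ties prefer the higher-SHM (most derived)
   valid parent, then the lexicographically smaller parent sequence.
4. Reported edge weights are Levenshtein distance divided by the parent
   sequence length; normalization applies to the report only, never to
   parent selection.

The SHM-ordering guarantee is structural: candidates are always placed
before their children in ascending SHM order, so every edge points from a
lower- (or equal-) SHM node to a higher one, for any input.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| grouping criteria | `strict` | lineage = identical V gene(s) + CDR1/2/3 lengths; `loose` merges keys with matching V genes and ≤ 3 nt total CDR-length difference |
| clonotype definition | `vregion` | node identity; `fullcdr` (concatenated CDRs) is coarser and faster — running both is informative |
| SHM combination | `mean` | per-member rate for paired chains: `heavy`, `max` or `mean` of hSHM/lSHM; bulk data always uses `heavy` |
| depth threshold | 2 | lineages with depth ≥ 2 are "deep" (showing maturation); tree files are emitted for these |
| branch `wMax` | 0.1 | max normalized edge weight inside a branch of closely related nodes |
| branch `dMin`, `sMin` | 2, 5 | minimum internal depth and node count for a reported branch |

Isotype is read from the heavy-chain `c_call` prefix (IGHM→IgM, …); this
column is optional in AIRR files, and records without it are "unknown"
and treated as class-switched (no root-tie priority). Non-productive
records are removed before grouping.

## The simulator

`simulateTree()` emulates germinal-centre expansion for benchmarking: a
uniform random germline of length *L* roots the tree; each node spawns
Poisson(λc) children; each child gains a zero-truncated Poisson(λm)
number of new substitutions at previously unmutated positions (so
parental mutations are always inherited and positions never revert);
10 % of positions are hotspots with 3× sampling weight; growth stops at
*N* nodes or when a node's mutated fraction reaches 0.95. Defaults cover
the biologically motivated ranges used throughout: L ∈ {100, 200}
(single/paired-chain full-CDR scale), N ∈ {100, 200}, λm ∈ {1, 2}
(observed 1–2 mutations per generation), λc ∈ {2, 3, 4} (about three
dark-zone cell cycles).

Two free choices deserve emphasis:

* **Zero-truncated λm.** A zero-mutation child would be sequence-identical
  to its parent and collapse into the same clonotype at reconstruction,
  making ground-truth comparison ill-defined; truncation keeps node
  sequences unique (coincidental duplicates are redrawn). This is the most
  consequential free choice in the simulator: allowing silent children
  would make reconstruction strictly harder.
* **Breadth-first growth.** The node cap interacts with growth order;
  generation-by-generation growth fills shallow levels first, which
  mirrors synchronized germinal-centre cycling.

What the simulator does *not* model: framework/CDR partition within the
simulated sequence (the whole sequence acts as one CDR), indels, isotype
switching, selection coefficients and clonal abundance. Passing
benchmarks therefore demonstrate correct recovery of inheritance-ordered
substitution trees, not robustness to indels, annotation errors or
abundance-driven tie-breaking in real repertoires.

## Benchmarking and problem sizes

Reconstruction is scored by graph edit distance. Because true and
reconstructed trees share an identical, uniquely labelled node set and
relabelling costs nothing, GED reduces exactly to the directed-edge
symmetric difference — twice the number of mis-assigned parents — which is
exact and fast (no approximate search). Directed edges are compared since
both structures are rooted.

The full benchmark grid is {L: 100, 200} × {N: 100, 200} ×
{λm: 1, 2} × {λc: 2, 3, 4} with 50 repetitions per combination (1200
trees). The test suite exercises the ordering/inheritance invariants on
120 reconstructed lineages spanning the grid at node caps 20–40, the
full-size protocol on four grid rows at 100 trees each, and the
cap-monotonicity trend at 30 trees per cap — sizes chosen to keep the
default run in minutes while leaving every scientific claim exercised at
full sequence length. `scripts/acceptance.R` re-runs the four-row
protocol at its full 100-tree size.

## Numerical choices and degenerate inputs

* SHM comparability: a position contributes to the SHM rate only when
  both observed and germline characters are A/C/G/T; IMGT gap dots, `-`
  and `N` are excluded from numerator and denominator. An alignment with
  no comparable positions has SHM 0.
* CDR location: CDR fields are located as exact substrings of the
  ungapped sequence alignment and mapped into alignment coordinates; a
  CDR that cannot be located is a hard error for that cell.
* Ties everywhere are broken deterministically (lexicographic sequence
  order as the final key), so trees are invariant to input row order and
  node shuffling.
* Single-node lineages build a one-node tree with depth 0; they appear in
  the node table but are excluded from summary distributions and tree
  file output.
* Empty repertoires after filtering warn and produce header-only tables.

## Known limitations

* Clonal grouping ignores junction-sequence similarity; unrelated
  rearrangements sharing V genes and CDR lengths can co-group, and the
  loose mode's founder-anchored greedy merge is deterministic but not a
  transitive closure.
* Inheritance is evaluated on CDR substitutions only; indels within CDRs
  separate lineages (strict mode) or surface as large edge weights rather
  than being modelled.
* The universal-root fallback guarantees connectivity but places
  non-inheriting nodes as direct root children; on germline-rooted
  simulated data fallbacks never occur, and flagged edges should be
  inspected in real data.
* V(D)J annotation and germline inference are upstream concerns: the
  package consumes AIRR rearrangement files and trusts their
  `germline_alignment`.
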