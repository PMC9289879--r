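---
title: "Ring-system scaffold analysis: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-system scaffold analysis: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringscape)
```

ringscape analyzes the ring-system content of small-molecule libraries: it
decomposes molecules into ring systems and frameworks, classifies molecular
novelty against a reference drug ring set, catalogs ring systems with their
growth vectors, enumerates close mutational neighbors of known rings, and
studies ring co-occurrence as a network. This vignette documents the exact
definitions the package implements and the design decisions behind them,
so results can be interpreted (and reproduced) without reading the source.

## Standardization and filters

Structure handling is delegated to Open Babel (via ChemmineOB/ChemmineR):
SMILES and SDF parsing, aromaticity perception and canonical SMILES all
come from one toolkit, so every comparison in the package reduces to string
equality of canonical SMILES ("canonical keys").

`standardize_library()` applies a fixed, documented transform list:

1. **Salt stripping** — keep the largest fragment, preferring
   carbon-containing fragments.
2. **Charge neutralization** — add or remove protons where a neutral
   valence state exists. Charge-separated groups whose charges cannot be
   neutralized by (de)protonation alone (nitro, N-oxides, azides) are left
   intact.
3. **Keto–enol normalization** — non-ring enols `C=C-OH` are rewritten to
   the keto form; ring "enols" such as phenol are untouched.

The contract is determinism and idempotence, both enforced by tests.
`filter_library()` then removes molecules by the first failing rule, in
the order: failed standardization; contains a metal (any element outside
H, B, C, N, O, Si, P, S, Se and the halogens); any smallest-set ring with
more than 9 bonds (macrocycles); molecular weight of 1000 Da or more
(strict cutoff, average atomic masses). `enforce_phase_exclusivity()`
keeps each structure only in the highest phase it reaches
(`other < phase1 < phase2 < phase3 < drug`).

## Ring systems, frameworks and growth vectors

A **ring system** is a connected union of rings — fused, bridged and spiro
rings all merge, since they share an atom or a bond — plus any *retained
exocyclic double-bond atoms*: terminal atoms (O, S, N or C by default)
double-bonded to a ring atom. Substituents are replaced by hydrogen and
the result is canonicalized into the ring key. Chlorthalidone is the
worked example: it decomposes into benzene and the isoindolinone bicycle,
whose exocyclic carbonyl oxygen stays part of the ring system:

```{r chlorthalidone}
rs <- extract_ring_systems(
  standardize_smiles("OC1(c2cc(ccc2Cl)S(N)(=O)=O)c2ccccc2C(=O)N1"))
rs[, c("ring_key", "n_rings", "exo_double_bonds", "vectors")]
```

The **framework** is the molecule reduced to its ring systems plus the
linkers connecting them: terminal atoms are pruned iteratively until only
rings and inter-ring paths remain, then exocyclic double-bond atoms
attached to kept atoms are added back. A consequence worth stating
explicitly: a terminal acyl substituent on a single ring (as in
acetophenone) is pruned entirely, so acetophenone's framework is plain
benzene, while an amide linker *between* two rings keeps its carbonyl
oxygen. This matches the iterative-pruning definition of frameworks and
the Chlorthalidone decomposition above, where the sulfonamide side chain
disappears from the framework.

Each bond cut while isolating a ring system is recorded as a **growth
vector** at the attachment atom's *canonical symmetry rank* within the
isolated ring system. Ranks come from a Morgan-style iterative refinement
of atom invariants, so symmetry-equivalent positions collapse: any
mono-substituted benzene reports the same single vector, and
para-disubstituted benzene reports two vectors at one rank. Two deliberate
properties of the ranking:

* **Kekulé independence.** Ring-bond orders are excluded from the rank
  invariants (ring bonds contribute topology only; acyclic bonds,
  including exocyclic double bonds, contribute their order). Aromatic
  rings are kekulized arbitrarily by the SMILES writer, and the same ring
  embedded in different molecules must expose identical ranks. The cost is
  a resolution limit: positions that differ only by the placement of a
  fixed double bond *inside* a non-aromatic ring (e.g. the two sp3
  neighbors of a cyclohexenone) can share a rank.
* **Relative, not absolute positions.** Because equivalent positions share
  a rank, vector multisets distinguish e.g. 2- from 3-substituted
  pyridine, but not ortho- from para-disubstituted benzene (all benzene
  positions are equivalent in isolation).

When an attachment atom carries a tetrahedral SMILES specification, the
growth vector is tagged with its **enantiomeric form**. Tags are SMILES
parity labels (`@` reported as "S", `@@` as "R" by convention), not CIP
assignments; they distinguish the two forms consistently but are not
claimed to match IUPAC R/S names.

## Novelty classification

Against a reference drug ring set, a molecule is:
class 1 (all ring systems known), class 2 (known rings plus exactly one
novel ring), class 3 (known rings plus two or more novel rings), class 4a
(a single ring system, novel), class 4b (two or more ring systems, all
novel), or class 5 (no ring systems). Membership is exact canonical-key
matching. `classify_phase()` reports per-phase class counts with integer
percentages over two denominators: all molecules, and molecules containing
at least one ring system.

## Ring catalogs

`build_catalog()` aggregates fragmentation output into a key-indexed
catalog storing `frequency` (distinct molecules containing the ring),
`occurrences` (total copies), source tags, phases, and the observed
growth-vector combinations. Merging is commutative and associative with
the empty catalog as identity, so large libraries can be processed in
shards. Catalogs record the fragmentation settings used to build them and
refuse comparisons across different settings.

## N+1 / N+2 enumeration

`mutate_ring()` enumerates every ring system within one or two elementary
edits of a seed: substitution of a ring atom's element within a
configurable set (default C, N, O, S), and addition or removal of an
exocyclic double-bond atom (default `=O`). Edits never change ring count
or ring sizes. Two-edit enumeration composes single edits without
requiring the intermediate to be valid — distance is defined by atom
differences, not by valid paths. Candidates must pass valence checks
(which also rejects unkekulizable aromatic edits, since editing happens on
the kekulized graph), survive canonicalization and re-parsing, and avoid a
configurable SMARTS stability blacklist. The defaults forbid ring O–O,
S–S and O–S bonds, three contiguous non-aromatic ring nitrogens, and
geminal ring diols; the list is a package convention, chosen to exclude
textbook-unstable motifs, and can be replaced wholesale.

```{r azines}
spec <- mutation_spec(max_changes = 2, substitution_elements = c("C", "N"),
                      exo_edit = FALSE)
mutate_ring("c1ccccc1", spec)
```

`overlap_within_n()` reports how much of a novel ring set lies within one
or two edits of a seed set; `build_future_set()` intersects the mutation
neighborhood of a seed set with a large reference catalog, keeping rings
reported strictly more than a frequency threshold and within heteroatom
cutoffs derived from the seed distribution. Seeds with more than
`max_rings` (default 5) rings are skipped with a warning.

## Co-occurrence networks

In the scaffold graph each node is a ring system; two nodes are connected
if some molecule contains both, with edge weight equal to the number of
such molecules. `network_stats()` reports the standard simple-graph
density `2E/(N(N-1))` and the isolated fraction. Clustering uses the
Girvan–Newman edge-betweenness algorithm on the unweighted graph,
returning the best-modularity partition by default (a specific cluster
count can be requested); clusters are numbered by decreasing size.
Centrality rankings (degree, eigenvector, betweenness) break ties by
ascending ring molecular weight, then key. A ring is **target-specific**
for a label when strictly more than half of the molecules containing it
carry that label.

## Synthetic ground-truth libraries

Because the compound collections behind published scaffold analyses are
generally not deposited, `generate_library()` assembles phase-labeled
libraries bottom-up from a ring vocabulary joined by acyclic linkers, so
the true ring systems, growth vectors, novelty class, and target labels of
every molecule are known by construction. The generator supports planted
co-occurrence blocks (every molecule draws its drug rings from one block,
so block structure is exactly recoverable from the drug-ring subgraph) and
probabilistic target-label rules. Generation is deterministic for a fixed
spec and leaves the session RNG untouched. The default vocabularies are
small curated sets (about forty common drug rings, twenty "novel" rings);
the generator makes no attempt to mimic real property distributions beyond
what the class mix and block structure encode.

This closes the validation loop exercised by the test suite: a
2,000-molecule library fragments back to exactly the planted rings and
vectors, classifies with zero misassignments against the manifest,
recovers the planted three-block structure exactly at best modularity, and
flags planted target-specific rings exactly under the strict majority
rule.

## Known limitations

* Stereo growth-vector tags are parity labels, not CIP assignments.
* Rank resolution inside non-aromatic rings with fixed double bonds is
  deliberately reduced by kekulé independence (see above).
* Tautomer handling is limited to the non-ring keto–enol rule; no general
  tautomer canonicalization is attempted.
* The stability blacklist is a convention, not a learned model; published
  analyses name such filters without listing them.
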