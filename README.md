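# ringscape

Ring-system scaffold analysis for small-molecule libraries.

Most approved drugs are built from a surprisingly small vocabulary of ring
systems, and tracking how that vocabulary grows — which rings are new, where
substituents attach, which rings co-occur — is a standard lens on medicinal
chemistry libraries. ringscape implements that analysis end to end:

* **Standardization and filtering** — salt stripping, charge neutralization,
  keto–enol normalization; removal of metals, macrocycles (> 9-bond rings)
  and heavy molecules (≥ 1000 Da), with per-rule attribution.
* **Fragmentation** — decomposition into ring systems (fused/bridged/spiro
  rings merge; terminal exocyclic double-bond atoms are retained) and
  molecular frameworks, with **growth vectors**: substituent attachment
  points reported at canonical, kekulé-independent symmetry ranks.
* **Novelty classification** — classes 1–5 relative to a reference drug
  ring set, tabulated per development phase.
* **Ring catalogs** — frequency/occurrence-indexed catalogs that merge
  associatively, so libraries can be processed in shards.
* **N+1/N+2 enumeration** — all ring systems within one or two elementary
  edits (ring-atom element substitution, exocyclic `=O` add/remove) of a
  seed, filtered by valence and a SMARTS stability blacklist; overlap and
  "future set" construction against a large catalog.
* **Co-occurrence networks** — ring–ring graphs with density/centrality
  statistics, Girvan–Newman clustering, and strict-majority target-class
  labeling.
* **Synthetic ground-truth libraries** — a seeded generator that assembles
  phase-labeled libraries from known rings and linkers, with planted
  co-occurrence blocks and target labels, so every downstream result can be
  checked against a manifest.

Structure handling (parsing, aromaticity, canonical SMILES) is delegated to
Open Babel via ChemmineOB/ChemmineR; graph algorithms come from igraph.

## Worked example

```r
library(ringscape)

# 1. Generate a small ground-truthed demo library
spec <- library_spec(
  seed = 42,
  n_molecules = c(drug = 60, phase3 = 30, phase2 = 30, phase1 = 30),
  class_mix = c(class1 = 0.67, class2 = 0.24, class3 = 0.02,
                class4a = 0.06, class4b = 0.01))
lib <- generate_library(spec)
head(lib$records[, c("id", "smiles_std", "phase")], 3)
#>          id                        smiles_std phase
#> 1 drug_0001                     C1CC2(C1)CNC2  drug
#> 2 drug_0002 O=C1NCCC(C1)OCCc1cocc1CCCC1CCCCS1  drug
#> 3 drug_0003         C1CC2(C1)COC2OCc1n[nH]nc1  drug

# 2. Filters (generated molecules are already standardized; all pass)
flt <- filter_library(lib$records)
flt$report
#> filter report: 150/150 kept

# 3. Fragment into ring systems with growth vectors
frag <- fragment_library(flt$records)
head(frag$rings[, c("molecule_id", "ring_key", "n_rings", "vectors")], 4)
#>   molecule_id      ring_key n_rings vectors
#> 1   drug_0001 C1CC2(C1)CNC2       2
#> 2   drug_0002    O=C1CCCCN1       1       1
#> 3   drug_0002       c1ccco1       1     1;1
#> 4   drug_0002      C1CCCSC1       1       3

# 4. Classify novelty against the drug ring vocabulary
cls <- classify_phase(enforce_phase_exclusivity(flt$records), frag$rings,
                      canonical_smiles(default_drug_rings()))
subset(cls, phase == "phase1" & n > 0)
#>    phase   class  n pct_all pct_ringed
#> 1 phase1  class1 17      57         57
#> 2 phase1  class2  7      23         23
#> 3 phase1  class3  1       3          3
#> 4 phase1 class4a  2       7          7
#> 5 phase1 class4b  3      10         10

# 5. Catalog
cat3 <- build_catalog(frag$rings, tag = "demo")
cat3
#> ring catalog: 58 ring systems, 2 singletons
head(catalog_as_data_frame(cat3), 3)
#>           ring_key frequency occurrences n_rings sources phases n_vector_combos
#> 1  c1ccc2c(c1)scc2        15          15       2    demo                      7
#> 2 c1ccc2c(c1)nccc2        10          10       2    demo                      9
#> 3         c1ccncn1        10          10       1    demo                      5

# 6. Enumeration: azines within two changes of benzene
mutate_ring("c1ccccc1",
            mutation_spec(max_changes = 2,
                          substitution_elements = c("C", "N"),
                          exo_edit = FALSE))
#> [1] "c1cccnc1" "c1ccnnc1" "c1ccncn1" "n1ccncc1"

# 7. Co-occurrence network
g <- build_scaffold_graph(frag$rings, flt$records)
network_stats(g)
#> nodes 58  edges 198  isolated 0.00  density 0.1198 (11.98 x10^-2)
head(scaffold_centrality(g, "degree"), 3)
#>             ring_key score rank
#> 1    c1ccc2c(c1)scc2    18    1
#> 2 c1ncc2c(n1)nc[nH]2    14    2
#> 3   c1ccc2c(c1)nccc2    14    3

# 8. Chlorthalidone decomposes into benzene + an isoindolinone bicycle
#    whose exocyclic carbonyl oxygen is retained
extract_ring_systems(
  standardize_smiles("OC1(c2cc(ccc2Cl)S(N)(=O)=O)c2ccccc2C(=O)N1")
)[, c("ring_key", "n_rings", "exo_double_bonds", "vectors")]
#>          ring_key n_rings exo_double_bonds vectors
#> 1 O=C1NCc2c1cccc2       2                1     5;5
#> 2        c1ccccc1       1                0   1;1;1
```

The growth vectors `1;1;1` for benzene illustrate canonical symmetry ranks:
all six positions of isolated benzene are equivalent, so every attachment
reports rank 1.

## Command line

A dispatcher script covering the whole pipeline ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ringscape.R", package="ringscape"))')" \
  simulate --spec spec.yaml --out library.csv --truth manifest.json
```

Subcommands: `standardize`, `fragment`, `catalog` (build/merge/query),
`classify`, `mutate`, `network`, `report`, `simulate`. Run any subcommand
without options to see the usage block at the top of the script.

## Documentation

The methods vignette (`vignettes/ring-system-analysis.Rmd`) documents the
exact definitions — ring systems, frameworks, growth-vector ranks and their
deliberate kekulé independence, the stability blacklist, the synthetic
generator — and the known limitations.

## License

MIT (see `LICENSE`).
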