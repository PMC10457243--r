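# plasmidnet

In-silico characterization of small circular bacterial plasmids, built
around the workflow used for multireplicon isolates such as the Antarctic
*Psychrobacter* strains: find the replication origin's iteron array,
judge a module's suitability for vector construction by its restriction
sites, and group and type plasmid proteins through a reciprocated
similarity network.

## Who this is for

Researchers dissecting a plasmidome — a set of small (3–14 kb) circular
replicons — into functional modules: the **REP module** (replication
initiator gene plus *oriV*, marked by ~20–22 bp tandem **iterons** that
bind the Rep protein) and the **MOB module** (relaxase gene enabling
conjugal mobilization), plus auxiliary cargo. The package provides the
full path from annotated GenBank/FASTA records to summary tables, and a
truth-tracked synthetic-data generator so every stage can be validated
without downloading anything.

## The methods at the core

* **Circular coordinates.** 1-based inclusive spans; `start > end` runs
  forward through the origin, so a region `2,670–2,399` on a 3,124-bp
  plasmid is the 2,854-bp fragment `(L − start + 1) + end`.
* **Iteron detection.** Maximal arrays of adjacent repeat copies (unit
  18–24 bp, ≥3 copies) whose copies each differ from the column-majority
  consensus at ≤ 15% of positions; variable consensus columns are
  rendered in the field's `(X/Y)` notation, e.g.
  `CT(A/T)(T/G)ATGACTACAAATCCTTAC`.
* **Restriction screening.** Exact IUPAC matching on both strands of the
  circular replicon; an extracted module is screened as linear DNA, and
  every enzyme *not* cutting remains available for the vector's MCS.
  Default panel: the 13 common MCS endonucleases (BamHI … XhoI).
* **Similarity network.** All-vs-all Smith–Waterman (BLOSUM62, gap
  11/1), Karlin–Altschul E-values `E = K·m·n·e^(−λS)` (λ = 0.267,
  K = 0.041), and an edge only for *reciprocated* similarity with
  E ≤ 1e-10, identity ≥ 30% and HSP coverage ≥ 90% in both directions;
  edge weight = identity × coverage. Connected components define protein
  families; labeled references type them (Rep_3 / RepA-like / Rep_1,
  MOB_P / MOB_Q / MOB_V) at E ≤ 1e-2.

## Worked example

```r
library(plasmidnet)

# a 6,238-bp synthetic plasmid: rep gene with 4 planted 22-bp iterons
# upstream, and a 1.5-kb region kept free of MCS restriction sites
unit <- "CATAAAGCTACGTTTAGCGACC"
gen <- generate_plasmid(6238, gc = 0.382,
                        modules = list(rep = list(iteron_unit = unit,
                                                  copies = 4),
                                       site_free = list(start = 4500,
                                                        end = 6000)),
                        seed = 42, id = "pDEMO")
rec <- gen$record
rec
#> PlasmidRecord 'pDEMO': 6,238 bp, circular, 1 feature(s)

detect_iterons(rec, window = 500)[[1]]
#> IteronArray: 4 x 22 bp at 293 (+ strand), consensus CATAAAGCTACGTTTAGCGACC

screen_module(rec, module_region("pDEMO", 4500, 6000, "REP"))
#> ScreenResult: REP 4500-6000 (1501 bp), 0 cutting / 13 available
#>   not cutting: BamHI, EcoRI, EcoRV, HindIII, KpnI, NcoI, NheI, PstI,
#>   SacI, SalI, SphI, XbaI, XhoI

# four planted protein families, five members each, recovered as the
# network's four connected components
fam <- generate_protein_families(4, 5, within_identity = 0.85,
                                 between_identity = 0.15,
                                 length = 300, seed = 7)
build_network(fam$proteins)
#> SimilarityNetwork: 20 proteins, 40 edges, 4 components

# a relaxase pair built at 87% similarity reports it back as positives
b <- mutate_to_similarity(fam$proteins$sequence[1], 0.87, seed = 8)
reciprocal_similarity(fam$proteins[1, ], protein_set("relB", b))
#>   query subject identity_pct positives_pct query_coverage_pct ...
#> 1 F1_M1    relB     85.33333      86.66667                100
#> 2  relB   F1_M1     85.33333      86.66667                100
```

The iteron array prints at window position 293 because the 500-bp
upstream window wraps through the plasmid origin; the consensus equals
the planted unit exactly. The screen reports all 13 enzymes available —
the planted region is site-free by construction, the ideal case for a
cloning-ready module. The relaxase pair realizes the requested percent
positives within sampling noise.

Published tables for the ANT_H3 plasmid set (GenBank MN657079–MN657089)
ship as inputs: `ant_h3_summary()` (sizes, GC, modules),
`ant_h3_rep_regions()` (REP-module coordinates and non-cutting enzyme
sets), `ant_h3_iteron_consensi()` (the quoted degenerate consensus
strings). A command-line wrapper lives at `inst/scripts/plasmidnet.R`.

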