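---
title: "Characterizing small plasmid replicons: iterons, restriction screens, and protein-similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing small plasmid replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidnet)
```

## The problem

Small bacterial plasmids (roughly 3–14 kb) are built from exchangeable
genetic modules: a replication (REP) module — the initiator `rep` gene and
its origin of replication (*oriV*) — and, usually, a mobilization (MOB)
module whose relaxase nicks the plasmid at *oriT* for conjugal transfer.
Multireplicon strains such as the Antarctic *Psychrobacter* isolates can
carry a dozen such plasmids at once, and their modules are the natural
building blocks for cold-active cloning vectors. Characterizing a
plasmidome *in silico* therefore asks four recurring questions, which this
package answers as four composable stages:

1. **Where is the origin?** Theta-replicating plasmids of the Rep_3 family
   typically carry an array of ~20–22 bp direct repeats (*iterons*)
   immediately upstream of `rep`, the binding sites of the initiator
   protein (`find_iteron_arrays()`, `detect_iterons()`).
2. **Is the module clonable?** A REP module destined for a vector should
   be *poor* in the restriction sites used in multiple-cloning sites, so
   those enzymes remain usable (`scan_sites()`, `screen_module()`).
3. **Which proteins are homologous across replicons?** An all-vs-all
   local-alignment network with reciprocated-similarity edges groups
   proteins into families (`build_network()`), and labeled reference sets
   type them into Rep_3 / RepA-like / Rep_1 replicases or MOB_P / MOB_Q /
   MOB_V relaxases (`classify_protein()`).
4. **What does the set look like as a whole?** `run_characterization()`
   orchestrates the stages into per-replicon summary tables.

A fifth, first-class stage is the synthetic-data generator: every detector
above is validated against plasmids and protein families with *planted,
truth-tracked* structure, so the whole pipeline is testable without any
sequence download.

## Coordinate model

Coordinates are 1-based and inclusive throughout, the GenBank convention.
Circularity is encoded by allowing `start > end`: such a span runs forward
through the sequence origin, so its length is `(L - start + 1) + end` on a
replicon of length `L`. This matches how module coordinates are quoted for
deposited plasmid records (e.g. a REP module at `2,670–2,399` of a
3,124-bp plasmid is a 2,854-bp fragment through the origin). The same
convention applies to origin-spanning CDS features (`join` locations are
collapsed to a `start > end` span on reading). Published coordinate pairs
of this form are assumed to run forward through the origin; the notation
itself does not distinguish the two readings, and the forward reading is
the only one consistent with the quoted module sizes.

## Iteron detection

`find_iteron_arrays()` scans a candidate *oriV* window for maximal arrays
of adjacent repeat copies. For every unit length in `unit_range`
(default 18–24 bp, bracketing the documented 20–22 bp iterons) an O(n)
prescreen finds positions whose two adjacent windows differ at no more
than twice the per-copy budget; surviving seeds are grown rightwards while
every copy stays within `max_mismatch_frac` (default 0.15) of the running
column-majority consensus. Copies must be strictly tandem by default
(`max_spacer = 0`, configurable up to 10 bp).

Three numerical choices matter:

* **Overlap resolution.** Overlapping candidates are deduplicated by
  highest copy count, then lowest mean mismatch fraction, then smallest
  unit, then leftmost start. Note that a tandem array is intrinsically
  *phase-ambiguous*: when noise makes two phases equally good, the
  leftmost rule may report a start shifted by up to one unit relative to
  the planted phase while still describing the same array. Recovery is
  therefore judged on unit length and copy count, not on the exact phase.
* **Low-complexity guard.** A consensus with fewer than three distinct
  bases is suppressed, so homopolymer and dinucleotide tracts never
  surface as iterons.
* **`min_copies = 3`,** although canonical arrays have four copies:
  degraded arrays should still be reported, and the copy count is part of
  the output for downstream filtering.

The degenerate consensus uses the field's `(X/Y)` notation: a variable
column lists its observed bases by descending count, ties alphabetical
(`build_consensus()`, `render_consensus()`, `parse_consensus()` are
mutually inverse). The packaged `ant_h3_iteron_consensi()` table carries
the eight published consensus strings of the ANT_H3 plasmids; they parse
to 22 (six strings), 21 and 20 positions respectively.

The upstream search window defaults to 500 bp before the `rep` start
codon (strand-aware, wrapping through the origin), and both strands of
the window are scanned, since iteron orientation is not fixed a priori.
The window size, the mismatch tolerance and the strand policy are this
package's choices — published iteron calls rarely state them — and all are
exposed as parameters.

## Restriction screening

`scan_sites()` performs exact IUPAC matching on both strands; on circular
sequences the subject is extended by the first `|site| − 1` bases so
origin-spanning sites are found, and palindromic duplicates are collapsed.
The default panel (`default_enzymes()`) is the 13-endonuclease set common
in multiple-cloning sites (BamHI … XhoI, all 6-bp palindromes).

`screen_module()` extracts the (possibly wrapping) module from its
circular replicon and then scans the fragment **as linear DNA**: a module
cloned into a vector is interrupted at its ends, so a site that would
only form across the fragment boundary is not a cut in the construct.
The wrap logic applies solely to extracting the fragment from the
replicon. Whether the original web-tool screens of published availability
tables treated the fragment as linear or circular is not documented; the
linear choice is asserted here because it matches the vector-construction
use case, and it is the conservative choice (it can only report *fewer*
cuts, never a spurious one).

## The similarity network

Pairwise alignment is Smith–Waterman with affine gaps (BLOSUM62, gap open
11, extend 1 — the standard gapped protein-search scheme), delegated to
`Biostrings::pairwiseAlignment()` and validated against an independent
dynamic-programming oracle in the test suite. On the single best local
alignment (the HSP), identity and positives are fractions of alignment
columns (gap columns count in the denominator, as in a BLAST hit table).

E-values use the Karlin–Altschul form `E = K·m·n·exp(−λS)` with the
published gapped BLOSUM62/11/1 parameters (λ = 0.267, K = 0.041). They
act as a similarity *filter* here, not a statistic of record, and the
parameters are configurable.

`build_network()` adds an edge only when **both** directed hits pass all
three thresholds — E ≤ 1e-10, identity ≥ 30%, HSP coverage ≥ 90%, the
stringent setting standard for plasmid-proteome homology networks — and
weights it by the mean over directions of identity × coverage, so every
edge weight lies in [0.27, 1] at the defaults. Design choices made where
the convention is genuinely open:

* **Coverage denominator.** "HSP coverage" is reported with the *shorter*
  protein as denominator, which is symmetric and matches the
  reciprocated-edge semantics; per-side query and subject coverage are
  also stored. Thresholds are applied per direction.
* **Similarity percentages.** Quoted relaxase "similarity" figures are
  compared against percent *positives* (aligned pairs with positive
  matrix score) — the quantity BLAST prints as similarity — with identity
  reported alongside (`reciprocal_similarity()`).
* **Single best HSP,** no HSP tiling: the simplest faithful reading of
  "HSP coverage".

Connected components (via igraph) define protein families;
`classify_protein()` types queries against labeled references at the
conventional E ≤ 1e-2, and `count_families()` counts *plasmids* per
family, so a composite replicon carrying two replication systems counts
once in each.

## What the synthetic generator emulates — and what it does not

`generate_plasmid()` plants modules into i.i.d. background DNA of
requested GC: a `rep` ORF with an upstream tandem-iteron array (unit,
copy number, per-copy substitution probability), a relaxase ORF, and
spans kept free of a restriction panel's sites. `mutate_to_identity()`
substitutes a fixed number of distinct positions so the realized global
identity equals its target up to rounding; `mutate_to_similarity()`
derives the identity target for a wanted *positives* level analytically
from the matrix (a random substitution still scores positive with
probability ≈ 0.11 under BLOSUM62). `generate_protein_families()` builds
each family from an independent ancestor with per-member divergence
`1 − sqrt(within_identity)`, giving the requested pairwise structure.
All generators take explicit seeds, are bit-reproducible, and leave the
caller's RNG stream untouched.

Default study conditions mirror the documented plasmidome: replicon sizes
3,124–13,249 bp, GC near 35–43%, 22-bp iteron units in four tandem
copies, protein length ~300 residues (relaxase-scale). The per-copy
substitution level used for noisy-recovery experiments is 0.03 per base
(~0.7 substitutions per 22-bp copy), the divergence level actually shown
by the published *imperfect* iteron consensi, whose variable columns
imply roughly one substitution per copy. At substantially higher noise
(5% per base) a 4-copy array has an appreciable chance (~10%) that one
copy exceeds the 15% per-copy mismatch contract, in which case *no*
contract-honoring detector can report it as a 4-copy array — a limit of
the detection contract, not of the implementation.

What the generator does **not** emulate: codon structure and real gene
content (planted ORFs are ATG + random filler + stop), indels and
recombination in protein families (substitutions only), AT-rich regions
and DnaA boxes around origins, and methylation. Passing tests on this
material therefore demonstrate the detectors' contracts — recovery of
planted structure under controlled noise — not performance on the full
messiness of real annotations.

## Problem sizes and tolerances used in validation

The shipped validation suite uses: 1–2 kb plasmids (detection), a 10-kb
size for GC-tracking checks (binomial noise sd ≈ 0.5 points sits well
inside the ±2-point contract; at 3 kb the sampling noise itself
approaches the contract), 100 seeded plasmids for the ≥95% noisy-recovery
bound, 200 random length-8 peptide pairs against the alignment oracle,
4 × 5 planted families at 0.85/0.15 within/between identity for perfect
(ARI = 1) family recovery, and 3-kb fragments against the sliding-window
restriction oracle. Relaxase-pair similarity checks use ±5 percentage
points, reflecting that the aligner settings behind published similarity
figures are generally unspecified.

## Known limitations

* The GenBank reader covers the flat-file subset this workflow needs
  (LOCUS topology, CDS/locus_tag/product/translation, `complement` and
  origin-spanning `join` locations); it is not a general-purpose parser.
* E-values are first-order Karlin–Altschul estimates without edge-effect
  or composition corrections; rankings are stable but absolute values
  differ from a full BLAST implementation.
* The all-vs-all stage is quadratic in protein count and aimed at
  plasmidome scale (tens to hundreds of proteins), not whole proteomes.
* Iteron detection assumes substitution-only divergence between copies;
  spacer insertions inside an array are only handled up to `max_spacer`.
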