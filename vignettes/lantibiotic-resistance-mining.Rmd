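---
title: "Mining lantibiotic resistance operons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining lantibiotic resistance operons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lantiscan)
```

`lantiscan` re-implements, as a deterministic and testable pipeline, the
in-silico workflow used to survey lantibiotic resistance traits in
bacterial genomes: protein homology screening, domain-based role
assignment, gene-neighborhood operon assembly, membrane-topology
classification of BceAB-like transporter systems, bacteriocin gene
cluster (BGC) class assignment, 16S distance phylogenies, and
microdilution MIC analysis. This vignette explains each model, its
assumptions and tunable parameters, what the synthetic-data generators do
and do not emulate, and the design choices made where the methodology was
genuinely open.

## Homology screening

Desk-scale inputs make exact dynamic programming affordable, so every
"BLASTP hit" in this package is an exact Smith–Waterman local alignment
(global Needleman–Wunsch for percent identities) under BLOSUM62 with
affine gap costs: a gap of length $k$ costs `gap_open` $+ k\,$`gap_extend`
(defaults 11 and 1, the classic BLASTP setting). This removes heuristic
seeding as a source of irreproducibility; scores are verified in the test
suite against an independent brute-force three-state recursion.

Significance uses the Karlin–Altschul expectation
$E = K m n e^{-\lambda S}$ with the standard published gapped parameters
for BLOSUM62/11/1 ($\lambda = 0.267$, $K = 0.041$), where $m$ and $n$ are
by default the lengths of the two sequences of each pair
(`search_space = "pairwise"`); an `"effective"` mode using the total
proteome length is available for sensitivity analysis. Exact BLAST
effective-length corrections are intentionally out of scope, so absolute
E-values approximate NCBI BLAST rather than reproduce it; the contract is
the behavior of the $E < 10^{-10}$ retention filter on planted homologs
versus decoys, which the tests pin down (homologs at 30–70 % identity to
queries of ≥150 aa are always retained, composition-typical random decoys
never are).

One caveat is worth stating: Karlin–Altschul statistics assume a
negative expected pair score. Membrane proteins violate this — two
unrelated 10-helix permeases share hydrophobic tracts that align with
positive drift, exactly as compositionally biased regions do in real
BLAST practice. Hits between membrane-protein queries and planted
membrane proteins are therefore expected and harmless here (the trait
logic works on domain roles and locus architectures, not on raw hit
lists), but E-values between hydrophobic sequences should not be read as
calibrated probabilities.

Percent identity counts identical columns over the full alignment length
*including* gap columns — the conservative reading of "sequence identity"
— both for local hits and for the global identities quoted for
lysyltransferase and peptidase homologs.

## Query panel and domain signatures

The screen uses a fixed panel of query proteins (DltA; MprF/LysX; two NSR
exemplars; NBD subunits NisF/CprA/VraD/NsrF and the *Corynebacterium*
transporter pair; permease subunits NisE/NisG/CprB/CprC/VraE/NsrP; NisT,
NisI and the nisin precursor; LanM/LanC modification-enzyme and Class III
stand-ins). The bundled sequences are synthetic stand-ins built
deterministically in code: each carries the documented signature content
(Walker A/B boxes, the S41 `TASSAEM` catalytic box and an N-domain
anchor, FtsX-like permease motif, kinase H- and G-boxes, receiver-domain
signatures, 10-TMH architecture with or without a 218 aa ECD, realistic
lengths) at realistic positions, embedded in natural-composition random
sequence. They are not the UniProt records they stand in for; each entry
records the corresponding accession so users can substitute real
sequences by replacing the `sequence` column of `query_registry()`.

Domain detection likewise uses bundled degenerate PROSITE-style patterns
(`inst/extdata/domain_models.txt`) instead of profile HMMs: Pfam models
cannot be shipped, and for this pipeline's purpose — deterministic role
labels on exemplar-derived sequences — pattern matching with a
`min_matches` threshold per model is sufficient and fully transparent.
The patterns were authored against the bundled exemplars and are
validated on them (and on their mutated descendants) in the tests; they
are *not* calibrated against Pfam on real proteomes, which is the main
cost of this substitution.

The catalytic-box finder scores every 7-mer window against `TASSAEM` and
reports the best window with ≥4/7 identities **and** the serine at window
position 3. The threshold accepts the naturally degenerate `TGSSGEA` box
(4/7, serine conserved) while a random 7-mer passes with probability far
below the per-protein noise floor; both the threshold and the rule are
explicit arguments.

Role precedence for multi-domain proteins is
permease > NSR peptidase > HK > RR > NBD, giving every gene one
deterministic label for locus typing. A protein with no domain call but a
retained hit to a LysX/MprF query is labelled `LysX_like`.

## Operon assembly and architectures

"Adjacent" is formalized as: two role-bearing genes join one locus when
their intergenic distance is ≤ 2000 bp **and** at most one role-less gene
lies between them; loci are maximal under this relation. Both knobs live
in `cluster_config()`. The defaults keep operon-scale gene runs (tens to
hundreds of bp apart) intact while splitting unrelated hits; strand is
deliberately ignored for clustering (divergently transcribed TCS /
transporter pairs are common) and recorded per member. Only
operon-machinery roles (permease, NSR peptidase, HK, RR, NBD) seed loci;
`LysX_like` genes are cell-envelope modification enzymes, reported
genome-wide rather than clustered.

Architecture labels recompute from member roles: ABC present iff both NBD
and permease occur; TCS iff HK and RR; the label is the combination
(`ABC_TCS_NSR` down to `NSR_only`). A locus whose roles complete no group
— an HK without its RR, a lone NBD from a biosynthesis transporter —
raises a classification error; the pipeline logs and drops such loci so
they cannot masquerade as resistance systems.

A peptidase split over two ORFs is recognized from homology geometry:
two neighboring ORFs whose hit spans on the same NSR query overlap by
< 20 % of the shorter span while jointly covering ≥ 60 % of the query are
called fragments (`fragmented_NSR`, printed `(+)` in the trait matrix).
The published fragment call is qualitative; both thresholds are explicit
arguments of `detect_fragmented()`.

## Membrane topology

Topology prediction is the classic hydropathy plot: Kyte–Doolittle
values, centered window of 19 residues, candidate helix = maximal run of
positions with window mean ≥ 1.6, runs closer than 3 residues merged,
runs shorter than 15 discarded. Orientation follows the positive-inside
rule — the N-terminal side is chosen to maximize K+R over inside loops,
ties resolved to "inside". All five knobs live in `topology_config()`
with those published defaults. This replaces an HMM-based predictor
(whose model files are not redistributable) and is adequate for the
count-and-loop-geometry rules the classification needs; it does not
produce posterior probabilities, does not detect signal peptides, and —
inherently — cannot resolve inter-helix connectors much shorter than the
window (see the generator notes below).

The discrimination rules are then purely structural. A permease is
considered Pep7E-like only with exactly 10 predicted TMHs; among those,
an outside loop of ≥ 50 aa strictly between TMH 7 and TMH 8 marks the
classical ECD-bearing BceAB architecture, and its absence marks the
unusual ECD-less type. The 50 aa threshold separates a ~200 aa ECD
cleanly from ordinary 3–30 aa Pep7E loops and is configurable
(`ecd_min_len`). Kinases: 0 TMH → cytoplasmic; 2 TMHs with a short
outside connector → BceS-like; 2 TMHs with an outside loop ≥ 50 aa →
CprK-like; anything else → other.

## Bacteriocin gene clusters

BGC detection replaces a web-service screen with explicit rules.
Precursor candidates are proteins of 20–80 aa with combined Ser+Thr+Cys
content ≥ 20 % (the residues dehydrated or thioether-bridged in
lanthipeptides). Candidate clusters grow from each precursor over
"interesting" neighbors (role-bearing genes and homologs of the
modification/Class III queries) under the same adjacency rule as operon
assembly. Classes: **I** — precursor plus a member homologous to a
modification-enzyme query; **II** — precursor plus a
transporter/peptidase member but no modification enzyme; **III** — a
member of ≥ 90 aa homologous to the Class III query; precedence
I > II > III. Nisin-likeness of a precursor is a retained local alignment
against the nisin query under a relaxed cutoff of $10^{-3}$ — the global
$10^{-10}$ filter is uninformative for a 34 aa query, where even a
perfect self-hit has limited score headroom. Clusters are cross-referenced
against the resistance hit set by locus tag, mirroring the survey's check
that no BGC gene doubled as a resistance hit. No concordance with any
external BGC tool is claimed, and no leader-peptide or modification
chemistry is modelled.

## 16S phylogeny

Distances are Jukes–Cantor: per pair, columns with a gap or `N` in either
row are excluded, $p$ is the mismatch fraction over the rest, and
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. The distance model behind the
published tree is not recorded; JC69 is the defensible minimal choice and
a raw p-distance is available by flag. Saturated pairs ($p \ge 3/4$)
receive a ceiling distance of 5 substitutions/site with a warning rather
than an error, so bootstrap replicates always complete. Trees come from
neighbor-joining (`ape::nj`); negative branch lengths are clamped to
zero. Bootstrap support resamples columns with replacement, rebuilds the
NJ tree per replicate, and reports for each internal edge of the
full-data tree the fraction of replicates containing the same
bipartition; an all-identical alignment is a star tree and gets supports
of 1 by convention, with a warning. Input is a pre-aligned FASTA — the
multiple-alignment step itself is out of scope, and the simulator emits
aligned data directly.

## MIC analysis

Relative growth per well is
$(\mathrm{OD}_{24h} - \mathrm{OD}_{0h}) / (\mathrm{OD}^{untr}_{24h} -
\mathrm{OD}^{untr}_{0h})$, normalized within each strain × condition
series. The dose-response family is the decreasing Gompertz curve
$G(d) = A \exp(-\exp(s \ln(d/m)))$ — amplitude $A$ as $d \to 0$,
inflection at dose $m$ (µg/mL), dimensionless slope $s$. The exact
parameterization behind the published fits is a black box of the
graphing software used; this form is documented, monotone decreasing,
and none of the MIC logic depends on it. Fitting is bounded
Levenberg–Marquardt least squares ($A \in (0, 1.5]$, $m$ within the
tested range × [1/4, 4], $s \in (0.1, 50]$) initialized at
$A_0 = \max$ observed growth, $m_0$ = geometric mean of the
concentrations bracketing half-maximal growth, $s_0 = 4$. A steep
transition can make $(m, s)$ locally unidentifiable for derivative-based
steps (only one dose mid-transition); the fitter then falls back to a
Nelder–Mead search on log-parameters. Fits at a box bound are flagged
`boundary`.

The MIC itself is read from the wells, not the fit: the lowest tested
concentration whose relative growth is ≤ τ = 0.05 *and* whose every
higher tested concentration also is — the standard contiguous no-growth
tail of a serial dilution. Isolated sub-τ dips with regrowth above are
ignored and logged. τ = 0.05 operationalizes "no growth detected" at a
plate-reader noise floor and is an argument. Whether published MIC calls
came from wells or fits is ambiguous in the source methodology; this
package reads wells and reports the fit separately. Fold-changes are MIC
ratios and are undefined (with a reason) when either value is censored
(`> max tested`).

## Synthetic data: what it emulates, and what it does not

All generators are seed-deterministic and attach truth metadata.

**Genomes** (`build_genome()`, `synthesize_survey()`). Operon plants
follow the three characterized layouts (NBD–permease–peptidase;
RR–HK–NBD–permease–peptidase; permease–NBD–HK–RR), with members diverged
from the registry templates to a target identity (default 0.5, the
middle of the 40–60 % band the recovery tests exercise) by
positive-scoring BLOSUM62 substitutions; signature motifs are locked so
domain calls survive divergence, and no indels are introduced. Proteins
are back-translated with uniform synonymous codons (codon bias is
irrelevant to every downstream stage), genes sit 60–140 bp apart within
a plant, and plants are insulated by blocks of decoy genes
(natural-composition random proteins, re-sampled until they contain no
signature pattern) so distance clustering cannot bridge unrelated
elements. The fragmented-peptidase plant splits a diverged NSR into an
N-terminal 209 aa ORF and the C-terminal remainder carrying the
catalytic box, adjacent on the chromosome. What this does *not* emulate:
real intergenic signal (promoters, terminators, RBSs), pseudogenes,
horizontal-transfer composition anomalies, or annotation errors — so
passing recovery tests demonstrates the pipeline's logic, not robustness
to noisy real-world annotation.

**Membrane proteins** (`build_membrane_protein()`). Helices are 21 aa
draws from L/I/V; loops have a three-residue mildly polar "interface"
band at each edge and a strongly hydrophilic core (K/R-enriched inside,
K/R-free outside), which guarantees the positive-inside rule recovers
the intended orientation and that each helix yields a detectable window
run. Inter-helix connectors of ≥ 10 aa are reliably resolved; shorter
connectors are below the physical resolution of a 19-residue hydropathy
window, and the validation suites use resolvable lengths. Real membrane
proteins with marginal helices or 5 aa connectors will not behave this
cleanly.

**Alignments** (`evolve_alignment()`). Sites evolve independently under
JC dynamics along a known tree; no indels, no rate heterogeneity, no
base-composition bias — matching the JC69 inference model by design, so
tree-recovery rates measure the NJ machinery, not model misspecification.
Benchmarks use 8 taxa × 2000 sites with branch lengths uniform on
[0.05, 0.3] substitutions/site.

**Plates** (`simulate_assay()`). Relative growth follows the Gompertz
curve with $m =$ MIC/2, so with slope ≥ 8 the τ = 0.05 crossing falls
between the planted MIC and the next lower dilution and the noise-free
plate reads back the planted value exactly — this calibration is what
makes the generator/extractor round-trip a non-tautological test of the
reading rule. Readings become OD600 with a 0.05 starting OD and an
untreated increment of 1.0. Noise is signal-proportional Gaussian
(`sd = noise_sd × signal + 0.005` OD): microdilution reading works in
practice precisely because wells with no growth read far more quietly
than dense wells, and a homoscedastic alternative at sd 0.05 would make
any τ = 0.05 threshold rule misread a multi-well tail most of the time.
The default dilution grid is a 12-step two-fold series; the worked
examples anchor it at 40 µg/mL (or 50 µg/mL for the wider-range strain)
so that the printed reference concentrations — 1.25, 5.00, 0.625,
12.5, 25 µg/mL — lie exactly on the grid. A single two-fold series
cannot contain both 12.5 and 1.25 µg/mL, so the published table
evidently mixes two anchors; the simulators accept any grid.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GFF3 convention).
* Translation uses the bacterial code (table 11); codons containing `N`
  translate to `X`; initiator codons are translated literally so
  translation round-trips generated sequences; internal stops are errors
  naming the gene.
* Local alignment raw scores are clamped at 0 (an empty local alignment
  is always admissible); alignment tie-breaks follow the deterministic
  traceback of the alignment engine.
* `which.max`-style ties (catalytic windows) resolve to the smallest
  start; NJ tie-breaks are the engine's deterministic choice.
* JC69 with zero comparable columns for a pair is an error naming the
  pair; saturation is a warning plus ceiling, not an error.
* Gompertz fits that hit a parameter bound are flagged rather than
  silently returned; monotone-rising profiles end at the slope bound.
* All simulation entry points take a single integer seed and are
  reproducible byte-for-byte.

## Problem sizes used in validation

The shipped test and acceptance suites run entirely on synthetic data at
desk scale, chosen to exercise every rule with comfortable statistical
margins: 6 survey genomes of ~15–25 genes each, ≥ 150 alignment-oracle
pairs of ≤ 30 aa, 50–60 membrane constructs, 20 additive and 50 simulated
8-taxon × 2000-site tree recoveries, 100 noisy Gompertz fits and 500
noisy plates.

## Known limitations

* E-values approximate BLAST only up to effective-length corrections and
  break down between compositionally biased (hydrophobic) sequences.
* Pattern-based domain calls are validated on the bundled exemplars, not
  against Pfam HMMs on real proteomes.
* The hydropathy predictor cannot resolve sub-window loop lengths and
  disagrees with HMM predictors near threshold; on real accessions the
  documented tuning ranges of `topology_config()` may be needed.
* BGC class assignment is rule-transparent but makes no concordance
  claim with dedicated BGC miners on real genomes.
* The pipeline requires existing gene annotations (or a proteome); it
  does not call ORFs.
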