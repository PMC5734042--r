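---
title: "Detecting pseudogenizing lesions and resurrecting ancestral ORFs"
author: "orfrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pseudogenizing lesions and resurrecting ancestral ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfrescue)
```

## The problem

Subtelomeric gene families turn over fast. In the yeast aryl-alcohol
dehydrogenase (AAD) family — seven paralogs of a ~34 kDa aldo-keto
reductase, each sitting near a chromosome end — most copies are degenerating:
one carries a missense substitution at a catalytic residue, one has been
split into two annotated ORFs by a single-base deletion, one lost its
N-terminal third to a premature stop upstream of the annotated start, and
one lost its 5' half outright. The analytic question this package answers
is: *given a candidate locus and a trusted full-length reference protein,
which minimal single-base edit (if any) resurrects an ancestral full-length
ORF, and how should the locus be classified?*

The package also covers the machinery around that inference: pairwise
similarity surveys of family copies across strains, alignment-free k-mer
trees of orthologs, and Michaelis–Menten characterization of resurrected
enzymes — plus a synthetic-family generator so every stage can be exercised
against planted ground truth.

## The decision rule

A degraded locus is accepted as an ancestrally intact gene when four
criteria hold (thresholds configurable via `repair_thresholds()`):

1. the out-of-frame nucleotide sequence shares at least 80% consensus
   positions with the reference CDS (`consensus_fraction()`);
2. a **single** simulated base-pair edit restores the reading frame
   (`scan_single_edit_repairs()`);
3. the restored ORF is similar in length to the reference CDS (within a
   0.9–1.1 band by default);
4. the restored protein shares at least 80% amino-acid similarity with the
   reference (`percent_similarity()`).

`classify_locus()` arranges these into a ladder: `intact`,
`missense_catalytic`, `frameshift_split`, `nonsense_truncated`,
`partial_deletion`, `absent`. Multi-edit repair is deliberately out of
scope: the model of pseudogenization here is a *single* lesion, and the
search space is exactly the `3L` substitutions, `4(L+1)` insertions and `L`
deletions inside the scan window (annotated CDS ± 1 kb by default).

## Alignment conventions

"Similarity" is not defined in most survey tables that print it; this
package uses an auditable rule. Protein similarity is the percentage of
aligned columns with a strictly positive BLOSUM62 score; nucleotide
similarity is percent identity. Alignments are end-to-end global
(Needleman–Wunsch, affine gaps, end gaps penalized) because the survey
compares annotated full-length ORFs; the gap cost of a length-k gap is
`open + k * extend` with defaults +2/−3, 5/2 (nucleotide) and BLOSUM62,
11/1 (protein). Gap columns count in every denominator. All of these
choices are recorded in survey output headers so a reader of a report knows
which convention produced the numbers.

## The repair scan

Every single-base edit in the window is evaluated by a compiled kernel that
rescans the three forward frames of the edited context (loci are normalized
to CDS-forward orientation on ingest). An edit survives when the edited
context contains an ATG-initiated, stop-terminated ORF that overlaps the
annotated CDS and is at least `0.9 ×` the reference length. Two details
matter in practice:

* **Canonical ORF choice.** A stop-bounded segment can hold several ATGs,
  and random flanking sequence occasionally contributes a spurious upstream
  in-frame ATG. Among qualifying starts the kernel picks the ORF whose
  length is closest to the reference (ties: longer, then 5'-most). Taking
  the longest instead would systematically overshoot into the flank.
* **Canonical indel coordinates.** An insertion into a homopolymer run is
  the same molecule wherever in the run you put it; indels are therefore
  left-aligned (5'-most equivalent coordinate) and deduplicated before
  ranking, so reports are stable and comparable.

Surviving edits are translated, aligned to the reference in one vectorized
pass, filtered by the length band and similarity threshold, and ranked as a
parsimony ladder: amino-acid **identity** to the reference first, then
(when a reference CDS is available) **nucleotide identity** of the
reconstructed CDS, then positive-matrix similarity, then ORF length, then
proximity to the annotated start. The order is deliberate and was chosen
for identifiability, not convenience. Ranking by similarity first looks
natural — similarity is the acceptance criterion — but it is not
discriminating enough to recover the true edit: a stop-removing
substitution that restores the exact ancestral residue *ties* on
similarity with one that leaves a conservative substitute (Trp vs Tyr both
score positively against Trp), and a frameshift repair one codon away from
the true junction leaves a short frame-scrambled stretch that can tie or
even win on similarity by chance. Identity resolves the first case; the
DNA-level key resolves the second, because a scrambled window almost never
matches the reference DNA as well as the locus's own diverged sequence
does. Even so the truth is not always identifiable: when neutral divergence
lands immediately beside a frameshift, a competing single-base insertion
can be *exactly* as parsimonious as the planted one at both the protein and
the DNA level. The recovery guarantee is therefore a property over seeds
(the top proposal reverses the planted edit in at least 95% of generated
families; measured, it does in ~97%), not a per-locus certainty — which is
also the honest statement of what minimal-edit reconstruction can promise
on real loci.

Upstream coordinates follow the convention of the motivating study: −1 is
the base immediately 5' of the A of the annotated ATG, and there is no
position 0. `scan_upstream_stop_repairs()` reports stop-removing
substitutions in the 5' flank together with the extension they regain, in
nucleotides and residues; among possible upstream starts it reports the one
whose protein best matches the reference.

## Classification floors

Two operational cutoffs complete the ladder. The *alignable fraction* of
the reference is measured by locally aligning (Smith–Waterman) the
reference protein against each of the three forward-frame translations of
the context and counting, across frames, the reference positions whose
alignment column scores positively. Local alignment makes the measure
frame-robust — a frameshifted copy is covered piecewise by two frames —
while a 5'-deleted copy leaves the missing positions uncovered in every
frame; counting positive columns only (rather than the whole aligned span)
keeps chance extensions of a local alignment from inflating coverage, and
alignments below a score floor of 60 are ignored outright, since chance
local alignments of unrelated translated sequence plateau in the 30s–40s
under BLOSUM62 with 11/1 gaps while any genuine homologous fragment scores
in the hundreds. Under this measure intact and frameshifted family copies
sit above 0.9, half-deleted copies near 0.4, and unrelated sequence at
essentially 0. A locus is `partial_deletion` below 0.5 (also the honest
fallback for a locus that is largely alignable but cannot be repaired by
any single edit) and `absent` below 0.3; both cutoffs and the score floor
are parameters.

## Kinetics

`fit_mm()` fits `v = Vmax·S/(Km+S)` by Levenberg–Marquardt nonlinear least
squares (not a Lineweaver–Burk linearization, which distorts error
structure), started at `Vmax0 = max(v)` and `Km0 =` the concentration whose
rate is nearest `Vmax0/2`, with standard errors from the curvature of the
least-squares surface at the optimum and an honest convergence flag.
`specific_activity()` carries the Beer–Lambert bookkeeping for the NAD(P)H
assays (ε₃₄₀ = 6.2, ε₃₅₅ = 5.12 mM⁻¹·cm⁻¹), `kcat_from_vmax()` the
µmol·min⁻¹·mg⁻¹ → min⁻¹ conversion, which always takes the molar mass as
an explicit input (tagged fusions and native proteins differ, and no
default could be defended). `compare_to_blank()` is the two-tailed
two-sample t test (equal-variance by default, Welch optional) used for
activity-vs-control calls.

## The phylogeny module

Ortholog sets are reduced to one hit per species by the published filter
(score ≥ 60, length strictly > 150 bp, best rank wins). Distances are
alignment-free: `d = 1 − |A∩B| / min(|A|,|B|)` over distinct 15-mer sets
(N-containing k-mers dropped), a parameter-free standard choice; a Jaccard
variant is available and the formula used is recorded in the matrix
attributes. The distance is a pseudometric (symmetric, zero
self-distance); the triangle inequality is not guaranteed and not needed by
neighbor joining. Trees are canonical Saitou–Nei NJ, unrooted, with
negative branch lengths clamped to zero with a warning. Forward-strand
k-mers are used because CDS inputs are orientation-normalized upstream.

## What the generator emulates — and what it does not

`generate_family()` produces a duplicated family from one ancestor
(default 330 codons, GC 0.40 — a yeast-like aldo-keto-reductase-sized gene)
under neutral divergence (default 5% per-base substitutions, uniform across
sites, with internal-stop rejection), one planted lesion per copy, and 1 kb
i.i.d. uniform flanks. The default seven-copy catalog mirrors the
motivating family: two intact copies, a catalytic missense (Tyr→Cys at
reference position 76, presented at target position 73 through a 3-codon
N-terminal trim, lesion at CDS nt 218), a frameshift deletion (the G at CDS
nt 518, repaired by insertion at junction 517/518), an upstream nonsense
with re-annotated start (stop at −36..−34, repairable at −35, regaining
264 nt / 88 residues), a 5' deletion (60% of the CDS — decidedly more than
half, so the lesion is unambiguous under the 50% alignable cutoff), and an
intact copy carrying an upstream scar (the dual-report case: the annotated
ORF is fine *and* an upstream repair exists).

Deliberate simplifications: no background indels (they would confound
single-edit ground truth), no codon-usage or rate heterogeneity, no
subtelomeric recombination, flanks with no homology structure, and
catalytic sites protected from neutral divergence so missense lesions stay
unambiguous. Passing the planted-truth tests therefore demonstrates that
the *inference machinery* is correct under its own model; it does not
demonstrate robustness to real subtelomeric sequence evolution, where
repeated DNA and multi-lesion histories occur.

Kinetics data are generated on an 8-point log-spaced grid spanning
0.1–10 × Km in triplicate with 5% multiplicative Gaussian noise — a
realistic bench design for initial-rate assays, and the one used by the
package's own Monte-Carlo recovery checks (100 datasets per condition,
medians compared at ±10%).

## Numerical and degenerate-input choices

* Codons containing N translate to `X`; k-mers containing N are skipped.
* Start codons: ATG only by default (the family's genes are
  ATG-initiated); `scan_orfs(require_atg = FALSE)` relaxes this.
* Standard genetic code only (fungal nuclear genes; no alternative tables).
* The annotated interval of a locus is *not* required to be a multiple of
  3 — broken genes have broken annotations — and minus-strand loci are
  reverse-complemented on ingest so every coordinate downstream is
  CDS-forward.
* `kmer_distance()` errors on two empty profiles and returns 1 when
  exactly one is empty; `neighbor_joining()` rejects asymmetric or
  negative matrices and returns the trivial tree for n = 2.
* `fit_mm()` reports parameters with `converged = FALSE` rather than
  erroring when the optimizer stalls.
* Test problem sizes: oracle-equivalence runs use ≤ 230 nt contexts and
  ≤ 12-residue alignment pairs (exhaustive DP); classifier ground-truth
  runs use 20 generator seeds at the default family geometry; kinetics
  Monte-Carlo uses 100 datasets per condition. These sizes make the full
  suite comfortably reproducible on a laptop while keeping every check
  statistically meaningful.

## Known limitations

* The repair scan models exactly one edit; loci degraded by several
  lesions fall into the `partial_deletion` catch-all with their alignable
  fraction reported, rather than being force-fitted to a repair story.
* Sequence-level repair is necessary, not sufficient: a catalytically dead
  but sequence-plausible repair (the fate of the real catalytic-missense
  paralog, which stayed inactive after repair) is invisible at this level.
  The package reports sequence plausibility only.
* BLAST searches, chromosome-rearrangement checks against assembly
  scaffolds, structural modeling and dN/dS dating are out of scope; the
  locus-context flag and the hit-table filter are the declared reductions
  of those steps.
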