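---
title: "Methods and design notes for wrkyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for wrkyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyscan)
```

`wrkyscan` packages the analyses of a genome-wide WRKY transcription
factor survey as tested, reusable functions. This vignette records the
models it implements, the conventions and tunable parameters, what the
synthetic generator does and does not emulate, and the design choices
made where the design was genuinely open.

## Coordinates and sequence plumbing

All coordinates are 1-based inclusive, the native convention of GFF3 and
of the Bioconductor containers the package leans on (Biostrings,
rtracklayer, IRanges). We deliberately did not introduce an internal
0-based half-open convention: in an R implementation every neighboring
API is 1-based, so a second convention would create the very off-by-one
surface it is meant to remove. Conversion happens nowhere; round-trip
tests (`write_gff3()` → `read_gff3()`) assert bit-exact coordinates.

Promoters are anchored at the first CDS base ("upstream of the start
codon"), not at the transcript start: `upstream_length` (default 2000 bp)
bases 5′ of that anchor, reverse-complemented for minus-strand genes.
Windows are truncated, never padded, at contig edges, and the truncation
is flagged — genes on short scaffolds therefore yield shorter promoters
rather than being dropped. Translation uses the standard code; a single
terminal stop is removed, an internal stop is an error, and codons with
unresolved ambiguity codes translate to `X` (tolerant of draft genomes).

## Domain scanner and group rules

The family is recognized structurally, not by profile HMM: every `WRKY`
core is located, its variant recorded (the canonical `WRKYGQK`, the
known 7-mer variants, or the conserved 5-mer `WRKYG` when the tail is
non-canonical), and a zinc finger searched within `window` residues
downstream (default 60). The finger patterns are the canonical WRKY
literature spacings, configurable via `zf_config()`:

* C2H2: `C-x(4,5)-C-x(22,23)-H-x-H`
* C2HC: `C-x(7)-C-x(23)-H-x-C`

Group rules: ≥ 2 complete domains, all C2H2 → I; one complete C2H2 → II;
one complete C2HC → III; heptapeptide(s) but no complete finger → IV.
Where complete domains disagree (one C2H2 and one C2HC), the protein is
*not* group I; the C-terminal-most complete domain decides — the
C-terminal domain is the DNA-binding one in two-domain WRKYs, so it is
the conservative tie-breaker. Subgroups IIa–IIe are assigned by UPGMA
co-clustering with labeled reference domains; the bundled reference set
is synthetic (see below) and users supply their own for real analyses.
Subgroup output is optional; the primary report uses I/II/III/IV.

## Physicochemical table

Molecular weight sums average (not monoisotopic) residue masses plus one
water, the ProtParam convention. The isoelectric point solves the
Henderson–Hasselbalch net-charge equation by bisection on [0, 14] to
0.001 pH; the default pKa set is Bjellqvist-style with residue-specific
terminal corrections (approximating ExPASy ProtParam), with the EMBOSS
table selectable. GRAVY is the mean Kyte–Doolittle hydropathy. The
instability index uses the published Guruprasad dipeptide-weight table,
`II = (10/L) Σ w(x_i, x_{i+1})`, with the conventional threshold of 40
(not stated in gene-family surveys; exposed as a parameter).
`check_cds_consistency()` encodes `CDS = 3(aa + 1)`; published tables
occasionally violate it (a known erratum row in the bundled bilberry
table is flagged, not corrected).

## Duplication detection

Pairs are aligned with Smith–Waterman local alignment under affine gaps
(Biostrings engine; BLOSUM62, gap open 10, extend 0.5 — the EMBOSS Water
defaults). Identity and similarity are percentages over alignment
columns; similarity counts positively scoring residue pairs and is the
thresholded quantity. Criteria: similarity ≥ 70 % is a duplication; same
contig with the gap between gene spans ≤ 100 kb (inclusive, measured end
of upstream gene to start of downstream gene) → tandem, otherwise
segmental; similarity > 98 % flags a recent duplicate. Segmental calls
are purely similarity-based — no synteny-block inference — mirroring the
survey criterion this models.

One addition beyond that criterion: `min_alignment_length` (default
30 aa). Percent similarity over a *local* alignment is degenerate when
the alignment is a handful of columns — any two family members share the
exact heptapeptide, which alone yields 100 % similarity over 7 columns
and would label every member pair a duplicate. Requiring ~half a WRKY
domain of aligned columns removes that artifact without touching the
published thresholds.

`summarize_ages()` excludes undefined (NaN) times everywhere and
excludes zeros from the mean — an identical pair dates the duplication
as "now" with no information content — while keeping them in the range.
This is the only rule under which the bundled published per-pair times
reproduce the published mean ages (8.27 Mya tandem, 26.43 Mya
segmental); reproducing the segmental mean also requires *including* the
one pair computed with a different program, so the `note` column only
gates the internal Ka/Ks consistency checks, not the age summary.

## NG86 Ka/Ks and dating

`ng86()` implements classical Nei–Gojobori (1986) counting: per codon,
each position contributes one site split by the fraction of its three
single-base changes that are synonymous, with changes to stop codons
counted as nonsynonymous opportunities — the convention of the standard
implementations (verified against an independent one on frozen
fixtures), and the one that keeps `N + S = 3 × codons` exact. Codons
differing at k positions are averaged over all k! mutational pathways
with equal weights; pathways through stop codons are excluded (with a
fall-back to all pathways if every ordering is blocked). Proportions are
Jukes–Cantor corrected, `d = -(3/4) ln(1 - (4/3) p)`; any undefined
intermediate (saturation `p ≥ 3/4`, `Ks = 0`) propagates as NaN, and
selection is classified by the ratio (neutral within `neutral_tolerance`,
default 1e-9, i.e. exact equality in practice).

Codon alignments are built by back-translating the Smith–Waterman
protein alignment; gap columns and terminal stops are dropped, and a
CDS/protein translation mismatch is an error.

Dating: `T = k / (2 r) × 1e-6` Mya. The default follows the published
formula verbatim (`k = Ks`, `r = 6.1e-9`/site/year). The published
bilberry per-pair times, however, are internally proportional to the
printed *Ka* with an implied rate of 6.56e-9 — we verified this across
every defined row before exposing it — so
`evolution_config(preset = "table2-compat")` reproduces those printed
times. The package takes no position on which convention the original
analysis intended; both are available and documented.

## Phylogeny

Distances are p-distances (mismatches over pairwise-deleted columns) or
Poisson distances `-ln(1 - p)` from a supplied alignment, or p-distances
over pairwise global alignments when no MSA is given. This replaces the
JTT/Bayesian machinery of full phylogenomic studies: the package's uses
of the tree (subgroup co-clustering, fixture-level clustering checks)
need only relative distances. `upgma()` merges the closest pair with
size-weighted average linkage; node height is half the merge distance,
so trees are ultrametric by construction. Ties are broken by the
lexicographically smallest pair of cluster representative labels, making
output invariant to input order. Newick serialization round-trips
through `ape`.

## Expression summaries

FPKM is `counts × 1e9 / (length × column_total)`; a zero column total is
an error naming the sample. "Expressed" means FPKM strictly above the
threshold, default 0 — detection semantics, which is what reproduces
published expressed-gene tallies of the kind this models (e.g. 24,491 of
36,405 annotated genes → 67 %); the threshold is configurable.
Percentages are rounded half-up to integers to match how such tables are
printed. Venn partitions are computed over all samples; `classical_mds()`
embeds Euclidean distances between `log2(FPKM + 1)` profiles over the 500
most variable genes (a common leading-variance practice, configurable,
not from any specific protocol) with cmdscale, fixing each axis's sign so
the first sample is non-negative. Differential-expression model fitting
(limma/edgeR/DESeq2) is deliberately out of scope; heatmap-style outputs
are plain log2 matrices.

## Synthetic generator

`simulate_family()` states a small world and emits it byte-reproducibly:
one master seed fans out to fixed per-component substreams, so adding a
component never perturbs another's draws. Proteins are built from the
group rules directly (planted heptapeptide + finger skeletons; filler
residues exclude W/C/H so no spurious cores or fingers can arise);
defaults plant two genes per group on three contigs. CDS are uniform
random back-translations plus a stop. Promoters are motif-free
backgrounds — generated, scanned, and point-repaired until clean — with
requested motif instances written in and re-verified, so expected hit
counts equal planted counts *exactly*; planting windows may not overlap,
and cross-matching motif pairs (e.g. palindromes) should be avoided in
plans. Duplicates are evolved with `evolve_pair()`: random single-base
proposals, synonymous changes accepted at rate 1, nonsynonymous at rate
ω, stops rejected, until accepted synonymous events per synonymous site
reach the target Ks. Domain-signature residues (heptapeptide core and
finger C/H) are under absolute constraint during this evolution —
without it, nonsynonymous hits destroy the planted group at moderate
divergence. Counts are zero-truncated negative-binomial for expressed
cells (a planted expressed gene is never invisible) and exactly zero
otherwise.

What the generator does **not** emulate: indels and rearrangements, gene
loss, base composition and codon-usage bias, UTRs and alternative
isoforms, promoter motif clustering, overdispersed library composition,
or read-level noise. A green closed-loop test therefore establishes that
the estimators and classifiers are correct on data satisfying their
assumptions — not that they are robust to real-genome messiness, and not
that any genome-wide published count (family size, cis-element type
counts, pair counts) is reproduced; those depend on the external genome
and databases and are documented non-goals. The bundled subgroup
reference FASTA is likewise synthetic (labelled so in its filename):
subgroup identity in this package is defined relative to whatever
reference set the user supplies.

## Numerical and degenerate-input choices

* Bisection tolerance for pI: 0.001 pH; tests compare against a
  brute-force grid oracle at 0.01.
* Instability index of length-1 sequences: 0/stable with a warning.
* Empty promoter (start codon at the contig edge): empty string plus a
  warning, not an error.
* Local alignments with no positively scoring pair: score 0, empty
  alignment, similarity 0.
* Zero hits in a promoter scan: category percentages reported as 0 with
  a `no_hits` flag rather than NaN.
* UPGMA on non-finite or asymmetric matrices: error; ties broken
  deterministically as above.
* All randomness is seeded; pipeline runs are deterministic given inputs,
  and the run manifest records input hashes, versions and parameters.

## Known limitations

Rule-based domain scanning is stricter than profile HMMs: genuinely
divergent domains (unusual finger spacings, heptapeptide variants beyond
the recorded set) can be missed, which is why the spacings are
configurable. Similarity-based segmental calls cannot distinguish true
segmental duplication from ancient tandem events separated by
rearrangement. NG86 ignores transition/transversion bias and codon
frequencies — at high divergence it saturates (NaN), as the published
tables themselves show. The subgroup assignment is only as good as the
reference set.
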