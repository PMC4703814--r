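---
title: "Methods: MasD marker-gene diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MasD marker-gene diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`masdiv` analyses amplicon surveys of MasD, the catalytic subunit of
(1-methylalkyl)succinate synthase, the glycyl-radical enzyme by which
anaerobic bacteria add n-alkanes to fumarate. A survey of this kind
yields barcoded, pyrosequencing-style reads of a protein-coding gene
fragment from several sediment sites; the analysis must (i) remove
sequencing artefacts aggressively, because errors inflate protein OTU
richness more than they inflate nucleotide OTU richness, (ii) recognise
the target gene among co-amplified paralogues, (iii) cluster protein
fragments at taxonomically calibrated identity thresholds, and (iv)
summarise within-site diversity and between-site structure. The package
implements each step as an exported function and chains them in
`run_pipeline()`.

This vignette documents the modelling choices, tunable parameters, the
synthetic data generator, numerical conventions, and limitations. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` recompute.

# Identity convention

All percent identities use one convention: Needleman–Wunsch global
alignment (BLOSUM62, gap open 10, extend 0.5 for protein; +2/−3, open
5, extend 2 for nucleotide); identity = identical columns / aligned
columns, with terminal gap columns (overhangs) excluded from the
denominator and internal gap columns counted as mismatches. Excluding
overhangs makes identity robust to comparing a partial amplicon with a
full-length reference; counting internal gaps penalises genuine indels.

Two numerical details matter:

- *Gapless fast path.* For an equal-length pair at moderate divergence
  the optimal affine-gap global alignment is gapless (a gap pair costs
  more than any run of mismatches it could avoid), so position-wise
  identity is exact. The implementation uses this shortcut whenever the
  lengths match and the position-wise identity is at least 50 %, and
  falls back to the full alignment otherwise. The oracle tests compare
  the two routes on random sequences.
- *Symmetry.* Alignment tie-breaks depend on argument order, so
  `pairwise_identity()` canonicalises the order (shorter, then
  lexicographically smaller, sequence first) before aligning; symmetry
  is property-tested.

# Synthetic data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline's accuracy claims are made.

`community_spec()` defaults mirror the structure of the original
12-site survey: 12 sites, 420 species-level OTUs, 428 reads per site
(≈ 5,100 quality reads total), lognormal OTU abundances
(meanlog 0, sdlog 2 — uneven communities in which the top OTU holds on
the order of 10 % of reads), `cosmopolitan_fraction = 0.005` (≈ 2 of
420 OTUs present at every site) and `site_overlap = 0.05`, under which
a non-cosmopolitan OTU occupies `1 + Binomial(n_sites − 1, 0.05)`
sites, so roughly `0.95^11 ≈ 57 %` of OTUs are single-site — matching
the dominance of locally restricted OTUs in such surveys.

`error_model()` defaults emulate 454 chemistry: substitutions at
10⁻³/base, indels at 5·10⁻⁴/base outside homopolymers boosted 10× for
bases inside a run of ≥ 3 (the failure mode that motivates the
homopolymer filter), 5 % chimeras, 10 % off-target reads (the share of
NmsA/BssA amplicons from unspecific primer binding was ≈ 12 % in the
original survey), and per-base Phred scores from a truncated normal
(mean 33, sd 4, clamped to [2, 40]). Quality scores and errors are
drawn independently — a documented simplification; the quality filter
therefore removes low-quality reads but not specifically erroneous
ones.

Reads are assembled as barcode + forward primer (a concrete instance of
the degenerate forward primer, so primer matching sees zero mismatches)
+ back-translated coding sequence + reverse-complemented reverse
primer. Back-translation (`back_translate()`) uses a fixed codon table
with seeded uniform synonymous choice (a codon-usage weighting is a
parameter); realizations containing a homopolymer run longer than 8 are
resampled, because the generator emits amplifiable template molecules
while the homopolymer filter targets sequencing artefacts. Chimeras
join two parent reads of the same site at a uniform crossover within
the central 60 % of the read, so both segments remain detectable.

Reference OTUs (`masd_reference_set()`) evolve from a synthetic
180-residue anchor at divergences evenly spaced in [0.05, 0.5];
substitutions never touch the motif or catalytic-cysteine columns. Any
two references then differ by well over the species threshold inside
the analysis region, so an error-free simulation is recoverable exactly
— the property the ground-truth tests assert.

*Anchor.* The real coordinate system (motif ≈ column 435, catalytic
cysteine 477 of the reference strain's MasD) lives in database
sequences that cannot be bundled; the package ships a synthetic,
deterministically generated anchor with the same topology — motif
FECIR at column 41, catalytic Cys at column 83, and a 120-column
analysis region (columns 31–150) mirroring the 120-position clustering
window. All coordinates are parameters of `masd_anchor`, so a real
anchor drops in. Coordinates are 1-based inclusive throughout, the R
convention.

`simulate_strain_pairs()` places strains on a star phylogeny whose
per-strain protein divergence follows the line
`S_prot = a + b·S_16S` evaluated at the strain's realized 16S
divergence. Per-strain substitution sets are disjoint, so pairwise
divergences are exactly additive, and substitution counts use
randomized rounding — both choices prevent quantization from tilting
the fitted slope. Pairwise noise of sd `noise_sd` is induced by
per-strain jitter of sd `noise_sd/√2`; exact independent per-pair noise
is impossible on a star topology (the simulator is star-only by
design). The default ancestor is a 600-residue synthetic full-length
protein: strain-level comparisons use full genes, and the longer
sequence keeps count quantization negligible (at 180 residues a single
substitution is worth 0.6 identity points pairwise, enough to wobble a
fitted slope by a few percent).

# Read quality control

Rules run in a fixed order — primer → length → homopolymer → quality →
ambiguity → chimera — and each read is ledgered under its first failing
rule, so reports are reproducible and counts reconcile. Defaults:
maximum 0 forward-primer mismatches (IUPAC-aware: primer degeneracy
matches its expansion, read ambiguities count as mismatches unless
covered), minimum 200 bp after trimming, maximum homopolymer run 8
(read as run *length*, the amplicon-QC convention), minimum mean Phred
20 over the post-trim read (the prose "average quality" reading), no
ambiguity codes. The reverse primer is not required — fragments may end
before it — but when found it and trailing bases are trimmed before the
length check (a config flag governs this, as the original protocol
leaves it unstated).

## Chimera screen

The screen is a deliberately simplified segment scorer, not a k-mer
chunked search, and is pluggable. Dereplicated sequences are processed
in decreasing abundance (id-lexicographic tie-break); candidate parents
are previously processed, unflagged sequences with ≥ 2× the query's
abundance. At each crossover point on a grid (fractions 0.25–0.75,
step 0.05), the best *distinct* parent pair maximizing the smaller
segment identity is found; the score is that segment identity minus the
best full-length identity to any single parent. A query is flagged when
score > 0.05 and both segments match their parents at ≥ 0.90.

Two defaults deserve justification. The score of a perfect 50/50 join
of parents with mutual identity q against the better parent is
`(1 − s)(1 − q)` for larger-segment share s ∈ [0.5, 0.8], i.e. at most
0.5 and typically 0.05–0.25 — so the flagging threshold must sit low
(0.05). With a threshold that low, finite-length fluctuations of
segment identities between genuinely distinct OTUs would produce a
small false-positive rate; the minimum-segment-identity guard (0.90)
removes those, since a true chimera's segments match their parents
nearly perfectly while a non-chimeric read's best "mosaic" explanation
plateaus near its full-length identity. The grid is denser than a
three-point grid so that true chimeras at off-grid crossovers keep
segment identity above the guard. On spiked simulations the screen
reaches recall ≥ 0.6 at zero measured false positives (property-tested;
recomputed by the acceptance script).

# ORF screening

Reads are translated in the three forward frames only — amplicons are
orientation-fixed by the forward primer (a reverse-complement scan is a
config flag). Frame choice prefers a motif-bearing frame without
internal stops, then a motif-bearing frame, then a stop-free frame,
then frame 0. Motif matching is exact over the six diagnostic motifs;
degenerate motif variants are knowingly missed (about a tenth of
database MasD/AssA proteins carry none of the six at the expected
column). The catalytic-cysteine check aligns the read to the anchor and
inspects the residue aligned to the annotated column; alignments below
25 % identity are "unalignable". Family classification is best-hit
identity against a labelled panel with threshold 0.40 — above the
twilight zone (~0.30), below within-family identity; the original
assignment method is unstated, so this is the package's choice.
Classification aligns panel members below the gapless fast path only
when no length-matched member reaches it: a sub-50 % hit cannot
out-rank a confident best hit. Reads are accepted iff motif ∧ no stop ∧
cysteine ∧ MasD, ledgered by first failure. The glycyl-radical (RVXG)
motif is deliberately *not* checked — it lies outside the amplified
region. No frameshift correction is attempted (the original study fixed
~15 reads manually); such reads fail screening and are ledgered.

# Threshold calibration

`build_pairs()` computes all C(n, 2) pairwise identities;
`fit_threshold_model()` fits OLS (orthogonal regression is offered as a
config alternative; the published figure shows a simple regression
line) and maps the 16S thresholds through the line, rounding to integer
percent and clamping to [0, 100]. Thresholds at the species (98.7 %)
and family (86.5 %) levels map to 96 % and 72 % MasD identity on the
published coupling; the package's synthetic strain panels are generated
on the line through exactly those two anchor points, so genus- and
phylum-level mappings (88 and 49 on the line) deviate from published
readings (86 and 52) that came off a real, imperfectly linear scatter.
With realistic pairwise noise (sd 2 identity points) a single 15-strain
panel determines the extrapolated family threshold only to within a few
points (the slope's standard error is ≈ 0.2 under strain-level noise
correlation), which is why the acceptance script averages mapped
thresholds over 30 replicate panels — the same estimator as the
parameter-recovery property (replicate means within ±2 points).

# OTU clustering

The analysis region is read off the alignment to the anchor (sequences
covering < 80 % of the region are dropped and ledgered), sequences are
dereplicated, distances are `1 − identity/100`, and clustering is
agglomerative with furthest-neighbour linkage by default — the
conservative choice that cannot chain clusters past the identity
threshold; average and nearest linkage are options, and partitions are
oracle-tested against an exhaustive merge implementation. Merging stops
when the minimal inter-cluster linkage exceeds the threshold
(species 0.04, genus 0.14, family 0.28 from the calibrated 96/86/72).
The published "120 amino acid positions (398–500)" is internally
inconsistent (103 positions); the package treats the anchor-column
interval as authoritative and makes both endpoints configuration
values, with the bundled synthetic anchor carrying a 120-column region.
OTU tables order columns by total abundance (OTU1 = most abundant,
ties by first appearance).

Error inflation is real and quantified: under furthest-neighbour
linkage a read whose region carries ≥ 4 amino-acid errors breaks out of
its OTU. At the error model's default substitution rate (10⁻³/base,
≈ 0.5 expected amino-acid changes per 120-column region) breakaways are
rare and recovery stays within ±10 % of truth (property-tested at
3 × 100 reads, 20 OTUs); at 5·10⁻³ the same configuration more than
doubles apparent richness — the quantitative reason the original
filtering is as strict as it is, and the reason absolute published OTU
counts are not reproduction targets.

# Diversity statistics

Definitions as in the README: SSO_abs / SSO_rel singleton taxonomy
(both senses of "locally restricted" — read-count singletons and
single-site occupancy — are implemented as separately named
statistics); Good's coverage `C = (1 − n/N)·100` with
n = SSO_abs + SSO_rel, rounded to integer percent as in the published
table; inverse Simpson in the plug-in form `1/Σp²` by default (clean
bounds [1, S]; the small-sample form is a switch and is undefined for a
single read — absolute 1/D values are toolchain-dependent and not an
acceptance surface); closed-form hypergeometric rarefaction computed in
log space and oracle-tested against Monte-Carlo subsampling; seeded
single-draw subsampling to the smallest per-site count by default (a
mean over repeated draws is an option). Occupancy classification uses
≥ 10 of 12 sites for "cosmopolitan" and exactly 1 for "locally
restricted".

One published per-site row (AMV760) is internally inconsistent — its
printed singleton percentages imply coverage 86, not the printed 89 —
and is excluded from the coverage reproduction (the other six
reproducible sites are checked exactly).

# Community structure

Bray–Curtis through `vegan::vegdist`; NMDS through `vegan::monoMDS`
under an explicit best-of-n-starts wrapper (first start metric scaling,
the rest random, all seeded) so that stress is non-increasing in the
number of starts by construction, with 20 starts and the < 0.2 stress
adequacy convention as defaults; Ward through
`hclust(method = "ward.D2")` — the squared-dissimilarity convention
that minimizes within-cluster variance (`ward.D` is a switch) — and
oracle-tested against a naive Lance–Williams implementation; shared-OTU
percentages use the Jaccard denominator (the published denominator is
unstated; intersection/min-richness is a config alternative; neither is
an acceptance surface); hierarchical clustering accepts either
Bray–Curtis or a co-occurrence-derived input, as the published use is
ambiguous between them. The presence-absence network is bipartite
(site and OTU nodes) with seeded Fruchterman–Reingold layout; sites
sharing many OTUs end up close through their shared OTU nodes
(property-tested over 100 seeded layouts). Plotting itself is out of
scope — coordinates, trees and matrices are returned/emitted for
external visualization.

# Pipeline, seeds and problem sizes

`run_pipeline()` executes simulate (or ingest) → demultiplex/QC →
screen → cluster → diversity → community with a manifest whose counts
reconcile at every stage; with an output directory it writes stage
files and md5 checksums, and a rerun under the same configuration is
bit-identical (the "resume" notion reduces to deterministic
re-execution, which is cheap at these scales). All stochastic stages
derive their seeds from one master seed.

Tests and the acceptance script run deliberately scaled-down problems
chosen as the smallest sizes at which each property is
non-trivial: 3–4 sites × 60–100 reads for recovery (uniform
abundances and full site overlap, so that every reference OTU is
actually sequenced and "recovers exactly n_otus" is well-posed),
3 × 200 reads with 10 % chimeras for screen performance, 15-strain
panels (105 pairs) for calibration, and n ≤ 10 matrices for clustering
oracles. The full 12-site, 420-OTU default is generated and analysed
identically, just not inside the routine test budget.

# Known limitations

- No flowgram-level 454 simulation, no quality–error coupling, no
  phylogenetic tree simulation beyond the star topology; no
  phylogenetic tree reconstruction, probe design, or FISH-related
  functionality (out of scope by design).
- The chimera screen is a simplified scorer with the same contract as,
  but not the algorithm of, reference chimera detectors; it assumes
  abundant, well-separated parents.
- Exact-motif screening loses genuinely divergent MasD variants.
- Synthetic anchors and panels reproduce the statistical structure of
  the survey, not its biology: passing tests demonstrate correctness of
  the machinery and its behaviour under the modelled error processes,
  not agreement with any particular environmental dataset.
- Absolute OTU counts from real data depend on the upstream denoising
  and the clustering linkage of the toolchain used; only
  threshold-calibrated, property-level statements transfer.
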