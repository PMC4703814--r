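# masdiv

Diversity analysis of **MasD**, the catalytic subunit of
(1-methylalkyl)succinate synthase (alkylsuccinate synthase) — the
glycyl-radical enzyme with which anaerobic bacteria activate n-alkanes by
addition to fumarate. Marine hydrocarbon seeps host diverse communities
of such alkane degraders, and `masD`/`assA` amplicon surveys are the
standard way to census them. This package implements the complete
analysis chain for such functional-gene surveys, for microbial ecologists
who want to analyse (or simulate and stress-test) protein-coding marker
amplicons rather than 16S rRNA tags:

- **Simulation** (`generate_dataset()`): multi-site communities of
  motif-bearing protein-coding OTUs with lognormal abundances, barcoded
  pyrosequencing-style reads, homopolymer-biased indels, PCR chimeras,
  off-target (NmsA/BssA-like) spikes, and a complete per-read truth
  table.
- **Read QC** (`filter_reads()`): the stringent amplicon filter cascade —
  no forward-primer mismatch, ≥ 200 bp, homopolymer runs ≤ 8, mean
  Phred ≥ 20, no ambiguities — plus a simplified de novo chimera screen
  over dereplicated reads (`detect_chimeras()`).
- **ORF screening** (`screen_reads()`): three-frame translation, search
  for the six diagnostic motifs (FECIR, FECIK, FECQR, FECVR, FDCIR,
  FDNIA), stop-codon rejection, catalytic-cysteine check against an
  annotated anchor, and family classification (MasD / NmsA / BssA / Pfl)
  against a labelled reference panel.
- **Threshold calibration** (`fit_threshold_model()`): protein OTU
  identity cut-offs derived by ordinary least squares of pairwise MasD
  amino-acid identity on pairwise 16S rRNA identity across cultivated
  alkane-degrading strains,

  `S_prot = a + b · S_16S`,

  evaluated at the canonical 16S thresholds (species 98.7 %, genus
  94.5 %, family 86.5 %, phylum 75 %). The species level maps to ~96 %
  MasD identity and the family level to ~72 %.
- **OTU clustering** (`cluster_otus()`): global-alignment percent
  identity over a 120-column anchor region, distance `d = 1 − S/100`,
  furthest-neighbour agglomerative clustering at calibrated thresholds
  (species 0.04, genus 0.14*, family 0.28).
- **Diversity statistics** (`diversity_report()`): per-site reads N,
  richness, absolute and relative single-sequence OTUs (SSO_abs: one
  read in the whole dataset; SSO_rel: one read here, more elsewhere),
  Good's coverage `C = (1 − n/N)·100` with n = SSO_abs + SSO_rel,
  inverse Simpson `1/D = 1/Σ p_i²`, closed-form rarefaction
  `E[S_m] = S − Σ_i C(N−n_i, m)/C(N, m)`, seeded subsampling, and
  occupancy classes (cosmopolitan: ≥ 10 of 12 sites; locally
  restricted: exactly 1).
- **Community structure** (`bray_curtis()`, `nmds_ordination()`,
  `ward_cluster()`, `cooccurrence()`, `layout_network()`): Bray–Curtis
  dissimilarities, 2-D NMDS (best of 20 seeded starts, Kruskal
  stress-1), Ward clustering (`ward.D2`), shared-OTU fractions,
  co-occurrence counts, and a Fruchterman–Reingold layout of the
  site–OTU presence-absence network.

`run_pipeline()` chains all stages from one configuration with
reconciling per-stage ledgers and bit-reproducible seeded output.

Because the original strain and read data live behind sequence-archive
accessions, the package ships *synthetic* stand-ins (a deterministic
anchor protein, reference panel, and strain simulator) that reproduce
the statistical structure of the survey; accession metadata for the real
strain panel is included under `inst/extdata/alkane_strain_accessions.tsv`.

## Worked example

Simulate a clean four-site community with 12 reference OTUs, run the
full pipeline, and calibrate thresholds from a simulated strain panel:

```r
library(masdiv)

spec <- community_spec(n_sites = 4, n_otus = 12, reads_per_site = 80,
                       abundance_model = "uniform",
                       cosmopolitan_fraction = 1, seed = 2)
res <- run_pipeline(pipeline_config(spec = spec,
                                    error = error_model_clean(),
                                    references = masd_reference_set(12),
                                    nmds_starts = 5, seed = 9))
res
#> MasD diversity pipeline
#>   reads in:         320
#>   QC pass:          320
#>   MasD accepted:    320
#>   OTUs (species):   12  (threshold 0.04)
#>   NMDS stress:      0.0000

res$diversity
#>  site  N S_obs sso_abs sso_rel coverage inv_simpson S_subsampled
#>   S01 80    12       0       2       98        9.47           12
#>   S02 80    12       0       0      100        9.85           12
#>   S03 80    12       0       0      100        9.52           12
#>   S04 80    12       0       0      100        9.73           12

st <- simulate_strain_pairs(strain_pair_spec(noise_sd = 0, seed = 1))
fit_threshold_model(build_pairs(st))
#> Protein/16S identity calibration (105 pairs)
#>   sprot = -99.901 + 1.985 * s16   (R^2 = 0.999)
#>   mapped thresholds (% protein identity):
#>     species  16S  98.7% -> 96%
#>     genus    16S  94.5% -> 88%
#>     family   16S  86.5% -> 72%
#>     phylum   16S  75.0% -> 49%
```

Every error-free read survives QC and screening, the clustering recovers
exactly the 12 simulated OTUs at the species threshold, each site's
coverage and inverse Simpson reflect the even 12-OTU community, and the
calibration maps the 16S species and family levels to 96 % and 72 %
MasD identity.

*The genus value printed by the example (88) comes from evaluating the
fitted line at 94.5 %; published genus/phylum values were read off a
real, imperfectly linear scatter, so only the species and family
anchors are reproduced by construction.

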