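# oligoscope

Sub-OTU **oligotyping** and microdiversity ecology for aligned 16S rRNA
amplicons, built for two-transect spatial sampling designs such as deep-sea
sediment observatories.

Organisms whose 16S genes are ≥97% identical end up in one OTU, yet can
occupy distinct niches. `oligoscope` decomposes each OTU's alignment into
*oligotypes* — sub-OTU groups defined by the characters reads carry at
high-entropy alignment positions — and then asks what those oligotypes do
ecologically:

* **Decomposition** — recursively split read groups at the leftmost
  alignment position maximising base-2 Shannon entropy
  `H = −Σ f_c log₂ f_c` over `{A,C,G,T,-}`, while a group has ≥ 21
  sequences and max entropy > 0.6 bits (one alternative character per six
  dominant ones); only OTUs with > 100 reads are decomposed; reads with
  missing coverage (`.`) at a discriminant position are set aside, and
  absolute singletons are removed.
* **Screening** — per OTU, mean pairwise checkerboard
  `C = (r_i − S)(r_j − S)` and togetherness `T = S·A` scores of the
  oligotype presence matrix; OTUs strictly exceeding the third quartile of
  both score distributions carry candidate "resolving" oligotypes.
* **Constrained ordination** — redundancy analysis (vegan) of
  Hellinger-transformed oligotype matrices on z-scored environmental and
  spatial variables (protein, CPE pigment, easting, northing, depth,
  porosity), with double-stopping forward selection, permutation tests,
  Benjamini–Hochberg correction, VIF < 10 checks, and a
  \>50%-constrained-variation filter.
* **Association networks** — Whittaker's index of association
  `IA = 100 − ½ Σ|p_s − q_s|` between percentage-scaled profiles, a
  200-permutation null with BH correction, edges at IA > 85 and adjusted
  p < 0.05, closed-form network statistics, and Markov clustering
  (inflation 2.5) on edge weights rescaled from [85, 100] to
  [0.001, 0.15].
* **Synthetic communities** — a generator emulating 13 sites on two
  intersecting transects (bathymetric 1284–3535 m; latitudinal at
  ~2500 m), planting sub-populations with depth/CPE-linked, checkerboard,
  aggregated or neutral site profiles and per-base sequencing error, with
  full ground truth for parameter-recovery validation.

## Worked example

The `analysis/` directory holds the staged workflow
(`01_simulate.R` … `05_network.R`), each a thin driver over the package
functions that prints what it found and writes tables under `results/`.
A 30-OTU run (55,028 reads, seed 20260923) prints, in order:

```
oligotyped 30 OTUs into 122 oligotypes (8 singletons removed, 0 reads set aside as incomplete)
oligotypes per OTU: min 1, median 4, max 5

scored 29 OTU matrices; Q3(C) = 7.10, Q3(T) = 14.40
3 OTUs exceed both quartiles (candidate resolving oligotypes)

9 models exceed 50% constrained variation at adjusted p < 0.05:
 otu_id                 class n_oligotypes   formula constrained_pct
 OTU002        Acidimicrobiia            4   Y ~ cpe              90
 OTU016      Planctomycetacia            4 Y ~ depth              57
 ...
max VIF across selected models: 1.00 (all < 10: TRUE)

network: 122 nodes, 203 edges, 58 connected components (largest 18)
density 0.028, clustering coefficient 0.35, heterogeneity 1.30, centralization 0.11, mean neighbors 3.33
MCL (inflation 2.5, 10 iterations): 59 clusters
```

Read: the entropy decomposition resolved each OTU into its planted
sub-populations; the quartile screen flags the OTUs whose oligotypes
partition and aggregate across sites; forward-selected RDA models recover
the depth/CPE gradients that generated the abundances (constrained
percentages are the share of each matrix's variance the model explains);
and the IA network links proportionally co-varying oligotypes across OTU
boundaries, which Markov clustering cuts into co-occurrence guilds.

The same machinery runs end-to-end via `run_pipeline(run_config(...))`,
which writes per-stage TSV/JSON/GraphML outputs plus a manifest with
read-conservation accounting, and is byte-identical across runs with the
same seed.

## Scope

No OTU clustering, taxonomy assignment, chimera handling, denoising or
flowgram error modelling; no CCA/partial RDA; no abundance-weighted C/T
variants; no force-directed layout (GraphML export is provided for
external visualization). See the methods vignette
(`vignettes/oligotype-microdiversity.Rmd`) for the models, parameter
choices and known limitations.
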