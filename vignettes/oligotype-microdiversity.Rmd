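---
title: "Sub-OTU oligotyping and microdiversity ecology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-OTU oligotyping and microdiversity ecology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscope)
```

## The problem

Clustering 16S rRNA amplicons into operational taxonomic units (OTUs) at 97%
identity hides variation that can matter ecologically: organisms whose 16S
sequences differ at one or a few positions may occupy distinct niches.
`oligoscope` implements an entropy-based decomposition of per-OTU alignments
into *oligotypes* — sub-OTU groups defined by the characters reads carry at
high-information alignment positions — and a downstream ecology toolkit that
asks three questions of the resulting oligotype × site count matrices:

1. Do an OTU's oligotypes partition sites (checkerboard patterns) or travel
   together (aggregation)?
2. Are oligotype abundances structured by environmental or spatial gradients?
3. Which oligotypes co-occur across OTU boundaries, and how does the resulting
   association network decompose into clusters?

The package targets the sampling design of a deep-sea sediment observatory
with two intersecting transects — a bathymetric transect spanning roughly
1300–3500 m water depth and a latitudinal transect running at ~2500 m — and
ships a synthetic community generator emulating that design, so every stage
can be validated against planted ground truth.

## Entropy decomposition

For an alignment column, Shannon entropy is computed in bits over the
characters `{A, C, G, T, -}` after excluding missing-coverage marks (`.`):

$$H = -\sum_c f_c \log_2 f_c .$$

`decompose()` recursively splits a read group at the leftmost
maximum-entropy position whenever the group holds at least 21 sequences and
the maximum entropy exceeds 0.6 bits; groups failing either threshold are
terminal oligotypes, labelled by the characters at their ancestral
discriminant positions. Only OTUs with more than 100 reads are decomposed.

The 0.6-bit threshold corresponds to one alternative character per six
instances of the dominant character (dominant fraction 85.7%); in a binary
column the exact entropy at that ratio is 0.5917 bits, conventionally
rounded to 0.6. Lower thresholds increasingly promote sequencing errors to
oligotypes; higher ones lose sensitivity. The tie rule (leftmost position,
one position per round) is a reproducibility choice: recursion achieves
multi-position discrimination regardless of whether tied positions are
taken singly or jointly.

Two coverage conventions are distinguished deliberately: `-` is an internal
alignment gap and a legitimate oligotype character, while `.` marks missing
terminal coverage. Reads with `.` at a discriminant position are set aside
at that split; `drop_incomplete()` then either retains an oligotype's
complete reads (default) or removes the oligotype wholesale
(`remove_mixed = TRUE`) — the stricter reading of removing oligotypes
"derived from an incomplete alignment". The default was chosen because it
preserves information whenever any complete read witnesses the oligotype,
and conservation is then exact: reads in = reads in oligotypes + reads set
aside. Absolute singletons (one read in the whole dataset) are removed from
count tables before any downstream analysis.

## Screening for resolving oligotypes

Presence/absence structure is scored per OTU by the mean pairwise
checkerboard score $C_{ij} = (r_i - S_{ij})(r_j - S_{ij})$ and togetherness
score $T_{ij} = S_{ij} A_{ij}$, where $r$ counts occupied sites, $S$ jointly
occupied sites and $A$ jointly empty sites. These are raw unit counts —
numbers of 2×2 checkerboard submatrices and of jointly-present/jointly-absent
site pairs — not normalized indices, so they are comparable with published
matrix-level averages. OTUs whose mean C **and** mean T strictly exceed the
third quartiles of the respective distributions over all scored OTUs are
flagged as carrying "resolving" oligotypes. The quartile uses the common
linear-interpolation definition (type 7); presence is `count > 0` on raw
counts, since the scores are binary by construction — the Hellinger
transform enters only for heatmap ordering (`order_rows()`: UPGMA on
Bray–Curtis dissimilarities) and for ordination.

## Constrained ordination

Oligotype counts (sites as objects) are Hellinger-transformed and related to
z-scored environmental/spatial variables by redundancy analysis (vegan's
RDA). Forward selection follows the double-stopping rule: the global model
holding all candidates must pass a permutation test at $\alpha = 0.05$, and
variables are then added greedily by explained-variance gain, each addition
requiring a marginal permutation p-value (conditioning on the selected set)
at or below $\alpha$ and the cumulative adjusted $R^2$ not to exceed the
global model's. One deliberate refinement: the adjusted-$R^2$ cap is
enforced from the second variable onward. When a single variable carries
most of the signal, the single-variable adjusted $R^2$ and the global
adjusted $R^2$ estimate the same quantity, so the former exceeds the latter
by sampling noise about half the time; capping the first step would
therefore void the procedure's power exactly in the clearest cases, while
the global significance gate already protects that step.

Permutation tests use 999 permutations by default with the add-one
convention ($p_{\min} = 1/1000$). Every analysed OTU contributes one final
model p-value to the Benjamini–Hochberg family (the selected model's where
selection is non-empty, the global model's otherwise). Reported models must
exceed 50% constrained variation with adjusted $p < 0.05$, and variance
inflation factors are checked against the conventional threshold of 10.
The default candidate set is {protein, CPE, easting, northing, depth,
porosity}; porosity is included because depth-linked sediment porosity is a
standard covariate in this setting, and the set is configurable where a
narrower design is wanted.

## Association networks

Pairwise association between oligotype profiles uses Whittaker's index of
association on percentage-scaled profiles,

$$IA = 100 - \tfrac12 \sum_s |p_s - q_s|,$$

so proportional profiles score 100 and disjoint ones 0. Significance comes
from independently permuting the site order within every profile (200
permutations by default) and recomputing all pairwise IA values. The
probability of an observed IA given the permuted values is estimated by the
plug-in proportion `hits / n_perm`, which can reach exactly zero. This
choice is structural, not cosmetic: with the conservative add-one estimator
the smallest attainable p-value at 200 permutations is 1/201 ≈ 0.005, and
under Benjamini–Hochberg correction over all node pairs such a p-value is
significant at 0.05 only if about 10% of *all* pairs attain it — so
essentially no network could ever have edges. The add-one estimator remains
available (`convention = "add-one"`) for users who prefer it and accept the
consequence. Edges require IA > 85 and adjusted p < 0.05; nodes require
total abundance ≥ 2 (absolute singletons are already gone).

Network statistics use fixed closed forms: density $2E/N(N-1)$, mean local
clustering coefficient with degree-<2 nodes contributing zero, degree
heterogeneity $\mathrm{sd}(k)/\bar k$, degree centralization
$\frac{N}{N-2}(k_{\max}/(N-1) - \text{density})$, and a least-squares
power-law fit of the raw degree histogram on log–log axes (approximate by
construction; no heavy-tail hypothesis test is attempted).

Markov clustering runs on edge weights linearly rescaled from IA ∈ [85, 100]
to [0.001, 0.15] (an increasing map — stronger association, more flow), with
self-loops set to each node's maximum incident weight, inflation 2.5,
pruning at $10^{-5}$, and convergence declared at a maximum entry change
below $10^{-8}$. Attractor rows whose supports overlap are merged through
connected components; nodes attracted by several attractors resolve to the
heaviest, so the output is always a partition.

## The synthetic community generator

`generate_env_table()` draws the two-transect design: monotone depth along
the bathymetric transect (1284–3535 m), near-constant ~2500 m depth along
the latitudinal transect, one shared central site, CPE pigment declining
with depth by construction (a phytodetritus proxy; r ≤ −0.6), porosity
weakly depth-linked, protein tracking CPE, and UTM coordinates inside the
observatory's ranges.

`generate_community()` plants, per OTU, 1–5 sub-populations distinguished
by unique characters (including `-`) at up to five interior alignment
positions. Sub-population weights get a floor of $1/2s$, which keeps every
variant column's minority fraction well above the 1:6 detectability limit
of the 0.6-bit threshold, so error-free recovery of the planted partition
is an honest expectation rather than an accident of seeds. Per-site counts
are Poisson around scenario-defined expectations:

* `depth_linear` / `cpe_linked` — expectation $\propto \exp(b\,z)$ with
  slopes $|b| \in [0.8, 1.4]$ of alternating sign per sub-population, the
  log-linear niche response RDA is designed to detect;
* `checkerboard_pair` — two blocks of sub-populations on disjoint site
  supports (about a third of sites each, the rest empty), giving high
  cross-block C scores and, with more than two sub-populations, high
  within-block T scores;
* `aggregated_block` — all sub-populations share one support block;
* `neutral` — uniform expectations.

The default scenario mix is 40% neutral, 20% depth, 10% CPE, 15%
checkerboard, 15% aggregated — most microdiversity unstructured, a minority
strongly patterned, which is what the screening and ordination stages are
built to detect. Total reads per OTU are drawn from [100, 3000]; read
length defaults to 400 bases; sequencing error substitutes each base
independently at rate 0.001, uniformly over the three alternatives, never
touching gaps or missing coverage; 5% of reads carry a terminal `.` stretch
of up to 10 positions (variant positions are kept clear of the termini, so
incomplete coverage exercises the bookkeeping without destroying planted
structure). A per-site effort multiplier is exposed rather than a guessed
uneven read-depth distribution.

What the generator does **not** emulate: chimeras, quality scores,
homopolymer/flowgram error structure, phylogenetically correlated base
composition, compositional coupling between OTUs, or realistic taxon
abundance distributions. Passing recovery tests therefore demonstrates the
correctness of the algorithms under the stated statistical assumptions, not
performance on raw pyrosequencing data.

## Problem sizes and numerical choices

The validation suite runs, as the package's own choice of scale: a 50-OTU
default-design community for partition recovery (pooled adjusted Rand index;
1.0 error-free, ≥ 0.95 at error rate 0.001); 100 random 8 × 13 presence
matrices for exact C/T oracle agreement; 200 depth-structured and 200
pure-noise responses for forward-selection operating rates (199 permutations
inside the loops — enough to resolve $\alpha = 0.05$); 100 independent
random tables for the IA null's false-edge control; a 20-node, 4-block
graph for MCL against an independently coded reference iteration; and a
12-OTU end-to-end run, twice, for byte-identical determinism. Degenerate
inputs are contracts, not afterthoughts: empty columns after `.` removal,
zero-total profiles, constant environmental columns, rank-deficient
explanatory matrices and sub-minimum designs all raise informative errors.

## Known limitations

* One position per decomposition round; joint selection of tied positions is
  not implemented (equivalent in the limit, but labels can differ).
* The C/T screen is binary and blind to abundance differences among
  co-occurring oligotypes; abundance-weighted variants are out of scope.
* The power-law fit is descriptive least squares, not a maximum-likelihood
  tail estimate.
* The permutation null for IA treats sites as exchangeable; spatial
  autocorrelation along the transects is not preserved by the shuffle.
* No chimera handling, OTU clustering, taxonomy assignment, or supervised
  refinement of oligotype sets.
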