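---
title: "Inferring biogeochemical cycle couplings from function-taxon networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring biogeochemical cycle couplings from function-taxon networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biogeonet)
```

## The inference problem

Microbial taxa whose genomes carry biomarker genes for processes of two
different element cycles (C, N, P, S, Fe) are candidate drivers of the
*coupling* of those cycles. Given metagenomic contigs that carry both a
functional annotation (KEGG KO or Pfam accession) and a taxonomic
assignment, the evidence for such coupling is relational: a contig links one
pathway to one taxon, and pooling these links over a survey yields a
weighted bipartite graph between pathways and taxa. Community structure in
that graph — modules containing pathways of several cycles together with
shared taxa — is the signal this package extracts. Everything upstream
(assembly, gene prediction, HMM/KO annotation, taxonomic classification) is
out of scope: the input contract is a plain TSV of per-contig annotations.

## The marker catalog

A pathway is represented by exactly one biomarker gene, chosen in the
literature as its rate-limiting step. The built-in catalog carries:

* the P-cycle markers (acid phosphatase PF03767, alkaline phosphatase
  K01077, phytase K01083, oxidative phosphorylation K00937, substrate
  phosphorylation K08483, polyphosphatase PF00719),
* the Fe-cycle markers (ferrous oxidation PF00210, ferric reduction
  PF01794),
* six pathways whose KO markers are routinely replaced by an equivalent
  Pfam family when the KO is not recovered across all samples of a survey
  (methanogenesis K14084→PF06253, N₂ fixation K02588→PF00142,
  ammonification K05904→PF01077, S oxidation K17227→PF08770, dissimilatory
  sulfate reduction K00394→PF13187, polysulfide reduction K08352→PF14589).
  The replacement map is applied at profiling time, so contigs annotated
  with the original KO are counted for the substitute's pathway.

The remaining C/N/S pathways are identified in the literature only by gene
symbol (coxL, LDH, KorB, PRK, glnA, ccoN, narG, norB, modA, GDH2, sseA, …).
Their accessions are **deliberately not invented**: they ship as
`UNSET:<symbol>` placeholders that profiling never matches, and a
user-supplied catalog TSV (merged over the built-in by pathway name,
case-insensitively) must provide them before real data can be profiled.
A wrong accession would silently miscount contigs; a refused match fails
loudly. Two labels in the catalog follow their source's usage rather than
textbook convention (narG listed under "nitrite oxidation", ccoN under
"anammox"); users can override both via the catalog file.

## Profiling conventions

* **Denominator.** Pathway proportions divide by *all* contigs of a sample,
  not by marker-bearing contigs, matching the "% of all contigs" observable
  used in survey reports. Pooled proportions divide summed counts by summed
  totals, which differs from the mean of per-sample proportions when depths
  differ — both are exposed.
* **Multi-marker contigs** count once per distinct pathway, once only for
  several markers of the same pathway.
* **Aggregation rank** defaults to genus (driver taxa are conventionally
  reported at genus level); any rank from kingdom to genus is accepted.
  Contigs unassigned at the chosen rank are tallied per pathway but never
  enter the network.
* **Pooling.** Function-taxon weights are pooled over all samples — the
  survey produces one network, not one per sample.

## Gradient statistics

Diversity uses Shannon H′ in natural log units (the base is a convention;
nats make the uniform k-vector score ln k) and richness as the count of
observed pathways. Community dissimilarity is Bray–Curtis (via
`vegan::vegdist`), ordinated by classical PCoA. The PCoA is computed from
the eigendecomposition of the double-centred −D²/2 matrix; negative
eigenvalues (non-Euclidean D) are reported but excluded from both the axes
and the relative-eigenvalue denominator, and no Lingoes/Cailliez correction
is applied — users see the spectrum and can judge distortion. Axes are
oriented so the first nonzero loading is positive, making coordinates
reproducible across platforms.

Geographic distances are haversine great-circle distances with Earth radius
6371 km. Distance-decay regresses similarity (1 − Bray–Curtis) on distance
over the unfolded upper triangle. MRM regresses a response distance
triangle on predictor triangles by OLS. For both, inference is by Mantel
permutation: rows and columns of the *response* matrix are permuted
jointly, the statistic (|slope|, |coefficient|, R²) recomputed, and the
p-value taken with the add-one rule p = (1 + #exceedances)/(1 + n_perm),
so p ∈ (0, 1] and can never be zero. 999 permutations is the default; the
permutation stream is owned by an explicit seed and never touches the
caller's RNG state.

Latitude trends fit a Gaussian GLM (identity link — equivalent to OLS,
chosen because proportions here are far from the 0/1 boundaries where a
binomial family would matter) per pathway and flag two-sided p < 0.05.
Raw p-values are the flagging criterion; a Benjamini–Hochberg column is
included for transparency but not used for flagging, matching the
convention of flagging at raw P < 0.05 in gradient surveys. Spearman
gene–environment correlations use midranks for ties and the t
approximation for p-values.

## The network model and its optimisation

The bipartite graph is scored with ordinary weighted Newman modularity with
a resolution parameter γ (default 1), treating the graph as a plain
undirected weighted graph. This matches the behaviour of general-purpose
network tools used in practice for such networks; Barber's
bipartite-specific null model is a documented alternative, not implemented.
Edge weights are pooled contig counts by default (presence/absence behind a
flag); since modularity is invariant to scaling all weights, the choice
affects results only through relative weighting. The minimum edge weight
defaults to 1, i.e. no filtering.

Optimisation is exact for graphs of at most 8 nodes: all set partitions
(Bell(8) = 4140) are enumerated. This is not a luxury — single-node local
search, in any variant we examined, has inescapable local optima on tiny
graphs (on the 6-node path, reaching the optimum from the natural
three-pair partition requires an intermediate move that *lowers* Q, so
Louvain- and Leiden-style movers both stall at Q = 0.26 instead of 0.30 in
most runs). Above 8 nodes a seeded multilevel optimiser runs: local moves
in a seed-shuffled visit order with ties broken toward the lowest module
id, aggregation of communities into supernodes, and — the important
addition — refinement sweeps back at the original node level, iterated
until Q stops improving, with five restarts on derived seeds keeping the
best Q. On planted-partition benchmarks this matches the modularity reached
by reference implementations of Leiden. Results are deterministic given the
seed; module ids are renumbered by decreasing module size.

A module couples two cycles when it contains pathway nodes of both; driver
taxa for a coupling are the module's taxa adjacent, within the module's
induced subgraph, to at least one pathway of each cycle. The report is a
pure function of (partition, graph, catalog) and independent of node order.

## The synthetic transect

The generator emulates the statistical structure the analysis assumes,
with defaults fixed at the survey design it mimics:

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 45 | sites along the transect |
| `lat_range` | 18–48 °N | transect extent |
| `ph0`, `ph_beta` | 4.5, 5/30 per ° | pH rises ~5 units across the transect |
| `sigma_ph` | 0.25 | pH noise (pH units) |
| `n_modules` | 8 | planted function-taxon modules |
| `functions_per_module` | 2 | 16 pathways, cycles assigned round-robin |
| `taxa_per_module` | 6 | 48 taxa |
| `contigs_per_sample` | 5000 | fixed depth N_s |
| `marker_fraction` | 0.5 | contigs carrying any marker |
| slopes b_f | ±log 2/30, 0 | a third double, a third halve, a third flat |
| `eps_out` | 0.05 | out-of-module taxon emission |
| `rho_assign` | 0.7 | genus assignment probability |

Marker counts per sample are multinomial with probabilities ∝
exp(a_f + b_f·lat) over a *fixed* per-sample depth, so proportions are
exactly comparable across samples — the natural model for a "% of all
contigs" observable (per-pathway Poisson would add depth variation the
statistics would then have to undo). A marker contig's taxon comes from its
pathway's planted module with probability 1 − ε_out, else uniformly from
all taxa; its genus is withheld with probability 1 − ρ. Latitude jitter is
uniform ±0.3°; longitudes lie on a smooth arc and matter only to the
haversine tests. Synthetic accessions use a reserved `SYN#####` space that
cannot collide with real KO/Pfam ids, and the generator returns its own
matching catalog plus a `planted_truth()` object (module map, slopes) for
recovery scoring.

Because pathway counts are compositional (they share a fixed multinomial
total), planting nonzero slopes on some pathways induces genuine opposite
trends in the proportions of the zero-slope ones. Type-I error of the trend
test is therefore assessed under the all-slopes-zero configuration, where
the test is calibrated; under the default mixed-slope configuration most
pathways genuinely trend and are flagged.

What the generator does **not** emulate: sequence-level artefacts (chimeric
contigs, coverage-dependent assembly bias), per-sample depth variation,
phylogenetically structured taxon abundances, or spatial autocorrelation
beyond the latitude gradient. Passing the recovery tests therefore shows
the chain is correct on data satisfying its own assumptions, not that those
assumptions hold for any real survey.

## Numerical choices and degenerate inputs

* Distance matrices must be symmetric within 1e-12 with an exactly zero
  diagonal; label mismatches are errors, not silent reordering.
* An all-zero abundance row is an error naming the sample (its Bray–Curtis
  distances are undefined).
* A pathway with zero marker contigs has a *missing* assignment rate, not
  zero; a sample with zero contigs has missing proportions.
* Modularity of an empty-weight graph is defined as 0; gain ties during
  local moves break toward the lowest candidate module id; Q comparisons
  use a 1e-12 slack.
* PCoA eigenvalues are thresholded at a relative 1e-10 to separate genuine
  positive eigenvalues from numerical zeros; requesting more axes than
  exist returns fewer with a warning.
* All randomness (permutations, generator draws, optimiser visit orders) is
  scoped: functions take an explicit seed and restore the caller's RNG
  state.

## Problem sizes used by the test suite

The suite checks exhaustive-oracle agreement on graphs up to 8 nodes
(brute force over all partitions); planted-partition recovery on 20-seed
ensembles of the K = 4, 16-function, 40-taxon benchmark; noise degradation
through the full generator at 15 samples × 1000 contigs over 20 seeds per
noise level; permutation calibration with 200 null replicates at 199
permutations; trend type-I/power at the full 45-sample, 5000-contig design
over 100 and 50 seeds using the generator's count-level fast path; and full
end-to-end reproducibility on the default 45 × 5000 configuration. These
sizes were chosen to make each property measurable with comfortable
statistical margins while keeping the suite quick to run.

On the K = 4 planted-partition benchmark one caveat is worth recording: at
within-block density 0.5 roughly a quarter of taxa have at most one
within-module edge, and the *global optimum* of modularity then genuinely
disagrees with the planted labels on a few nodes — in most seeds the
optimiser finds partitions with Q strictly above the planted partition's Q.
Mean adjusted Rand against the truth plateaus near 0.92 for any
modularity-maximising method at these densities; perfect recovery is only
observed at lower noise (e.g. the ε_out = 0 end of the degradation study,
where recovery is exact).

## Known limitations

* Couplings are co-membership evidence, not demonstrated metabolic
  interactions; spatially or temporally separated couplings between
  *different* taxa are invisible to this design.
* Modules carry no significance measure (none is standard for modularity
  partitions); stability under the seed and resolution is the practical
  check.
* The MRM predictor set is whatever numeric metadata the user supplies;
  collinear predictors are rejected rather than regularised.
* The built-in catalog is intentionally incomplete (placeholder accessions)
  until completed from a user's marker table.
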