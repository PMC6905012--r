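---
title: "Multi-analyte correlation network analysis: model, conventions, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-analyte correlation network analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macna)
```

## The analysis model

`macna` implements correlation-based network analysis (CNA) for small
case–control panels that measure continuous biomarkers across several
*variable groups* — typically anthropometric measures, metabolic measures,
immune cell abundance scores, serum cytokine concentrations and gut
microbial genus abundances. The model is deliberately simple:

1. **Complete-case exclusion at the biomarker level.** Any biomarker column
   with a missing measurement is removed entirely before correlation, so
   every retained pair shares one common sample size $n$. Samples are never
   dropped. The measured roster of each group is retained even for excluded
   biomarkers, because it is the default denominator universe for density.
2. **Pairwise Pearson correlation** $\rho_{ij}$ of every biomarker with
   every other biomarker, across group boundaries, on the analysed scale
   (apply `log_transform()` first when the data are log-scale by
   convention).
3. **Hard thresholding.** An edge exists iff $|\rho_{ij}| \ge \rho_0$ with
   $\rho_0 = 0.7$ by default. In a panel of $n \approx 11$–$12$ samples a
   high magnitude cut-off substitutes for significance testing; no p-values
   are attached or corrected. The comparison is *inclusive*: in the study
   regime this package targets, coefficients printed exactly at the
   threshold (0.70) appear as network edges, which a strict rule would
   drop. A strictness flag flips the behaviour.
4. **Network metrics.** Node degree; normalized betweenness centrality
   $bc(v) = \frac{2}{(m-1)(m-2)} \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$
   over the $m$ nodes of the graph being scored, with unweighted shortest
   paths ($|\rho|$ is never a distance) and fractional credit over all
   shortest paths; per-group density
   $\text{edges} / \binom{\text{universe}}{2}$; hubs are the nodes with
   $bc > 0.1$ (strictly greater; degree is reported but not part of the
   rule).
5. **Group-level collapse.** Cross-group biomarker edges between a pair of
   variable groups are rendered as a single connector, whatever their
   number; within-group counts are tallied per group.
6. **Cohort comparison.** The pipeline runs per cohort; the report
   enumerates total edge counts, cohort-specific edges, connectors present
   in one cohort and absent in the other, and hub overlap. Unpaired t-tests
   (per biomarker, on the log scale) are provided for contrast with the
   network view, both from raw data and from published mean/SD/n rows.

## Conventions that matter (and why)

* **Density universe = measured group roster** (default). With a
  16-biomarker immune roster, 11 and 7 within-group edges give
  $11/\binom{16}{2} = 0.092$ and $7/\binom{16}{2} = 0.058$ — matching the
  2 d.p. values 0.09 and 0.06 that this kind of study reports. A
  connected-node denominator does not reproduce them; it is available as
  `density_universe = "connected_nodes"`.
* **Betweenness scope = within-group induced subgraph** (default), because
  per-group properties are what small-panel CNA reports compare; hub
  ranking is then meaningful *within* a group. Full-network scope is one
  configuration flag away. Exact published BC scores from the motivating
  study are not reproducible — part of its immune edge list is unprinted —
  so the tests assert oracle equivalence and fixture values instead.
* **Welch t-test by default.** "Unpaired t-test" under-determines the
  variant; Welch is the safer default under unequal variances and the
  pooled form is selectable so printed p-values can be bracketed.
* **No multiplicity correction**, mirroring the analysis style the package
  reproduces; every rendered report carries an explicit banner saying the
  p-values are raw.

## The synthetic cohort generator

Raw per-participant data for studies of this design are typically not
public, so `synthetic_config()` / `simulate_cohort()` /
`make_study_emulation()` generate the *stated world* the pipeline assumes:
two cohorts (disease $n = 11$, control $n = 12$ by default), five variable
groups of 8/12/16/25/30 biomarkers, approximately lognormal marginals
(per-group latent location/scale chosen to resemble published log-scale
abundance tables, e.g. immune scores with means ≈ 2–12 and SDs ≈ 0.2–0.7),
planted signed correlations and planted hubs, and optional MCAR missing
cells.

Sampling is a Gaussian copula: draw multivariate normal data with the
target correlation, then exponentiate for lognormal marginals. The planted
Pearson structure is therefore *exact on the log scale*, where the pipeline
computes correlations; Pearson on the raw lognormal scale would differ, and
that is intentional.

Three numerical choices deserve a paragraph each:

**Hub plants must respect positive semidefiniteness.** A center correlated
at $\rho$ with $k$ mutually-uncorrelated spokes is not a correlation matrix
for $k > 1$ (the $3 \times 3$ minor already has a negative eigenvalue at
$\rho = 0.8$). Connected plant components are therefore completed by the
Markov (graphical-model) extension: every non-adjacent pair in a component
receives the signed product of plant weights along a shortest path. For
trees and sign-balanced cliques this is exactly PSD. It also fixes the
plant magnitude: at $|\rho| = 0.85$ the implied second-neighbour
correlation is $0.7225$, *above* the 0.7 threshold, planting edges the
recipe never asked for; at $|\rho| = 0.8$ it is $0.64$, safely below.
Connected components therefore plant at 0.8 while isolated pairs plant at
0.85, and those implied $0.64$ correlations are a feature, not a bug: they
are exactly the sub-threshold "shadow" structure a real correlated block
produces, and at small or moderate $n$ they occasionally cross the
threshold, which is realistic.

**The background shell is low-rank, not i.i.d.** Filling all
$\binom{91}{2}$ off-diagonals with independent uniform noise of half-width
0.2 produces a matrix whose spectrum dips far below zero; the nearest-PSD
repair then erodes the planted 0.8–0.85 entries to roughly 0.73 (measured
during development). The generator instead draws the background block from
a low-rank Gram construction (`cov2cor(WW' + \delta I)`, entry SD ≈ half
the shell width, so the stated shell of ±0.2 at the default
`background_rho_max = 0.1` is a ≈4σ envelope), and confines it to
biomarkers that carry no planted structure. The overall target is then
block-PSD by construction, the repair is a no-op, and the ground truth's
`rho_true` equals the requested plants exactly.

**PSD repair is alternating projections with Dykstra's correction**
(tolerance $10^{-8}$, 200 iterations): project onto the PSD cone, restore
the unit diagonal, repeat. Already-valid input is a fixed point. Every
target passes through the repair regardless, so a hand-specified recipe can
never silently sample from an invalid matrix; a small ridge ($10^{-7}$)
guards the Cholesky factor against the repair's eigenvalue slack.

`make_study_emulation()` wires these pieces into the qualitative world of
the motivating design: the disease cohort's true structure carries the
eight published within-immune edges (three hub centers: Treg, neutrophils,
cytotoxic cells), cross-group correlations for all ten group pairs and one
within-group pair per remaining group; the control cohort carries seven
disjoint within-immune pairs (hence zero betweenness everywhere, no hubs)
and eight of the ten group connectors, with immune–anthropometric and
immune–metabolic connectivity absent *by construction*.

### What a green test does and does not establish

The generator emulates correlation structure, marginal scale and
missingness — not compositionality, zero-inflation or sequencing depth of
real microbiome data, nor the count nature of immune abundance scores.
Recovery tests at $n = 1000$ establish that the pipeline finds what was
planted when the signal is identifiable (Fisher-z separation between 0.8
and the 0.2 shell is many standard errors at that $n$); the small-$n$
realism test asserts the opposite — at $n = 11$ recovery is *unreliable*
(edge-set Jaccard to the plan well below 1) — so nothing about the
stability of real 11-sample networks should be inferred from green tests.

## Degenerate inputs and tie-breaks

Constant biomarkers are a hard error (not silently excluded) so the
analysis universe stays auditable. Zero-variance t-tests: equal means give
$p = 1$ by convention, unequal means are an error. Components of one or two
nodes score betweenness 0. Report ordering is deterministic: descending
betweenness, then descending degree, then name; edge lists sort
lexicographically by (a, b).

## Known limitations

* Correlation networks on $n \approx 11$ are descriptive, not inferential;
  the package deliberately offers no edge-wise significance or
  differential-correlation testing.
* The group-level collapse discards edge multiplicity in the visual
  convention (a single connector); the count is retained in the report.
* GraphML export records the configured betweenness scope only; consumers
  wanting both scopes should export twice.
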