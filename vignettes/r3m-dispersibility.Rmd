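---
title: "R3m and the probability of amorphous solid dispersion formation"
author: "RGetaway authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{R3m and the probability of ASD formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RGetaway)
```

## The problem

An amorphous solid dispersion (ASD) — a drug dissolved molecularly in a
carrier polymer — is a standard way to rescue the oral bioavailability of a
poorly soluble active pharmaceutical ingredient (API). Whether a given API
will actually form and keep a single-phase dispersion with a given polymer
is usually settled by trial and error. For the widely used copolymer PVPVA,
a single 3D molecular descriptor, R3m, separates melt-quench dispersible
APIs from non-dispersible ones remarkably well, and this package implements
that descriptor and the probabilistic classification model built on it.

## The descriptor

R3m belongs to the GETAWAY (GEometry, Topology and Atom-Weights AssemblY)
family. For a conformation with atoms $1,\dots,A$, centered coordinate
matrix $M \in \mathbb{R}^{A\times 3}$:

* the **molecular influence matrix** $H = M (M^\top M)^{-} M^\top$ is the
  regression hat matrix of the coordinates; its diagonal $h_{ii}$
  (leverages) measures how far atom $i$ sits from the molecular geometric
  center, with $0 \le h_{ii} \le 1$ and $\mathrm{tr}(H)$ equal to the rank
  of $M$ (3 generic, 2 planar, 1 collinear);
* $r_{ij}$ is the Euclidean distance and $d_{ij}$ the topological (minimum
  bond count) distance;
* $w_i$ is the atom weight; for the mass scheme, the IUPAC conventional
  standard atomic weight normalized to carbon ($w_C = 1$, $w_H = 0.0839$,
  $w_S = 2.669$).

The R-autocorrelation at lag $k$ is

$$R_{k\cdot w} \;=\; \sum_{i<j} \frac{\sqrt{h_{ii}h_{jj}}}{r_{ij}}\,
w_i w_j \,\delta(k; d_{ij}),$$

and `r3m()` is the $k=3$, mass-weighted case. Hydrogens are retained
throughout; published structure figures omit them only for legibility, not
from the computation. The descriptor rises when heavy atoms occupy
high-leverage, peripheral positions — exactly the positions from which they
can form non-covalent contacts with a polymer.

Two collinear carbon chains make the arithmetic transparent (leverages are
$x_i^2/\sum x^2$, and only pairs three bonds apart contribute):

```{r chains}
descriptorValue(r3m(makeChainMolecule(4)))  # single pair: 0.45/3
descriptorValue(r3m(makeChainMolecule(5)))  # two pairs: 2/15
```

## Conformers and the distribution of R3m

A molecule in an amorphous phase samples many conformations, and torsional
changes move both the leverages and the $r_{ij}$ at lag 3, so R3m is
properly a distribution. `ConformerEnsemble` holds one topology with many
coordinate frames (read from multi-record SDF, multi-block XYZ or
multi-MODEL PDB); `ensembleDescriptor()`/`r3m()` return one value per frame
and `summarizeDistribution()` reduces them to box-plot statistics.

The reference workflow this mirrors samples 7 equally spaced frames
(inclusive of both window endpoints, `selectFrames(200, 500, 7)` giving
50 ps spacing) from the equilibrated final 300 ps of each of 3 replicate
amorphous-cell simulations of 40 molecules, i.e. $3 \times 7 \times 40 =
840$ conformations per API and $15 \times 840 = 12{,}600$ labeled points
for the model. `extractMolecules()` performs the per-molecule splitting of
packed frames.

## The dispersibility model

Each conformer value inherits its API's experimental 0/1 outcome, and a
univariate logistic regression links R3m to the probability of dispersing
in PVPVA. The published coefficients are fixed in `publishedModel()`:

$$\operatorname{logit} P(Y) = -46.79 + 74.01\,\mathrm{R3m}$$

```{r model}
pm <- publishedModel()
decisionBoundary(pm)                     # 50% at R3m = 0.632
100 * predictProbability(0.570, pm)      # < 1%
100 * predictProbability(0.654, pm)      # > 80%
round(r3mAtProbability(0.99, pm), 3)
```

Note the last number: with the printed (rounded) coefficients the 99%
threshold solves to 0.694, while 0.693 is often quoted from the unrounded
fit. Reports in this package band values by *probability* (below 1%, above
99%, intermediate), which keeps the bands self-consistent whichever
descriptor-scale cut one prefers; the footnote in `predict` output records
the discrepancy.

`fitLogistic()` refits the model by maximum likelihood (binomial IRLS via
`stats::glm`, log-likelihood tolerance $10^{-10}$, at most 100 iterations;
non-convergence is an error, never a silent partial result). Diagnostics
are likelihood based: $\chi^2 = 2(LL - LL_0)$ on 1 df and McFadden's
pseudo-$R^2 = 1 - LL/LL_0$. McFadden's definition was chosen because it is
the common default for logistic fits and needs nothing beyond the two
log-likelihoods; alternatives (Cox–Snell, Nagelkerke) are out of scope.

**Complete separation.** With one conformation per API the classes do not
overlap, maximum likelihood diverges, and logistic regression is the wrong
tool; the historical boundary was instead the midpoint between the edge
values of the two classes. The package detects separation (a perfectly
classifying threshold in the data, or coefficient norm beyond $10^3$),
warns, flags `separated = TRUE`, and `midpointBoundary()` implements the
midpoint rule — on the shipped 15-API library table it gives
$(0.595 + 0.687)/2 = 0.641$ for the CORINA-conformation values printed
there.

Classification is strict: a value exactly at the boundary classifies as
"fails". The legacy boundary 0.65 is available via
`runConfig(boundary = 0.65)`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 3 | topological lag of the autocorrelation (bonds) |
| `weights` | `"mass"` | atom weighting; `"unit"` isolates geometry |
| `factor` (bond perception) | 1.2 | multiplier on summed covalent radii (dimensionless) |
| `boundary` | model 50% point (0.632) | classification cut on R3m |
| `deltaThreshold` | 0.05 | "small difference" cut in `compareValueSets()` |
| `maxTwist` | — | half-width (degrees) of uniform torsion perturbations |

Bond perception uses Cordero-style single-bond covalent radii (from the
periodic-table data in `bio3d`); 1.2 is the usual cheminformatics tolerance
and comfortably covers normal single bonds (C–C at 1.54 Å against a 1.82 Å
cutoff) without bridging non-bonded contacts at van der Waals range. The
factor is exposed because unusually long coordination bonds may need a
larger value.

## Numerical choices

* **Centering** is unweighted (geometric), matching the definition of the
  influence matrix on the centered molecular matrix; `influenceMatrix()`
  refuses visibly non-centered input (column mean beyond $10^{-6}$ of the
  coordinate scale) rather than silently re-centering.
* **Rank deficiency**: planar and collinear molecules make $M^\top M$
  singular; a Moore–Penrose pseudo-inverse (`MASS::ginv`) yields the
  correct projection, and tiny negative leverages from round-off are
  clamped to $[0,1]$.
* **Coincident atoms** on a contributing pair ($r_{ij}=0$) raise an error
  instead of being skipped — silent skipping would mask corrupt input.
* **Per-atom attribution** splits each pair term half-and-half between its
  two atoms. Any split summing to the pair term would conserve the total;
  the equal split is the only symmetric choice, and it reproduces sensible
  element-class percentages (e.g. a C–C–C–S chain attributes 50% of its
  single lag-3 pair to sulfur). `atomContributions()` reports a zero-valued
  descriptor as 0% by convention.
* **Box-plot conventions**: quartiles by linear interpolation of order
  statistics (type 7) and whiskers at the most extreme points within
  1.5 × IQR; points beyond are outliers. Threshold exceedance
  (`fractionAbove`) is strict.
* **Topological distances** are exact integers from BFS (`igraph`);
  disconnected pairs are infinite and never contribute.
* Atom indices are 1-based everywhere, matching both R and the native
  indexing of SDF/PDB files.

## Synthetic fixtures

The generators in this package produce desk-scale inputs with known
answers, and they define the conditions under which the test suite and the
acceptance checks run:

* `makeChainMolecule()` — collinear chains with closed-form leverages and
  descriptor values (`chainGroundTruth()` computes them independently of
  the production code path), plus a zig-zag variant with real torsional
  degrees of freedom.
* `perturbTorsions()` — rigid rotations about acyclic, non-terminal bonds
  with independent uniform twists within ±`maxTwist`. Bond lengths are
  preserved exactly. Twists are uniform, **not** Boltzmann-weighted: these
  ensembles exercise descriptor plumbing and distribution bookkeeping.
  They emulate the *shape* of conformational spread, not molecular
  dynamics; force fields, packing, and periodic boundaries are explicitly
  out of scope, so a passing suite says nothing about any particular MD
  engine's trajectories.
* `simulateLabeledDataset()` — descriptor values uniform on an interval
  (default (0.55, 0.72), the neighbourhood of the decision boundary where
  the model is actually exercised) with Bernoulli labels from a chosen
  logistic law. Used for parameter recovery: at $n = 5000$ the refit
  recovers the published coefficients within three standard errors and the
  0.632 boundary to about 0.01.

All generators take an explicit seed, produce bit-identical output for the
same seed, and restore the caller's RNG state.

Problem sizes in the shipped tests — ensembles of up to 840 six-atom
conformers, 100 random-tree invariance trials, 50 distance-oracle trees,
5000-point refits — were chosen so the whole suite completes in well under
a minute while keeping every Monte-Carlo band (3 standard errors) tight
enough to be informative.

## Known limitations

* The descriptor is only as good as the conformations supplied. The package
  consumes ensembles; it does not generate physically weighted ones.
* The model is specific to binary API–PVPVA dispersions prepared by
  melt-quenching; other polymers, solvent-based processes, surfactants and
  low drug loadings are outside its calibrated domain.
* External crystal-structure anchors (the aripiprazole polymorph pair with
  R3m 0.951/1.204) require licensed CCDC downloads and are therefore
  checked only when the user supplies the structures locally; the
  hydrogen-inclusion convention is otherwise validated only against the
  analytic fixtures.
* Periodic-boundary unwrapping is assumed done upstream: frames must
  contain whole molecules.
* Only the R-autocorrelation family is implemented, generalized over lag
  and over mass/unit weights; the wider GETAWAY battery (H-indices, ITH,
  ISH, HATS) is not.
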