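---
title: "Predicting B-value distributions from graphlet degree vectors"
author: "GraphletADP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting B-value distributions from graphlet degree vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GraphletADP)
```

## The model

Atomic displacement parameters (*B* values, Å²) in macromolecular models
mix genuine atomic mobility with sample-to-sample static disorder.  Their
magnitude is strongly tied to local packing: buried, densely contacted
atoms move less.  GraphletADP models this relationship with nothing but
the coordinates.

A structure is turned into a simple undirected **contact graph**: atoms
are nodes; an edge joins two atoms iff their center-to-center distance is
strictly below a cutoff.  Edges do not distinguish covalent from
non-covalent contacts, and no van der Waals radii enter the criterion.
Each atom is then summarized by its **graphlet degree vector (GDV)**: for
every automorphism orbit of the nine connected graphlets on 2–4 nodes
(*G*₀–*G*₈, 15 orbits *O*₀…*O*₁₄), the number of induced connected
subgraph occurrences that touch the atom at that orbit.  Counts are per
occurrence, and graphlets are *induced* subgraphs: a triangle is a
triangle, never also a path.  Orbit *O*₀ is the ordinary degree; the
higher orbits encode how an atom's neighbors are wired among themselves
— "deep contacts" that a plain contact count cannot see.

The predictor is ordinary least squares on the standardized orbit
columns,

$$B_n = b_0 + \sum_{k=0}^{14} \beta_k\, O_{n,k} + \varepsilon_n,$$

with two variants: the **GDV model** (all 15 orbits) and the classical
**contact model** (the single predictor *O*₀), which ships as a preset
with intercept 0 and slope −0.64 on the standardized contact count.
Both predict the *distribution* of *B* values: responses are normalized
per structure (mean 0, sd 1), and predictions live on that normalized
scale.  Mapping back to Å² requires a target mean and standard deviation,
which are resolution-dependent and wide-ranging; `rescaleToRawB()` exists
but is documented as unreliable by construction.

### Assumptions

* *B* values are (approximately) linear in the standardized GDV features
  within one structure, with i.i.d. Gaussian residuals — adequate for a
  distribution-level predictor, not for atom-exact inference.
* The response is unimodal after normalization.  Structures whose chains,
  domains or TLS groups sit at clearly different *B* levels violate this;
  normalize per group (`normalizeB(..., groupBy = "chain")` or an
  explicit label vector).  Group choice is case-dependent and left to the
  user; no automatic mode detection is attempted.
* Crystal packing matters at the surface.  The package does not generate
  symmetry mates; supply a pre-expanded model and flag the copies with
  `markEnvironment()`.  Environment atoms are graph nodes and smoothing
  neighbors but never regression rows or evaluation targets.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| graph cutoff (GDV) | 5.0 | Å | shortest cutoff on the observed accuracy plateau (5–8 Å); minimizes computation |
| graph cutoff (contact) | 7.0 | Å | the classical optimum for the contact-number model |
| smoothing radius | 2.0 | Å | just above covalent bond lengths, mimicking bonded-ADP similarity restraints |
| smoothing | on | — | one pass: value + mean of neighbors within the radius |
| response normalization | per structure | — | makes entries comparable; per-chain/label for multimodal cases |
| CV folds | 10 | — | folds partition *structures*, never atoms |
| SIGD shift *B*₀ | 0.9 × min *B* | Å² | the standard convention for shifted-inverse-gamma ADP analysis |
| QC thresholds | see `qcThresholds()` | — | strict boundary semantics; boundary values pass |

## Pipeline and numerical choices

The canonical feature pipeline is **count → smooth → z-score**:

1. `buildContactGraph()` uses strict `<` at the cutoff (an exact-cutoff
   pair is *not* an edge).  The cell-list search is bit-identical in edge
   membership to the all-pairs check and is tested as such.
2. `smoothFeatures()` operates on *raw* orbit counts and uses an
   *inclusive* `≤` radius — deliberately different from the graph
   inequality, so exact covalent-bond-length pairs are captured.  Atoms
   with an empty neighborhood keep their value.  A single pass is
   applied, not an iteration.
3. `zscoreColumns()` standardizes with the sample (n−1) standard
   deviation; constant columns map to zero with a warning.  Z-scoring is
   idempotent to 1e−12.  Columns are standardized over the rows actually
   entering the regression, i.e. after environment atoms are dropped:
   the design matrix the model sees is the thing standardized.
4. `fitLinear()` refuses rank-deficient designs, naming the collinear
   columns, rather than silently dropping aliased coefficients.
   Importance is |t| rescaled to max 100.
5. Correlation is Pearson's r, matching the linear-model setting;
   constant vectors are an error, not an NA.
6. Cross-validation fold assignment is a pure function of entry order
   and seed; reruns are bit-identical.

Structure I/O (via bio3d) keeps heavy protein atoms by default:
hydrogens are excluded (reference datasets count non-H atoms; inclusion
is a flag), as are waters and hetero compounds.  Alternate locations are
collapsed to one conformer per atom site — highest occupancy wins, ties
break lexicographically (A before B) — because the graph needs a single
position per atom.  Multi-model files use model 1 with a warning; ANISOU
records are ignored.  The B column is written as `%6.2f`, and negative
values (normalized scores) are permitted in both directions of the round
trip.

### Orbit counting and its oracle

The production counter enumerates every connected induced subgraph of
size 3 and 4 exactly once (ESU enumeration, C++) and classifies it by
its (edge count, within-subgraph degree) signature, which determines the
graphlet type and each node's orbit uniquely.  Correctness is defined by
an independent brute-force oracle written in R: exhaustive `combn`
subset enumeration with vectorized pair indicators and an explicit
orbit/degree classification table.  The two agree entrywise on the
worked 9-node example (whose printed degrees pin the orbit numbering),
on canonical graphs (cliques, paths, cycles, stars), and on hundreds of
random graphs; the orbit-sum identities (e.g. ΣO₀ = 2|E|, ΣO₁ = 2ΣO₂,
ΣO₃ = 3·#triangles, and the general multiplicity identity per graphlet)
are asserted against the oracle's graphlet tally.

### SIGD fitting

`fitSigd()` fixes the shift at *B*₀ = 0.9 × min *B*, then maximizes the
inverse-gamma likelihood in (shape α, scale β) on *B* − *B*₀: β has the
closed form α / mean(1/x) at the optimum, and α solves the profiled
digamma score equation by bracketed root search (method-of-moments
start).  Given the shift, this is the exact MLE, and the tests verify it
against an independent direct 2-D likelihood maximization.

One property deserves emphasis: the fixed-shift rule is a convention,
not an estimator of the true shift.  When the underlying distribution
keeps its mass well away from its shift (large α·β), the sample minimum
sits substantially above *B*₀, the rule overshoots, and the conditional
MLE of α and β is biased low.  This is a property of the convention
itself — the same likelihood machinery recovers parameters accurately
when the true shift is supplied — and is visible in the package's
parameter-recovery tests.  For screening real structures, where the rule
is the definition of *B*₀ rather than an estimate of anything, this is
immaterial.

## Synthetic data

`syntheticStructure()` generates protein-like coordinates — by default a
helix: rise 1.5 Å and ~100° twist per 4-atom residue on a 2.3 Å-radius
curve with 0.4 Å Gaussian jitter, giving 5 Å contact counts in the range
of real folds; alternatively a uniform cloud at 0.05 atoms/Å³ — and
draws the true normalized response from the model itself: features are
computed through the standard pipeline, multiplied by a known
coefficient set, plus Gaussian noise (default sd 0.5, roughly matching
the explained-variance level seen on real entries).  The default
generating coefficients are all negative with dominant weights on the
path orbits O4, O1, O5, echoing the empirical importance ranking.  Raw
*B* columns are `30 + 10·truth` Å², floored at 1.0.  Generators are pure
functions of their arguments including the seed, and restore the global
RNG state.

What this emulates: the statistical structure the regression assumes
(linearity, homoscedastic noise, realistic feature collinearity from
real-ish packing geometry).  What it does not: crystal packing and
symmetry mates, chemical heterogeneity (everything is a poly-alanine-like
chain), multimodal *B* distributions, radiation damage, or model errors.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under the stated model — not field accuracy on deposited
structures, which depends on a large re-refined corpus that desk-scale
testing does not include.

Test and recovery problem sizes were chosen once for statistical
resolution: oracle equivalence on 200+ random graphs up to 25 nodes;
regression recovery on 20 entries × 2000 atoms (noise sd 0.5) against a
direct Monte-Carlo oracle for the expected per-entry correlation; SIGD
recovery on 5000 draws × 10 seeds.

## Coefficients

Fitted GDV coefficient sets are serialized as round-trippable key=value
text (`writeCoefficients()`/`readCoefficients()`).  Only the contact
preset ships built in; published multi-orbit coefficient values must be
transcribed by the user into a coefficient file, since transcription —
not invention — is the only faithful way to import them.

## Known limitations

* Normalized-scale predictions only; absolute Å² rescaling is explicitly
  unreliable.
* Proteins only: nucleic acids and ligands are excluded by the default
  selection and unmodelled.
* No symmetry expansion; surface-atom accuracy depends on the user
  supplying environment atoms.
* Isotropic *B* values only; anisotropic ADPs are ignored.
* Graphlets stop at 4 nodes; no size-5 orbits, weights or directions.
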