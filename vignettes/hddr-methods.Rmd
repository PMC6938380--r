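---
title: "Restraint-based comparative modeling in hddr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-based comparative modeling in hddr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hddr)
```

# The modeling problem

Comparative modeling predicts the 3D structure of a target protein from
one or more homologous template structures and a target–template
alignment. `hddr` implements the classical *satisfaction of spatial
restraints* formulation of this problem at desk scale: alignments and
template coordinates are converted into probabilistic restraints on model
interatomic distances, the restraints are combined with stereochemical
terms (and optionally knowledge-based statistical potentials) into a
single objective function, and models are produced by minimizing that
objective from template-derived starting points.

The package exists to make the *restraint machinery itself* measurable.
Its experiments ask: how does the choice of restraint standard deviations
(σ values), of multi-template weights, and of statistical-potential
weights change the quality of the final models? Because these are
property-level questions, everything runs on synthetic folds generated in
code, with every random choice seeded.

# Homology-derived distance restraints

For model atoms *i, j* with equivalent template atoms at distance
$d_t$, the restraint on the model distance $d_m$ is a Gaussian density
$f(d_m) = \mathcal{N}(d_m;\, d_t, \sigma)$, contributing the harmonic
objective term

$$\mathrm{obj}(d_m) = \frac{(d_m - d_t)^2}{2\sigma^2}
  + \ln\!\big(\sigma\sqrt{2\pi}\big).$$

A deviation of exactly one σ adds exactly 1/2 above the minimum — one of
the exact identities the test suite asserts. With $U$ templates the
density becomes the mixture
$f(d_m) = \sum_{u} w_u\, \mathcal{N}(d_m;\, d_{t,u}, \sigma_u)$ with
weights summing to one.

Restraints are generated for four atom groups: Cα–Cα, backbone amide-N
vs carbonyl-O (N–O), side chain–main chain (SCMC), and side chain–side
chain (SCSC). The literature names these groups without publishing exact
atom lists or distance ceilings, so the following are explicit,
configurable package defaults, logged with every run:

| group | atoms | template-distance ceiling | min. residue separation |
|-------|-------|--------------------------|------------------------|
| CA-CA | Cα vs Cα | 14 Å | 2 |
| N-O   | backbone N vs backbone O | 11 Å | 2 |
| SCMC  | any side-chain atom vs any backbone atom | 6.5 Å | 1 |
| SCSC  | side-chain vs side-chain | 6.5 Å | 1 |

The 2-residue minimum separation for the backbone groups keeps HDDRs off
distances that the covalent stereochemistry already fixes. SCMC/SCSC use
*all* heavy-atom pairs under the ceiling rather than representative
atoms; with the reduced side chains of the synthetic corpus (below) the
distinction is small, and the choice is logged.

Multi-template restraints merge one entry per covering template; a
template covers an atom pair when both atoms map through the alignment
and their template distance is under the group ceiling.

## Template weights

Three weighting schemes are provided:

* **uniform** — $w_u = 1/U$;
* **only-lowest (OL)** — weight 1 for the template with the smallest σ,
  0 for the rest; ties break to the lowest template index (a pure
  determinism choice — note that relabeling templates can therefore flip
  tied winners, which the tests treat as equivalent);
* **similarity** — weights proportional to the fraction of identities in
  an 11-residue alignment window around the restrained residues
  (averaged over the two residues), floored at 0.05 before
  normalization. Published descriptions say only that weights are a
  function of local sequence similarity; this windowed-identity form is
  a pluggable stand-in.

# Optimal σ values

If the native structure is known, the σ that maximizes the likelihood of
recovering the native distance $d_n$ is
$|\Delta d_n| = |d_n - d_t|$: maximizing
$\mathcal{N}(d_n; d_t, \sigma)$ over σ gives exactly this value, and the
test suite confirms it by grid search. For mixtures the optimum is
$\sigma_u = |\Delta d_{n,u}|$ together with OL weights — the mixture at
$d_n$ is linear in the weights, so after optimizing each component the
best vertex of the simplex is the component with the smallest
$|\Delta d_{n,u}|$; a brute-force search over a simplex grid (step 0.05)
and σ grids verifies this for $U = 2, 3$.

Raw $|\Delta d_n|$ values are floored at **0.05 Å** before use. Real
homolog pairs (and the synthetic corpus, by construction) produce many
values near zero; a near-zero σ makes the harmonic term punish any
deviation astronomically, and model building then aborts on the
objective ceiling (below). Two ordering questions are unstated in the
literature and resolved here as package policy:

* the floor is applied **before** the OL argmin (so a raw 0.02 Å vs
  0.6 Å pair floors to 0.05/0.6 and the first template still wins);
* per-group mean σ values (`m_obs`) are computed on the **floored**
  values, because those are the σ actually deployed.

# Simulating σ estimators of controlled accuracy

To study how estimation error in $|\Delta d_n|$ degrades models, signed
deltas are perturbed as $p_i = |\Delta d_{n,i} + \varepsilon_i|$ with
$\varepsilon_i \sim \mathrm{Laplace}(0, b)$. Laplace noise keeps the
perturbed values approximately exponential-like and right-tailed, like
the unperturbed distributions. A sweep of 5000 trials over a linear
$b$ grid from $0.005\,m_{obs}$ to $25\,m_{obs}$ ($m_{obs}$ = mean of the
unperturbed absolute list) selects the trial whose Pearson correlation
(PCC) with the unperturbed list is closest to the requested
$PCC_{SEL}$; the selected list is then rescaled so its mean equals

$$m_{pt} = PCC_{SEL} \cdot m_{obs} + (1 - PCC_{SEL}) \cdot m_{grp},$$

which prevents heavy perturbation from simply inflating the average σ
of a model ($m_{grp}$ is a group-global mean; it defaults to $m_{obs}$
when no corpus-wide value is supplied). Design points worth making
explicit:

* the **signed** deltas are perturbed, exactly as the absolute-value
  composition above requires; when only unsigned values are available
  (TSV input) signs would have to be re-assigned randomly — the package
  instead keeps the signed values alongside (`d_n`, `d_t` columns);
* scaling happens **after** trial selection; PCC is scale-invariant, so
  the selected trial is unaffected — the tests assert this;
* each of the four HDDR groups, and each template, is perturbed
  **independently** with its own derived seed, and the trial-loop PCCs
  are computed per group (the pooled alternative would let a large group
  dominate the b selection of a small one);
* the achieved-vs-requested deviation is typically well under the 0.003
  tolerance the heuristic is specified to reach; the acceptance script
  recomputes it from scratch at every run.

The model-level summary $PCC_{MODEL}$ averages, over perturbed sets and
templates, the PCC between each original per-template list and its
perturbed counterpart.

# The composite objective

$$F_{TOT} = F_{PHYS} + F_{HOM} + w_{SP}\,F_{SP}$$

with the weights of $F_{PHYS}$ and $F_{HOM}$ fixed at 1.

**$F_{PHYS}$** is a deliberately simplified stereochemistry: harmonic
bonds and angles on the same ideal-geometry constants the synthetic
builder uses (so a freshly built structure is at its own physical
minimum), plus a quadratic soft-sphere repulsion below 2.8 Å for atoms
more than two covalent bonds apart. There is no attractive non-bonded
physical term — consistent with the restraint-based formulation, where
attraction is homology's job. Force constants (100 bond, 20 angle, 10
repulsion, in objective units per Å² or rad²) are package defaults
exposed through `energy_params()`.

**$F_{HOM}$** sums $-\ln f(d_m)$ over restraints, evaluated with a
log-sum-exp so that tight mixtures cannot underflow.

**$F_{SP}$** sums per-atom-type-pair statistical-potential terms over
non-bonded heavy-atom pairs within an 8 Å contact shell (knowledge-based
terms are essentially flat beyond it). Terms are natural cubic splines
through tabulated knots — natural boundary conditions are an explicit
choice, since published tables do not state theirs — evaluated exactly at
knots and identically zero past the cutoff. Real tables load from a TSV
(`type_a, type_b, knot, energy`); a built-in smooth toy potential
(repulsive core + contact-distance well on a 0.25 Å grid over coarse
types N/CA/C/O/side-chain) stands in when none is supplied, and is
labelled a synthetic stand-in, not a database fit.

All three terms have analytic Cartesian gradients, verified against
central finite differences term by term on random conformations.

# Optimization

Models are initialized from the highest-coverage template (aligned atoms
copied by name; unaligned runs keep ideal-geometry coordinates rigidly
shifted to connect; a small seeded jitter of 0.1 Å per coordinate makes
decoys start apart). Optimization is conjugate gradients, then a
Metropolis simulated-annealing schedule on Cartesian coordinates, then a
final CG quench; the returned model never has a higher $F_{TOT}$ than
the start. The annealing stage replaces a molecular-dynamics run: at
this scale its role — escape local minima, then quench — is preserved
with moves of 0.05–0.3 Å scaled by temperature. The `very_fast`
protocol uses 3 temperature stages, `slow` uses 10 with ≥ 3× the steps,
mirroring the roughly 3.4× duration ratio of the named reference
protocols; all schedule parameters are plain arguments.

A configurable **objective ceiling** (default $\max(10^6,\;10^4 \times
n_{restraints})$, i.e. 10⁶ per 100 restraints) aborts a build whose
$F_{TOT}$ exceeds it, raising a typed condition. This reproduces the
documented failure mode of unfloored near-zero σ values: restraints from
different templates (or conserved-core zeros against any start-point
deviation) become mutually unsatisfiable at enormous objective values,
while the 0.05 Å floor keeps the same build finishing normally.

# Model quality

* **GDT-HA**: mean over the 0.5/1/2/4 Å cutoffs of the largest fraction
  of Cα atoms simultaneously within the cutoff under a rigid
  superposition. The search is heuristic — seeds from the global
  least-squares fit and all contiguous 3/5/7-residue fragments, refined
  by iterative extension — and is validated on small toys against an
  exhaustive oracle seeded from every 3-residue subset. By construction
  the score can never fall below the fraction achieved by the plain
  least-squares superposition. Note the metric's floor is $1/n$ per
  cutoff, not 0: a rigid transform can always centre one atom.
* **lDDT**: superposition-free; over native heavy-atom pairs from
  different residues within a 15 Å inclusion radius, the fraction whose
  model distance differs by less than each of 0.5/1/2/4 Å, averaged over
  thresholds. This is the distance-difference component only — no
  stereochemical penalty — which is stated openly wherever scores are
  reported.
* **Cα RMSD** after Kabsch superposition.

Cutoff sets and the inclusion radius follow the metrics' standard
published definitions and are fixed configuration with logged values.
Overall scores are arithmetic means over decoys (16 per model at
reference scale; reduced counts in the test suite).

# The synthetic corpus

`generate_pair()` builds a native fold from ideal secondary-structure
geometry (helix, hairpin, or mixed φ/ψ patterns) with reduced side
chains — Cβ plus a single Cγ pseudo-atom standing in for the side-chain
centroid — which keeps all four restraint groups exercisable without a
rotamer library. Templates are derived by *mode-structured* deformation:
rigid rotations/translations of ~8-residue segments plus per-atom jitter
applied to a random ~70% of atoms, rescaled iteratively until the
superposed Cα RMSD is within 15% of the requested divergence. Two
consequences are intentional:

* $|\Delta d_n|$ profiles have spatial autocorrelation, as real homolog
  pairs do, instead of white noise;
* the ~30% unjittered atoms form conserved patches whose intra-segment
  distances survive the rigid moves exactly, giving the $|\Delta d_n|$
  distribution its strong near-zero mode — the feature that makes raw
  (unfloored) σ values genuinely unusable, as observed on real data.

Alignments are identity alignments with a requested fraction of ±1
register shifts realized as short gapped segments.

What the generator does **not** emulate: real side-chain packing and
rotamers, sequence-dependent secondary structure, domain architecture,
the diversity of a PDB-derived benchmark set, or realistic
alignment-error structure from profile aligners. A green corpus-level
test therefore establishes *orderings and monotone trends* of the
restraint machinery (optimal σ > uniform σ; multi-template OL ≥ best
single template; quality rising with $PCC_{MODEL}$), not the effect
magnitudes published for PDB benchmarks, which are set-specific and are
deliberately not asserted anywhere in the suite.

# Numerical and scale choices

* σ floor 0.05 Å; floors are re-applied after perturbation scaling,
  before deployment as σ.
* Mixture terms are evaluated in log space; zero-weight entries are
  dropped from the compiled energy model.
* OL ties break to the lowest template index; `which.min` semantics.
* Degenerate inputs error early with named positions: missing Cα,
  multi-chain files, insertion codes, all-gap alignment rows, constant
  delta lists (undefined PCC), < 3 superposition points, collinear point
  sets.
* The test suite scales the reference protocol down — 20-target corpora,
  18–24-residue folds, 2 decoys per condition, a 4-point $PCC_{SEL}$
  grid with 1500 b-sweep trials, and a shortened annealing schedule — to
  keep the full run inside desk/CI budgets. The b-sweep acceptance
  target itself always runs at the full 5000 trials. The 5-sets × 8
  decoys and 16-decoy reference protocols are available through the same
  API (`n_sets`, `decoys`, `n_decoys` arguments) when time permits.
* Experiment configuration files are JSON (not YAML) so the package
  needs no dependency beyond `jsonlite`; CLI flags override file values.

# Known limitations

* Single-chain structures only; no mmCIF, ligands, or NMR multi-model
  files.
* The baseline σ strategy (`"baseline"`) draws sigmas from an
  exponential matched to the group mean — a stand-in for histogram-based
  σ estimation, adequate for the orderings studied here because randomly
  assigned σ values with a realistic mean are known to behave comparably.
* The optimizer is not molecular dynamics; timing-sensitive questions
  (e.g. how much a longer MD schedule relaxes stereochemistry) can only
  be answered qualitatively through the `slow` protocol.
* lDDT omits the stereochemical-plausibility component of the full
  published metric.
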