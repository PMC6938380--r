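# hddr — homology-derived distance restraints for comparative protein modeling

`hddr` is a desk-scale R implementation of comparative ("homology")
protein-structure modeling by *satisfaction of spatial restraints*, built
so that the properties of the restraint machinery itself — how restraint
variances, template weights and statistical-potential terms shape 3D model
quality — can be studied and tested end to end on synthetic folds, with no
external modeling program and no structure database.

## Who it is for

Structural bioinformaticians and method developers who want a transparent,
fully seeded, pure-R sandbox for the classical restraint-based modeling
objective: every term, parameter and optimizer step is inspectable, and a
built-in generator produces native/template pairs with controlled
structural divergence and alignment error.

## The model

For a model interatomic distance *d<sub>m</sub>* whose equivalent template
distance is *d<sub>t</sub>*, a homology-derived distance restraint (HDDR)
is the Gaussian pdf

> f(d<sub>m</sub>) = N(d<sub>m</sub>; d<sub>t</sub>, σ),

whose objective-function term is the harmonic −ln f(d<sub>m</sub>) =
(d<sub>m</sub> − d<sub>t</sub>)²/(2σ²) + ln(σ√(2π)). With *U* templates
the pdf becomes the weighted mixture Σ<sub>u</sub> w<sub>u</sub>
N(d<sub>m</sub>; d<sub>t,u</sub>, σ<sub>u</sub>). Restraints are built for
four atom groups: Cα–Cα, backbone N–O, side chain–main chain (SCMC) and
side chain–side chain (SCSC). The total objective is

> F<sub>TOT</sub> = F<sub>PHYS</sub> + F<sub>HOM</sub> +
> w<sub>SP</sub>·F<sub>SP</sub>,

where F<sub>PHYS</sub> holds simplified stereochemical terms (harmonic
bonds/angles, soft-sphere repulsion), F<sub>HOM</sub> the restraint terms,
and F<sub>SP</sub> spline-interpolated pairwise statistical-potential
terms with an 8 Å contact shell. Models are built by conjugate-gradient
minimization plus Metropolis simulated annealing, several times per
target ("decoys"), and scored against the native structure with GDT-HA,
lDDT and Cα RMSD, reported as decoy averages.

Three theoretical ingredients drive the package's experiments:

* **Optimal σ** — given the native structure, the likelihood-maximizing σ
  of a restraint is |Δd<sub>n</sub>| = |d<sub>n</sub> − d<sub>t</sub>|,
  floored at 0.05 Å (raw values are often ≈ 0 and make the harmonic terms
  unsatisfiable).
* **Only-lowest (OL) weighting** — for multi-template restraints the
  optimal weights put all mass on the template with the smallest σ.
* **Controlled-noise estimators** — signed Δd<sub>n</sub> lists are
  perturbed with Laplace noise, p<sub>i</sub> = |Δd<sub>n,i</sub> +
  ε<sub>i</sub>|; a 5000-trial sweep over the Laplace scale *b* (linear in
  0.005·m<sub>obs</sub> … 25·m<sub>obs</sub>) picks the trial whose
  Pearson correlation with the unperturbed list is closest to a requested
  PCC<sub>SEL</sub>, and the result is rescaled to the mean
  m<sub>pt</sub> = PCC<sub>SEL</sub>·m<sub>obs</sub> + (1 −
  PCC<sub>SEL</sub>)·m<sub>grp</sub>. This simulates |Δd<sub>n</sub>|
  estimators of chosen accuracy.

## Worked example

```r
library(hddr)

## a 24-residue mixed fold, one template at 1.5 A Calpha divergence,
## 5% alignment error
spec <- toy_spec(length = 24, fold = "mixed", divergence = 1.5,
                 aln_error = 0.05, seed = 42)
pair <- generate_pair(spec)
pair$realized
#>   template requested realized
#> 1        1       1.5 1.461317

rs <- build_hddrs(pair$aln, pair$templates, pair$native)
rs
#> <hddr_restraint_set 'syn0042': 904 restraints (CA-CA=96, N-O=145,
#>  SCMC=566, SCSC=97), 904 entries>

## optimal sigmas (floored |delta d_n|) + only-lowest weights
rs_opt <- set_optimal_sigma(rs, pair$native)
sigma_profile(rs_opt)
#>   group n_entries     m_obs
#> 1 CA-CA        96 0.7246928
#> 2   N-O       145 0.9171289
#> 3  SCMC       566 0.7168876
#> 4  SCSC        97 0.8348627

dk <- generate_decoys(pair$aln, pair$templates, pair$native, rs_opt,
                      n_decoys = 2, base_seed = 7)
quality_report(dk$decoys, pair$native)
#> <hddr_quality_report: 2 decoys (0 failed)> GDT-HA 0.7188, lDDT 0.8760,
#>  CA-RMSD 1.16 A

## the same build with a 1.0 A uniform sigma is visibly worse
dk2 <- generate_decoys(pair$aln, pair$templates, pair$native,
                       set_uniform_sigma(rs, 1.0), n_decoys = 2,
                       base_seed = 7)
quality_report(dk2$decoys, pair$native)
#> <hddr_quality_report: 2 decoys (0 failed)> GDT-HA 0.6719, lDDT 0.7833,
#>  CA-RMSD 1.62 A
```

`m_obs` is the per-group mean of the deployed sigmas (Å); GDT-HA and lDDT
are in [0, 1] (1 = identical to native). The native-informed sigmas steer
the decoys measurably closer to the native fold than a flat 1 Å sigma on
the same restraints, alignment and seeds.

## Command line

A single entry point wires the subcommands
`simulate`, `optimal-sigma`, `perturb-sweep`, `build`, `score`,
`experiment` (see `exec/hddr` or call `hddr::hddr_main()`); every run
writes a `run-manifest.json` with the resolved configuration, seeds and
output digests.

```sh
Rscript -e 'hddr::hddr_main()' simulate --n 5 --seed 1 --out corpus/
```

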