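# cisevolve

In-silico evolutionary design of bacterial cis-regulatory regions that may
regulate their own transcription.

Most bacterial transcription factors (TFs) bind the promoters of their own
genes. This package provides a complete computational laboratory for
studying *why* auto-regulation is so common, aimed at systems-biology
researchers modelling gene-regulatory circuits. A regulatory system is
specified entirely by sequences — one cis-regulatory nucleotide region and
the DNA-binding domains of three TFs (two inputs, TF1 and TF2, and the
output auto-regulator TF3) — and everything else is derived:

* **Sequence → energy.** TF binding free energies are additive over
  amino-acid/base contacts, `G = Σᵢ ε(aᵢ, bᵢ)` from a 20 × 4 contact
  matrix (kT), with `Kd = K₀ e^G`; RNA polymerase binds the fixed core
  promoter (−35/−10 hexamers, 29-bp footprint) with a log-score energy
  `E = −Σᵢ ln s(bᵢ, i)` from a position-score model.
* **Energy → occupancy.** Equilibrium promoter occupancy follows the
  Shea–Ackers partition function over *all* configurations of
  non-overlapping bound molecules, with nearest-neighbour cooperativity
  (ω_coop for edge gaps ≤ 18 bp), regulated recruitment (ω_act for TFs
  within 20 bp of the RNAP footprint) and steric exclusion, evaluated
  exactly by a dynamic programme:
  `P_on = Z_on / (Z_on + Z_off)`.
* **Occupancy → dynamics.** The output obeys
  `dc₃/dt = β·P_on(c₁, c₂, c₃) − μ·c₃` (c_max = β/μ = 1000 nM), giving
  steady-state response surfaces, bistability detection and penalties,
  response times, and a linear-noise intrinsic-noise magnitude with the
  Poisson limit `σ = √(c₃*/V)` for constitutive genes.
* **Dynamics → fitness → evolution.** Ten transcriptional gate goal
  functions (AND, OR, NOR, NAND, ACT, IN, LACT, LIN, MEAN, NMEAN), the
  composite score `S = S₀ − E_RF − λ_RT·E_RT − λ_N·E_N` with ramped
  dynamic weights, and a seeded mutation/truncation-selection algorithm in
  which auto-regulation is free to evolve — and does, whenever it helps.
* **Analysis.** Feedback measure F (mean squared response shift when TF3
  binding is switched off), computational DNA footprints, binding-site
  calling with BED export, model simplification, regulator in-degree
  statistics, and closed-form minimal models with sensitivity analysis and
  affinity optimization.

## A worked example

The recurring NAND design — a hetero-cooperative TF1/TF2 repression module
on the promoter, sustained by TF3 auto-activation — as an engineered
reference genotype:

```r
library(cisevolve)
models <- model_set()                     # synthetic matrix + consensus promoter
g <- reference_design("NAND_autoact", models, seed = 1)

response_surface(g, models, evaluation_grid(2L, type = "corners"))
#>     c1   c2        c3   ss_high penalty
#> 1    0    0 737.07966 737.07966       0
#> 2 1000    0 578.39859 578.39859       0
#> 3    0 1000 588.40759 588.40759       0
#> 4 1000 1000  51.69341  51.69341       0
```

The output is high (> 500 nM) unless *both* inputs are high — NAND logic —
and no corner is bistable (`penalty` 0). Switching off all TF3 binding and
recomputing the surface quantifies how much the behaviour relies on
feedback:

```r
feedback_measure(g, models)
#> [1] 94883.99        # nM^2; ~0 for feedback-free designs, >1e3 when used
```

Computational footprinting recovers the three designed sites and their
roles from occupancy alone:

```r
call_binding_sites(footprint(g, models), models)
#>    tf start end     o_max           role
#> 3 TF3    59  68 0.9919114 auto-activator
#> 1 TF1    88  97 0.8937934      repressor
#> 2 TF2    98 107 0.8906850      repressor
```

And the minimal-model analysis shows why auto-activation is needed for
sharp repression: without it, two cooperative repressor sites can never
exceed a logarithmic sensitivity of 2, no matter the parameters:

```r
res <- max_sensitivity(minimal_model_spec("rep_2site_coop"),
                       param_ranges = list(K1 = c(1, 10000),
                                           omega = c(1, 100),
                                           p = c(0.1, 100)))
res$s_max
#> [1] 1.999998
```

Evolving a gate from random sequence is one call
(`evolve(evolution_config(gate = "NAND", seed = 1), models)`), or from the
shell via the thin launcher:

```sh
Rscript inst/cli/cisevolve evolve --gate NAND --pop 200 --cycles 1000 \
        --seed 7 --out rundir/
```

which writes a per-cycle `runlog.tsv`, the final population as FASTA and
the full configuration as JSON. Subcommands `fixtures`, `analyze`,
`footprint` and `minimal` cover the rest of the workflow; see
`?cisevolve_cli`.

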