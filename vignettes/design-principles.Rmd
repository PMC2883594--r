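---
title: "Evolving auto-regulatory cis-regulatory regions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving auto-regulatory cis-regulatory regions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisevolve)
```

## The question

A majority of bacterial transcription factors (TFs) regulate their own
genes. `cisevolve` implements an in-silico laboratory for asking *why*:
a sequence-level biophysical model of transcription regulation is coupled
to an evolutionary algorithm that selects cis-regulatory regions for
predefined response functions (transcriptional logic gates and linear
responses). Auto-regulation is never imposed; the output TF (TF3) is simply
allowed to bind its own cis-regulatory region, and feedback evolves
whenever it provides a benefit.

## The model, layer by layer

### Sequence to binding energy

A regulatory system (a `genotype()`) consists of one cis-regulatory
nucleotide sequence and the amino-acid sequences of the DNA-binding domains
of three TFs: two inputs (TF1, TF2) and the auto-regulator TF3. Each
residue contacts exactly one base, so the binding free energy of a TF for a
site is a sum of contact energies from a 20 x 4 matrix (kT units),

$$G(\text{tf}, \text{site}) = \sum_i \varepsilon(a_i, b_i),$$

and the dissociation constant follows as $K_d = K_0 e^{G}$. The published
crystallography-derived contact matrix is not reproduced here;
`make_synthetic_matrix()` ships a seeded synthetic matrix in which every
amino acid strongly favours one nucleotide (about $-3\,kT$) while the other
contacts are mildly unfavourable with a wide jitter. Two properties matter,
and both are tested: (i) achievable affinities span the biologically
required 1-10000 nM range (a perfect 9-mer site reaches about 1 nM under
the default calibration $K_0 = e^{27}$ nM, random sites sit far above
$10^4$ nM), and (ii) sums of contact energies form a dense set, so
evolution (and the fixture designer) can tune site affinities essentially
continuously. Gate designs are insensitive to the individual matrix
elements; only this tunability matters.

RNA polymerase binds only the core promoter, whose anatomy is anchored to
the right (transcription-start) end of the region: -10 hexamer at
positions -12..-7, 17-bp spacer, -35 hexamer at -35..-30, footprint
-35..-7 (29 bp). The promoter binding energy is a log-score sum over the 12
hexamer positions, $E = -\sum_i \ln s(b_i, i)$, with per-position scores
interpreted as base frequencies normalized by 1/4. The published frequency
table is likewise not reproduced; `consensus_promoter_model()` peaks the
frequencies (0.55) on the canonical TTGACA / TATAAT hexamers and spreads
the remainder unequally over the other bases — the unequal split matters
only in that it makes promoter strengths tunable in fine steps. The
calibration `default_K0R()` sets the basal RNAP weight
$q_R = [\text{RNAP}]/K_d^{\text{prom}}$ to 1 for a consensus promoter at
the default 30 nM RNAP.

### Binding configurations to promoter occupancy

The transcription rate is proportional to the equilibrium probability that
RNAP occupies the promoter, computed in the grand-canonical
(Shea-Ackers) formalism. A configuration is any set of non-overlapping TF
placements, optionally with RNAP on its footprint; its weight is

$$\prod_{\text{bound}} \frac{c}{K_d}
  \times \omega_{\text{coop}}^{\#\,\text{adjacent pairs}}
  \times \omega_{\text{act}}^{\#\,\text{recruiting TFs}} \times q_R,$$

where cooperativity applies between *nearest-neighbour* bound TFs with
edge-to-edge gap at most `d_coop` (default 18 bp; chains of molecules gain
factors transitively, which is what makes a linear-scan dynamic programme
exact), recruitment applies to each bound TF within `d_act` (default
20 bp) of the footprint, several TFs may recruit simultaneously
(multiplicatively), and any TF whose site overlaps the footprint excludes
RNAP. The defaults $\omega_{\text{coop}} = \omega_{\text{act}} = 50$ sit in
the biologically supported 10-100 range. `partition_sums()` evaluates
$Z_{\text{on}}$ (RNAP bound) and $Z_{\text{off}}$ by a forward dynamic
programme over "end position of the last placed molecule" — exact for the
nearest-neighbour rule, and verified in the test suite against exhaustive
enumeration of all configurations on short regions (relative error below
$10^{-9}$ on hundreds of randomized systems). Promoter occupancy is
$P_{\text{on}} = Z_{\text{on}}/(Z_{\text{on}} + Z_{\text{off}})$, and
per-site occupancies come from the same forward pass combined with a
backward pass.

### Occupancy to dynamics

The output concentration follows
$dc_3/dt = \beta P_{\text{on}}(c_1, c_2, c_3) - \mu c_3$ with
$\beta/\mu = c_{\max} = 1000$ nM, so outputs live in [0, 1000] nM and match
the input domain. Absolute time scales are irrelevant to every steady-state
measure; time is quoted in units of $1/\mu$. Because the dynamics are
one-dimensional, the flow from any initial condition converges monotonically
to the first stable fixed point in the direction of the initial drift;
`steady_state()` exploits this by bracketing that root (a geometric march
whose step is capped at $c_{\max}/64$ so that narrow attractor basins are
not stepped over) and polishing by bisection plus secant, then verifying
the residual $|\beta P_{\text{on}} - \mu c_3| < \mu\,\varepsilon_{ss}$
(default $\varepsilon_{ss} = 0.1$ nM). `response_time()` integrates the
ODE with an adaptive embedded Runge-Kutta scheme (relative tolerance
$10^{-8}$) until the trajectory first enters an
$\varepsilon_{rt} = 1$ nM band around the steady state; it is checked
against both the closed-form exponential relaxation of constitutive genes
and an independent `deSolve` integration.

Bistability — possible once auto-activation evolves — is handled exactly as
in the fitness protocol: `detect_bistability()` solves from $c_3 = 0$ and
$c_3 = c_{\max}$ and penalizes any difference by its square (in units of
$c_0^2$, $c_0 = 1$ nM), which suffices to eliminate bistable gates from
evolving populations; `bistability_scan()` is the thorough after-the-fact
check (dense sign-change scan refined by `uniroot`). The in-run two-start
protocol has finite resolution: an attractor whose basin is narrower than
the march cap can in principle be missed, which is why the scan exists.

### Intrinsic noise

Selection against noise uses the stationary small-noise (linear-noise)
approximation for the birth-death dynamics with production
$f(c_3) = \beta P_{\text{on}}$ and degradation $\mu c_3$:

$$\sigma^2 = \frac{f(c_3^*) + \mu c_3^*}{2 V (\mu - f'(c_3^*))},$$

with $V$ the volume factor converting concentration to copy number
(default 1 molecule/nM). For a constitutive gene ($f' = 0$) this is exactly
the Poisson limit $\sigma = \sqrt{c_3^*/V}$, which the tests assert;
auto-activation ($f' > 0$) amplifies noise, auto-repression ($f' < 0$)
suppresses it, and $\sigma$ diverges as $f' \to \mu$ (marginal stability,
treated as the worst fitness). Derivatives are computed by central finite
differences with a 0.1 nM step — ample accuracy for a fitness *ranking* —
and the second derivative is reported as a mean-shift diagnostic without
entering $\sigma$.

## Gates, fitness and the evolutionary algorithm

Ten goal functions are defined on inputs in [0, 1000] nM: six logic gates
(AND, OR, NOR, NAND, ACT, IN) mapping low/high input classes (500 nM
threshold; "high" means $\geq 500$) to 0 or 1000 nM, and four graded gates
(LACT: $c_1$; LIN: $1000 - c_1$; MEAN: $(c_1+c_2)/2$; NMEAN:
$1000 - (c_1+c_2)/2$). Two-input gates are scored on the 16 combinations of
$\{125, 375, 625, 875\}$ nM — two representatives per logic class, placed
symmetrically about the threshold — and one-input gates on 7 equally spaced
values; these grid choices are configurable. The response-function error
$E_{RF}$ is the sum of squared deviations from the goal (in $c_0^2$) plus
the bistability penalty; $E_{RT}$ sums the 32 (or 14) response times from
both extreme initial conditions; $E_N$ sums the 16 noise standard
deviations. The total score is
$S = S_0 - E_{RF} - \lambda_{RT}(t) E_{RT} - \lambda_N(t) E_N$ with the
$\lambda$ weights ramped linearly from zero over `t_ramp` cycles (default
500) — starting the dynamic selection pressures at zero avoids the local
optimum in which a silent, dysfunctional gate is retained because its
response times are trivially short. $S_0$ (default $10^8$) is an arbitrary
offset chosen large enough that every realized score is positive, including
the worst random two-input populations plus bistability penalties; it has
no effect on selection order.

Evolution proceeds by truncation selection: each cycle the top 20% of the
population (default size 200, default 1000 cycles; the smoke tests in this
package use 60 x 300) survive *unchanged*, the population is refilled by
duplicating random survivors, and every duplicate is mutated: one cis base
substituted with probability 0.5, a single-base indel with probability 0.1
(promoter anatomy stays anchored to the right end, deletions below 40 bp
and insertions above 300 bp are skipped), and one residue of each TF
replaced with probability 0.03. Keeping the survivors unmutated is a
deliberate design choice: it makes the best score exactly monotone
(truncation elitism), which the test suite asserts as an invariant, while
the 80% offspring supply ample variation. The alternative — mutating the
whole population before scoring — would make the recorded best fitness
stochastically dip whenever all copies of the incumbent take deleterious
mutations. Mutation rates are not critical as long as variation is
generated and good gates persist; the defaults satisfy both at the
population sizes used. All randomness flows from R's RNG seeded once per
run, so runs are bit-reproducible.

Initial populations are uniformly random sequences (`random_genotype()`,
default 200 bp cis regions — long enough for tandem arrays of five or more
sites, short enough to keep the scan cheap). A random promoter is orders of
magnitude below consensus strength, so evolution must *build* the gate:
typical trajectories strengthen hexamers and discover recruiting activator
sites within tens of cycles.

## Post-hoc analyses

The feedback measure $F$ quantifies how much auto-regulation shapes a
response: the surface is recomputed with every TF3 affinity set to zero and
$F$ is the mean squared difference over the evaluation grid (nM²). A
uniform 100 nM shift gives exactly $F = 10^4$; evolved designs that exploit
feedback typically show $F$ of $10^4$-$10^6$, while feedback-free designs
sit near zero.

Computational DNA footprints (`footprint()`) evaluate every site's
equilibrium occupancy at the four corner conditions
$(c_1, c_2) \in \{0, 1000\}^2$ nM with $c_3$ at its self-consistent steady
state, and record the maximum $O_{\max}$. Pooled over evolved genotypes the
$O_{\max}$ histogram is strongly bimodal — a large pseudo-site mode near 0
and a functional mode near 1 — so a single stringent cutoff (default 0.5)
separates binding sites from pseudo-sites. `call_binding_sites()` applies
the cutoff, merges overlapping same-TF calls (keeping the
highest-occupancy start) and annotates roles by geometry (repressor on the
footprint, activator within recruiting distance, distal otherwise; "auto-"
prefix for TF3). `simplify_and_verify()` then rebuilds the system from the
called sites alone and reports the maximal deviation of the reduced
response surface; when the stringent cutoff drops a weak-but-important
site, lowering it restores the reduction — the same fallback the
footprinting idea implies. `degree_stats()` summarizes regulator in-degree
tables per auto-regulation class.

## Minimal models

Six stylized layouts with explicit dissociation constants reproduce the
design principles that recur in evolved gates in closed form: single-site
and two-site cooperative activation, conditional auto-activation (a TF3
operator that acts only by stabilizing the input TF on its recruiting
site), cooperative two-site repression with and without an auto-activation
site, and linear repression with unequal repressor sites. A single $\omega$
plays the cooperativity and recruitment roles, and $p$ is the normalized
RNAP weight. Each layout's occupancy function is assembled from its
configuration sum (`minimal_pon()`), and `minimal_to_engine()` places
explicit-Kd sites on a synthetic region whose geometry reproduces the same
interaction pattern under the engine's distance rules — the strongest
oracle in the package: every layout is required to agree with the full
machinery to $10^{-4}$ relative on random parameters.

The analyses built on these layouts:

* **Sensitivity.** $S(c_1) = |d\ln c_3^*/d\ln c_1|$ by central log-log
  differences (step factor 1.01). `max_sensitivity()` sweeps log grids
  (20 points per decade by default) of the parameters. Without
  auto-activation, two cooperative repressor sites can never exceed
  $S = 2$ — the number of repressor sites — which the sweep approaches but
  does not cross; adding the auto-activation site produces sweep points
  well above 2; and for conditional auto-activation the maximal sensitivity
  grows without apparent bound as the promoter weight decreases (the tests
  assert monotone growth over three decades). The stripped-down analytic
  estimates of these maxima are not reproduced; the numerical sweep is the
  verification path.
* **Affinity optimization.** `optimize_affinities()` minimizes $E_{RF}$
  over log-affinities (Nelder-Mead for several parameters, bounded Brent
  for one; bounds $[1, 10^6]$ nM, the upper bound modelling removal of a
  site) from seeded random restarts, never returning anything worse than
  its best start. Two-site cooperative activation beats single-site
  activation for the step-like ACT goal; for the linear LACT goal the TF3
  operator of the conditional-auto-activation layout is driven to the
  weak-binding bound at moderate promoter strengths, and — the substance of
  the replacement argument — swapping the TF3 operator for a TF1 site never
  fits a linear-activation goal worse, at any promoter strength we tested.
  (At very weak basal promoters the imperfect fit leaves room for weak
  feedback to help slightly; the replacement layout still does at least as
  well.)
* **Linear repression.** Along the fixed-point branch,
  $dc_3^*/dc_1 = (\partial\Phi/\partial c_1)/(1 - \partial\Phi/\partial c_3)$
  with $\Phi = (\beta/\mu) P_{\text{on}}$;
  `linear_repression_derivative_check()` verifies the identity numerically
  (residuals below $10^{-6}$). Without auto-regulation the denominator is
  exactly 1 and the slope is that of a Hill-type function — necessarily
  curved; auto-regulation supplies the denominator that can flatten it,
  which is why evolved LIN and NMEAN gates always use auto-activation.

## Reference designs

`reference_design()` hand-constructs genotypes for five recurring design
schematics (AND by hetero-cooperative activation, AND by conditional
auto-activation, NAND with auto-activation, linear repression with
auto-activation, and a bistable auto-activation switch) by *inverting* the
energy model: site sequences are greedily designed to hit target
dissociation constants, TF residues are chosen so that sites overlapping
promoter hexamers favour exactly the consensus bases, accidental background
sites are hill-climbed away (to 10^7 nM outside the RNAP footprint, where
cooperative chains can amplify weak sites up to
$\omega_{\text{act}}\omega_{\text{coop}}$-fold, and 10^5 nM on the
footprint, where sites cannot recruit), and the realized genotype is
accepted only if it displays the intended qualitative behaviour under the
default models — site energies live on a discrete lattice, so designed
affinities realize only approximately and a draw occasionally needs to be
repeated. "Quadrant" assertions for the two-input designs are evaluated at
the four footprint corner conditions; hand-built two-site modules are not
sharp enough to clear 500 nM at all four points of the high/high quadrant
of the 4 x 4 fitness grid, whereas evolved multi-site designs are.

## What the synthetic data do and do not show

Everything in this package is exercised on synthetic inputs: the seeded
contact matrix, the consensus-peaked promoter model, random genotypes and
the engineered reference designs. These emulate the *structure* of the real
problem — tunable affinities over the biological range, a weak-to-strong
promoter axis, cooperative and recruiting interactions — but not real
E. coli sequence statistics: no published contact matrix, no empirical
promoter frequency table, no real cis-regulatory sequences, single-strand
scanning only (no reverse-complement sites), no DNA looping, no extended
-10 elements, and intrinsic noise only (extrinsic noise raises definitional
questions the model deliberately avoids). Passing tests therefore
demonstrate the internal correctness of the machinery and the robustness of
the design principles to model details, not agreement with any particular
measured promoter. Likewise, the evolutionary outcome *tallies* of specific
studies (how many of 20 replicates find a given design) depend on the exact
matrix and mutation rates and are reproduced here only qualitatively: what
is asserted is that ACT runs improve their response error at least
ten-fold, that NAND runs evolve strong auto-activation (feedback measure
above $10^3$ nM², typically $10^5$), and that best fitness is exactly
monotone.

## Problem sizes and numerical choices

The test suite runs the evolutionary smoke tests at population 60 for 300
cycles (five seeds each for ACT and NAND), the DP-versus-enumeration
comparison on 200 randomized systems of 40 bp, and the minimal-model/
full-engine equivalence on 50 random parameter sets per layout; these sizes
were chosen so the whole suite completes in minutes on one core while still
exercising every code path at meaningful scale. Steady states are solved to
a residual far below $\varepsilon_{ss}$ (bisection to $10^{-3}$ nM followed
by secant polish to machine-level), because the minimal-model equivalence
check compares two independently computed fixed points at $10^{-4}$
relative. Ties in selection are broken by stable order for determinism.
Degenerate inputs follow the documented contracts: deletion at the minimum
cis length is skipped, marginal stability returns a flagged worst-fitness
value rather than an error, and a genotype whose evaluation fails receives
the worst score instead of aborting a run.
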