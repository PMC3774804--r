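# itkmaxent

Simulation and maximum-entropy robustness ranking of candidate reaction
networks for IP4/PIP3-regulated membrane recruitment of the T-cell
kinase Itk.

## The problem

In developing thymocytes, Itk is recruited to the plasma membrane when
its PH domain binds the lipid PIP3; the soluble messenger IP4, produced
downstream of active Itk, binds the same domain and can both *promote*
(allosterically, at low dose) and *suppress* (competitively, at high
dose) PIP3 binding. Whether Itk PH domains act as dimers, and whether
the positive IP4 feedback exists at all, cannot currently be settled by
direct measurement. This package is for modelers who want to
discriminate such wirings indirectly: it encodes seven candidate
mass-action networks (M1–M7, differing in Itk oligomericity and in the
allosteric feedback wiring), simulates them deterministically (ODE) and
stochastically (exact Gillespie), and ranks them by how *robustly* they
reproduce population-level PLCγ1 phosphorylation kinetics under
cell-to-cell parameter variability.

## The method

Each single-cell transient of PIP3-bound Itk is reduced to a peak
amplitude *A*, peak time *τ*<sub>p</sub>, peak width *τ*<sub>w</sub>
(time at or above half-maximum) and asymmetry ratio
*R* = *τ*<sub>w</sub>/*τ*<sub>p</sub>. Extrinsic variability is
emulated by sampling every rate constant uniformly in [base/10,
10·base] and every initial concentration within ±35% of its base (with
the affinity ratio α = K<sub>D</sub><sup>low</sup>/K<sub>D</sub><sup>high</sup>
drawn per model). Given population-average targets
(*τ*<sub>p</sub><sup>expt</sup>, *R*<sup>expt</sup>, optionally
*A*<sup>expt</sup>), the maximum-entropy distribution over the sampled
parameter sets is the exponential tilt

&nbsp;&nbsp;&nbsp;&nbsp;*w*<sub>i</sub> ∝ exp(−λ₁ *τ*<sub>p,i</sub> − λ₂ *R*<sub>i</sub> − λ₃ *A*<sub>i</sub>)

whose weighted means hit the targets, and the robustness score is its
Kullback-Leibler distance to the uniform prior over the *n* valid
samples, in log10 units:

&nbsp;&nbsp;&nbsp;&nbsp;*D*<sub>KL</sub> = Σ<sub>i</sub> *w*<sub>i</sub> log₁₀(*w*<sub>i</sub> *n*).

Small *D*<sub>KL</sub> means the network reproduces the observed
kinetics over a broad swath of parameter space; large *D*<sub>KL</sub>
(or outright infeasibility) means it reaches them only in a thin
corner, or never. Models are ranked by ascending *D*<sub>KL</sub>.

## Worked example

```r
library(itkmaxent)

## published peak statistics of the tetramer-stimulation experiments
tb <- table2_fixture()
round_ratio(asymmetry_ratio(tb$tau_p, tb$tau_w))
#> [1] 1.9 4.3 3.8 2.1     # OVA, Q4R7, Q4H7, G4 — all > 1 (right-skewed)

## one calibrated trajectory of the dimer feedback model M3
m  <- build_model("M3")
tr <- integrate_ode(m, default_base_params("M3"),
                    initial_state(m, Itk0 = 100, PIP3_0 = 370))
summarize_trajectory(tr)
#> <trajectory_summary [OK] A = 35.99, tau_p = 1.976, tau_w = 4.115, R = 2.083>
```

The readout peaks at ~36 active Itk molecules around 2 minutes and
decays on a comparable time scale (R ≈ 2.1) — the transient, slightly
right-skewed pulse seen in the population immunoblots.

```r
## robustness of M3 under extrinsic variability, constrained to
## tau_p = 2 min, R = 2, A = 20 molecules
ec  <- ensemble_config(n_samples = 200, seed = 1)
tbl <- evaluate_ensemble(m, draw_ensemble(ec, "M3"))
solve_maxent(tbl, c(tau_p = 2, R = 2, A = 20))
#> <maxent_solution M3: D_KL = 0.8562 (log10), n_valid = 190>
```

190 of the 200 sampled parameter sets give a well-defined transient;
tilting them to the experimental constraint point costs
*D*<sub>KL</sub> ≈ 0.86. Re-running `solve_maxent()` with the same
targets on the no-feedback models (M5, M6) reports them infeasible —
they cannot produce *R* near 2 for any sampled parameter set — which is
the package-scale version of the conclusion that dimeric-Itk feedback
circuits are the most robust explanation of the observed kinetics.
`run_robustness_pipeline()` wraps the whole scan (all models, a grid of
*R* and *A* targets, CSV/JSON artifacts with seeds and config hashes).

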