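# redoxmotor

Kinetics and stochastic simulation of a chemically fuelled, enzyme-controlled
rotary molecular motor.

## The problem

A biphenyl triol with two *ortho* hydroxymethyl arms is achiral, but
enantioselective enzymatic oxidation of one arm produces a transient, axially
chiral monoaldehyde whose atropisomeric conformers interconvert rapidly
(an intramolecular H-bond lowers the rotation barrier of the oxidized state).
A non-selective reductant — ammonia borane — returns the aldehyde to the
triol. Run concurrently, the two reactions form a dissipative cyclic redox
network: each oxidation–reduction cycle has a biased chance of returning the
molecule as the degenerate rotamer reached by a 180° anticlockwise rotation,
so the motor rotates continuously about its C–C single bond, with
directionality supplied by the enzyme's enantioselectivity (an information
ratchet). The same network applied to a chiral analogue performs a cyclic
deracemization instead.

`redoxmotor` is for chemists and modellers working on such dissipative
reaction networks. It provides:

* **kinetics** — Eyring conversions between rotational barriers
  ΔG‡ (kJ mol⁻¹) and rate constants, k = (k_B·T/h)·exp(−ΔG‡/RT); the
  rate-hierarchy check r_enant > r_red > r_ox; the closed-form step
  ("flip") probability p = k_enant/(k_red_eff + 2·k_enant); progress-curve
  fits for pseudo-zero-order oxidation and pseudo-first-order reduction.
* **reaction_network** — deterministic ODE model (deSolve) of the cycle in
  deracemization and motor topologies, with fuel depletion and pulse
  schedules.
* **motor_simulator** — stochastic per-molecule ensembles: signed half-turn
  counts, net-angle histograms, a closed-form drift oracle, and benzylic
  deuterium-incorporation bookkeeping under deuterated fuel.
* **isotopomer** — exact estimators of the oxidation selectivity
  s = r_ox(Sa)/r_ox(Ra) (ee = (s−1)/(s+1)) and the kinetic isotope effect
  from deuterium-distribution ratios, with bootstrap confidence intervals.
* **synthetic data + pipeline** — seeded generators for every measurement
  modality and a reproducible `run_pipeline()` with manifests.

## Worked example

Standard operating conditions (10 mM motor, 100 mM fuel, 40 °C, measured
rate laws) are the defaults of `rate_parameters()`:

```r
library(redoxmotor)
params <- rate_parameters()

eyring_rate(barrier_spec(79, 313.15))
#> [1] 0.434
hierarchy_report(params)
#> r_red/r_enant = 0.5 -> hierarchy satisfied
#> note: r_red >> r_ox assumed (reduced state is the resting state);
#>       steady-state oxidized conc 0.00266 mM (0.0266% of total)
```

The 79 kJ mol⁻¹ rotation barrier of the oxidized state converts to
0.43 s⁻¹ — the aldehyde racemizes in under a second — while reduction at
100 mM fuel proceeds at half that rate (ratio 0.50 < 1, as rotation
requires) and the oxidized state is a 0.03% trace at steady state.

Simulate 10⁵ motor molecules for 48 h and estimate the oxidation ee from
the two isotopomer experiments (93:7 and 5:95 label distributions):

```r
simulate_motor(params, motor_sim_config(1e5, seed = 1))
#> Motor ensemble: 100000 molecules, 9.65 cycles/molecule (constant fuel, complete racemization)
#>   mean rotations 2.1108 +/- 0.0035 (sd 1.097)

bootstrap_ci(isotopomer_observation("Sa", 0.93, 0.07, integral_sd = 0.02),
             isotopomer_observation("Ra", 0.05, 0.95, integral_sd = 0.02),
             n_boot = 5000, seed = 1)
#> Oxidation selectivity (joint_two_experiment): s = 15.89, ee = 88.2%, KIE = 1.2
#>   ee 95% CI: [82.6%, 94.7%]
```

Each molecule completes ~9.7 redox cycles in 48 h and accumulates a mean of
2.11 net full rotations (anticlockwise); the isotopomer pair implies the
oxidation prefers the Sa aldehyde ~16:1 (88.2% ee) with a primary KIE of
1.20. The methods vignette (`vignettes/redox-rotary-motor.Rmd`) documents
the model assumptions, the two treatments of the transient aldehyde phase,
and all numerical choices.

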