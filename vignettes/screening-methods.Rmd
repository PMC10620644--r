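---
title: "Methods: reactivator screening, DS-MD sampling and MSM landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactivator screening, DS-MD sampling and MSM landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The screening problem

Organophosphates inhibit acetylcholinesterase (AChE) by phosphorylating the
catalytic serine S203. An oxime antidote reactivates the enzyme through
in-line nucleophilic attack: its oxime oxygen must approach the adduct
phosphorus closely (small d_OP) and roughly opposite the serine hydroxyl
oxygen (attack angle θ_OPO near 180°) — the *apical* or near-attack
conformation. A centrally acting antidote additionally has to clear CNS
drug-likeness and blood–brain-barrier constraints. `oximescreen` implements
the computational funnel for electron-donating-group (EDG) substituted
pyridinium-aldoxime analogs: enumeration → drug-likeness filter → apical
pose filter → hybrid-QM energy ranking → per-residue interaction analysis →
adaptive-sampling dynamics with free-energy-landscape readout.

The package deliberately contains **no electronic-structure or all-atom MD
engine**. Quantum energies, docking scores and PIEDA components are
*ingested* (as CSV) and combined arithmetically; the dynamics layer runs on
a toy Langevin system with planted ground truth. What the package owns is
the logic between those inputs: the counting, filtering, selection,
estimation and landscape analysis.

# Analog enumeration and drug-likeness

The scaffold is 1-methylpyridinium-2-aldoxime. Substituents graft at the
ring carbons ortho (R2) and para (R1) **relative to the aldoxime-bearing
carbon**; the source protocol names positions only loosely ("para and/or
ortho position of the pyridinium core"), and the aldoxime-relative reading
is the one that matters for conjugation into the reacting oxime. Codes are
`"R1-R2"` strings with `0` for unsubstituted (`"0-0"` = parent).

The registry ships nine EDGs in the stated strength partition (3 weak, 2
moderate, 4 strong). Identities 1–3 (methyl, 2-methyl-2-butene, phenyl) are
authoritative; **ids 4–9 are placeholders** (common EDGs: acetamido,
acetoxy, hydroxy, methoxy, amino, dimethylamino) because the original
identities live in unavailable supplementary material. Every count the
pipeline produces is independent of fragment identity, so the placeholders
affect only the SMILES column.

Descriptors (MW, HBD, HBA, rotatable bonds, Crippen logP, TPSA, heavy
atoms) are delegated to RDKit through a python subprocess; descriptor
values are engine-dependent, which is why all filter tests run on fixture
profiles rather than recomputed chemistry. The CNS filter uses inclusive
bounds with defaults MW ≤ 450 Da, HBD ≤ 7, HBA ≤ 3, cLogP ≤ 5,
PSA ≤ 70 Å², 12 ≤ heavy ≤ 30, plus a BBB flag. Two deliberate oddities,
both configurable:

* **HBD ≤ 7 / HBA ≤ 3** is kept exactly as printed in the source protocol,
  although the conventional CNS rule swaps them (3 donors / 7 acceptors).
* **PSA ≤ 70 Å²** resolves the printed "60–70 Å" range to its permissive
  end; a single testable bound is required.

The BBB surrogate (`psa ≤ 79 Å² and 0.4 ≤ clogp ≤ 6`) is a deterministic
stand-in for empirical classifiers, overridable by an ingested column. The
published "24 analogs passed" count depends on the original descriptor
software and is therefore *not* desk-reproducible; the ingestion path is
validated against a clearly-labelled synthetic descriptor table with the
pass composition planted by construction.

# Pose geometry

`compute_geometry()` is plain vector arithmetic: d_OP is the Euclidean
O···P distance; θ_OPO is the angle at the phosphorus vertex. The apical
zone is d_OP < 8 Å (strict, as specified) and 120° < θ_OPO ≤ 180°. The
upper angle bound is **inclusive** although the source text writes
"< 180°": 180° is the in-line ideal and only attainable as a boundary, so
excluding it would be an artifact of notation rather than intent.

PDB input is handled by a minimal fixed-width ATOM/HETATM reader (one pose
per MODEL record), because no PDB-parsing R package is available in the
supported stack; alternate locations beyond the first are dropped and no
symmetry handling is attempted. Atom selection is by configurable
(residue name, atom name) pairs, since covalent-adduct naming varies across
preparation pipelines. Failed selections are reported per pose (role named
in the message), never silently dropped.

# Energy combination, counting and selection

The two-layer subtractive extrapolation is
`E_high(real) ≈ E_high(model) + E_low(real) − E_low(model)`; the package
treats it as exact arithmetic over ingested numbers, with non-finite inputs
rejected. Energy tables carry a reference row (the parent oxime) whose Δ
columns are exactly zero; Unicode minus signs are normalized on ingestion.

Quartile selection ranks affinities ascending (most negative = best, ties
broken by code) and drops ranks strictly above the real-valued 3n/4 mark,
except ties with the boundary value, which are kept. With 24 candidates
plus the reference, this places 7 scores in Q4 and keeps 18 analogs —
matching the published selection. A ceiling-based boundary
(`ranks > ⌈3n/4⌉`) would keep 19 for n = 25 and was rejected for that
reason.

"Better binding than the reference" is interpreted as Δ < 0 (more negative
is more favorable); this reading is validated by the packaged table, where
exactly 13 analogs have negative MP2-level Δ.

# PIEDA and consensus

`pie_total()` is the five-component sum
(electrostatic + charge-transfer/mixing + dispersion + exchange +
solvation), signs ingested as printed. ΔPIE fingerprints treat residues
missing from one fragmentation list as zero-with-a-flag rather than errors,
because FMO fragmentations differ per ligand. Interaction *detection* is
out of scope: the consensus operation consumes boolean matrices and returns
residues present in ≥ the consensus fraction (default 50 %) of analogs.

# The toy world: what it emulates and what it does not

The synthetic dynamics live on the (d_OP, θ_OPO) plane under a
sum-of-Gaussian-wells potential with kT ≡ 1 (all energies in k_BT):

* `two_basin_side_GM`: a *side* basin at (4.4 Å, 90°) — deeper by
  1.5 k_BT — and an *apical* basin at (3.5 Å, 160°), widths
  (σ_d, σ_θ) = (0.35 Å, 12°) for both. Depths are calibrated by root
  search so the inter-basin saddle sits exactly `barrier_kbt` (default 5)
  above the apical minimum.
* `single_basin_apical`: the apical basin alone.

Basin centers echo printed near-attack geometries (apical d ≈ 3.5 Å as in
the top-ranked analog complex; side θ well below the 120° zone); they are
scenario defaults, not claims about real AChE. Widths were chosen once so a
basin spans several analysis-grid bins per coordinate (the 30×30 default
grid has 0.27 Å × 6° bins); the 1.5 k_BT depth offset makes the side basin
an unambiguous global minimum while leaving both hopping directions
observable within the default sampling budget.

Dynamics are overdamped Euler–Maruyama with per-coordinate friction,
reflecting walls for θ at 0°/180° (an angle range is not periodic) and for
d at 2/10 Å (confining the walker to the analysis window). One recorded
frame = 1 time unit (the toy analog of 1 ps), realized as `substeps`
integrator steps. Scenario parameters: dt = 8×10⁻⁴ with 1250
substeps/frame, γ = (1, 0.05). Two things are deliberate here:

* The generic parameter defaults (dt = 0.01, isotropic γ = 1) **fail the
  stability bound** dt·max|U″|/γ < 0.1 on the calibrated surfaces
  (max|U″| ≈ 95 k_BT/Ų) — the propagator constructor warns. Scenario
  parameters are the supported configuration.
* Friction is anisotropic because the coordinates have incommensurate
  units: γ_θ = 0.05 gives the angle a diffusivity (20 deg²/time) under
  which basin hopping over 5–6.5 k_BT occurs on the scale of tens of
  cycles, so a default-size run contains enough transitions to estimate
  the landscape.

The toy emulates: metastability with a tunable barrier, the distance/angle
coupling that DS-MD exploits, Boltzmann statistics at kT = 1, and trajectory
segmentation identical to the real protocol. It does **not** emulate
inertial dynamics, solvent memory, all-atom roughness, or any real AChE
energetics — so a green landscape test establishes that the estimator
recovers planted physics, not that the physics matches the enzyme.

# DS-MD

Each replicate runs `n_cycles` (default 100) segments of `steps_per_cycle`
(default 100) frames; the next cycle restarts from the earliest frame of
the current segment attaining the minimum selection metric (the
ligand–phosphorus distance by default, configurable). Positions are
inherited; stochastic degrees of freedom are re-drawn under the new cycle
seed — restarting with identical noise would replay the segment. Because
frame 0 of every segment reproduces the restart state, the selected metric
is non-increasing by construction; this is asserted, not assumed.

Per-cycle seeds are drawn once from the master seed into a
replicate × cycle table, so runs are bit-reproducible and replicates
independent. The published protocol's stated totals ("1 ns") conflict with
its cycle arithmetic (100 × 100 ps); the cycle parameters are authoritative
here and totals are derived.

A known property of the greedy ratchet: once the selected distance reaches
the low-d plateau below the apical basin it can pin at the reflecting wall
(the selection never releases a minimum). This over-sharpens *sampling*
toward small d, which is precisely why the landscape is read from the MSM
(transition statistics) rather than from raw occupancy.

First-passage comparisons against plain MD use the 2σ core of the apical
basin (d < 4.2 Å, θ > 136°; `toy_system()$apical_core`) as the target:
the 120° zone edge alone can be grazed by side-basin fluctuations without a
basin change, which would contaminate the measurement.

# MSM and free-energy landscapes

Frames from cycles after the burn-in (default 30) are discretized on a
regular 30×30 grid over d ∈ [2, 10] Å, θ ∈ [0, 180]° (half-open bins,
closed final bin, out-of-range frames clipped with a warning — the grid is
explicit configuration because the original analysis does not state one).
Transitions are counted at lag 25 frames strictly **within** per-cycle
segments: a selection restart is a discontinuity, not dynamics, so counts
never bridge it. Whether the original analysis crossed cycle boundaries is
unknowable from the text; excluding them is the defensible choice and is
flagged as a divergence risk.

Estimation is non-reversible maximum likelihood: restrict to the largest
strongly-connected component of the count graph (guaranteeing a unique
stationary distribution), row-normalize, and obtain π by power iteration
(fixed-point residual < 1e-8 enforced; agreement with a direct eigen-solve
is a test). Reversible estimators were rejected because they are iterative
and implementation-dependent, while row normalization is exactly
reproducible; the price is that detailed balance is not enforced, so the
model reports the largest flux asymmetry `max |π_i T_ij − π_j T_ji|` as a
diagnostic.

The landscape is F_i = −ln(π_i/π_max) in k_BT, zero at the global-minimum
bin, undefined off the active set. Minima analysis:

* GM = lowest-F active bin (ties: lowest column-major index).
* LM = active bins strictly below all 8-connected active neighbors, with at
  least one active neighbor, F ≤ `lm_cap` (default 4 k_BT), excluding the
  GM.
* Barrier(LM → GM) = minimax path height (Dijkstra with max-along-path
  cost over active bins, validated against exhaustive enumeration) minus
  F(LM).
* **Prominence filter** (`min_prominence`, default 2 k_BT): strict grid
  minima whose barrier to the GM is below the threshold are discarded.
  Sparse bins carry ~1 k_BT noise in estimated F, which otherwise
  manufactures shallow "minima" on basin flanks; genuine metastable states
  in this problem sit behind ≳4 k_BT barriers, so the 2 k_BT threshold
  separates the populations cleanly. This filter is the package's own
  robustness addition to the stated minima definition.

# Numerical conventions

* Energies compared exactly as ingested; the reference row's Δ is set to an
  exact 0. Unicode minus and en-dash normalize to ASCII.
* Ties: earliest frame at equal selection metric; lowest bin index at equal
  F; code order at equal affinity/energy.
* Seeds: every stochastic entry point takes an explicit seed; per-cycle
  seeds derive from the master seed via one `sample.int()` table; all seeds
  stay below 2³¹.
* PDB coordinates are written at 10⁻³ Å precision; the pose generator
  samples with safety margins so rounding cannot flip an apical
  classification.

# Known limitations

* Registry ids 4–9 are placeholder chemistry; SMILES-level conclusions for
  those ids are illustrative only.
* The BBB surrogate is a threshold rule, not a validated classifier.
* Descriptor values inherit whatever RDKit version is on the PATH;
  cross-version drift in logP/TPSA is possible (counts in the shipped
  tests do not depend on it).
* The MSM layer implements no implied-timescale or lag validation, no
  reversible estimation, and no coarse-graining; it is a landscape
  estimator for the toy world, not a general MSM toolkit.
* Barrier estimates from the default sampling budget carry a few-tenths
  k_BT of bias (discretization plus minimax-over-noisy-bins), well inside
  the ±1 k_BT acceptance band but visible against the calibrated truth.
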