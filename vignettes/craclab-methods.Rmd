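---
title: "Models and methods behind craclab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind craclab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craclab)
```

craclab models store-operated Ca²⁺ entry (SOCE) through CRAC channels built
from the ORAI1/2/3 subunit isoforms, and implements the quantification rules
used to score single-cell Ca²⁺ recordings. This vignette explains the models,
their assumptions, the tunable parameters, and the design choices made where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The ORAI dimer equilibrium model

CRAC channels are hexamers, but a hexamer-resolved model would need 28–56
species with distinct conductances and is far beyond what knockout influx
data can constrain. The model therefore stops at the dimer level: monomers
$O_1, O_2, O_3$ with fixed totals $I_i$ associate pairwise at equilibrium,

$$O_{ij} = K_{ij} O_i O_j,$$

with symmetric association constants $K_{ij}$ (units 1/concentration; only
ratios are meaningful). Conservation of each isoform reads

$$O_i + 2 K_{ii} O_i^2 + \sum_{j \ne i} K_{ij} O_i O_j = I_i ,$$

and each dimer species carries a conductance $\alpha_{ij}$, so the
population Ca²⁺ influx is $J_\mathrm{in} = \sum \alpha_{ij} O_{ij}$.
Knockout genotypes are represented by zeroing the corresponding totals —
nothing else in the model changes.

`solve_equilibrium()` finds the unique non-negative root of the coupled
conservation equations by damped Newton iteration on $\log O_i$
(positivity is automatic; isoforms with $I_i = 0$ are dropped from the
system), falling back to the globally convergent damped fixed-point map
$O_i \leftarrow I_i / (1 + 2K_{ii}O_i + \sum_{j\ne i} K_{ij}O_j)$ when
Newton stalls. The default tolerance is a maximum conservation residual of
1e-10. The test suite checks the solver against this fixed-point map run as
an independent oracle, and against the closed-form quadratic root for the
single-isoform case.

A note on conventions: one published rendering of the single-isoform
conservation equation counts the free monomer twice
($2O_1 + 2K_{11}O_1^2 = I_1$). That form is inconsistent with the
three-isoform conservation laws above, so craclab defaults to the
mass-balance form and retains the doubled-monomer variant as
`convention = "doubled_monomer"` in `solve_homodimer_K()` for exact comparison
with the published algebra. Both conventions are exercised in tests.

## Calibrating the binding constants

The calibration inputs are seven genotype influx targets
$d_{11}, d_{12}, d_{13}, d_{22}, d_{23}, d_{33}, d_{123}$ (the influx when
the indicated isoforms are present; defaults 0.06, 0.05, 0.05, 0.002,
0.002, 0.001, 0.045). Estimation is staged:

1. **Homodimers, algebraically.** With one isoform present,
   $d = \alpha K O^2$ together with conservation gives
   $O = I - 2d/\alpha$ and $K = d/(\alpha O^2)$, feasible only when
   $I > 2d/\alpha$ (`solve_homodimer_K()`).
2. **Cross constants, by one-dimensional root scan.** With two isoforms
   present the three unknowns reduce to one: for each trial $K_{ij}$ the
   two conservation equations fix the free monomers, and the influx
   equation becomes a scalar root problem, scanned over $[1, 500]$ on a
   log grid and refined by `uniroot` to 1e-8 (`solve_cross_K()`). When
   several sign changes are bracketed the smallest root is returned with a
   warning.
3. **Feasibility continuation.** The cross-constant root exists only where
   sequestration into weakly conducting cross dimers can actually lower
   the predicted influx to the target, i.e. only when
   $\alpha_{11}/\alpha_{1j}$ is large enough. `feasibility_boundary()`
   scans that conductance ratio, records where the root exists, and
   refines the single crossing by bisection. The boundary is exactly
   invariant under jointly rescaling all $d$ and $\alpha$ by a common
   factor (a property the tests assert). Its numerical location is,
   however, sensitive to the *separate* scale of the $d$ targets relative
   to $\alpha$, because that scale sets how deeply the ORAI1 pool is
   dimerized; the acceptance suite records where the boundary falls under
   the literal printed inputs.
4. **Least squares.** `fit_all_K()` minimizes the misfit of all seven
   influx equations over the six constants, parametrized in log space,
   using Levenberg–Marquardt. Because the targets span a 60-fold range, an
   optional relative-error weighting is provided and is the right choice
   whenever the small targets ($d_{22}, d_{33}$) must constrain their
   constants; the recovery tests use it. The fit is deterministic given
   its starting point (normally `init_from_algebra()`, i.e. stages 1–2),
   and its residual never exceeds the initialization residual.

Identifiability has sharp edges worth knowing: the homodimer algebra
amplifies noise in $d_{11}$ roughly tenfold into $K_{11}$ when the free
monomer pool is small, and the printed target set is not exactly
representable by the model (no parameter set makes the wild-type influx
strictly smaller than the ORAI3-knockout influx while fitting both), so a
least-squares compromise equalizes the ORAI1-containing genotypes. The
round-trip tests therefore quantify recovery on *forward-generated*
calibrations, where ground truth exists: exact recovery without noise, and
a median per-constant relative error around 20% at 5% multiplicative noise.

## The whole-cell Ca²⁺ oscillation model

The Ca²⁺ dynamics layer is a deliberately standard two-compartment
oscillator; it is a stand-in for the much larger published model family it
emulates, because its role here is qualitative: reproduce the *orderings*
(frequency rises with agonist; high-influx genotypes plateau earlier;
store-depletion re-addition responses order by influx) rather than absolute
periods or amplitudes. State variables are cytosolic Ca²⁺ $c$ (µM), ER
Ca²⁺ $c_{ER}$ (µM), and an IP₃R inactivation gate $h \in [0,1]$:

$$\frac{dc}{dt} = J_\mathrm{rel} - J_\mathrm{SERCA}
  + J_\mathrm{in}\, s(c_{ER}) - J_\mathrm{PM},\qquad
  \frac{dc_{ER}}{dt} = \gamma\,(J_\mathrm{SERCA} - J_\mathrm{rel}),$$

with $J_\mathrm{rel} = (k_f P_o^3 + \nu_\mathrm{leak})(c_{ER} - c)$,
$P_o = \frac{p}{p + K_p}\,\frac{c}{c + K_a}\,h$, first-order relaxation of
$h$ toward $K_i/(K_i + c)$ with time constant $\tau_h$, Hill-2 SERCA and
plasma-membrane pumps, and store-operated entry gated by the decreasing
sigmoid $s(c_{ER}) = K_s^n/(K_s^n + c_{ER}^n)$ ($n = 4$; $K_s$ chosen so
the resting store gives $s \approx 0.1$, i.e. mostly closed at rest). The
parameter $p$ (µM) is the agonist surrogate. $J_\mathrm{in}$ is the dimer
model's genotype influx on the calibration scale (wild type 0.045), and
`calibrated_influx()` bridges the two modules.

Two design constraints shaped the defaults (`oscillator_params()`):

* **PM fluxes are small relative to ER exchange** (extrusion capacity
  0.005 µM/s against SERCA capacity 0.225 µM/s), so spikes are IP₃R-driven
  while the *net Ca²⁺ load* — and with it the oscillation frequency — is
  set by influx. This is what makes frequency a read-out of $J_\mathrm{in}$
  and makes oscillations transient when influx is zero: each spike loses
  Ca²⁺ across the PM that only store-operated entry can replace.
* **Time scale.** The vector field is calibrated so spike periods sit
  around a minute (an exact time-rescaling of the dynamics; it changes no
  ordering), which matches the cadence of the imaging experiments the
  trace classifier was designed for and keeps model spikes well above the
  classifier's peak-separation window.

Integration uses `deSolve::ode` (lsoda, relative tolerance 1e-8) segment
by segment along a `cell_protocol()`; thapsigargin is modeled by setting
the SERCA flux to exactly zero, and Ca²⁺-free episodes by disabling entry.
`agonist_staircase()` and `thapsigargin_protocol()` wrap the two standard
protocols; `staircase_summary()` reduces a staircase to per-level
frequency, mean, and CV, labeling a level a plateau when its
post-transient CV falls below 0.1 while the mean stays above rest. With
influx-free ("triple knockout") parameters the closed-cell invariant
$c + c_{ER}/\gamma = \text{const}$ holds to solver tolerance when the PM
fluxes are switched off, and this is tested.

Simulated traces in the tests use dwells of 1680 s per staircase level
(five levels), 1600 s + 1200 s thapsigargin protocols, and a 3600 s run
for the transience check; at 1–2 s output sampling these integrate in
well under a second each.

## Trace classification and quantification rules

The published scoring of Fura2 recordings was manual; craclab
operationalizes it with explicit, config-exposed knobs
(`classification_rules()`):

* baseline = median of the 60 s before stimulation;
* candidate peaks are local maxima of the (lightly smoothed) signal above
  baseline + 10% of the peak-to-baseline span, at least 30 s apart;
* a peak "returns to baseline" when the trace drops below baseline + 20%
  of the span before the next peak; only returning peaks are counted
  (the last peak is counted unconditionally since the window may truncate
  its decay);
* **plateau**: signal continuously at or above 25% of the initial peak for
  at least 300 s after stimulation (tested to be sharp at the 5-minute
  boundary);
* **oscillating**: at least two counted peaks; the count is reported over
  the 840 s (14 min) window after stimulation;
* **non-responder**: everything else — flat traces (span below the
  `min_response` threshold, default 0.05 signal units; the published rule
  gives no numeric threshold for "no response", so this choice is exposed
  and flagged) or a single initial spike.

Two defaults deserve justification because they differ from the obvious
first choice. A minimum peak separation of 20 s with no smoothing admits
noise-induced secondary maxima on spike decay flanks — measured on the
generator's own default populations this miscounts over 10% of
oscillating cells. The shipped defaults (30 s separation plus a 10 s
moving-average pre-filter) bring label accuracy and exact-count accuracy
to 100% on the default populations across 20 seeds, which the acceptance
tests verify. Both knobs remain configurable for data with a different
cadence.

The remaining quantifications are direct formulas: SOCE magnitude as the
post-re-addition maximum over a 60 s pre-re-addition baseline-window mean
(clipped at zero with a flag); fast Ca²⁺-dependent inactivation as the
fraction of peak current remaining at 146 ms (linear interpolation);
three-cube FRET as $F_c = I_{DA} - \mathrm{bleed}_d I_{DD} -
\mathrm{bleed}_a I_{AA}$ with apparent efficiency
$E = F_c/(F_c + G\,I_{DD})$ — a published rendering with an extra $F_c$
factor is preserved as `formula = "replication"` since it appears to be a
typesetting error, and the discrepancy is pinned down in tests
($F_c = G I_{DD} = 2$ gives 0.5 standard vs 1.0 replication; the standard
form is also scale-invariant, which is asserted); and NFAT translocation
as nuclear over total fluorescence.

## The synthetic-data generator

`gen_population()` emulates the recording structure the classifier was
built for: 960 s recordings sampled at 2 s, stimulation at 60 s, a
0.65/0.26/0.09 mixture of oscillating/plateau/non-responding cells, Fura2
ratio units (baseline 0.3, spike amplitude 0.5 ± 15%), oscillation counts
uniform on 4–8 per 14-minute window, and i.i.d. Gaussian noise (default
SD 0.02). Spikes are asymmetric gamma-like pulses (fast rise, slower
decay) so the classifier is not tuned to one pulse shape; plateaus hold at
55% of their peak, comfortably above the 25% rule line (margin at least
twice the noise SD by construction); non-responders are flat or show a
single initial spike. Everything is reproducible from the spec's seed.

What the generator does *not* emulate — photobleaching, focus drift,
motion artifacts, segmentation errors, baseline wander, heterogeneous
per-cell noise — bounds what passing tests show: the classifier
implements the stated rules faithfully and robustly against additive
Gaussian noise, not against every artifact of real imaging.
`gen_fret_set()` inverts the standard E-FRET relation so the noiseless
ground truth is exact, and `gen_calibration()` forward-generates influx
targets from known binding constants for the estimation round trips.

## Hexamer combinatorics

When position on the hexameric ring matters, arrangements are counted up
to the 12 dihedral symmetries of the hexagon by Burnside's Lemma: the
rotations contribute cycle counts 6, 1, 2, 3, 2, 1 and the reflections
$3 \times 4$ and $3 \times 3$, giving
$\frac{1}{12}(n^6 + 2n + 2n^2 + 4n^3 + 3n^4)$ distinct arrangements of
$n$ isoform types — 92 for three, 13 for two, 1 for one. Inclusion–
exclusion then yields exact-palette counts (56 using all three isoforms;
33 using exactly two, summed over pairs). When only stoichiometry matters
the count is the stars-and-bars value $\binom{n+5}{6}$ (28, 15, 10 for the
corresponding cases). A rotation-only ("necklace") mode is provided
because a membrane-embedded channel arguably cannot be reflected; no
claim is made about which symmetry is physical, and the dihedral mode
remains the default. Every counting mode is verified against exhaustive
canonicalization of all $n^6$ labellings (guarded at $n \le 4$), with the
lexicographically smallest group image as the canonical representative.

## Known limitations

* The dimer model ignores hexamer assembly, STIM binding kinetics, and
  Ca²⁺-dependent inactivation; its influx is an equilibrium quantity.
* The oscillator is a stand-in: absolute periods, amplitudes and agonist
  thresholds are tuning parameters, not predictions. Only orderings and
  monotonicities across genotypes and agonist levels are treated as
  results, and only those are tested.
* The feasibility boundary's numerical value depends on the overall scale
  chosen for the influx targets; craclab reports it for the inputs given
  rather than asserting a universal constant.
* The classifier's operational thresholds are one reasonable encoding of
  a manual protocol; per-laboratory retuning via `classification_rules()`
  is expected.
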