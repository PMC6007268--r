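---
title: "Fitting RNA nearest-neighbor parameters through an ensemble melting model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting RNA nearest-neighbor parameters through an ensemble melting model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamelt)
```

## The problem

Nearest-neighbor (NN) free-energy parameters for RNA Watson–Crick helices
are traditionally obtained in two steps: each optical melting curve is fit
under the two-state assumption (molecules are either fully duplexed or
fully denatured) to yield per-duplex ΔH° and ΔS°, and NN terms are then
obtained by linear regression over many duplexes. But partition-function
calculations with those same parameters — and NMR experiments — show
partially melted helices, in particular fraying of terminal base pairs.
`rnamelt` implements the alternative: fit the NN enthalpies and entropies
*directly* to the melting curves through an ensemble (partition-function)
model that allows every intermediate pairing state, with the classical
two-state analyses retained as comparison baselines.

## Model and assumptions

**No-slip ensemble.** For a duplex of `L` pairs, a pairing state is any
subset of positions paired to their complements; strands cannot shift
register (the duplexes are designed with a unique registration), hairpins
and higher-order species are out of scope. Unpaired runs between two
helices are symmetric disordered internal loops, parameterized only by
per-side length `n = 1..8` ("8×8"); nothing larger is realizable at
`L ≤ 10`. Frayed single-stranded ends carry zero energy (no dangling-end
terms).

**Energy model.** A state's ΔG° is: intermolecular initiation (once), one
stack term per adjacent pair of paired positions, one `loop_n` term per
internal gap, a terminal AU penalty for each A-U/U-A pair at a helix end,
and, for self-complementary duplexes, a fixed symmetry correction
ΔS_sym = −R ln 2 = −1.377 cal/(mol·K) per paired structure. Two choices
here were genuinely open:

- *Terminal AU placement.* The penalty is applied at **every** helix end —
  duplex-terminal, loop-flanking, and fray-flanking — the consistent
  helix-end convention. An isolated pair pays it on both sides. The
  alternative (outer ends only) is a one-line change in the layout code.
- *Symmetry correction.* Self-complementary duplexes receive the fixed
  (not fitted) −R ln 2 entropy once per structure, assigned to the
  initiation weight so the left/right factorization counts it once. This
  matches the convention of the literature parameter set used for
  comparison. Notably, one corpus strand (5′-UUAUCGAUAA) is its own
  reverse complement even though the source annotates it as melted against
  a separate complementary strand; the package derives self-complementarity
  from the sequence and preserves the source annotation separately in the
  fixture.

**Recursions.** `Q_L,i` / `Q_R,i` are built from the 5′/3′ ends with
stack, loop and end-term transition weights. The implementation pins them
to two exact identities rather than to any particular bookkeeping:
`Σ_i Q_L,i = Q − 1` (classification by rightmost pair) and
`Q_L,i · Q_R,i` = total weight of structures containing pair `i` with
initiation counted once, so conditional pair probabilities are
`P_i = Q_L,i Q_R,i / (Q − 1)`. Both identities are tested against
brute-force enumeration over all valid states at `1e-9` relative
tolerance.

**Concentration algebra.** The probability that any pairing exists comes
from bimolecular mass balance with ensemble constant `K = Q − 1`:
`P = (1 + x − sqrt(1+2x))/x` with `x = K·C_T` for heteroduplexes, and
`P = (1 + 4x − sqrt(1+8x))/(4x)` for self-complementary strands. These are
evaluated in conjugate form (`x/(1+x+sqrt(1+2x))`, `4x/(1+4x+sqrt(1+8x))`),
which is exact and cancellation-free down to `x = 0`. The small-`x` limits
are `x/2` and `2x`; the naive series statement `x` sometimes quoted for the
self-complementary case is off by a factor of two (Taylor expansion and the
mass-balance oracle agree on `2x`).

**Fraction of maximal pairs.** `X(T) = P_bp · Σ_{i=1..L} P_i / L`. The sum
runs over *all* positions including the terminal pairs; excluding them
would cap `X` below 1 for a fully paired duplex and contradict the
denominator `L`.

## Data transformation

Absorbance curves are transformed with linear baselines fitted to the
first/last 10% of points (fractions of the point count, overridable per
curve through the manifest — mirroring the manual window adjustment that
melting studies describe; no automatic window search is attempted).
Fractions are deliberately **not clamped** to [0, 1]: the least-squares
objective must see real noise excursions. Temperatures are °C at all
interfaces and kelvin internally. Experimental Tm is the first 0.5 crossing
by increasing temperature (with a warning if noise produces several).

A systematic effect worth knowing about: thermodynamic melts never reach
`X = 1` or `X = 0` exactly (residual dissociation at low temperature, end
fraying, residual association at high temperature), so the "baseline"
windows of weak or AU-rich duplexes are contaminated by transition signal.
Estimated baselines are then biased, and parameters informed mainly by such
melts can drift far while still fitting the distorted fractions well — the
test suite quantifies this on synthetic data (`test-synthetic.R`). Exactly
this motivates manual window adjustment in practice; the package exposes
per-curve overrides and a `transform = "exact"` mode (generating baselines)
in the synthetic generator to separate the two error sources.

## Fitting

The 40 parameters (ΔH°, ΔS° for 10 stacks + initiation + terminal AU + 8
loop lengths) minimize the unweighted sum of squared per-point differences
between measured and modeled fractions. Implementation choices:

- **Scaling.** ΔH°/10 and ΔS°·(310.15/10000) bring both families to
  magnitude ~1 for the optimizer.
- **Algorithm.** Levenberg–Marquardt with Marquardt (scaled-diagonal)
  damping and a Nielsen-style gain-ratio λ update; forward finite-difference
  Jacobian (step 1e-6 on scaled parameters). The damping diagonal is
  floored at 1e-6 of its largest element: loop parameters have essentially
  zero curvature on loop-free data and undamped steps would explode along
  those directions.
- **Globalization.** Strongly perturbed starts (the ±20% multistart
  protocol) can displace every predicted transition outside the measured
  temperature window; there the finite-difference gradient is numerically
  dead and damped least squares stalls on a plateau. A 1-D pre-search over
  a global stability offset — applied to the initiation enthalpy, the one
  feature every duplex carries exactly once — recentres the ensemble for a
  few dozen residual evaluations before the main iteration, and is a no-op
  for well-placed starts. With it, all multistart runs reach the same
  minimum on synthetic corpora.
- **Convergence.** Relative residual-norm reduction < 1e-10, relative step
  norm < 1e-10, or residual norm < 1e-6 absolute (the last fires only on
  noiseless synthetic data, where the optimum is exactly zero and relative
  criteria never trigger). Non-convergence within `max_iter` is reported as
  a flagged result, not an error.
- **Multistart.** Starts are the base parameters perturbed by independent
  uniform variates of up to ±20%; a master seed spawns per-start
  substreams. On loop-free data the residual norm and the helix-feature
  ΔG°37 agree across starts to ≤ 0.001 and ≤ 0.01 kcal/mol respectively,
  while loop parameters scatter widely — they simply are not constrained.
- **Reporting.** ΔH° and ΔS° are strongly anti-correlated over the narrow
  melting range; ΔG°37 is the comparable quantity and is what fits,
  jackknife summaries and spreads report.

The two-state baselines: per-curve non-linear fits of absorbance with
joint linear baselines and a bimolecular two-state transition; and the
error-weighted linear NN regression over per-duplex ΔH°/ΔS°/ΔG°37
summaries, solved by SVD (weights 1/σ², uncertainties from the
variance–covariance diagonal, rank deficiencies reported by feature name —
the full 34-duplex design is full-rank, but small subsets often are not).
When two-state parameter sets are evaluated inside the ensemble model their
missing loop terms are set to ΔH° = 10.0 kcal/mol, ΔS° = −1.0 cal/(mol·K)
(~10 kcal/mol penalty), which effectively forbids loop formation, as a
two-state model requires.

Jackknife: one refit per left-out duplex (warm-started from the full-data
fit), held-out RMSD per duplex, and plain standard deviations of the
parameters across resamples as the uncertainty (no n−1 inflation beyond
`sd()`; the jackknife-specific variance inflation would scale these by
√(n−1) and is noted here as the alternative convention).

## Synthetic data: the stated world

The generator emulates the experimental design of the melting corpus:

| knob | default | why |
|---|---|---|
| temperature grid | 10–90 °C, 0.5 °C | ~160 points per melt, the typical instrument range |
| baselines | lower 5e-4·T + 0.60, upper 1.2e-3·T + 0.70 AU | upward-sloping, ~0.10–0.13 AU hyperchromic gap, non-crossing in-grid |
| absorbance noise | 0.002 AU additive Gaussian | instrument-scale noise on the measured quantity (not on fractions); the value is a fixture choice, configurable |
| concentrations | per-duplex: two-state midpoint at 45 °C, ×2^(−3.5..3.5) | experimenters pick strand concentrations per duplex so transitions sit inside the measured range; 8 melts over a ~180-fold range |
| generating parameters | literature helix set + loops ΔH° = 0, ΔS° = −(8+n) e.u. | loop ΔG°37 ≈ 2.8–5.0 kcal/mol, the expected magnitude for symmetric disordered loops |

Curves are deterministic given the master seed. What a green test on this
world establishes: the estimator recovers the generating thermodynamics
from data with the assumed structure (linear baselines, additive noise,
ensemble transitions, correct model family). What it does not establish:
robustness to heat-capacity effects (ΔCp is assumed zero), wavelength or
hypochromicity sequence dependence, instrument drift, or model
misspecification — none of which the generator emulates.

## Numerical notes

- Boltzmann factors are computed from fully accumulated ΔG per transition;
  at `L ≤ 10` and physical parameter ranges no log-space arithmetic is
  needed, and non-finite partition values raise an explicit error.
- Predicted Tm uses bisection to 0.001 °C (robust to flat tails), not
  Newton.
- Degenerate inputs: baselines that do not separate raise errors in the
  fraction transform; flat curves are flagged degenerate; curves that never
  cross 0.5 raise a no-transition error; a zero-variance paired t-test is
  reported undefined and not significant.

## Known limitations

- GU wobble pairs, sequence-dependent loop terms, dangling ends, coaxial
  stacking, hairpins and slipped registers are out of scope.
- ΔCp = 0: parameters are most accurate near the duplex melting
  temperatures, reasonable roughly between 10 and 60 °C.
- The raw 285-curve experimental corpus behind the reference duplex list is
  not publicly deposited; the package's quantitative claims are therefore
  validated on exact combinatorial targets and on synthetic data, not by
  reproducing the published fitted values.
- Baseline-window contamination by fraying biases the end-to-end pipeline
  for weak or AU-rich duplexes (see above); per-curve window overrides are
  the intended mitigation.
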