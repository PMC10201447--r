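---
title: "RNA duplex thermodynamics under molecular crowding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA duplex thermodynamics under molecular crowding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdnn)
```

## The problem

Classical RNA nearest-neighbor (NN) parameters were measured in dilute
1 M NaCl.  Cells are different on both axes: monovalent salt sits near
100 mM (mostly K⁺, with Mg²⁺ present), and 20–40% of the volume is
occupied by macromolecules.  Crowding acts on duplex stability through
two separable physical channels — the volume excluded to cosolutes, and
the depression of water activity — while the cation environment acts
through charge screening.  `crowdnn` implements an NN parameter set
determined directly under a crowded, physiological-salt condition
(40 wt% PEG200, 100 mM NaCl; 122 mM total Na⁺ counting the buffer), and a
four-term decomposition of every NN free energy that allows the set to be
recomposed for other cosolutes, concentrations and cation modes.

## Model and assumptions

Duplex formation is additive over dinucleotide stacks:
$\Delta G^\circ_{37} = \sum_i \Delta G^\circ_{37,\mathrm{NN}(i)}
 + \Delta G^\circ_{37,\mathrm{init}} + k\,\Delta G^\circ_{37,\mathrm{term\,AU}}
 + \Delta G^\circ_{37,\mathrm{sym}}$,
with 10 canonical Watson–Crick stack types, one initiation parameter, a
per-terminal-A·U penalty ($k \in \{0,1,2\}$) and a symmetry correction
(+0.43 kcal mol⁻¹, ΔS° = −1.4 cal mol⁻¹ K⁻¹) applied only to
self-complementary strands.  Assumptions inherited from the experimental
analysis:

* **Two-state melting, ΔCp = 0.**  ΔG°(T) = ΔH° − TΔS°.
  `free_energy_at()` warns beyond ±25 K of 310.15 K, where the zero-ΔCp
  extrapolation degrades.
* **Bimolecular association** with the symmetry factor absorbed into
  $T_m^{-1} = R\ln(C_t/s)/\Delta H^\circ + \Delta S^\circ/\Delta H^\circ$,
  $s = 1$ (self-complementary) or $4$; $C_t$ is *total* strand
  concentration.  No per-strand $C_t/4$ convention is offered.
* **Only fully complementary duplexes** (plus declared G·U wobbles) are
  accepted.  Mismatches, bulges and dangling ends are out of scope.
* **G·U ≈ A·U.**  Both pairs carry two hydrogen bonds; declared wobbles
  are substituted G→A before parameter lookup.  A terminus closed by a
  normalized wobble counts as a terminal A·U — an extrapolation (the
  equivalence argument does not address the terminal penalty directly),
  flagged in prediction warnings.

The environmental decomposition is
$\Delta G^\circ_{37,\mathrm{NN}} = \Delta G^\circ_\mathrm{bulk}
 + \Delta G^\circ_\mathrm{cation} + \Delta G^\circ_\mathrm{ev}
 + \Delta G^\circ_\mathrm{wa}$,
per stack and for initiation; the terminal A·U penalty carries only bulk
and water-activity parts (terminal pairs are treated as Na⁺-independent,
and their excluded volume is already counted via initiation).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| gas constant R | kcal mol⁻¹ K⁻¹ | 1.9872×10⁻³ | free-energy relation uses 310.15 K explicitly |
| entropy unit | kcal mol⁻¹ K⁻¹ | converted once at load | tables print cal; a single conversion point prevents 1000× slips |
| wt% convention | g cosolute / 100 g water | `C = 10·w/M` | uniquely reproduces the −0.45 kcal mol⁻¹ excluded-volume benchmark of the 11-mer in 10 wt% EG (the mass-fraction reading gives −0.50) |
| monomer count N | — | 1 for small cosolutes; `round((M−18)/44)` for PEGs (PEG200 → 4) | with N = 4 the length-averaged per-stack excluded volume reproduces the tabulated −0.22 kcal mol⁻¹ |
| Δa_w (reference) | — | 0.0489 for 40 wt% PEG200 | row-mean of `dG_wa/m_PEG` over the decomposition table; rows agree within 0.001 |
| cation anchors | mM Na⁺ | 0 at 10; table column at 122 | only these anchors are published; other concentrations require a registered model, never silent interpolation |
| noise regime (generator) | kcal mol⁻¹ | σ(ΔG°₃₇) = 0.3, σ(ΔH°) = 3 | consistent with the ~4% replicate scatter of duplicate NN-set sequence pairs |
| stability floor (generator) | kcal mol⁻¹ | ΔG°₃₇ ≤ −4 | mirrors the experimental selection of analyzable two-state duplexes |

Osmometry is converted through the water potential,
$\ln a_w = \Psi M_w/(RT\rho_w)$ with
$\Psi(\mathrm{kPa}) = \mathrm{osmolality}\,(\mathrm{mmol\,kg^{-1}})
\times 10^3 / (-400)$.  Reading the quotient as kPa (not MPa) is a
deliberate dimensional reconciliation: it reproduces the physical
benchmark $a_w \approx 0.982$ at 1 osmol kg⁻¹, which the MPa reading
misses by three orders of magnitude.

## Composing a condition

`compose_condition_parameters()` assembles, per stack and initiation,
`bulk + cation + ev/n + m_cs·Δa_w`, and for the terminal A·U penalty
`bulk + m_cs·Δa_w`.  Because the per-stack excluded-volume share is the
duplex-level term divided by `n_bp` and applied to $(n-1)$ stacks plus
initiation, composing at the duplex's own length (what
`predict_in_condition()` does) makes the shares sum *exactly* to the
duplex-level term.  Composed sets are ΔG°₃₇-only: the decomposition is
defined for free energies, so ΔH°/ΔS° — and hence Tm — are available only
for tabulated conditions, and Tm requests on composed sets are refused.

K⁺ and intracellular predictions follow the published procedure: the Na⁺
prediction is computed first and a duplex-level affine map applied
(0.93x + 0.45 and 0.92x − 0.12 respectively).  These regressions were
fitted under 40 wt% PEG200 only; predictions under other crowders carry a
warning rather than a silent extrapolation.

## Hairpins and loops

Loop penalties (user-supplied dilute-solution values; none are bundled,
since classical loop tables are a separate body of data) rescale as
$\Delta G_\mathrm{loop}\,(1 - 11.8\,\Delta a_w)$ — a ~58% reduction of
loop destabilization at the 40 wt% PEG200 reference.  Internal loops use
the same single published rule.  `hairpin_stability()` sums composed stem
terms (bulk + cation + water activity), one initiation (the first stem
pair must still nucleate), rescaled loop penalties, and a structure-level
excluded-volume term from user geometry via the cylinder model
$V = N l^2 N_A k \times 10^{-27}$; without geometry that term is omitted
with a warning.  Two open choices were resolved conservatively and are
reported in the output: no terminal-A·U penalty is applied at either stem
end (the loop-closing pair is not a free terminus), and initiation is
included once per hairpin.

## Parameter fitting

`fit_parameters()` is ordinary (unweighted) least squares on the
stack-count design — 10 counts, an initiation column of ones, and the
terminal-A·U count — with the symmetry contribution subtracted from the
responses of self-complementary duplexes (its value is fixed, not
estimated, because it depends only on sequence complementarity).  ΔG°₃₇
and ΔH° are fitted independently, as in the original analysis; derived
ΔS° therefore inherits both fits' noise.  A weighted variant is available
behind the `weights` argument.  Rank deficiency is a hard failure that
names the unidentifiable parameter combinations from the design's null
space.

## The synthetic-data generator

`simulate_duplex_set()` emulates the measured study design: 45 duplexes
(20 self-complementary), lengths 6–12 bp, every stack present in ≥5
duplexes, a full-rank design, a stability floor of ΔG°₃₇ ≤ −4 kcal mol⁻¹,
and Gaussian response noise σ(ΔG°₃₇) = 0.3 / σ(ΔH°) = 3 kcal mol⁻¹.  It
can also emit per-duplex melting series (12 concentrations over a
100-fold range) for van't Hoff round trips.  What it does *not* emulate:
correlated ΔH°/ΔS° errors from shared baselines (enthalpy–entropy
compensation in real melts), sequence-dependent error magnitudes,
non-two-state transitions, and the hand-picked composition of the real
sequence panel.  Recovery tests on this generator therefore demonstrate
the correctness and conditioning of the estimator, not the field accuracy
of any particular measured dataset.  Under this noise regime the refit
residual profile (~2–4% in ΔG°₃₇, ~0.8–1.1 °C in Tm across seeds) brackets
the published residual summary (3.5%, 1.1 °C), and the K⁺ transfer error
(~3–5%) brackets the published 4.3%.

## Numerical choices

* All temperatures are kelvin internally; entropies kcal mol⁻¹ K⁻¹.
* Hess-law and decomposition closures are enforced at load time with a
  0.015 kcal mol⁻¹ tolerance — the half-ulp budget of values printed to
  two decimals; violations name the offending row.
* `Ct = s` makes the log term vanish and Tm = ΔH°/ΔS° without a special
  case; non-finite or non-positive Tm is an explicit error.
* The van't Hoff fit propagates standard errors by the delta method from
  the regression covariance; zero-residual (noiseless) input is legal and
  yields zero SEs.
* Seeds are mandatory for every simulation entry point, and the CLI
  echoes them.

## Problem sizes

The test suite runs the generator at its default 45-duplex size;
estimator bias and RMSE are assessed over 200 seeded replicates, chosen
as the smallest replicate count at which the Monte-Carlo error of the
RMSE (~7%) is well below the asserted bounds.  Under random (rather than
hand-picked) designs the initiation parameter is the least identifiable —
its column is nearly constant and partially collinear with total length —
so its RMSE bound (0.30 kcal mol⁻¹) is wider than that of the stacks
(0.15 kcal mol⁻¹).

## Known limitations

* Parameters cover RNA/RNA duplexes only; no DNA or hybrid sets are
  bundled (the loader accepts user tables in the same TSV format).
* The cation model is two-anchor; arbitrary Na⁺ concentrations need a
  user-registered dependence, and Mg²⁺/Ca²⁺ have no independent terms
  beyond the intracellular affine map.
* The excluded-volume length law was calibrated on 6–12 bp duplexes;
  outside that range the package warns.
* Mixed cosolutes, temperature-dependent water activity, and
  dielectric-constant effects are not modelled.
* Bulges, mismatches (other than declared G·U) and dangling ends are
  rejected by design.
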