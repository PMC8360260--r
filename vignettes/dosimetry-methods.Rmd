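---
title: "Methods: radioimmunoconjugate dosimetry with mirdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radioimmunoconjugate dosimetry with mirdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## The problem

Radioimmunotherapy development asks a quantitative question early: given the
biodistribution of a radiolabelled antibody (or fragment) in tumour-bearing
mice, what absorbed/equivalent doses will the tumour and the normal organs
receive — in the mouse, and projected to a patient? `mirdose` implements the
standard MIRD-schema answer as a reproducible pipeline, from per-animal
%ID/g tables through time-integrated activities and S-value dose kernels to
projected human doses, together with the saturation radioligand-binding
analysis used to characterise the conjugate's receptor affinity.

## Model and assumptions

**Activity reconstruction.** Biodistribution studies report decay-corrected
%ID/g. The absolute activity in a source region at time $t$ is

$$A_s(t) = \frac{\%ID/g(t)}{100} \cdot ID \cdot m_s \cdot e^{-\lambda t},$$

with $ID$ the injected activity (Bq), $m_s$ the region mass (g) and
$\lambda$ the physical decay constant (s$^{-1}$). The exponential re-applies
physical decay. If a user's table is *not* decay-corrected this term must be
suppressed (`decay = FALSE` throughout); the package makes the assumption
explicit and configurable rather than guessing.

**Time integration.** The cumulated activity is a trapezoidal AUC over the
sampling window $[0, T]$ (default $T = 48$ h) plus a tail $A_s(T)/\lambda$,
i.e. elimination after the last sample is assumed to be by radioactive decay
only. That tail assumption is conservative for slowly-cleared agents and is
the dominant term for long-lived nuclides: for ¹⁷⁷Lu sampled to 48 h the tail
typically exceeds the AUC. Three boundary rules handle the unobserved segment
before the first sample (6 h in the motivating design):

* `plateau` (default): hold the first observation back to $t=0$. Conservative
  for blood-borne agents, whose activity at early times is at least the 6-h
  value.
* `zero`: linear ramp from zero — appropriate for slowly accumulating regions.
* `linear`: back-extrapolate the first two observations, floored at zero.

The choice is recorded in every run's provenance log. Group means are
integrated by default (destructive sampling gives independent groups per time
point, so no per-animal curve exists); per-animal integration is available by
subsetting, for longitudinal (image-derived) data.

**Dose kernel.** $D(\text{target}) = \sum_s \tilde A_s \cdot
S(\text{target} \leftarrow s) \cdot W_R$, with $W_R = 1$ for β, γ and x-ray
emissions (configurable). S-value tables are **inputs**: the published
Snyder-style mouse tables and OLINDA human phantom/sphere values are
proprietary third-party data, so the package ships no numeric S-values —
tests and examples use clearly-labelled synthetic fixtures (below).
Self-dose-only tables are supported as a first-class degenerate case;
whether cross-organ contributions are included is a table property plus the
`cross_organ` flag, and is logged. Tumours are dosed exclusively through the
unit-density sphere self-dose model (no cross-dose to or from body organs),
with S interpolated **log-log linearly** in mass between the supplied curve
nodes — sphere self-dose S-values are close to power laws in mass, so
log-log interpolation is exact for the non-penetrating $S \propto 1/m$ limit
and accurate between tabulated nodes. Extrapolation outside the node range is
refused by default (nearest-node clamping available behind a flag, with a
warning).

**Human projection (%kg/g method).** Human source-organ uptake fractions are
$(\%ID/organ)_{human} = (\%ID/organ)_{mouse} \times BW_{mouse}/BW_{human}$,
with defaults 30 g and 56,900 g (adult female). Time points are left
unchanged (no allometric time scaling), so each projected organ TIA is
exactly the body-weight ratio times the mouse TIA; the implementation
exploits that identity and exposes the projected per-time %ID/organ table for
audit. The human tumour defaults to a 2 cm diameter unit-density sphere
(4.19 g) with its %ID time course projected like an organ.

**Binding assay.** Specific binding is $SB = \max(TB - NSB, 0)$; the one-site
model $SB(F) = B_{max} F/(K_d + F)$ is fitted by unweighted nonlinear least
squares (`nls`, port algorithm, positivity bounds), and the non-specific arm
as a zero-intercept line. Fitting SB after subtraction mirrors the classic
assay workflow; a joint $TB = B_{max}F/(K_d+F) + ns\,F$ fit and $1/Y^2$
weighting are available as alternative modes. Free concentration is the
nominal added concentration by default — note that with picomole-scale
$B_{max}$ in a 200 µL tube, ligand depletion at the low end of the series is
*not* always negligible; a depletion-corrected mode ($F = $ added −
bound/volume) exists but is only meaningful when supported by measured free
concentrations. $B_{max}$ converts to receptors per cell via Avogadro's
number.

**Rank-sum comparisons.** Group sizes of 3–5 animals put the Mann–Whitney
test in the exact regime: `rank_sum_exact()` enumerates all
$\binom{n_a+n_b}{n_a}$ assignments of the pooled midranks and returns the
exact two-sided p-value (proportion of assignments whose U deviates from
$n_a n_b/2$ at least as much as observed). Ties use midranks within the same
enumeration — deterministic and defensible at these sizes. Published
small-sample p-values often reflect software-specific conventions (e.g. 0.04
where complete separation of 4 vs 4 gives 2/70 ≈ 0.029); printed p-values are
therefore never used as test oracles, only the enumeration itself (checked
against a pairwise-count permutation oracle and, for untied data, R's exact
Wilcoxon test).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `T_h` | 48 | h | last biodistribution sampling time |
| `boundary_rule` | `plateau` | — | conservative for blood-borne agents; sensitivity reportable |
| `w_r` | 1 | — | radiation weighting factor for β/γ/x-ray |
| nuclide half-lives | 12.7 h (⁶⁴Cu), 6.7 d (¹⁷⁷Lu) | — | registry defaults reproduce the motivating study's arithmetic; override for precise physics (e.g. 6.647 d). Note ln2/6.7 d = 1.197×10⁻⁶ s⁻¹; a printed 1.21×10⁻⁶ corresponds to 6.647 d |
| body weights | 30 / 56,900 | g | mouse and adult-female reference weights for %kg/g |
| human tumour | 2 cm sphere (4.19 g) | — | reference lesion for projection |
| organ masses | bundled registry | g | standard ~30 g laboratory-mouse values (heart 0.15, lungs 0.2, liver 1.5, kidneys 0.4, blood 1.8, ...); studies rarely publish organ weights, so the registry is a documented default that per-animal `organ_mass_g` columns override |
| binding fit | subtract, unweighted, nominal F | — | fidelity to the classic workflow; joint/weighted/depletion modes selectable |

## The synthetic-data generators

`simulate_biodist()` emulates a destructive-sampling biodistribution study:
per time point a fresh group of animals, per organ a smooth kinetic truth
(biexponential decline, or uptake-washout for the tumour) multiplied by
mean-preserving lognormal noise (default CV 10%, the SEM/mean scale of
n = 3–5 groups). The bundled `paper_like_kinetics()` curves pass close to the
motivating study's group means — blood 10.6 → 1.9 %ID/g between 6 and 48 h,
tumour peaking near 24 h at ~15 %ID/g, liver declining slowly — and are a
convenience fixture, **not** a claim about true kinetics. What the generator
does *not* emulate: inter-animal kinetic correlation, weight variation,
counting statistics, dissection losses, or any imaging chain. A green test
against synthetic data therefore establishes the correctness of the
*arithmetic chain*, not the biology.

`make_s_value_fixture()` builds physically scaled stand-in S-value tables
from the non-penetrating-emission approximation $S = E_{mean}/m$ (J per decay
over kg). These are labelled synthetic in their provenance and exist because
the real phantom tables cannot be redistributed; their virtue is that the
energy-deposition oracle dose $= \tilde A \cdot E_{mean}/m$ is then exact, so
the entire pipeline can be verified to 10⁻⁹ relative. Doses computed from
them are *not* phantom-realistic (no photon cross-fire, no electron escape
from small organs).

## Numerical choices and degenerate inputs

* Trapezoidal AUC (the method the field's graphing tools implement); on a
  convex decaying curve the trapezoid overestimates each observed segment, so
  with an observed origin the computed total bounds the closed form
  $A_0/\lambda$ from above (a property the tests exercise).
* If the last observation precedes $T$, the tail attaches at the last
  observation with a warning rather than extrapolating unobserved clearance.
* A single-point curve integrates as rectangle plus tail under `plateau`.
* Organ masses are mandatory: there is no silent 1 g assumption.
* SB < 0 after NSB subtraction is floored at 0 with a warning.
* A fit with $K_d$ pinned at its positivity bound, or with no saturable
  component, raises a classed fit-failure error instead of returning numbers.
* Mean-preserving lognormal noise: $E[\text{factor}] = 1$ at any CV, so
  simulated group means converge to the kinetic truth (law of large numbers
  checks at n = 50 sit within 5%).
* All errors are classed conditions (`mirdose_schema_error`,
  `mirdose_missing_mass`, `mirdose_range_error`, ...) naming the offending
  row/organ, so pipelines can branch without parsing messages.

## Design choices made where the method description was open

* **Tumour/blood ratio convention.** Published tables are ambiguous between
  the ratio of group means and the mean of per-animal ratios (their 48-h T/B
  of 14.7 against printed means 15.3/1.1 ≈ 13.9 implies per-animal
  averaging). Both modes are implemented; `auto` prefers per-animal pairing
  when subject identifiers allow it, and printed-mean checks use
  `ratio_of_means` explicitly.
* **Whole-body dose source.** Reported whole-body doses rarely state their
  construction; both a measured `whole_body` row and the sum of organ TIAs
  are supported and the chosen mode is logged.
* **Integration of group means** rather than per-animal curves, matching
  destructive sampling; uncertainty propagation through the AUC is out of
  scope.
* **Replicates fitted individually** in the binding assay (no pre-averaging
  of duplicates).

## Known limitations

* No compartmental/biexponential model fitting for the AUC — integration is
  numerical, as in the motivating workflow.
* No decay-chain (daughter) dosimetry; emissions metadata are descriptive.
* No voxel/Monte-Carlo dosimetry; all spatial detail lives in the
  user-supplied S-values.
* The %kg/g projection keeps mouse kinetics unchanged — a known, simple
  convention, not a pharmacokinetic model of the human.
* Absolute dose tables from specific studies are not reproducible without
  their (unpublished) organ and tumour masses and the proprietary S-value
  tables; validation therefore rests on derived in-study quantities,
  arithmetic constants, simulation-based parameter recovery and exact
  property suites, which is what the test suite and `scripts/acceptance.R`
  compute.
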