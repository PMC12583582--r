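---
title: "Methods: risk indices, Pb-isotope mixing and the combined impact index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk indices, Pb-isotope mixing and the combined impact index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

This vignette explains the models implemented in `soilrisk`, the constants
they depend on and where those constants come from, the decisions taken where
the underlying methodology left room, and what the synthetic-data generators
do and do not emulate.

## Scope and data model

The package targets urban surface-soil surveys of the kind collected in
industrial mid-sized cities: per-sample concentrations of seven potentially
toxic elements (Zn, Cu, Ni, Pb, Cr, Cd, As; mg/kg) with pH and electrical
conductivity, per-sample profiles of fifteen USEPA priority PAHs (µg/kg),
and per-sample Pb isotope ratios with Pb concentration. Records are plain
data frames with a class tag; a below-detection PAH measurement is an
explicit `ND` state (stored as `NA`), never a silent zero, because the
ND policy materially changes sums such as the toxic equivalent concentration.

All constants live in one registry (`default_registry()`) with provenance
notes, so any exposure profile, toxicity constant or benchmark can be swapped
without touching the computational code.

## Ecological risk (Hakanson)

The single-element potential ecological risk factor is
$E_r = T_r \, C / C_n$, with the element's toxic-response factor $T_r$ and a
reference concentration $C_n$; the risk index is $RI = \sum E_r$. We use the
study's toxic-response factors (Zn 1, Cu 5, Pb 5, Cr 2, Cd 30, As 10) and the
standard Hakanson value $T_r = 5$ for Ni, which the source methodology text
omits but whose published Ni risk factors imply ($5 \times 56.19 / 20 =
14.05$, the printed mean). The references $C_n$ are the upper-continental-
crust row (Zn 31, Cu 29, Ni 20, Pb 15, Cr 35, Cd 0.09, As 4.8 mg/kg); that
choice back-solves every printed element-wise risk factor to its 2-dp
rounding.

The published threshold table is internally garbled; we adopt the standard
reading (Er: <40 low, then 80/160/320; RI: <150 low, then 300/600), which
matches the study's prose conclusions. Boundary values go to the *higher*
class (lower-inclusive intervals): an Er of exactly 40 grades moderate.

Two published inconsistencies are deliberately not reproduced: the Cd range
is printed both as 0.1–6.24 and 0.19–1.6 mg/kg (we use 0.19/1.6, the pair
that reproduces the printed Cd risk factors 63.33/533.33), and the printed
mean Cd risk factor (91.32) is inconsistent with $30 \times 0.24 / 0.09 =
80$; we compute from the printed mean and make no assertion about 91.32.

## Human health risk for PTEs (USEPA scheme)

Average daily dose per pathway, for receptor profiles `pte_child` /
`pte_adult` (ingestion rate 200/100 mg soil/day, inhalation 7.6/20 m³/day,
EF 350 d/yr, ED 6/30 yr, skin area 2800/3300 cm², adherence 0.2/0.7 mg/cm²,
dermal absorption 0.001, BW 15/70 kg, CF 1e-6 kg/mg, PEF 1.36e9 m³/kg;
AT = 365·ED days non-carcinogenic, 25 550 days carcinogenic):

$$ADD_{ing} = \frac{C \cdot IngR \cdot CF \cdot EF \cdot ED}{BW \cdot AT},
\qquad
ADD_{derm} = \frac{C \cdot SA \cdot CF \cdot AF \cdot ABS \cdot EF \cdot ED}{BW \cdot AT}.$$

The source prints the inhalation dose with the *ingestion* rate and a
kg/mg conversion factor inside it, which is dimensionally wrong: the particle
emission factor PEF already converts m³ of air to kg of soil. Our default is
the standard form $ADD_{inh} = C \cdot InhR \cdot EF \cdot ED / (PEF \cdot BW
\cdot AT)$; `compute_add(..., strict_paper = TRUE)` reproduces the literal
printed formula for comparison. Since no published hazard quotient is
recoverable anyway (see below), correctness wins by default.

Hazard quotient $HQ = ADD / RfD$, hazard index $HI = \sum HQ$ (HI < 1: no
expected adverse effect), carcinogenic risk $CR = (\sum_{3\,pathways} ADD)
\times SF$, banded at 1e-6 and 1e-4. The skin-adherence factor is printed in
mg/cm²/h; we treat it as a per-event daily adherence (one event per day), the
standard convention.

**Reference doses and slope factors are not printed in the source.** The
registry ships configurable IRIS-style defaults (e.g. RfD: Zn 0.3, Cu 0.04,
Ni 0.02, Pb 0.0035, Cr 0.003, Cd 0.001, As 3e-4 mg/kg/day; SF: Ni 0.84,
Pb 0.0085, Cr 0.5, Cd 6.3, As 1.5 (mg/kg/day)⁻¹), and the tests assert only
structural properties of HQ/HI/CR — linearity in concentration, inverse
body-weight scaling, the cancellation of ED when AT = 365·ED, and the
child > adult ingestion ordering — not any published magnitude.

## PAH toxicity equivalents and cancer risk

$BaPeq_i = C_i \times TEF_i$ and $TEQ = \sum_i BaPeq_i$. Two TEF sets are
selectable: the `"paper"` set exactly as printed in the study's
risk-quotient table (including its nonstandard BaA value of 0.001) and the
standard `"nisbet_lagoy"` set (BaA 0.1, Flt 0.001), because the study's own
ecosystem-risk text assigns surrogates by the standard values. BaP and BghiP
were below detection in the study; ND compounds are excluded from TEQ by
default, with a half-LOD option.

Incremental lifetime cancer risk uses the cancer-risk profiles
(`ilcr_child`/`ilcr_adult`: BW 15/61.5 kg, EF 180 d/yr, ED 6/24 yr,
IR_ing 200/100, IR_inh 10/20 m³/day, SA 2800/5700 cm², AF 0.2/0.07,
ABS 0.13, AT 25 550 days, PEF 1.36e9) and pathway slope factors
(ingestion 3.7, dermal 25, inhalation 85.3), each scaled by
$(BW/70)^{1/3}$. The 1e6 divisor in the ingestion and dermal forms is the
µg/kg→kg conversion; inhalation divides by PEF instead — implemented exactly
as printed.

The study's printed ILCR table is not recoverable from its own inputs (its
TEQ is printed as both 83.17 and 73.55 µg/kg, and no parameter combination
we tried reproduces the printed pathway risks). The package therefore pins
an independently hand-evaluated oracle instead: at TEQ = 73.55 µg/kg the
child ingestion ILCR is 9.18e-5, and the receptor *orderings* the study
reports (child ingestion > adult; adult dermal > child) hold and are tested.

ERL/ERM screening classifies each compound as minimal (< ERL), possible
([ERL, ERM)) or probable (≥ ERM), lower-inclusive at both boundaries.
Composition summaries report LMW (2–3 ring) / HMW (4–6 ring) and
carcinogenic mass fractions over detected compounds.

## PAH risk quotients

$RQ = C / benchmark$ against negligible (NC) and maximum-permissible (MPC)
concentrations; MPC = 100·NC for every benchmark in the registry, so
$RQ_{MPC} = RQ_{NC}/100$ holds exactly. Individual classification: both < 1
negligible; NC-quotient ≥ 1 only, low-to-moderate; MPC-quotient ≥ 1, high.
Cumulative quotients sum only the terms ≥ 1; the combined grid's overlap at
an NC-sum of exactly 800 with an MPC-sum ≥ 1 is resolved to the higher class.

Three of the thirteen benchmarked compounds (BbF, BkF, InP) have no printed
survey mean; the registry back-fills them from the printed quotients
(RQ·NC: 356.5, 62.4 and 17.7 µg/kg). For BbF this contradicts a prose value
(51.356 µg/kg), but the back-filled value is the only reading consistent
with the printed total-PAH mean (sum of all means ≈ 848.8 vs printed
850.81), so the table wins. The printed *cumulative* quotients (363.1 NC,
3.663 MPC) cannot be recovered from the printed per-compound column (which
sums to 365.2 and 2.601 under the ≥1 rule); the package asserts the
per-compound values only.

## Pb-isotope mixing model

Three end-members — geogenic ($R_1 = 1.2252$, $C_1 = 6681$ mg/kg),
industrial ($R_2 \in [1.1427, 1.1567]$, default the midpoint 1.1497,
$C_2 = 2397$ mg/kg) and traffic ($R_3 = 1.097$, $C_3 = C_2$) — where $R$ is
²⁰⁶Pb/²⁰⁷Pb. The source prints the industrial concentration as both 2397 and
2379 mg/kg; both are selectable, 2397 (the symbol-list value) is the
default. The traffic concentration is only ever printed via a duplicated
line assigning 2397 to "vehicle traffic sources", hence $C_3 = C_2$.

The per-sample system is linear and exactly determined:

$$F_1 + F_2 + F_3 = 1, \quad \sum_i F_i R_i = R_{soil}, \quad
\sum_i F_i / C_i = 1/C_{soil}.$$

The concentration balance is *harmonic* (the fractions are mass fractions of
soil, and mixing soil masses mixes inverse Pb concentrations); the
conventional linear balance $\sum F_i C_i = C_{soil}$ is available behind
`mass_balance = "linear"` for comparison but is never the default.
Solutions with any fraction outside $[0,1]$ are returned with
`feasible = FALSE` and full diagnostics — observations outside the mixing
envelope are a physical finding, not a numerical nuisance — and an optional
Euclidean projection onto the simplex is opt-in.

The overdetermined variant adds the ²⁰⁸Pb/²⁰⁷Pb balance as a fourth
equation and minimises the scaled residual subject to the exact sum-to-one
constraint (null-space parametrisation, so the constraint holds to machine
precision even for noisy data). The source defines the second ratio but
supplies no fourth equation, so this is a package extension; the ²⁰⁸Pb/²⁰⁷Pb
end-member ratios are likewise unpublished and the defaults (2.47, 2.42,
2.36) are *synthetic* literature-typical values used only by this solver and
the generator.

Numerics: the 3×3 solve uses base `solve()` after an explicit determinant
check (|det| < 1e-14 raises a named singularity error — pairwise-distinct
ratios alone do not guarantee invertibility; two sources identical in both
ratio and concentration do make the system singular). The condition number
is reported with every solution so users can see when the end-member
geometry makes fractions ill-determined.

The published per-sample contribution table is printed to 2 dp and its
column means (25.8/51.3/22.9%) contradict the accompanying prose
(24.2/38.5/37.3%); since the per-sample observed ratios live in unpublished
supplementary material, the package asserts only the sum-to-one invariant of
the printed rows and the round-trip identity of its own solver.

## Combined Isotopic Impact Index

Chemical indices are min–max scalings over the analysed batch (or an
external reference range): $CI = (x - x_{min})/(x_{max} - x_{min})$. The
source prints the *reciprocal* of this formula, which is unbounded as
$x \to x_{min}$; every printed CI value lies in $[0,1]$ with the
maximum-valued sample at exactly 1.0000, so the printed formula is treated
as a typo and standard min–max is implemented.

Isotopic indices are $II = 1 - |R - R_{ref}|/R_{ref}$ with reference ratios
1.2 (²⁰⁶Pb/²⁰⁷Pb) and 2.5 (²⁰⁸Pb/²⁰⁷Pb). II is *not* clamped at zero by
default: the study's own low-contamination sample implies relative
deviations of 83% and 47%, implausibly large for Pb ratios, which suggests
an undocumented upstream transformation; we implement the printed formula
and surface negative values rather than hide them (`clamp_ii = TRUE` exists
for strict boundedness).

$CISI = w_1 \overline{CI} + w_2 \overline{II}$ with defaults
$w_1 = 0.6, w_2 = 0.4$. The published worked example reproduces exactly:

```{r}
compute_cisi(0.0778, c(0.1675, 0.5316))
```

The source says the weights came from a sensitivity analysis without
specifying it; `sensitivity_weights()` implements a documented grid search
maximising the between-sample variance of CISI (the most discriminating
weighting), with the published pair as one grid point. PCA validation
(`validate_pca()`) z-scores the CI/II feature matrix, uses `stats::prcomp`,
and fixes signs deterministically by making each loading's
largest-magnitude element positive; explained-variance fractions sum to 1
and zero-variance features are dropped with a warning. The study's "65% of
total variance" figure depends on unpublished per-sample data and is not a
reproduction target.

## Synthetic-data generators

The generators define the study conditions for all pipeline tests:

* **PTE survey** (default n = 53): each element is drawn from a lognormal
  truncated to the published [min, max] whose *truncated* distribution is
  moment-matched to the published mean and sd. The truncated mean is matched
  exactly (root-finding in the location parameter, which the mean is
  strictly increasing in); the sd is matched as closely as the family
  allows, with the log-scale parameter optimised over a bounded range that
  keeps both the closed-form moments and inverse-CDF sampling in a
  numerically exact regime. For extremely skewed targets (Cd: mean 0.24,
  sd 0.19 on [0.19, 1.6]; similarly As) the bounded-lognormal family cannot
  reach the target sd (Cd saturates near 0.065) — the mean remains exact,
  and no test asserts generated sds for those elements. Lognormality itself
  is motivated by the published skewness/kurtosis, which indicate strongly
  right-skewed concentration distributions. pH is uniform within its
  published range; infeasible targets (sd² ≥ (mean−min)(max−mean)) raise an
  error.
* **PAH survey**: independent lognormals with the published compound means
  and a common CV of 1.0 (chosen once as typical of urban PAH surveys,
  consistent with the published max/mean ratios of roughly 3–8); BaP and
  BghiP are generated all-ND, mirroring the study.
* **Isotope survey**: fraction triples are Dirichlet draws (default
  α = (2.6, 5.1, 2.3), centred on the published mean contributions), pushed
  through the forward mixing model; optional multiplicative lognormal noise
  on the ratios. The ²⁰⁷Pb/²⁰⁴Pb ratio is fixed at 15.62 and the
  ²⁰⁴Pb-based columns derived from it, so the six ratio columns are mutually
  consistent by construction. Ground-truth fractions are returned for
  recovery testing: noiseless surveys are recovered to < 1e-8.

What the generators do **not** emulate: inter-element and element–PAH
correlations (not reported in the study, so draws are independent), spatial
autocorrelation, and land-use-conditional concentration shifts (tags are an
independent mixture). Passing tests therefore demonstrate the correctness of
the index arithmetic, the mixing inversion and the classification logic
under realistic marginal distributions — not that the package reproduces the
multivariate structure of any real survey.

Determinism: a single top-level seed derives one sub-seed per generator
stream, so adding a stage never perturbs another stage's draws, and repeated
runs are byte-identical. Default problem sizes (53 samples end-to-end;
5 000 for calibration checks; 200 for round-trip sweeps) keep the whole
suite under ten seconds while leaving Monte-Carlo error well inside the
asserted tolerances.

## Interface notes

The package is function-first: `run_pipeline()` chains all stages on a
survey bundle and `write_report()` serialises CSV/JSON reports at full
precision (display rounding is the caller's concern). These, plus the
generators, constitute the package's operational surface; no shell entry
point is shipped because every realistic use starts in R.

## Known limitations

* Published HQ/CR and ILCR tables are not reproduction targets (unprinted
  RfD/SF; internally inconsistent ILCR inputs); structural properties are
  tested instead.
* The mixing model is exactly determined only with three end-members; it
  does not extend to more sources, and the overdetermined variant's
  ²⁰⁸Pb/²⁰⁷Pb end-members are synthetic defaults that users should replace
  with region-specific measurements.
* CISI depends on batch min/max by default, so adding a sample can change
  every chemical index; supply fixed external ranges for cross-survey
  comparability.
* The bounded-lognormal generator cannot reach the published sd for the two
  most skewed elements (Cd, As); means are exact.
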