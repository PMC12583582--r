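# soilrisk

Quantitative risk assessment of potentially toxic elements (PTEs) and
polycyclic aromatic hydrocarbons (PAHs) in urban surface soils, with
Pb stable-isotope source apportionment and a composite contamination index.
The package is aimed at environmental geochemists and exposure scientists who
need the full index chain — from raw survey tables to graded, per-sample risk
reports — as tested, reusable functions rather than spreadsheet formulas.

## What it computes

**Ecological risk (Hakanson).** For each element, the single-element risk
factor and their sum over the assessed elements:

    Er_i = Tr_i * C_i / Cn_i          RI = sum_i Er_i

with toxic-response factors `Tr` (Zn 1, Cu 5, Ni 5, Pb 5, Cr 2, Cd 30, As 10),
upper-continental-crust references `Cn`, and the standard grade thresholds
(Er: 40/80/160/320; RI: 150/300/600, lower-inclusive).

**Human health risk (USEPA).** Average daily dose per pathway, e.g. ingestion

    ADD_ing = C * IngR * CF * EF * ED / (BW * AT)

then `HQ = ADD/RfD`, `HI = sum(HQ)` and carcinogenic risk
`CR = (ADD_ing + ADD_inh + ADD_derm) * SF`, for child and adult receptor
profiles.

**PAH toxicity.** Benzo[a]pyrene equivalents `BaPeq_i = C_i * TEF_i`, their
sum TEQ, ERL/ERM screening, LMW/HMW composition, and incremental lifetime
cancer risk per pathway, e.g.

    ILCR_ing = TEQ * CSF_ing * (BW/70)^(1/3) * IR_ing * EF * ED / (BW * AT * 1e6)

**PAH risk quotients.** `RQ = C / benchmark` against negligible (NC) and
maximum-permissible (MPC) concentrations, individual and cumulative
classification (cumulative sums include only quotients >= 1).

**Pb-isotope source apportionment.** A three-end-member mixing model
(geogenic / industrial / traffic) solving

    F1 + F2 + F3 = 1
    F1*R1 + F2*R2 + F3*R3 = R_soil          (R = 206Pb/207Pb)
    F1/C1 + F2/C2 + F3/C3 = 1/C_soil

exactly per sample, plus a constrained least-squares variant that also uses
the 208Pb/207Pb ratio. Infeasible solutions (outside the simplex) are
flagged, never clipped.

**Combined Isotopic Impact Index (CISI).** Min–max-scaled chemical indices
(pH, Fe, Mn, Pb, Ca), isotopic deviation indices
`II = 1 - |R - R_ref| / R_ref` (refs 1.2 and 2.5), aggregated as
`CISI = 0.6 * mean(CI) + 0.4 * mean(II)`, with PCA validation and a weight
sensitivity sweep.

**Synthetic surveys.** Seeded generators calibrated to a 53-sample urban
survey (truncated-lognormal PTEs moment-matched to published summary
statistics, lognormal PAH profiles, isotope measurements forward-generated
from the mixing model with known ground-truth fractions) so the entire
pipeline is testable without external data.

## Worked example

```r
library(soilrisk)

bundle <- generate_survey(generator_spec(n_samples = 53, seed = 7))
report <- run_pipeline(bundle)

report$eco_risk
#> <eco_risk> 53 samples, 7 elements
#> RI range: 103.35 - 217.91
#> RI grades: low=37 moderate=16 considerable=0 high=0

report$pb_sources$summary
#>       source      mean        min       max
#> 1   geogenic 0.2756239 0.03035454 0.6335478
#> 2 industrial 0.4892677 0.21424889 0.8140829
#> 3    traffic 0.2351083 0.03743729 0.5320781

report$pah_tox$teq
#> TEQ = 73.21 ug/kg over 13 compounds (TEQ/sumPAH = 0.0903)

report$pah_rq$cumulative
#> cumulative RQ: NC 333.4, MPC 1.425 -> moderate_2
```

Most simulated samples grade as low ecological risk with cadmium dominating
the element-wise factors; industrial sources carry the largest mean share of
soil Pb (~49% here); the PAH mixture's toxic equivalent is ~73 ug/kg (about
9% of the total PAH mass), and the cumulative risk quotient grid lands in
the moderate band because two compounds exceed their maximum-permissible
benchmark. The published worked example of the composite index also
reproduces directly:

```r
compute_cisi(0.0778, c(0.1675, 0.5316))
#> CISI = 0.1865 (mean CI 0.0778, mean II 0.3495)
```

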