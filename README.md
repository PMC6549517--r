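# lvflow

Left-ventricular flow-component analysis for 4D flow cardiovascular MRI.

## The problem

Time-resolved, three-directional phase-contrast CMR ("4D flow") measures
the blood velocity vector in every voxel of the heart across the cardiac
cycle. From those data plus end-diastolic (ED) and end-systolic (ES)
segmentations of the left ventricle, the end-diastolic blood volume can be
separated into four functional **flow components** by following virtual
blood particles (pathlines) through the velocity field:

| component | origin (previous ES) | fate (ES) |
|---|---|---|
| **Direct flow** (DF) | outside the LV | ejected |
| **Retained inflow** (RI) | outside the LV | retained |
| **Delayed ejection flow** (DEF) | inside the LV | ejected |
| **Residual volume** (RV) | inside the LV | retained |

Pathlines are emitted at ED from an isotropic grid filling the ED
segmentation (one per grid cell, each representing a blood volume equal to
the grid density, e.g. 2.8^3 mm^3), traced **backward** in the reversed
velocity field to the preceding end-systole and **forward** to end-systole
with a fourth-order Runge–Kutta integrator, and classified by whether their
two endpoints fall inside the ES segmentation. Per component the pipeline
reports the volume `V(c) = n(c) · h^3` and its share of the LVEDV, and the
end-diastolic kinetic energy

```
KE(c) = Σ_{p ∈ c} ½ · ρ · V_p · |v_p(t_ED)|²     (ρ = 1060 kg/m³)
```

with its share of total ED KE. Derived quantities follow as sums —
LV inflow = DF + RI, stroke volume = DF + DEF, non-ejected volume =
RI + RV — along with the late-diastolic fraction of inflow (volume and KE
entering after the onset of late diastole), conventional chamber metrics
(LVEF, BSA-indexed volumes, cardiac output, left-atrial fractional area
change), and an inflow-vs-outflow quality-control gate (exams with a
discrepancy above 15% of inflow fail). A cohort module runs paired
two-timepoint comparisons (paired t, Wilcoxon signed-rank,
Kolmogorov–Smirnov normality) over any set of metrics.

Because clinical 4D flow exams are rarely shareable, the package also ships
**synthetic phantoms with exact ground truth**: a duct phantom whose lanes
realize prescribed component fractions with closed-form trajectories and
entry times, affine phantoms (rotation, translation, contraction) with
closed-form pathlines for integrator validation, and a forward model of the
phase-contrast encoding artifacts — quartic background phase, velocity
aliasing at the VENC, Gaussian phase noise — matched by the correction
steps (`detect_static_tissue()`, `correct_background_phase()`,
`unwrap_temporal()`).

Audience: CMR physicists and cardiovascular-imaging researchers who want a
tested, scriptable implementation of flow-component analysis, and method
developers who need phantoms with analytic ground truth.

## Worked example

A compact duct phantom with prescribed fractions (0.30, 0.20, 0.18, 0.32),
analysed end to end:

```r
library(lvflow)

spec <- phantom_spec("duct", dims = c(26, 24, 24), n_frames = 20,
                     es_frame = 6, late_onset_frame = 14,
                     fractions = c(0.30, 0.20, 0.18, 0.32))
phantom <- make_duct_phantom(spec)

timing <- timing_result(ed_frame = 0, es_frame = 6, late_onset_frame = 14,
                        n_frames = 20, cycle_s = 1.0)
result <- analyze_lv_flow(phantom$field, phantom$ed_mask, phantom$es_mask,
                          timing)
result
#> <lvflow_result>
#>   LVEDV 8.4 ml, LVEF 29.7%
#>   Direct flow               2.5 ml ( 29.7%)  KE  0.0082 mJ (100.0%)
#>   Retained inflow           1.7 ml ( 20.3%)  KE  0.0000 mJ (  0.0%)
#>   Delayed ejection flow     1.6 ml ( 18.8%)  KE  0.0000 mJ (  0.0%)
#>   Residual volume           2.6 ml ( 31.2%)  KE  0.0000 mJ (  0.0%)
#>   inflow 4.2 ml, outflow 4.1 ml, discrepancy 3.12% (pass)
#>   late-diastolic inflow: 59.9% of volume, 66.7% of KE
```

The component shares land within one cross-section lane of the
prescription (29.7 / 20.3 / 18.8 / 31.2 vs 30 / 20 / 18 / 32 on this small
grid). The 3.12% inflow–outflow discrepancy is the phantom's intrinsic
|RI − DEF| imbalance and passes the 15% gate. Only the direct-flow lanes
are moving at the ED instant in this phantom, so all end-diastolic KE sits
in DF. Results are tibbles throughout:

```r
glance(result)[, c("direct_flow_pct", "residual_volume_pct",
                   "qc_discrepancy_pct", "late_inflow_volume_pct")]
#> # A tibble: 1 × 4
#>   direct_flow_pct residual_volume_pct qc_discrepancy_pct late_inflow_volume_pct
#>             <dbl>               <dbl>              <dbl>                  <dbl>
#> 1            29.7                31.2               3.12                   59.9
```

`tidy(result)` gives the long metric table, `autoplot(result)` the
component volume/KE bar figure, `plot_pathlines()` the projected
trajectories coloured by component, and `write_case_results()` /
`cohort_compare()` take per-exam rows to a paired Time-1 vs Time-2 table.

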