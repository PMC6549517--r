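---
title: "Separating the LV end-diastolic volume into flow components: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating the LV end-diastolic volume into flow components: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvflow)
```

## The model

4D flow CMR yields a velocity vector field $\mathbf v(\mathbf x, t)$ on a
regular voxel grid over one averaged cardiac cycle. Flow-component
analysis treats the left-ventricular end-diastolic volume (LVEDV) as a set
of virtual blood particles: one seed per cell of an isotropic lattice
filling the ED segmentation, each representing $h^3$ of blood ($h$ = seed
spacing, by default the voxel spacing). Each seed's pathline solves

$$\frac{d\mathbf x}{dt} = \mathbf v(\mathbf x, t),$$

integrated backward from the ED time to the preceding end-systole
(diastole: where did the blood come from?) and forward to end-systole
(systole: where is it going?). The ES segmentation decides both
endpoints' inside/outside status, which partitions the LVEDV exhaustively
and exclusively:

* origin outside, fate outside — **direct flow**;
* origin outside, fate inside — **retained inflow**;
* origin inside, fate outside — **delayed ejection flow**;
* origin inside, fate inside — **residual volume**.

Volumes are pathline counts times $h^3$; kinetic energy per component is
$\sum_p \tfrac12 \rho\, V_p\, |\mathbf v_p(t_{ED})|^2$ at the
end-diastolic instant. Inflow, stroke volume and non-ejected volume are
the pairwise sums DF+RI, DF+DEF and RI+RV. The late-diastolic inflow
fraction uses each inflow pathline's *entry time* — the last
outside-to-inside crossing of the ED segmentation on the backward branch —
against the late-diastole onset frame.

## Cardiac timing

ED is defined one frame after mitral-valve closure and ES one frame before
mitral-valve opening (`frames_from_valve_events()`, cyclic arithmetic);
the valve frames are manual annotations supplied per exam. The onset of
late diastole is the end of early filling, read off the LV volume curve:
after the early-filling peak of $dV/dt$ (central differences on the cyclic
curve), the first frame where $dV/dt$ drops below a configurable fraction
of that peak, 10% by default (`timing.diastasis_fraction`). The 10%
figure is a design choice — diastasis flow is near zero, so any small
threshold picks the same frame on curves with a genuine plateau; the
degenerate cases (monotone or flat diastolic curves) fall back to the
diastole midpoint with a warning rather than failing.

## Numerical choices

**Interpolation.** Velocities are interpolated trilinearly in space and
linearly in time between the two bracketing cardiac frames, cyclically.
The inside/outside test against a segmentation interpolates the binary
mask the same way and thresholds at 0.5, so classification is sub-voxel
consistent with the velocity sampling (`components.inside_test`;
a nearest-voxel variant is available).

**Integration.** Fixed-step RK4 with step = `step_fraction` ×
inter-frame interval (default 0.2). Steps tile each frame interval
exactly: the interpolated field is only $C^0$ at frame times, and aligning
steps to the intervals keeps the local truncation error $O(h^5)$ and the
global order 4 — which the tests verify as a ≈16× endpoint-error drop per
step halving on a solid-body-rotation field (where trilinear sampling is
exact and the closed form is known).

**Domain exits.** A trajectory that leaves the sampling hull of the grid
is frozen at the exit point and flagged `truncated`; non-finite velocities
invalidate the pathline. Neither is silently dropped: counts feed the
aberrant-trace fraction in QC, and flagged pathlines are excluded from the
component aggregates. This mirrors the practice of visually rejecting
aberrant traces that leave the cardiac confines.

**Units.** Positions and spacings are carried in millimetres (the field's
native convention for voxel sizes), velocities in m/s, times in seconds,
energies in joules (reported mJ). The single mm↔m factor lives in the
integrator stages and the KE formula; file readers convert declared
storage units (e.g. cm/s) at the I/O boundary.

## Correcting the phase-contrast artifacts

The measured phase is modelled as
$\varphi = \pi v/\mathrm{VENC} + P_4(\mathbf x) + \varepsilon$, wrapped
into $(-\pi, \pi]$, with $P_4$ a full three-variable polynomial of total
degree 4 (35 terms per velocity direction, evaluated on grid coordinates
normalized to $[-1,1]$) and $\varepsilon$ Gaussian in phase — Gaussian
phase noise, not velocity noise, because that is where the physical noise
enters the encoding.

* **Static tissue** is detected by temporal velocity SD below a threshold
  (default 0.03 m/s, a typical noise floor at VENC 120 cm/s), optionally
  gated by a signal-magnitude floor.
* **Background correction** fits the 35-term quartic per direction to the
  *temporal-mean* velocity over static voxels and subtracts the surface
  from every frame. Temporal-mean fitting (rather than per-frame) was
  chosen because eddy-current offsets are static over the cycle and the
  mean uses all frames' information against noise; the correction is
  idempotent and recovers any polynomial inside its own model class
  exactly, which the tests assert to 1e-9.
* **Temporal unwrapping** chooses per-frame integer wrap offsets in
  $[-K, K]$ (default $K = 2$: at VENC 120 cm/s that already admits 3.6 m/s,
  beyond LV physiology) minimizing the total absolute frame-to-frame
  velocity jump around the cyclic series, by exact dynamic programming
  over the offset states with the cyclic closure handled by conditioning
  on the first frame. The jump criterion is invariant to shifting every
  frame by the same offset, so ties are broken toward the smallest total
  $|v|$, anchoring the series at the physiologic range. Voxels whose
  measured series never jumps beyond the VENC are left bit-identical.

Temporal unwrapping is only well posed when the *true* series is smooth —
aliasing must create the large jumps it looks for. The piecewise-steady
duct phantom switches regimes within one frame interval, so the inversion
property is exercised on `make_pulsatile_duct_field()`: the same geometry
with a smooth $\sin^2$ temporal lane profile peaking at 1.5 × VENC. On
that phantom the full chain (encode → decode → static detection →
background fit → unwrap) restores the field to below $10^{-6}$ m/s, in
practice to machine precision.

## The phantoms: what they emulate and what they do not

**Duct phantom.** A box "LV" crossed by straight axial lanes, one
component per $(y,z)$ column of the cross-section, apportioned by largest
remainder so prescribed fractions are realized to within one column. Lane
speeds are piecewise steady, switched between a diastolic and a systolic
regime, and solved against the *linearly time-interpolated* speed profile
the tracer actually integrates — including the one-frame ramps at regime
switches — so that each lane's traced displacement equals the chamber
length plus a two-voxel margin. Retained-inflow and delayed-ejection
lanes carry zero-speed guard frames at their regime edges so the opposite
branch picks up no displacement bleed; without the guards, backward traces
of delayed-ejection seeds near the inflow face would drift out of the
chamber during the interpolation ramp and be mislabelled. All motion is
axial and seeds sit on voxel centres, so trajectories, entry times
(piecewise-quadratic closed form) and labels are exact. Inflow/outflow
tract extensions continue each lane so traces have somewhere to come from
and go to; speeds taper to zero at the domain edge, so conservative
phantom traces never leave the grid. A zero-velocity tissue shell
surrounds the flow domain and doubles as the static-tissue region.

The ES mask is the box minus the direct-flow columns' footprint. A single
static ES mask must contain the delayed-ejection blood at the *previous*
end-systole and the retained inflow at the *current* one, which pins its
footprint to the non-direct lanes; the consequence is that the phantom's
mask-volume EF equals the direct-flow fraction, not the flow-derived
EF — the phantom is a flow-topology oracle, not an anatomy model. For the
same reason the phantom's inflow–outflow discrepancy is exactly
$|RI - DEF|/(DF+RI)$: a prescription with $f_{RI} = f_{DEF}$ is exactly
mass-balanced, and the canonical test prescription (0.30, 0.20, 0.18,
0.32) carries an intrinsic 4% discrepancy, comfortably inside the 15%
exclusion gate.

Default phantom conditions: 64³ voxels at 2.8 mm isotropic, 40 frames over
a 1.0 s cycle (heart rate 60 bpm, the cohort range being roughly 48–71),
ED at frame 0, ES at frame 14 (0.35 s systole), late-diastole onset at
frame 27, fractions (0.37, 0.20, 0.19, 0.24) — component ratios typical of
recovered sinus rhythm, normalized to sum to one. The resulting LVEDV is
191 ml, matching an indexed volume near 88 ml/m² at a BSA of 2.16 m².

What the duct phantom does *not* emulate: chamber wall motion and
time-resolved segmentations (masks exist only at ED and ES, and entry
detection uses the ED mask as the diastolic chamber proxy — a limitation
shared with the pipeline itself), intracavitary vortices, velocity-field
divergence at the mitral annulus, measurement point-spread, or respiratory
and RR-variability effects. Passing tests on the phantom therefore
validates the *bookkeeping and numerics* of the pipeline, not its
robustness to segmentation error or flow complexity in patients.

**Affine phantoms.** A time-varying affine motion
$\mathbf x(t) = A(t)\mathbf x_0 + \mathbf b(t)$ induces the field
$\mathbf v = A'A^{-1}(\mathbf x - \mathbf b) + \mathbf b'$, linear in
space, so trilinear sampling is exact and any traced deviation from the
closed form is integrator error. Solid-body rotation is additionally
steady in time, making it the cleanest convergence oracle; the diagonal
contraction map resembles a beating chamber but is time-varying, so its
gridded field carries temporal-interpolation error and serves qualitative
checks.

## Quality control and statistics

The QC gate follows the exclusion rule used for patient data: discrepancy
= $|inflow - outflow|/inflow \times 100$ with outflow operationalized as
the flow-derived stroke volume (DF+DEF), keeping the check internal to the
pathline analysis; threshold 15%, configurable. The aberrant fraction
counts pathlines leaving the supplied bounds (default: the grid) or
invalidated during tracing.

Cohort comparisons are two-sided throughout: paired Student t, Wilcoxon
signed-rank (zero differences dropped; exact distribution up to 25
non-zero pairs, normal approximation above), and a plain
Kolmogorov–Smirnov test of the differences against a normal with
moment-estimated parameters as the normality flag. No multiple-testing
correction is applied, matching the descriptive use of these tables. The
tests are validated against the closed-form t statistic and a brute-force
enumeration of all sign assignments for the signed-rank statistic.

## Tunable parameters

| parameter | default | unit | where |
|---|---|---|---|
| seed spacing | voxel spacing (2.8) | mm | `seed_grid()` |
| `trace.step_fraction` | 0.2 | frame intervals | `trace_pathlines()` |
| `components.rho` | 1060 | kg/m³ | KE (blood density; configurable because KE conventions differ between groups) |
| `components.inside_test` | interpolated | — | endpoint test |
| `preprocess.sd_threshold` | 0.03 | m/s | static-tissue detection |
| `preprocess.polynomial_order` | 4 (fixed) | — | background model |
| `preprocess.max_wraps` | 2 | wraps | unwrap search |
| `timing.diastasis_fraction` | 0.1 | of E-peak dV/dt | late-diastole onset |
| `qc.discrepancy_threshold` | 15 | % of inflow | exclusion gate |
| BSA formula | Mosteller | — | Du Bois available |

## Problem sizes used in the checks

The packaged tests run the full pipeline on a 26×24×24 / 20-frame duct
phantom and all full-scale properties on the 64³ / 40-frame phantom
(≈8 700 pathlines); the integrator oracle uses a 32³ rotation phantom and
the artifact-inversion check a 32×30×30 / 40-frame pulsatile field. These
sizes were chosen so the whole suite completes in well under a minute per
file while the full-scale phantom still exercises the exact acquisition
geometry (2.8 mm, 40 frames, VENC 120 cm/s).

## Known limitations

* Entry times use the ED segmentation as a static diastolic chamber proxy;
  with no time-resolved masks in the pipeline, early-diastolic entries
  through a moving mitral annulus are located only to within the mask's
  geometry.
* Whether diastolic entry should be detected by valve-plane crossing
  rather than mask crossing is an open methodological question; the
  ES-mask endpoint convention is used for classification and the ED-mask
  crossing for entry times.
* The HDF5 exam-container dialect is not implemented in this build; the
  NIfTI triplet with a YAML sidecar is the on-disk format. The layout is
  this package's own and claims no compatibility with any vendor or
  in-house tool format.
* Concomitant-gradient (Maxwell) correction is assumed done at
  reconstruction, as is standard; only background polynomial and temporal
  wrap corrections are implemented. Spatial (region-growing) unwrapping is
  out of scope.
* The number of velocity encodings per sample (4, from interleaved
  three-directional encoding with a reference) is a parameter of
  `acquisition_temporal_resolution()`, not an assumption baked in.
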