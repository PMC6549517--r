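test_that("global LV metrics follow the volumetric definitions", {
  # EDV 160 ml, ESV 80 ml at 2 mm voxels -> EF 50%
  ed <- box_mask(c(40, 40, 40), 1:20, 1:40, 1:25, spacing = 2)   # 20000 vox
  es <- box_mask(c(40, 40, 40), 1:20, 1:25, 1:20, spacing = 2)   # 10000 vox
  m <- lv_global_metrics(ed, es, heart_rate_bpm = 60)
  expect_equal(m$lvedv_ml, 160)
  expect_equal(m$lvesv_ml, 80)
  expect_equal(m$lvef_pct, 50)
  expect_equal(m$sv_ml, 80)
  expect_equal(m$co_l_min, 4.8)

  # ESV = EDV -> EF 0
  m0 <- lv_global_metrics(ed, ed, heart_rate_bpm = 60)
  expect_equal(m0$lvef_pct, 0)

  # indexed volumes divide by BSA; cohort-mean indexed values imply the
  # printed EF: EDVI 85, ESVI 40 -> EF 52.9%
  expect_equal((85 - 40) / 85 * 100, 52.9, tolerance = 1e-3)
  mi <- lv_global_metrics(ed, es, 60, height_cm = 182, weight_kg = 92)
  expect_equal(mi$lvedvi_ml_m2, 160 / sqrt(182 * 92 / 3600), tolerance = 1e-9)

  empty <- box_mask(c(8, 8, 8), 1, 1, 1); empty$data[] <- 0
  expect_error(lv_global_metrics(empty, empty, 60), "EDV")
})

test_that("body surface area matches Mosteller and Du Bois", {
  expect_equal(body_surface_area(182, 92), 2.157, tolerance = 1e-3)
  expect_equal(body_surface_area(3600, 1), 1.0)
  expect_equal(body_surface_area(180, 72), 1.897, tolerance = 1e-3)
  expect_equal(body_surface_area(180, 72, "dubois"),
               0.007184 * 180^0.725 * 72^0.425)
  expect_error(body_surface_area(-1, 70), "positive")
})

test_that("LA fractional area change averages duplicate measurements", {
  expect_equal(la_fractional_area_change(c(36, 36), c(30, 30)), 16 + 2 / 3,
               tolerance = 1e-9)
  expect_equal(la_fractional_area_change(c(35, 35), c(35, 35)), 0)
  expect_equal(la_fractional_area_change(c(40, 40), c(30, 30)), 25)
  # scale invariance
  expect_equal(la_fractional_area_change(c(36, 38), c(28, 30)),
               la_fractional_area_change(3 * c(36, 38), 3 * c(28, 30)))
  expect_error(la_fractional_area_change(c(0, 0), c(0, 0)), "zero")
  expect_error(la_fractional_area_change(c(30, 30), c(36, 36)), "exceeds")
})

test_that("inflow-outflow discrepancy gates at the threshold", {
  vols <- function(df, ri, def, rv) tibble::tibble(
    component = factor(component_levels(), levels = component_levels()),
    n_pathlines = 0L, volume_ml = c(df, ri, def, rv),
    volume_pct = 0)
  # inflow 82, outflow 79 (Table-3-scale volumes): 3.66%, pass
  q <- inflow_outflow_discrepancy(vols(52, 30, 27, 40))
  expect_equal(q$inflow_ml, 82)
  expect_equal(q$outflow_ml, 79)
  expect_equal(q$discrepancy_pct, 3 / 82 * 100, tolerance = 1e-9)
  expect_true(q$pass)

  q0 <- inflow_outflow_discrepancy(vols(50, 25, 25, 30))
  expect_equal(q0$discrepancy_pct, 0)
  expect_true(q0$pass)

  qf <- inflow_outflow_discrepancy(vols(60, 40, 20, 30))
  expect_equal(qf$discrepancy_pct, 20)
  expect_false(qf$pass)

  expect_error(inflow_outflow_discrepancy(vols(0, 0, 10, 10)), "inflow")
})

test_that("mass-conserving phantoms pass the QC gate with small discrepancy", {
  sd <- small_duct()
  q <- sd$result$qc
  expect_lte(q$discrepancy_pct, 15)
  expect_true(q$pass)
  # the phantom's discrepancy is exactly |RI - DEF| / inflow
  v <- sd$result$volumes$volume_ml
  expect_equal(q$discrepancy_pct, abs(v[2] - v[3]) / (v[1] + v[2]) * 100,
               tolerance = 1e-9)
  # conservative flow never leaves the grid
  expect_equal(sd$result$qc$aberrant_pct, 0)
  # balanced retained/delayed fractions: discrepancy ~ 0
  phb <- make_duct_phantom(small_duct_spec(fractions = c(0.38, 0.16, 0.16, 0.30)))
  resb <- analyze_lv_flow(phb$field, phb$ed_mask, phb$es_mask, sd$timing,
                          keep_pathlines = FALSE)
  expect_lt(resb$qc$discrepancy_pct, 2)
})

test_that("aberrant fraction counts boundary leavers against given bounds", {
  sd <- small_duct()
  expect_equal(aberrant_fraction(sd$result$pathlines)$aberrant_pct, 0)
  # uniform-flow seeds near the outflow edge leave tight bounds
  f <- uniform_field(v = c(0.1, 0, 0), dims = c(60, 10, 10), n_frames = 10)
  m <- box_mask(c(60, 10, 10), 25:26, 4:6, 4:6)
  timing <- timing_result(0, 5, 8, 10, 1.0)
  pl <- trace_pathlines(f, seed_grid(m), timing)
  b <- rbind(c(0, 0, 0), c(100, 28, 28))
  ab <- aberrant_fraction(pl, bounds = b)
  expect_equal(ab$aberrant_pct, 100 * ab$n_aberrant / nrow(pl$status))
  expect_gt(ab$n_aberrant, 0)
})
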