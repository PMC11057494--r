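test_that("area-length volume matches its closed forms", {
  expect_equal(volume_area_length(0, 5), 0)
  expect_equal(volume_area_length(1, 8 / (3 * pi)), 1.0)
  # ellipse L = 4, D = 2: V = 8 (2 pi)^2 / (3 pi 4) = 8 pi / 3
  expect_equal(volume_area_length(2 * pi, 4), 8 * pi / 3, tolerance = 1e-12)
  expect_equal(volume_area_length(2 * pi, 4), pi * 2^2 * 4 / 6, tolerance = 1e-12)
  expect_error(volume_area_length(10, 0), "positive")
})

test_that("cycle EF and the all-cycle mean follow their definitions", {
  expect_equal(cycle_ef(100, 50), 50.0)
  expect_equal(cycle_ef(80, 80), 0.0)
  # isotropic shrink s = 0.8 -> ESV/EDV = 0.512 -> EF = 48.8
  expect_equal(cycle_ef(1, 0.8^3), 48.8, tolerance = 1e-12)
  expect_error(cycle_ef(0, 1), "positive")

  expect_equal(round(mean_ef(c(53.68, 51.28, 45.30)), 2), 50.09)
  expect_equal(mean_ef(42.0), 42.0)
  expect_equal(mean_ef(c(63.53, 62.86, 63.50)), 63.29666667, tolerance = 1e-8)
  expect_error(mean_ef(numeric(0)), "no cycles")
})

test_that("HF phenotype boundaries are strict at 40 and 50", {
  expect_equal(classify_hf(39.99), "HFrEF")
  expect_equal(classify_hf(40.0), "HFmrEF")
  expect_equal(classify_hf(49.999), "HFmrEF")
  expect_equal(classify_hf(50.0), "HFpEF")
  expect_equal(classify_hf(50.09), "HFpEF")
  expect_error(classify_hf(101), "\\[0, 100\\]")
})

test_that("EF is invariant under spatial rescaling (unit cancellation)", {
  a_ed <- 2400; a_es <- 1500; l_ed <- 80; l_es <- 66
  ef0 <- cycle_ef(volume_area_length(a_ed, l_ed), volume_area_length(a_es, l_es))
  for (s in c(0.5, 2, 3.7)) {
    efs <- cycle_ef(volume_area_length(s^2 * a_ed, s * l_ed),
                    volume_area_length(s^2 * a_es, s * l_es))
    expect_equal(efs, ef0, tolerance = 1e-12)
    # volumes scale as s^3
    expect_equal(volume_area_length(s^2 * a_ed, s * l_ed),
                 s^3 * volume_area_length(a_ed, l_ed), tolerance = 1e-9)
  }
  # EF strictly decreases in ESV at fixed EDV
  esvs <- seq(100, 900, by = 200)
  expect_true(all(diff(cycle_ef(1000, esvs)) < 0))
})

test_that("pipeline on clean synthetic masks recovers the target EF", {
  sim <- simulate_echo(rhythm_spec(3, 50, seed = 7), lv_shape_spec(80, 40, 55))
  out <- run_pipeline(sim$masks, config = pipeline_config(length_source = "height"))
  expect_equal(out$result$status, "ok")
  expect_equal(out$result$n_cycles, 3)
  expect_lt(abs(out$result$mean_ef - 55), 3)
  expect_equal(out$result$phenotype, "HFpEF")
  # determinism
  out2 <- run_pipeline(sim$masks, config = pipeline_config(length_source = "height"))
  expect_identical(out$result, out2$result)
  # mean EF is the mean of the per-cycle EFs; single-cycle mean is that cycle
  expect_equal(out$result$mean_ef, mean(out$result$cycles$ef))
  expect_equal(mean_ef(out$result$cycles$ef[1]), out$result$cycles$ef[1])
})

test_that("a constant mask stack reports insufficient cycles", {
  masks <- array(FALSE, dim = c(20, 20, 10)); masks[8:12, 8:12, ] <- TRUE
  expect_warning(out <- run_pipeline(masks,
                                     config = pipeline_config(length_source = "height")))
  expect_equal(out$result$status, "insufficient cycles")
  expect_equal(out$result$n_cycles, 0)
  expect_true(is.na(out$result$mean_ef))
  expect_equal(out$series$banner, "no cycles detected")
})

test_that("a raw video requires a segmentation model", {
  sim <- simulate_echo(rhythm_spec(1, 30, seed = 2), lv_shape_spec(50, 26, 50))
  expect_error(run_pipeline(sim$video, seg_model = NULL,
                            config = pipeline_config(length_source = "height")),
               "segmentation model")
})

test_that("visualiser payload carries one marker and label per cycle", {
  sim <- simulate_echo(rhythm_spec(3, 45, period_cv = 0.3, seed = 12),
                       lv_shape_spec(80, 40, c(55, 48, 60)))
  out <- run_pipeline(sim$masks, config = pipeline_config(length_source = "height"))
  sr <- out$series
  expect_length(sr$ed_markers, 3)
  expect_length(sr$es_markers, 3)
  expect_length(sr$ef_labels, 3)
  expect_true(all(sr$ed_markers %in% sr$frame_indices))
  expect_true(all(sr$es_markers %in% sr$frame_indices))
  # AF-like rhythm: successive ED-to-ED gaps differ
  expect_gt(length(unique(diff(sr$ed_markers))), 1)
  # serialisable to JSON
  expect_silent(jsonlite::toJSON(unclass(sr), auto_unbox = TRUE))
  # mismatched cycle counts are rejected
  cv <- new_area_curve(sim$truth$area)
  cs <- detect_ed_es(cv)
  expect_error(build_visualiser(cv, cs,
                                echolvef:::new_lvef_result(echolvef:::empty_cycle_frame(),
                                                           status = "insufficient cycles")),
               "mismatch")
})

test_that("trace-measured length can drive the pipeline", {
  sim <- simulate_echo(rhythm_spec(2, 40, seed = 3), lv_shape_spec(70, 36, 50))
  cv <- area_curve(sim$masks)
  cs <- detect_ed_es(cv)
  traces <- lapply(c(cs$pairs$ed_frame, cs$pairs$es_frame), function(f) {
    L <- sim$truth$long_axis[f + 1]
    structure(list(video_id = "s", frame_index = f,
                   points = rbind(c(55.5 - L / 2, 55.5), c(55.5 + L / 2, 55.5)),
                   axis_pair = c(1L, 2L)), class = "TraceAnnotation")
  })
  out <- run_pipeline(sim$masks, config = pipeline_config(length_source = "trace"),
                      traces = traces)
  expect_lt(abs(out$result$mean_ef - 50), 3)
})
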