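test_that("EF targeting inverts the prolate-spheroid ratio", {
  # anisotropic closed form: EF = 1 - (L_es D_es^2)/(L_ed D_ed^2)
  v_ed <- volume_area_length(pi * 80 * 40 / 4, 80)
  v_es <- volume_area_length(pi * 64 * 30 / 4, 64)
  expect_equal(cycle_ef(v_ed, v_es), 55.0)

  # isotropic shrink: EF 48.8% <=> s = 0.8 exactly at the ES frame
  ax <- make_axis_curves(rhythm_spec(2, 40, seed = 1),
                         lv_shape_spec(80, 40, per_cycle_ef = 48.8))
  es <- ax$es_frames + 1L
  expect_equal(ax$long[es], rep(0.8 * 80, 2), tolerance = 1e-12)
  expect_equal(ax$short[es], rep(0.8 * 40, 2), tolerance = 1e-12)

  expect_error(lv_shape_spec(80, 40, per_cycle_ef = 100), "strictly")
  expect_error(lv_shape_spec(80, 40, per_cycle_ef = 0), "strictly")
})

test_that("rendered masks match analytic ellipse areas", {
  shape <- lv_shape_spec(80, 40, 50)
  rm_ <- render_masks(list(long = 80, short = 40), shape)
  expect_equal(rm_$analytic_area, 800 * pi)
  expect_lt(abs(sum(rm_$masks[, , 1]) - 800 * pi) / (800 * pi), 0.02)

  circ <- render_masks(list(long = 40, short = 40), lv_shape_spec(40, 40, 50))
  expect_equal(circ$analytic_area, 400 * pi)

  # rotating by pi/2 with swapped axes gives the identical mask
  m1 <- ellipse_mask(80, 40, orientation = 0)
  m2 <- ellipse_mask(40, 80, orientation = pi / 2)
  expect_identical(m1, m2)

  # an ellipse that does not fit is rejected, naming the first bad frame
  big <- lv_shape_spec(200, 40, 50, canvas = c(112L, 112L))
  expect_error(render_masks(list(long = c(80, 200), short = c(40, 40)), big),
               "frame 1")
})

test_that("speckle is deterministic under a seed and varies across seeds", {
  masks <- render_masks(list(long = c(60, 50), short = c(30, 26)),
                        lv_shape_spec(60, 30, 50))$masks
  v1 <- add_speckle(masks, snr = 6, seed = 42)
  v2 <- add_speckle(masks, snr = 6, seed = 42)
  expect_identical(v1$frames, v2$frames)
  v3 <- add_speckle(masks, snr = 6, seed = 43)
  expect_true(any(v1$frames != v3$frames))
  # snr -> Inf approaches the noiseless rim/interior template
  clean <- add_speckle(masks, snr = 1e9, seed = 1)
  expect_equal(sort(unique(round(as.vector(clean$frames), 3))),
               c(0.10, 0.40, 0.85), tolerance = 1e-3)
  expect_error(add_speckle(masks, snr = 0), "snr")
})

test_that("outlier injection changes exactly the listed frames", {
  cv <- new_area_curve(c(10, 20, 30, 20, 10))
  expect_identical(corrupt_curve(cv, 2, 1)$areas, cv$areas)
  one <- corrupt_curve(cv, 2, 0.2)
  expect_equal(sum(one$areas != cv$areas), 1)
  expect_equal(one$areas[3], 30 * 0.2)
  expect_error(corrupt_curve(cv, 7, 0.5), "out of range")
  # corrupting the peak can move the argmax
  half <- corrupt_curve(cv, 2, 0.5)
  expect_false(which.max(half$areas) == which.max(cv$areas))
})

test_that("simulator truth satisfies its structural invariants", {
  sim <- simulate_echo(rhythm_spec(4, 45, period_cv = 0.25, seed = 8),
                       lv_shape_spec(80, 40, c(55, 40, 62, 48)))
  tr <- sim$truth
  expect_equal(dim(sim$masks)[3], dim(sim$video$frames)[3])
  # ED/ES strictly interleaved: ed < es < next ed
  expect_true(all(tr$ed_frames < tr$es_frames))
  expect_true(all(tr$es_frames[-length(tr$es_frames)] < tr$ed_frames[-1]))
  # overall EF is the mean of the per-cycle EFs, to machine precision
  expect_identical(tr$overall_ef, mean(tr$per_cycle_ef))
  # truth EDs are local maxima, ESs local minima of the analytic curve
  a <- tr$area
  for (f in tr$ed_frames) {
    i <- f + 1L
    expect_true(a[i] >= a[max(1, i - 1)] && a[i] >= a[min(length(a), i + 1)])
  }
  for (f in tr$es_frames) {
    i <- f + 1L
    expect_true(a[i] <= a[i - 1] && a[i] <= a[i + 1])
  }
  # determinism of the whole generator under a fixed seed
  sim2 <- simulate_echo(rhythm_spec(4, 45, period_cv = 0.25, seed = 8),
                        lv_shape_spec(80, 40, c(55, 40, 62, 48)))
  expect_identical(sim$video$frames, sim2$video$frames)
  expect_identical(sim$truth, sim2$truth)
})

test_that("area-length volume equals the prolate-spheroid volume for ellipses", {
  # analytic identity V = 8A^2/(3 pi L) = pi L D^2 / 6 when A = pi L D / 4
  for (pair in list(c(80, 40), c(60, 30), c(90, 55), c(40, 40), c(70, 22))) {
    L <- pair[1]; D <- pair[2]
    a <- pi * L * D / 4
    expect_equal(volume_area_length(a, L), pi * L * D^2 / 6, tolerance = 1e-12)
  }
})
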