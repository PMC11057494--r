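test_that("ED/ES detection finds the analytic extrema of clean sinusoids", {
  t <- 0:159
  x <- 100 + 50 * cos(2 * pi * t / 40)  # interior EDs at 40, 80, 120
  cs <- detect_ed_es(new_area_curve(x))
  expect_equal(cs$pairs$ed_frame, c(40, 80, 120))
  expect_equal(cs$pairs$es_frame, c(60, 100, 140))
  # ordering invariant ed_i < es_i < ed_{i+1}
  expect_true(all(cs$pairs$ed_frame < cs$pairs$es_frame))
  expect_true(all(cs$pairs$es_frame[-3] < cs$pairs$ed_frame[-1]))
})

test_that("constant and short curves yield empty cycle sets, not errors", {
  expect_equal(n_cycles(detect_ed_es(new_area_curve(rep(7, 100)))), 0)
  expect_warning(cs <- detect_ed_es(new_area_curve(c(1, 5, 1))), "min_distance")
  expect_equal(n_cycles(cs), 0)
})

test_that("sub-prominence spikes never create cycles", {
  t <- 0:159
  x <- 100 + 50 * cos(2 * pi * t / 40)
  rng <- max(x) - min(x)
  x_spiked <- x
  x_spiked[102] <- x_spiked[102] + 0.3 * rng  # between two EDs, below half range
  cs0 <- detect_ed_es(new_area_curve(x))
  cs1 <- detect_ed_es(new_area_curve(x_spiked))
  expect_equal(nrow(cs1$pairs), nrow(cs0$pairs))
  # the spike frame itself was not selected as an ED
  expect_false(101 %in% cs1$pairs$ed_frame)
  # prominence oracle: the spike's own prominence is below the threshold
  prom <- echolvef:::peak_prominence(x_spiked, 102L)
  expect_lt(prom, 0.5 * (max(x_spiked) - min(x_spiked)))
})

test_that("detection is invariant under positive affine rescaling", {
  set.seed(5)
  for (rep in 1:5) {
    sim <- simulate_echo(rhythm_spec(sample(2:4, 1), 45, period_cv = 0.2,
                                     seed = rep), lv_shape_spec(80, 40, 50))
    cv <- new_area_curve(sim$truth$area)
    a <- runif(1, 0.1, 8); b <- runif(1, -50, 400)
    cs1 <- detect_ed_es(cv)
    cs2 <- detect_ed_es(new_area_curve(a * cv$areas + b - min(a * cv$areas + b)))
    expect_equal(cs1$pairs, cs2$pairs)
  }
})

test_that("detected cycle count equals the simulated cycle count", {
  for (k in 1:6) {
    sim <- simulate_echo(rhythm_spec(k, 44, seed = 10 + k),
                         lv_shape_spec(80, 40, 52))
    cs <- detect_ed_es(new_area_curve(sim$truth$area))
    expect_equal(n_cycles(cs), k)
  }
})

test_that("percentile baseline follows the linear-interpolation convention", {
  expect_equal(baseline_percentile(new_area_curve(1:100)),
               c(a_ed = 90.1, a_es = 10.9))
  expect_equal(baseline_percentile(new_area_curve(rep(7, 12))),
               c(a_ed = 7, a_es = 7))
  expect_equal(baseline_percentile(new_area_curve(c(0, 100))),
               c(a_ed = 90.0, a_es = 10.0))
})

test_that("refinement pools behave as the literal step-by-step oracle", {
  sim <- simulate_echo(rhythm_spec(3, 50, period_cv = 0.2, seed = 21),
                       lv_shape_spec(80, 40, c(50, 58, 45)))
  cv <- new_area_curve(sim$truth$area)
  cs <- detect_ed_es(cv)
  for (ci in seq_len(n_cycles(cs))) {
    got <- refine_jeffrey(cv, cs, ci)
    want <- jeffrey_literal(cv$areas,
                            match(cs$pairs$ed_frame[ci], cv$frame_indices),
                            match(cs$pairs$es_frame[ci], cv$frame_indices))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # fraction -> 0 degenerates to the raw single-frame areas
  raw <- refine_jeffrey(cv, cs, 2, fraction = 0)
  i_ed <- match(cs$pairs$ed_frame[2], cv$frame_indices)
  i_es <- match(cs$pairs$es_frame[2], cv$frame_indices)
  expect_equal(unname(raw), c(cv$areas[i_ed], cv$areas[i_es]))
})

test_that("a two-level plateau curve refines to the plateau values", {
  # high plateau A0, low plateau A1; every member of the ED pool is A0
  x <- rep(c(rep(10, 4), rep(2, 6)), 4)
  cv <- new_area_curve(x)
  cs <- manual_cycles(cv, ed_frames = 11, es_frames = 15)
  got <- refine_jeffrey(cv, cs, 1)
  expect_equal(unname(got["a_ed"]), 10)
})

test_that("refinement pulls a corrupted ED area back toward the truth", {
  sim <- simulate_echo(rhythm_spec(3, 50, seed = 31), lv_shape_spec(80, 40, 55))
  cv <- new_area_curve(sim$truth$area)
  cs <- detect_ed_es(cv)
  ed2 <- cs$pairs$ed_frame[2]
  truth <- cv$areas[match(ed2, cv$frame_indices)]
  bad <- corrupt_curve(cv, ed2, 0.7)
  cs_bad <- manual_cycles(bad, cs$pairs$ed_frame, cs$pairs$es_frame)
  jeff <- refine_jeffrey(bad, cs_bad, 2)["a_ed"]
  raw <- bad$areas[match(ed2, bad$frame_indices)]
  expect_lt(abs(jeff - truth), abs(raw - truth))
})

test_that("three-part pooling averages the part means instead", {
  cv <- new_area_curve(c(5, 9, 14, 9, 5, 3, 2, 3, 5, 9, 14, 9, 5, 3, 2, 3))
  cs <- manual_cycles(cv, 2, 6)
  pooled <- refine_jeffrey(cv, cs, 1, fraction = 0.2, pooling = "pooled")
  three <- refine_jeffrey(cv, cs, 1, fraction = 0.2, pooling = "three_part")
  n_top <- ceiling(0.2 * 16); m_top <- ceiling(0.2 * 5)
  top_all <- sort(cv$areas, decreasing = TRUE)[1:n_top]
  top_win <- sort(cv$areas[3:7], decreasing = TRUE)[1:m_top]
  expect_equal(unname(pooled["a_ed"]), mean(c(14, top_all, top_win)))
  expect_equal(unname(three["a_ed"]), mean(c(14, mean(top_all), mean(top_win))))
})
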