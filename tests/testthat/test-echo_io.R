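test_that("video reading normalises intensities and resizes on request", {
  td <- withr::local_tempdir()
  # constant-255 8-bit stack reads back as all 1.0
  p <- file.path(td, "const.tiff")
  tiff::writeTIFF(replicate(3, matrix(1, 16, 16), simplify = FALSE), p,
                  bits.per.sample = 8)
  v <- read_video(p)
  expect_equal(dim(v$frames), c(16, 16, 3))
  expect_true(all(v$frames == 1.0))

  p0 <- file.path(td, "zero.tiff")
  tiff::writeTIFF(list(matrix(0, 8, 8)), p0, bits.per.sample = 8)
  v0 <- read_video(p0)
  expect_equal(dim(v0$frames)[3], 1)
  expect_true(all(v0$frames == 0))

  # 16x16 synthetic video resized to the network input size
  v112 <- read_video(p, target_size = c(112, 112))
  expect_equal(dim(v112$frames)[1:2], c(112, 112))
  expect_true(all(v112$frames >= 0 & v112$frames <= 1))

  expect_error(read_video(file.path(td, "missing.tiff")), "no such file")
  expect_error(read_video(file.path(td, "x.avi")), "codec")
})

test_that("TIFF write/read round-trip preserves frames up to quantisation", {
  td <- withr::local_tempdir()
  sim <- simulate_echo(rhythm_spec(1, 30, seed = 4), lv_shape_spec(50, 26, 45),
                       snr = 6)
  p8 <- file.path(td, "v8.tiff")
  write_video(sim$video, p8, bits = 8)
  back <- read_video(p8)
  expect_lt(max(abs(back$frames - sim$video$frames)), 1 / 255)
  p16 <- file.path(td, "v16.tiff")
  write_video(sim$video, p16, bits = 16)
  expect_lt(max(abs(read_video(p16)$frames - sim$video$frames)), 1 / 65535)
})

test_that("tracings parser assembles chord blocks into 42-point annotations", {
  td <- withr::local_tempdir()
  csv <- file.path(td, "tr.csv")
  set.seed(9)
  df <- data.frame(FileName = rep(c("a", "b", "a"), each = 21),
                   X1 = runif(63, 10, 20), Y1 = runif(63, 10, 20),
                   X2 = runif(63, 30, 40), Y2 = runif(63, 30, 40),
                   Frame = rep(c(5, 9, 44), each = 21))
  # interleave the two videos' blocks
  df <- df[order(rep(c(1, 2, 3), each = 21) %% 2), ]
  write.csv(df, csv, row.names = FALSE)
  tr <- read_tracings(csv)
  expect_named(tr, c("b", "a"), ignore.order = TRUE)
  # per-video annotation counts equal the independent group-by
  counts <- table(unique(data.frame(f = df$FileName, fr = df$Frame))$f)
  expect_equal(lengths(tr)[names(counts)], as.vector(counts),
               ignore_attr = TRUE)
  ann <- tr[["a"]][[1]]
  expect_equal(nrow(ann$points), 42)
  expect_equal(ann$axis_pair, c(1L, 2L))
  # point counts are even and >= 4 for every annotation
  for (v in tr) for (a in v) {
    expect_true(nrow(a$points) %% 2 == 0 && nrow(a$points) >= 4)
  }

  # header-only file: empty map
  write.csv(df[0, ], csv, row.names = FALSE)
  expect_length(read_tracings(csv), 0)

  # missing column and non-numeric coordinate are flagged
  write.csv(df[, -2], csv, row.names = FALSE)
  expect_error(read_tracings(csv), "X1")
  df2 <- df; df2$X1 <- as.character(df2$X1); df2$X1[3] <- "oops"
  write.csv(df2, csv, row.names = FALSE)
  expect_error(read_tracings(csv), "row 3")
})

test_that("label reader parses EF records and validates ranges", {
  td <- withr::local_tempdir()
  csv <- file.path(td, "labels.csv")
  writeLines(c("FileName,EF,EDV,ESV", "v1,62.1,120.0,45.5"), csv)
  lab <- read_labels(csv)
  expect_equal(lab$ef_ref, 62.1)
  expect_equal(lab$edv_ref, 120.0)

  writeLines("FileName,EF,EDV,ESV", csv)
  expect_equal(nrow(read_labels(csv)), 0)

  writeLines(c("FileName,EF,EDV,ESV", "v1,granted,120,45"), csv)
  expect_error(read_labels(csv), "non-numeric EF")
  writeLines(c("FileName,EF,EDV,ESV", "v1,140,120,45"), csv)
  expect_error(read_labels(csv), "row 1")
})

test_that("report write/read round-trip is the identity on all fields", {
  td <- withr::local_tempdir()
  sim <- simulate_echo(rhythm_spec(3, 45, seed = 6), lv_shape_spec(80, 40, c(55, 48, 60)))
  out <- run_pipeline(sim$masks, config = pipeline_config(length_source = "height"))
  for (fmt in c("json", "csv")) {
    p <- file.path(td, paste0("report.", fmt))
    write_report(out$result, p, fmt)
    back <- read_report(p, fmt)
    expect_identical(back$mean_ef, out$result$mean_ef)
    expect_identical(back$n_cycles, out$result$n_cycles)
    expect_identical(back$phenotype, out$result$phenotype)
    expect_identical(back$hfref_flag, out$result$hfref_flag)
    expect_equal(back$cycles, out$result$cycles, tolerance = 0)
  }
})
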