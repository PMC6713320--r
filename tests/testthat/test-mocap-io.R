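test_that("the two capture dialects parse to value-equal trajectory sets", {
  paths <- two_marker_fixture(withr::local_tempdir())
  tw <- read_trajectory_table(paths$wide, "tsv_wide")
  tl <- read_trajectory_table(paths$long, "csv_long")
  expect_s3_class(tw, "trajectory_set")
  expect_equal(length(tw$markers), 2L)
  expect_equal(n_frames(tw), 3L)
  expect_equal(tw$frame_rate, 100)
  expect_equal(tw$markers$A$positions, tl$markers$A$positions,
               ignore_attr = TRUE)
  expect_equal(tw$markers$B$positions, tl$markers$B$positions,
               ignore_attr = TRUE)
  expect_equal(tl$frame_rate, 100)
})

test_that("occlusion handling: blank cells, missing rows, and the zero flag", {
  dir <- withr::local_tempdir()
  # blank cell at frame 2 of marker A only
  rows <- c("0\t0\t0\t10\t10\t10", "\t\t\t11\t11\t11",
            "2\t2\t2\t12\t12\t12")
  f <- file.path(dir, "gap.tsv")
  writeLines(tsv_wide_fixture(rows), f)
  ts <- read_trajectory_table(f, "tsv_wide")
  expect_equal(ts$markers$A$valid, c(TRUE, FALSE, TRUE))
  expect_equal(ts$markers$B$valid, rep(TRUE, 3))
  # (0,0,0) is a legitimate point by default ...
  rows0 <- c("0\t0\t0\t10\t10\t10", "5\t5\t5\t11\t11\t11")
  f0 <- file.path(dir, "zero.tsv")
  writeLines(tsv_wide_fixture(rows0), f0)
  expect_true(all(read_trajectory_table(f0, "tsv_wide")$markers$A$valid))
  # ... and occlusion when the header says so
  fz <- file.path(dir, "zeroflag.tsv")
  writeLines(tsv_wide_fixture(rows0,
                              extra_header = "ZERO_AS_MISSING\t1"), fz)
  expect_equal(read_trajectory_table(fz, "tsv_wide")$markers$A$valid,
               c(FALSE, TRUE))
  # csv_long: an absent (frame, marker) row is an occlusion
  lf <- file.path(dir, "gap.csv")
  writeLines(c("frame,time,marker,x,y,z",
               "0,0,A,1,1,1", "1,0.01,A,2,2,2", "2,0.02,A,3,3,3",
               "0,0,B,9,9,9", "2,0.02,B,9,9,9"), lf)
  tl <- read_trajectory_table(lf, "csv_long")
  expect_equal(tl$markers$B$valid, c(TRUE, FALSE, TRUE))
})

test_that("malformed captures raise format/structure errors", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "nohead.tsv")
  writeLines(c("0\t0\t0"), f)
  expect_error(read_trajectory_table(f, "tsv_wide"), "format error")
  f2 <- file.path(dir, "ragged.tsv")
  writeLines(tsv_wide_fixture("0\t0\t0\t1\t1\t1\t9"), f2)
  expect_error(read_trajectory_table(f2, "tsv_wide"), "format error")
  f3 <- file.path(dir, "nc.csv")
  writeLines(c("frame,time,marker,x,y,z", "0,0,A,1,1,1", "2,0.02,A,2,2,2"),
             f3)
  expect_error(read_trajectory_table(f3, "csv_long"), "not contiguous")
})

test_that("trajectory tables round-trip through both writers", {
  dir <- withr::local_tempdir()
  ses <- simulate_session(simulation_config(n_reps = 2, rep_period = 1.5,
                                            marker_noise_sd = 0.7,
                                            seed = 11))
  ts <- ses$trajectories
  for (dialect in c("tsv_wide", "csv_long")) {
    p <- file.path(dir, paste0("rt.", dialect))
    write_trajectory_table(ts, p, dialect)
    back <- read_trajectory_table(p, dialect)
    expect_equal(back$frame_rate, ts$frame_rate)
    for (m in names(ts$markers)) {
      expect_equal(back$markers[[m]]$positions, ts$markers[[m]]$positions,
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(back$markers[[m]]$valid, ts$markers[[m]]$valid,
                   ignore_attr = TRUE)
    }
  }
})

test_that("fill_gaps interpolates short interior gaps only, idempotently", {
  pos <- cbind(c(0, NA, 2, NA, NA, NA, 6, 7), 2 * c(0, NA, 2, NA, NA, NA, 6, 7),
               -c(0, NA, 2, NA, NA, NA, 6, 7))
  ts <- trajectory_set(list(M = pos), frame_rate = 100)
  f1 <- fill_gaps(ts, 1)
  expect_equal(f1$markers$M$positions[2, ], c(x = 1, y = 2, z = -1))
  expect_equal(f1$markers$M$valid,
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # 3-frame gap untouched at max_gap 2, filled at 3
  f2 <- fill_gaps(ts, 2)
  expect_false(any(f2$markers$M$valid[4:6]))
  f3 <- fill_gaps(ts, 3)
  expect_equal(f3$markers$M$positions[4:6, 1], c(3, 4, 5))
  # edge gaps never filled
  pos_e <- cbind(c(NA, 1, 2, NA), c(NA, 1, 2, NA), c(NA, 1, 2, NA))
  fe <- fill_gaps(trajectory_set(list(M = pos_e), 100), 10)
  expect_equal(fe$markers$M$valid, c(FALSE, TRUE, TRUE, FALSE))
  # idempotence
  g <- fill_gaps(f1, 1)
  expect_equal(g$markers$M$positions, f1$markers$M$positions)
  expect_equal(g$markers$M$valid, f1$markers$M$valid)
})

test_that("derived-record files hold the logged quantities and round-trip", {
  dir <- withr::local_tempdir()
  ses <- simulate_session(simulation_config(n_reps = 2, rep_period = 1.5,
                                            seed = 5))
  ts <- ses$trajectories
  d <- derive_series(ts, default_role_map(), ses$profile)
  cs <- controls_from_derived(d)
  p <- file.path(dir, "rec.txt")
  write_derived_records(ts, d, cs, p)
  back <- read_derived_records(p)
  expect_equal(nrow(back), n_frames(ts))
  expect_equal(back$sb, d$sb, tolerance = 1e-9)
  expect_equal(back$bfd, d$bfd, tolerance = 1e-9)
  expect_equal(back$distortion, 1 - cs$quality, tolerance = 1e-9)
  expect_equal(back$volume_left, cs$gain_front, tolerance = 1e-9)
  expect_equal(back$L4_z, ts$markers$L4$positions[, 3], tolerance = 1e-9)
  # control-only session: audio columns blank
  p2 <- file.path(dir, "ctl.txt")
  write_derived_records(ts, d, NULL, p2)
  back2 <- read_derived_records(p2)
  expect_true(all(is.na(back2$distortion)))
  expect_true(all(is.na(back2$volume_right)))
  # zero-frame capture: header only
  expect_error(write_derived_records(ts, d[1:3, ], cs, p2),
               "contract error")
})
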