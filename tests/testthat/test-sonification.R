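test_that("the logistic map hits its closed-form values and midpoint", {
  # midpoint is 0.5 for any steepness
  for (a in c(0.5, 10, 15, 80))
    expect_equal(logistic_map(0.3, mapping_params(a, 0.3)), 0.5)
  # worked values against the closed form 1 - 1/(1 + exp(-a*(x-b)))
  expect_equal(logistic_map(0, spine_params()), 1 - 1 / (1 + exp(2)),
               tolerance = 1e-12)
  expect_equal(logistic_map(1, spine_params()), 1 - 1 / (1 + exp(-8)),
               tolerance = 1e-12)
  expect_equal(logistic_map(0, barbell_params()), 1 - 1 / (1 + exp(9)),
               tolerance = 1e-12)
  # asymptotes
  expect_equal(logistic_map(1e6, spine_params()), 0)
  expect_equal(logistic_map(-1e6, spine_params()), 1)
})

test_that("logistic map is strictly decreasing, bounded, and symmetric", {
  p <- mapping_params(7, 0.35)
  x <- sort(runif(200, -3, 3))
  y <- logistic_map(x, p)
  expect_true(all(diff(y) < 0))
  expect_true(all(y > 0 & y < 1))
  d <- runif(50, 0, 5)
  expect_equal(logistic_map(p$beta + d, p) + logistic_map(p$beta - d, p),
               rep(1, 50), tolerance = 1e-12)
})

test_that("feedback controls implement the channel semantics", {
  # spine: midpoint at beta, near-pristine in extension
  expect_equal(spine_control(0.2), 0.5)
  expect_lt(spine_control(1), 4e-4)
  expect_gt(spine_control(-0.5), 0.999)
  # barbell: complementary gains, front dominates toward the toes
  g <- barbell_control(c(0.6, 0, 2))
  expect_equal(g$gain_front + g$gain_surround, rep(1, 3))
  expect_equal(g$gain_front[1], 0.5)
  expect_gt(g$gain_front[2], 0.999)
  expect_lt(g$gain_front[3], 1e-6)
  # conservation over a random control series; NA propagates
  cs <- control_series(time = (0:99) / 100,
                       sb = c(NA, runif(99, -1, 2)),
                       bfd = c(runif(99, -1, 2), NA))
  ok <- !is.na(cs$gain_front)
  expect_equal(cs$gain_front[ok] + cs$gain_surround[ok],
               rep(1, sum(ok)), tolerance = 1e-12)
  expect_true(is.na(cs$quality[1]) && is.na(cs$gain_front[100]))
})

test_that("control series round-trip through CSV", {
  cs <- control_series(time = (0:9) / 100, sb = runif(10), bfd = runif(10))
  p <- withr::local_tempfile(fileext = ".csv")
  write_control_series(cs, p)
  back <- read_control_series(p)
  expect_equal(back$quality, cs$quality, tolerance = 1e-6)
  expect_equal(back$gain_surround, cs$gain_surround, tolerance = 1e-6)
})

test_that("WAV codec round-trips PCM16/24 and float32, mono and stereo", {
  dir <- withr::local_tempdir()
  set.seed(3)
  for (bits in c(16, 24, 32)) for (ch in 1:2) {
    x <- matrix(runif(400 * ch, -0.99, 0.99), ncol = ch)
    w <- wav(x, sample_rate = 8000, bit_depth = bits)
    p <- file.path(dir, sprintf("t%d_%d.wav", bits, ch))
    write_wav(w, p)
    back <- read_wav(p)
    expect_equal(back$sample_rate, 8000)
    expect_equal(ncol(back$samples), ch)
    tol <- if (bits == 32) 1e-7 else 2^-(bits - 1)
    expect_equal(back$samples, w$samples, tolerance = tol)
    # a second write of the read object is bit-identical to the first file
    p2 <- file.path(dir, "again.wav")
    write_wav(back, p2)
    expect_identical(readBin(p, "raw", file.info(p)$size),
                     readBin(p2, "raw", file.info(p2)$size))
  }
  expect_error(read_wav(file.path(dir, "missing.wav")), "not found")
})

test_that("renderer is the identity under pristine controls, bit-exactly", {
  set.seed(8)
  w <- wav(matrix(runif(1000, -0.9, 0.9), ncol = 2), sample_rate = 500,
           bit_depth = 16)
  # quality exactly 1, gains exactly (0, 1): far beyond both midpoints
  cs <- control_series(time = (0:49) / 100, sb = rep(-100, 50),
                       bfd = rep(100, 50))
  expect_equal(cs$quality, rep(1, 50))
  expect_equal(cs$gain_front, rep(0, 50))
  for (mode in c("spine", "barbell", "combination")) {
    out <- render_feedback(w, cs, mode)
    expect_identical(out$samples, w$samples)
  }
})

test_that("half quality holds every second sample; unit front gain kills width", {
  # impulse-train input so held samples are unambiguous
  x <- rep(0, 200); x[seq(1, 199, 2)] <- seq_len(100) / 100
  w <- wav(x, sample_rate = 200, bit_depth = 32)
  cs <- control_series(time = c(0), sb = 0.2, bfd = 0.6)  # quality 0.5
  out <- render_feedback(w, cs, "spine")
  expect_equal(out$samples[seq(2, 200, 2), 1],
               out$samples[seq(1, 199, 2), 1])
  expect_equal(out$samples[seq(1, 199, 2), 1], x[seq(1, 199, 2)])
  expect_equal(nrow(out$samples), 200)
  # gains (1, 0): stereo image collapses to mono -> zero side signal
  set.seed(1)
  ws <- wav(matrix(runif(600, -1, 1), ncol = 2), sample_rate = 300,
            bit_depth = 32)
  csf <- control_series(time = 0, sb = -100, bfd = -100)
  expect_equal(csf$gain_front, 1)
  outf <- render_feedback(ws, csf, "barbell")
  side <- (outf$samples[, 1] - outf$samples[, 2]) / 2
  expect_equal(sqrt(mean(side^2)), 0)
  # deterministic
  out2 <- render_feedback(ws, csf, "barbell")
  expect_identical(outf$samples, out2$samples)
})

test_that("renderer rejects control rates above the audio rate", {
  w <- wav(rep(0.1, 50), sample_rate = 50)
  cs <- control_series(time = (0:9) / 100, sb = rep(0, 10), bfd = rep(1, 10))
  expect_error(render_feedback(w, cs, "spine"), "control frame rate")
})
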