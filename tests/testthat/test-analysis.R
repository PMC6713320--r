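test_that("normality gate: branch decisions and degenerate input", {
  set.seed(1)
  r <- test_normality(rnorm(20))
  expect_true(is.list(r) && is.logical(r$is_normal))
  expect_true(r$p >= 0 && r$p <= 1)
  expect_error(test_normality(c(1, 2)), "sample-size")
  expect_warning(rc <- test_normality(rep(3, 10)), "zero-variance")
  expect_false(rc$is_normal)
})

test_that("heavy tails are flagged non-normal far more often than Gaussians", {
  set.seed(7)
  flags <- replicate(200, test_normality(rt(20, df = 1))$is_normal)
  expect_lt(mean(flags), 0.2)
  flags_g <- replicate(200, test_normality(rnorm(20))$is_normal)
  expect_gt(mean(flags_g), 0.9)
})

test_that("within-participant comparison branches and reports direction", {
  # zero-mean symmetric differences: t = 0, p = 1
  x <- c(1, -1, 2, -2); y <- rep(0, 4)
  r <- compare_within(x, y)
  expect_equal(unname(r$statistic), 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  # a consistent +0.5 shift is detected with a positive direction
  set.seed(2)
  ctl <- rnorm(10)
  r2 <- compare_within(ctl + 0.5 + rnorm(10, 0, 0.01), ctl)
  expect_lt(r2$p_value, 0.001)
  expect_match(r2$note, "positive")
  expect_true(r2$test_name %in% c("paired_t", "wilcoxon_signed_rank"))
  # identical pairs: degenerate, warning, no crash
  expect_warning(r3 <- compare_within(ctl, ctl), "zero-variance")
  expect_true(is.na(r3$p_value))
  expect_error(compare_within(1:4, 1:5), "pairing error")
  # skewed differences take the signed-rank branch
  set.seed(5)
  d <- rexp(20)^3
  r4 <- compare_within(ctl2 <- rnorm(20), ctl2 - d)
  expect_equal(r4$test_name, "wilcoxon_signed_rank")
  expect_false(r4$normality[["differences"]])
})

test_that("between-group comparison pools under normality, ranks otherwise", {
  set.seed(3)
  a <- rnorm(12)
  r <- compare_between(a, a)
  expect_equal(unname(r$statistic), 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  expect_equal(r$test_name, "independent_t")
  expect_equal(r$df, 22)               # pooled: n1 + n2 - 2
  # one grossly outlying sample flips the branch
  set.seed(4)
  b <- c(rnorm(29), 50)
  r2 <- compare_between(rnorm(30), b)
  expect_equal(r2$test_name, "rank_sum")
  expect_false(all(r2$normality))
  # a clear shift is detected
  set.seed(6)
  r3 <- compare_between(rnorm(50), rnorm(50, 1))
  expect_lt(r3$p_value, 0.01)
})

test_that("chi-square homogeneity matches the brute-force expected counts", {
  tab <- rbind(c(2, 9, 5), c(3, 6, 6))
  r <- homogeneity_chisq(tab)
  expect_equal(r$df, 2)
  # independent oracle: straight Pearson sum over expected counts
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(r$statistic), sum((tab - exp_counts)^2 / exp_counts),
               tolerance = 1e-12)
  # perfectly proportional table: statistic 0, p 1
  r0 <- homogeneity_chisq(rbind(c(2, 4, 6), c(1, 2, 3)))
  expect_equal(unname(r0$statistic), 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  expect_error(homogeneity_chisq(rbind(c(0, 0), c(1, 2))),
               "degenerate-table")
})

test_that("improvements difference feedback against control per participant", {
  rec <- data.frame(
    participant_id = rep(c("P1", "P2"), each = 2),
    group = "instruction", expertise = "B",
    condition = rep(c("control", "combination"), 2),
    mean_sb = c(0.3, 0.1, 0.2, 0.2),
    mean_bfd = c(0.4, 1.0, 0.5, 0.5))
  imp <- improvements(rec)
  expect_equal(imp$delta_sb, c(-0.2, 0))
  expect_equal(imp$delta_bfd, c(0.6, 0))
  # a participant missing the feedback session is skipped with a warning
  expect_warning(imp2 <- improvements(rec[-2, ]), "lacks")
  expect_equal(nrow(imp2), 1L)
})

test_that("nested expertise models recover an exactly level-dependent outcome", {
  lv <- rep(c("A", "B", "C"), times = c(6, 6, 6))
  imp <- data.frame(participant_id = sprintf("P%02d", 1:18),
                    group = rep(c("instruction", "sonification"), 9),
                    expertise = lv,
                    delta_bfd = c(A = 1.0, B = 0.2, C = 0.5)[lv],
                    delta_sb = 0)
  fit <- fit_expertise_models(imp, "delta_bfd")
  expect_equal(unname(fit$level_means),
               c(1.0, 0.2, 0.5), tolerance = 1e-12)
  cmp <- fit$comparisons
  expect_lt(cmp$p_value[cmp$model == "exp"], 1e-12)
  # single expertise level is a singular design
  imp1 <- imp; imp1$expertise <- "B"
  expect_error(fit_expertise_models(imp1, "delta_bfd"), "singular-design")
})

test_that("rating tests exclude zeros and use rank statistics", {
  set.seed(9)
  ratings <- data.frame(
    participant_id = sprintf("P%02d", 1:16),
    group = rep(c("instruction", "sonification"), each = 8),
    clarity = c(5, 6, 4, 0, 5, 7, 6, 5, 5, 6, 4, 5, 0, 7, 6, 5),
    motivation = c(rep(0, 8), 4, 5, 6, 4, 5, 6, 4, 5))
  imp <- stats::setNames(seq(0.1, 1.6, by = 0.1), ratings$participant_id)
  expect_warning(res <- rating_tests(ratings, improvement = imp),
                 "fewer than 3|skipped")
  expect_equal(res$group_tests$clarity$test_name, "mann_whitney_u")
  # identical rating vectors across groups: p = 1
  same <- data.frame(participant_id = sprintf("P%02d", 1:12),
                     group = rep(c("instruction", "sonification"), each = 6),
                     clarity = rep(c(3, 4, 5, 6, 5, 4), 2))
  r <- rating_tests(same)$group_tests$clarity
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  # perfect concordance / discordance in tau-b
  conc <- data.frame(participant_id = sprintf("P%02d", 1:8),
                     group = rep(c("instruction", "sonification"), 4),
                     clarity = 1:8 %% 7 + 1)
  conc$clarity <- c(1, 2, 3, 4, 5, 6, 7, 7) # ties at top
  imp_c <- stats::setNames(c(1:7, 7.5), conc$participant_id)
  rt <- rating_tests(conc, improvement = imp_c)
  expect_gt(rt$correlations$clarity$statistic, 0.9)
  imp_d <- stats::setNames(rev(1:8), conc$participant_id)
  rt2 <- rating_tests(conc, improvement = imp_d)
  expect_lt(rt2$correlations$clarity$statistic, -0.9)
})

test_that("branch decisions are recorded and the pipeline reruns identically", {
  coh <- simulate_cohort(seed = 42, method = "summary")
  an1 <- analyze_cohort(coh$records)
  an2 <- analyze_cohort(coh$records)
  for (nm in names(an1$within)) {
    expect_identical(an1$within[[nm]]$test_name, an2$within[[nm]]$test_name)
    expect_equal(an1$within[[nm]]$p_value, an2$within[[nm]]$p_value)
    expect_false(anyNA(an1$within[[nm]]$normality))
  }
  expect_equal(an1$homogeneity$df, 2)
  # Holm adjustment is monotone and >= raw p
  adj <- adjust_holm(an1$within)
  for (nm in names(adj))
    expect_gte(adj[[nm]]$p_adjusted, adj[[nm]]$p_value)
})

test_that("cohort tables round-trip and drive the full analysis", {
  coh <- simulate_cohort(n_instruction = 8, n_sonification = 8, seed = 5,
                         method = "summary")
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(coh$records, p)
  back <- read_cohort_table(p)
  expect_equal(back$mean_sb, coh$records$mean_sb, tolerance = 1e-9)
  an <- analyze_cohort(back)
  expect_s3_class(an, "cohort_analysis")
  expect_length(an$within, 4)
  expect_true(all(vapply(an$within, function(r) r$p_value >= 0 &&
                           r$p_value <= 1, logical(1))))
})
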