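# Normality-branched statistical evaluation pipeline
#
# Every comparison first checks normality (Shapiro-Wilk at alpha = 0.05) of
# the quantity actually tested — paired differences for within-participant
# comparisons, each sample for between-group ones — and then branches:
# parametric t test when normal, rank-based test otherwise. The branch taken
# is recorded on the result so the decision is reproducible. Tests are
# two-sided; no multiple-testing correction is applied by default (a Holm
# adjustment helper is provided).

new_comparison <- function(test_name, statistic, df = NA_real_, n = NA_real_,
                           p_value, normality = logical(),
                           note = NA_character_) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), n = n, p_value = unname(p_value),
                 normality = normality, note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  stat <- if (is.na(x$statistic)) "NA" else sprintf("%.4g", x$statistic)
  p <- if (is.na(x$p_value)) "NA" else sprintf("%.4g", x$p_value)
  cat(sprintf("<%s> statistic = %s, p = %s", x$test_name, stat, p))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  cat("\n")
  if (length(x$normality))
    cat("  normality:", paste(sprintf("%s=%s", names(x$normality),
                                      x$normality), collapse = ", "), "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param sample numeric vector, n >= 3.
#' @param alpha significance level for the branch decision (default 0.05).
#' @return list: `is_normal` (`p > alpha`), `W`, `p`. A zero-variance sample
#'   is returned as non-normal (`W = NA`) with a warning, so degenerate
#'   inputs branch to the rank tests instead of crashing.
#' @export
test_normality <- function(sample, alpha = 0.05) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 3L)
    stop("sample-size error: Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (stats::sd(sample) == 0) {
    warning("zero-variance sample: treated as non-normal")
    return(list(is_normal = FALSE, W = NA_real_, p = NA_real_))
  }
  sw <- stats::shapiro.test(sample)
  list(is_normal = unname(sw$p.value) > alpha, W = unname(sw$statistic),
       p = unname(sw$p.value))
}

#' Within-participant comparison (feedback vs control)
#'
#' Paired design: the same participants are measured in both conditions.
#' The paired differences are checked for normality; if normal, a paired t
#' test is used, otherwise a Wilcoxon signed-rank test. Zero-variance
#' differences produce a degenerate result with a warning.
#'
#' @param x_feedback,x_control paired numeric vectors, equal length,
#'   n >= 3.
#' @param alpha normality branch level.
#' @return a `comparison_result`; `note` records the effect direction
#'   (sign of the mean difference feedback - control).
#' @export
compare_within <- function(x_feedback, x_control, alpha = 0.05) {
  if (length(x_feedback) != length(x_control))
    stop("pairing error: samples differ in length", call. = FALSE)
  ok <- !is.na(x_feedback) & !is.na(x_control)
  x <- x_feedback[ok]; y <- x_control[ok]
  if (length(x) < 3L)
    stop("sample-size error: need >= 3 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("zero-variance paired differences: degenerate comparison")
    return(new_comparison("paired_t", NA_real_, n = length(d),
                          p_value = NA_real_,
                          normality = c(differences = NA),
                          note = "degenerate: identical pairs"))
  }
  nt <- test_normality(d, alpha)
  dir <- if (mean(d) > 0) "positive" else if (mean(d) < 0) "negative"
         else "null"
  if (nt$is_normal) {
    tt <- stats::t.test(x, y, paired = TRUE)
    new_comparison("paired_t", tt$statistic, df = tt$parameter,
                   n = length(d), p_value = tt$p.value,
                   normality = c(differences = TRUE),
                   note = paste0("direction ", dir))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    new_comparison("wilcoxon_signed_rank", wt$statistic, n = length(d),
                   p_value = wt$p.value, normality = c(differences = FALSE),
                   note = paste0("direction ", dir))
  }
}

#' Between-group comparison (independent samples)
#'
#' Both samples are checked for normality; if both pass, a Student t test
#' with pooled variance is used, otherwise a Wilcoxon rank-sum test.
#'
#' @param a,b independent numeric samples, n >= 3 each.
#' @param alpha normality branch level.
#' @param var_equal pool the variances in the t branch (default `TRUE`).
#' @return a `comparison_result`.
#' @export
compare_between <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("sample-size error: need n >= 3 per group", call. = FALSE)
  na <- test_normality(a, alpha); nb <- test_normality(b, alpha)
  if (na$is_normal && nb$is_normal) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    new_comparison("independent_t", tt$statistic, df = tt$parameter,
                   n = length(a) + length(b), p_value = tt$p.value,
                   normality = c(a = TRUE, b = TRUE))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    new_comparison("rank_sum", wt$statistic, n = length(a) + length(b),
                   p_value = wt$p.value,
                   normality = c(a = na$is_normal, b = nb$is_normal))
  }
}

#' Group-homogeneity chi-square test
#'
#' Pearson chi-square without continuity correction on a groups x levels
#' count table (e.g. feedback group by expertise level), df = (r-1)(c-1).
#'
#' @param table 2-D matrix of non-negative counts.
#' @return a `comparison_result`.
#' @export
homogeneity_chisq <- function(table) {
  table <- as.matrix(table)
  stopifnot(length(dim(table)) == 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate-table error: zero marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_comparison("chi_square", ct$statistic, df = ct$parameter,
                 n = sum(table), p_value = ct$p.value)
}

#' Per-participant movement improvements
#'
#' Delta of each summary quantity, feedback condition minus control.
#' Sign conventions: a negative `delta_sb` is an improvement (less forward
#' spine bending); a positive `delta_bfd` is an improvement (bar kept
#' farther from the toes, i.e. a more vertical bar path).
#'
#' @param records cohort data.frame with one row per participant x
#'   condition: columns `participant_id`, `group`, `expertise`, `condition`,
#'   `mean_sb`, `mean_bfd` (see [simulate_cohort()] or
#'   [read_cohort_table()]).
#' @param condition the feedback condition to difference against control
#'   (default `"combination"`).
#' @return data.frame: `participant_id`, `group`, `expertise`, `delta_sb`,
#'   `delta_bfd`. Participants missing either session are skipped with a
#'   warning.
#' @export
improvements <- function(records, condition = "combination") {
  need <- c("participant_id", "condition", "mean_sb", "mean_bfd")
  stopifnot(all(need %in% names(records)))
  ids <- unique(records$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- records[records$participant_id == id, , drop = FALSE]
    ctl <- sub[sub$condition == "control", , drop = FALSE]
    fb <- sub[sub$condition == condition, , drop = FALSE]
    if (nrow(ctl) != 1L || nrow(fb) != 1L) {
      warning("participant ", id, " lacks a ", condition,
              " or control summary; skipped")
      return(NULL)
    }
    data.frame(participant_id = id,
               group = if ("group" %in% names(sub)) sub$group[1L] else NA,
               expertise = if ("expertise" %in% names(sub))
                 sub$expertise[1L] else NA,
               delta_sb = fb$mean_sb - ctl$mean_sb,
               delta_bfd = fb$mean_bfd - ctl$mean_bfd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nested linear models for the effect of expertise
#'
#' Fits four ordinary-least-squares models of a movement improvement:
#' intercept only (null), + feedback type, + expertise (3-level factor),
#' and + both; compares each richer model to the null by a nested-model
#' F test (`anova`). Expertise enters as an unordered factor so the model
#' can produce free per-level means, which are reported from the
#' expertise-only model; an ordinal (polynomial-contrast) coding is
#' available via `ordered_expertise = TRUE`.
#'
#' @param imp improvement table from [improvements()]: needs columns
#'   `group`, `expertise`, and the outcome.
#' @param outcome `"delta_sb"` or `"delta_bfd"`.
#' @param ordered_expertise use ordered-factor (polynomial) coding.
#' @return list of class `expertise_fit`: `models` (named list of `lm`
#'   fits `null`, `fb`, `exp`, `full`), `comparisons` (data.frame of F
#'   tests vs the null), `level_means` (fitted mean per expertise level
#'   from the expertise-only model).
#' @export
fit_expertise_models <- function(imp, outcome = c("delta_bfd", "delta_sb"),
                                 ordered_expertise = FALSE) {
  outcome <- match.arg(outcome)
  stopifnot(all(c("group", "expertise", outcome) %in% names(imp)))
  dat <- imp[stats::complete.cases(imp[, c("group", "expertise", outcome)]), ]
  dat$group <- factor(dat$group)
  dat$expertise <- factor(dat$expertise, levels = sort(unique(dat$expertise)),
                          ordered = ordered_expertise)
  if (nlevels(dat$expertise) < 2L)
    stop("singular-design error: expertise has a single level (",
         levels(dat$expertise), ")", call. = FALSE)
  dat$y <- dat[[outcome]]
  models <- list(
    null = stats::lm(y ~ 1, data = dat),
    fb   = stats::lm(y ~ group, data = dat),
    exp  = stats::lm(y ~ expertise, data = dat),
    full = stats::lm(y ~ group + expertise, data = dat)
  )
  if (any(is.na(stats::coef(models$full))))
    stop("singular-design error: aliased term in the full model (",
         paste(names(which(is.na(stats::coef(models$full)))),
               collapse = ", "), ")", call. = FALSE)
  cmp <- do.call(rbind, lapply(c("fb", "exp", "full"), function(m) {
    an <- stats::anova(models$null, models[[m]])
    data.frame(model = m, df = an$Df[2L], F = an$F[2L],
               p_value = an$`Pr(>F)`[2L])
  }))
  lv <- levels(factor(dat$expertise, ordered = FALSE))
  nd <- data.frame(expertise = factor(lv, levels = levels(dat$expertise),
                                      ordered = ordered_expertise))
  level_means <- stats::setNames(
    as.numeric(stats::predict(models$exp, newdata = nd)), lv)
  structure(list(models = models, comparisons = cmp,
                 level_means = level_means, outcome = outcome),
            class = "expertise_fit")
}

#' @export
print.expertise_fit <- function(x, ...) {
  cat("<expertise_fit> outcome:", x$outcome, "\n")
  cat("model comparisons vs null (F tests):\n")
  print(x$comparisons, row.names = FALSE)
  cat("expertise-only fitted level means:\n")
  print(round(x$level_means, 4))
  invisible(x)
}

#' Rating comparisons and rating-improvement correlations
#'
#' Participants rated the feedback on 7-point scales; a 0 means no feedback
#' was perceived and is excluded before testing. For each rating
#' characteristic, the two feedback groups are compared with a two-sided
#' Mann-Whitney U test, and the rating is correlated with the movement
#' improvement by Kendall's tau-b (tie-corrected).
#'
#' @param ratings data.frame: `participant_id`, `group`, one column per
#'   rating characteristic (integer 0-7).
#' @param characteristics character vector of rating columns to test
#'   (default: every column after the first two).
#' @param improvement optional named numeric vector of improvements keyed
#'   by `participant_id` (enables the tau-b correlations).
#' @return list with `group_tests` and (if improvement supplied)
#'   `correlations`, each a named list of `comparison_result`s;
#'   characteristics empty after zero-exclusion are skipped with a warning.
#' @export
rating_tests <- function(ratings, characteristics = NULL,
                         improvement = NULL) {
  stopifnot(all(c("participant_id", "group") %in% names(ratings)))
  if (is.null(characteristics))
    characteristics <- setdiff(names(ratings),
                               c("participant_id", "group"))
  groups <- unique(ratings$group)
  if (length(groups) != 2L)
    stop("rating comparison needs exactly two groups", call. = FALSE)
  group_tests <- list(); correlations <- list()
  for (ch in characteristics) {
    v <- ratings[[ch]]
    keep <- !is.na(v) & v != 0
    if (!any(keep)) {
      warning("characteristic ", ch, " empty after zero-exclusion; skipped")
      next
    }
    a <- v[keep & ratings$group == groups[1L]]
    b <- v[keep & ratings$group == groups[2L]]
    if (length(a) >= 3L && length(b) >= 3L) {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      group_tests[[ch]] <- new_comparison(
        "mann_whitney_u", wt$statistic, n = length(a) + length(b),
        p_value = wt$p.value)
    } else {
      warning("characteristic ", ch, ": fewer than 3 ratings in a group; ",
              "group test skipped")
    }
    if (!is.null(improvement)) {
      ids <- ratings$participant_id[keep]
      imp <- improvement[match(ids, names(improvement))]
      ok <- !is.na(imp)
      if (sum(ok) >= 3L) {
        kt <- suppressWarnings(stats::cor.test(imp[ok], v[keep][ok],
                                               method = "kendall"))
        correlations[[ch]] <- new_comparison(
          "kendall_tau_b", kt$estimate, n = sum(ok), p_value = kt$p.value)
      }
    }
  }
  out <- list(group_tests = group_tests)
  if (!is.null(improvement)) out$correlations <- correlations
  out
}

#' Read / write a cohort table
#'
#' One row per participant x condition: `participant_id`, `group`
#' (`instruction`/`sonification`), `expertise` (`A` < `B` < `C`), `sex`,
#' `condition` (`control`/`spine`/`barbell`/`combination`), `mean_sb`,
#' `mean_bfd`, plus optional rating columns.
#'
#' @param path CSV path.
#' @return data.frame (read) / invisibly `path` (write).
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "expertise", "condition",
            "mean_sb", "mean_bfd")
  if (!all(need %in% names(df)))
    stop("format error: cohort table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_cohort_table
#' @param records cohort data.frame.
#' @export
write_cohort_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full cohort analysis
#'
#' The evaluation pipeline on a cohort table: per-group within-participant
#' comparisons of the feedback condition against control (for `mean_sb` and
#' `mean_bfd`), baseline and improvement comparisons between the groups,
#' expertise homogeneity, and the nested expertise models for both
#' improvement outcomes.
#'
#' @param records cohort table (see [read_cohort_table()]).
#' @param condition feedback condition analysed (default `"combination"`).
#' @return list of class `cohort_analysis`.
#' @export
analyze_cohort <- function(records, condition = "combination") {
  imp <- improvements(records, condition)
  groups <- sort(unique(records$group))
  wide <- function(cond, var)
    records[records$condition == cond, c("participant_id", "group", var)]
  within <- list()
  for (g in groups) for (var in c("mean_sb", "mean_bfd")) {
    ctl <- wide("control", var); fb <- wide(condition, var)
    ids <- intersect(ctl$participant_id[ctl$group == g],
                     fb$participant_id[fb$group == g])
    within[[paste(g, var, sep = ".")]] <- compare_within(
      fb[[var]][match(ids, fb$participant_id)],
      ctl[[var]][match(ids, ctl$participant_id)])
  }
  between <- list()
  if (length(groups) == 2L) {
    g1 <- imp$group == groups[1L]
    for (var in c("delta_sb", "delta_bfd"))
      between[[var]] <- compare_between(imp[[var]][g1], imp[[var]][!g1])
    ctl <- wide("control", "mean_sb")
    between$baseline_sb <- compare_between(
      ctl$mean_sb[ctl$group == groups[1L]],
      ctl$mean_sb[ctl$group == groups[2L]])
  }
  homog <- NULL
  if (all(c("group", "expertise") %in% names(imp)) &&
      length(unique(imp$expertise)) > 1L)
    homog <- homogeneity_chisq(table(imp$group, imp$expertise))
  expertise <- list(
    delta_sb = try_or_null(fit_expertise_models(imp, "delta_sb")),
    delta_bfd = try_or_null(fit_expertise_models(imp, "delta_bfd"))
  )
  structure(list(condition = condition, improvements = imp,
                 within = within, between = between,
                 homogeneity = homog, expertise = expertise),
            class = "cohort_analysis")
}

try_or_null <- function(expr) tryCatch(expr, error = function(e) NULL)

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> feedback condition:", x$condition, "\n")
  cat("-- within-group (feedback vs control) --\n")
  for (nm in names(x$within)) { cat(nm, ": "); print(x$within[[nm]]) }
  cat("-- between-group --\n")
  for (nm in names(x$between)) { cat(nm, ": "); print(x$between[[nm]]) }
  if (!is.null(x$homogeneity)) {
    cat("-- expertise homogeneity --\n"); print(x$homogeneity)
  }
  for (nm in names(x$expertise)) if (!is.null(x$expertise[[nm]])) {
    cat("-- expertise models:", nm, "--\n")
    print(x$expertise[[nm]])
  }
  invisible(x)
}

#' Holm adjustment of a set of comparison results
#' @param results named list of `comparison_result`s.
#' @return the list with `p_adjusted` added to each element.
#' @export
adjust_holm <- function(results) {
  p <- vapply(results, function(r) r$p_value, numeric(1))
  pa <- stats::p.adjust(p, method = "holm")
  for (i in seq_along(results)) results[[i]]$p_adjusted <- pa[[i]]
  results
}
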