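test_that("count matrix is complete, zero-filled and conserving", {
  reg <- two_group_registry(cases = c("S1", "S3"), controls = "S2")
  ct <- categorize(cohort_table(rbind(
    clean_call(func = "synonymous"),
    clean_call(func = "synonymous", pos = 2000L),
    clean_call(func = "synonymous", pos = 3000L)), reg))
  cm <- count_by_sample_category(ct)
  expect_equal(sort(rownames(cm)), c("S1", "S2", "S3"))
  expect_equal(unname(cm["S1", "synonymous"]), 3L)
  expect_equal(unname(cm["S2", "synonymous"]), 0L)
  expect_equal(unname(cm["S1", "all"]), 3L)

  # brute-force per-sample recount on a larger random table
  ct <- categorize(random_cohort(n_calls = 500, seed = 3))
  cm <- count_by_sample_category(ct)
  for (cat in CATEGORIES)
    expect_equal(sum(cm[, cat]), sum(ct$calls$category == cat))
  for (s in sample(rownames(cm), 5))
    expect_equal(unname(cm[s, "all"]), sum(ct$calls$sample_id == s))
})

test_that("count matrix round-trips through TSV", {
  ct <- categorize(random_cohort(n_calls = 80, seed = 5))
  cm <- count_by_sample_category(ct)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path)
  expect_equal(unclass(back)[, ], unclass(cm)[, ], ignore_attr = TRUE)
  expect_equal(attr(back, "group"), attr(cm, "group"))
})

test_that("student t matches the closed-form reference to 1e-9", {
  ref_student <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
  }
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  got <- student_t(x, y)
  want <- ref_student(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(sample(3:30, 1), 5); y <- rpois(sample(3:30, 1), 5)
    if (var(x) + var(y) == 0) next
    got <- student_t(x, y); want <- ref_student(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("welch t matches Welch-Satterthwaite reference and bounds its df", {
  ref_welch <- function(x, y) {
    v1 <- var(x) / length(x); v2 <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
  }
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(sample(3:30, 1), 5); y <- rpois(sample(3:30, 1), 9)
    if (var(x) == 0 && var(y) == 0) next
    got <- welch_t(x, y); want <- ref_welch(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    expect_lte(got$df, length(x) + length(y) - 2 + 1e-12)
  }
  # equal variances and equal n: Welch t coincides with Student t
  x <- c(1, 2, 3, 4, 5); y <- c(3, 4, 5, 6, 7)
  expect_equal(welch_t(x, y)$t, student_t(x, y)$t, tolerance = 1e-12)
})

test_that("t tests honour symmetry, antisymmetry and degeneracy", {
  x <- c(3, 5, 2, 8, 1)
  expect_equal(student_t(x, x)$t, 0)
  expect_equal(student_t(x, x)$p, 1)
  expect_equal(welch_t(x, x)$t, 0)
  y <- c(4, 4, 6, 2, 9)
  expect_equal(student_t(x, y)$t, -student_t(y, x)$t)
  expect_equal(student_t(x, y)$p, student_t(y, x)$p)
  expect_error(student_t(c(2, 2, 2), c(2, 2, 2)), "degenerate")
  expect_error(welch_t(c(2, 2), c(3, 3)), "degenerate")
  expect_error(student_t(1, c(1, 2)), "at least two")
})

test_that("burden_report reproduces group means, ratio and both tests", {
  # spread known group totals over per-sample counts
  counts_from_totals <- function(total, n) {
    v <- integer(n)
    v[seq_len(total %% n)] <- 1L
    v + total %/% n
  }
  m <- cbind(nonsense = c(counts_from_totals(14L, 54L),
                          counts_from_totals(13L, 120L)))
  rownames(m) <- c(sprintf("BC%03d", 1:54), sprintf("CT%03d", 1:120))
  attr(m, "group") <- setNames(rep(c("case", "control"), c(54, 120)),
                               rownames(m))
  br <- burden_report(m)
  expect_equal(round(br$mean_case, 2), 0.26)
  expect_equal(round(br$mean_control, 2), 0.11)
  expect_equal(round(br$ratio, 2), 2.39)
  expect_equal(br$df_student, 54 + 120 - 2)
  expect_lte(br$df_welch, br$df_student)
  expect_true(br$p_student > 0 && br$p_student <= 1)
})

test_that("identical groups give unit ratios; label swap inverts them", {
  ct <- categorize(random_cohort(n_calls = 400, n_cases = 8,
                                 n_controls = 8, seed = 7))
  cm <- count_by_sample_category(ct)
  grp <- attr(cm, "group")
  # duplicate the case block as the control block -> identical groups
  cases <- names(grp)[grp == "case"]
  m2 <- rbind(cm[cases, ], cm[cases, ])
  rownames(m2) <- c(cases, paste0("copy_", cases))
  attr(m2, "group") <- setNames(rep(c("case", "control"),
                                    each = length(cases)), rownames(m2))
  br <- burden_report(m2)
  informative <- !is.na(br$ratio) & !is.na(br$p_student)
  expect_true(all(br$ratio[informative] == 1))
  expect_true(all(br$p_student[informative] == 1))

  swapped <- cm
  attr(swapped, "group") <- setNames(
    ifelse(grp == "case", "control", "case"), names(grp))
  a <- burden_report(cm); b <- burden_report(swapped)
  ok <- !is.na(a$ratio) & !is.na(b$ratio) & a$mean_case > 0
  expect_equal(b$ratio[ok], 1 / a$ratio[ok])
  ok <- !is.na(a$t_student)
  expect_equal(b$t_student[ok], -a$t_student[ok])
  expect_equal(b$p_student[ok], a$p_student[ok])

  tiny <- cm[1:3, , drop = FALSE]
  attr(tiny, "group") <- grp[rownames(tiny)]
  expect_error(burden_report(tiny), ">= 2 samples")
  expect_error(burden_report(unclass(cm[, ])), "group attribute")
})

test_that("student t p agrees with a permutation oracle within MC error", {
  set.seed(17)
  x <- rpois(30, 5); y <- rpois(30, 6)
  obs <- student_t(x, y)
  pool <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  tstat <- function(a, b) {
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  B <- 20000L
  gt <- 0L; tie <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(pool), n1)
    tb <- abs(tstat(pool[idx], pool[-idx]))
    if (tb > abs(obs$t) + 1e-9) gt <- gt + 1L
    else if (tb > abs(obs$t) - 1e-9) tie <- tie + 1L
  }
  # mid-p tie convention: count data tie heavily at the observed split
  p_perm <- (gt + 0.5 * tie) / B
  mc <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(obs$p - p_perm), 3 * mc)
})
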