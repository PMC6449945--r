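#' Per-sample, per-category retained-variant count matrix
#'
#' Builds the samples-by-categories count matrix the burden comparison
#' operates on. Every registered non-excluded sample gets a row (zero
#' when it retains no calls); columns are the fixed category order plus
#' a final `all` column equal to the row sum. Group labels travel with
#' the matrix as the `group` attribute.
#'
#' @param cohort a categorised [cohort_table]
#' @return integer matrix of class `count_matrix` with `group`
#'   attribute (named character vector over the row names)
#' @export
count_by_sample_category <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (nrow(cohort$calls) > 0 && is.null(cohort$calls$category))
    stop("calls are not categorised; run categorize() first")
  reg <- active_samples(cohort)
  calls <- cohort$calls
  unreg <- setdiff(unique(calls$sample_id), cohort$samples$sample_id)
  if (length(unreg))
    stop("calls from unregistered sample(s): ", toString(unreg))
  calls <- calls[calls$sample_id %in% reg$sample_id, , drop = FALSE]
  m <- table(factor(calls$sample_id, levels = reg$sample_id),
             factor(calls$category, levels = CATEGORIES))
  m <- matrix(as.integer(m), nrow = nrow(reg),
              dimnames = list(reg$sample_id, CATEGORIES))
  m <- cbind(m, all = as.integer(rowSums(m)))
  structure(m, group = stats::setNames(reg$group, reg$sample_id),
            class = c("count_matrix", class(m)))
}

#' Write / read a count matrix as TSV
#'
#' Samples in rows; first columns `sample_id` and `group`, then one
#' column per category plus `all`.
#'
#' @param cm a `count_matrix`
#' @param path file path
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(sample_id = rownames(cm),
                   group = unname(attr(cm, "group")[rownames(cm)]),
                   as.data.frame(unclass(cm)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")),
                    drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$sample_id
  structure(m, group = stats::setNames(df$group, df$sample_id),
            class = c("count_matrix", class(m)))
}

#' Two-sample t-tests on per-sample counts
#'
#' `student_t()` is the classical equal-variance two-sample t-test
#' (degrees of freedom `n1 + n2 - 2`); `welch_t()` the unequal-variance
#' form with Welch-Satterthwaite degrees of freedom. Both are two-sided
#' and delegate to [stats::t.test()].
#'
#' @param x,y numeric vectors of per-sample counts, each of length >= 2
#' @return list with elements `t`, `df`, `p`
#' @examples
#' student_t(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
student_t <- function(x, y) {
  check_t_input(x, y)
  n1 <- length(x); n2 <- length(y)
  pooled <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (pooled <= 0) stop("degenerate samples: zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' @rdname student_t
#' @export
welch_t <- function(x, y) {
  check_t_input(x, y)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate samples: both variances zero")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

check_t_input <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two observations per group")
  if (anyNA(x) || anyNA(y)) stop("NA in count vector")
}

#' Case-control burden comparison per variant category
#'
#' For each category (and the `all` total) reports the per-sample group
#' means (group total / group size), the case/control fold-change
#' ratio, and both Student and Welch two-sided t-tests. No selection
#' between the two tests is made and no multiple-testing correction is
#' applied; `n_categories_tested` is attached so users can correct
#' downstream. Degenerate categories (zero variance in both groups)
#' carry `NA` test fields; the ratio is `NA` when the control mean is 0.
#'
#' @param cm a `count_matrix` from [count_by_sample_category()], or any
#'   integer matrix with a `group` attribute; both groups need >= 2
#'   samples
#' @return data.frame of class `burden_result`: one row per category
#'   with `category`, `n_case`, `n_control`, `total_case`,
#'   `total_control`, `mean_case`, `mean_control`, `ratio`,
#'   `t_student`, `df_student`, `p_student`, `t_welch`, `df_welch`,
#'   `p_welch`. Means and ratios are full precision; rounding is left
#'   to presentation (see `print.burden_result`).
#' @export
burden_report <- function(cm) {
  grp <- attr(cm, "group")
  if (is.null(grp)) stop("count matrix lacks a group attribute")
  grp <- grp[rownames(cm)]
  n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
  if (n1 < 2 || n2 < 2)
    stop(sprintf("need >= 2 samples per group (have %d case, %d control)",
                 n1, n2))
  rows <- lapply(colnames(cm), function(cat) {
    x <- cm[grp == "case", cat]
    y <- cm[grp == "control", cat]
    st <- tryCatch(student_t(x, y), error = function(e) NULL)
    we <- tryCatch(welch_t(x, y), error = function(e) NULL)
    if (is.null(st)) st <- list(t = NA_real_, df = NA_real_, p = NA_real_)
    if (is.null(we)) we <- list(t = NA_real_, df = NA_real_, p = NA_real_)
    mean_case <- sum(x) / n1
    mean_control <- sum(y) / n2
    data.frame(category = cat, n_case = n1, n_control = n2,
               total_case = sum(x), total_control = sum(y),
               mean_case = mean_case, mean_control = mean_control,
               ratio = ifelse(mean_control > 0,
                              mean_case / mean_control, NA_real_),
               t_student = st$t, df_student = st$df, p_student = st$p,
               t_welch = we$t, df_welch = we$df, p_welch = we$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_categories_tested") <- nrow(out)
  class(out) <- c("burden_result", "data.frame")
  out
}

#' @export
print.burden_result <- function(x, digits_mean = 2, digits_p = 4, ...) {
  need <- c("category", "mean_case", "mean_control", "ratio",
            "p_student", "p_welch")
  if (!all(need %in% names(x))) {
    print(as.data.frame(x), ...)
    return(invisible(x))
  }
  df <- data.frame(category = x$category,
                   mean_case = round(x$mean_case, digits_mean),
                   mean_control = round(x$mean_control, digits_mean),
                   ratio = round(x$ratio, digits_mean),
                   p_student = round(x$p_student, digits_p),
                   p_welch = round(x$p_welch, digits_p))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname burden_report
#' @param br a `burden_result`
#' @param path file path
#' @export
write_burden <- function(br, path) {
  utils::write.table(as.data.frame(br), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
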