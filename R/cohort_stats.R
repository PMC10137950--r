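# Cohort-level statistics: sex comparisons by Student's t-test, Pearson
# correlations between radiographic and 3D parameters, and intraclass
# correlation for rating reliability.

#' Two-group comparison of a cohort column
#'
#' Independent two-sample t-test of `column` between the levels of `group`
#' (pooled-variance Student's test by default; set `var_equal = FALSE` for
#' Welch).
#'
#' @param data A data frame.
#' @param column Name of the numeric column to compare.
#' @param group Name of the two-level grouping column (default `"sex"`).
#' @param var_equal Pooled-variance (Student) if `TRUE`, Welch otherwise.
#' @return A one-row [tibble::tibble()] with group means/SDs, `t`, `df` and
#'   `p_value`.
#' @export
group_compare <- function(data, column, group = "sex", var_equal = TRUE) {
  x <- data[[column]]
  g <- data[[group]]
  if (is.null(x) || is.null(g)) stop("column or group not found", call. = FALSE)
  lev <- unique(g)
  if (length(lev) != 2L || any(table(g) < 2L)) {
    stop("grouping must yield exactly two groups with >= 2 observations",
         call. = FALSE)
  }
  x1 <- x[g == lev[1L]]
  x2 <- x[g == lev[2L]]
  ht <- stats::t.test(x1, x2, var.equal = var_equal)
  tibble::tibble(
    column = column, group1 = as.character(lev[1L]), group2 = as.character(lev[2L]),
    n1 = length(x1), n2 = length(x2),
    mean1 = mean(x1), mean2 = mean(x2),
    sd1 = stats::sd(x1), sd2 = stats::sd(x2),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    method = if (var_equal) "student" else "welch"
  )
}

#' Pearson correlation between two cohort columns
#'
#' Pearson product-moment correlation with the two-sided p-value from the t
#' transform.
#'
#' @param data A data frame.
#' @param x,y Names of the numeric columns.
#' @return A one-row [tibble::tibble()] with `r`, `t`, `df`, `p_value`.
#' @export
correlate <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (is.null(xv) || is.null(yv)) stop("column not found", call. = FALSE)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) stop("correlation needs >= 3 paired observations", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation is degenerate: zero variance", call. = FALSE)
  }
  ht <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(x = x, y = y, n = length(xv), r = unname(ht$estimate),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Intraclass correlation coefficient
#'
#' Single-measure ICC from a subjects-by-raters rating matrix, computed from
#' the two-way ANOVA mean squares. `"ICC2"` (default) is the two-way random,
#' absolute-agreement, single-measure form ICC(2,1); `"ICC1"` the one-way
#' random form; `"ICC3"` the two-way mixed, consistency form.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters (or
#'   sessions) in columns; >= 5 subjects, >= 2 raters.
#' @param model `"ICC2"`, `"ICC1"` or `"ICC3"`.
#' @return A one-row [tibble::tibble()] with `icc`, the mean squares and the
#'   design size.
#' @export
icc <- function(ratings, model = c("ICC2", "ICC1", "ICC3")) {
  model <- match.arg(model)
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("ratings contain missing values", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5L || k < 2L) {
    stop("ICC needs >= 5 subjects and >= 2 raters", call. = FALSE)
  }
  if (stats::sd(as.vector(m)) == 0) {
    stop("ICC is degenerate: constant ratings", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  msw <- sum(sweep(m, 1L, row_m)^2) / (n * (k - 1))
  val <- switch(model,
    ICC1 = (msr - msw) / (msr + (k - 1) * msw),
    ICC2 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    ICC3 = (msr - mse) / (msr + (k - 1) * mse)
  )
  tibble::tibble(model = model, icc = val, msr = msr, msc = msc, mse = mse,
                 msw = msw, n_subjects = n, n_raters = k)
}

#' Cohort statistics report
#'
#' Reproduces the study's statistical analyses on a cohort measurement
#' table: sex-stratified means and SDs, Student's t-tests between sexes for
#' each offset parameter, the independent comparison of the 3D femoral and
#' cup offsets, and the Pearson correlations among the radiographic and 3D
#' parameters.
#'
#' @param data A [measure_cohort()] table (or any data frame with the same
#'   columns).
#' @param group Two-level grouping column (default `"sex"`).
#' @param compare_cols Columns compared between groups.
#' @param corr_pairs List of `c(x, y)` column-name pairs to correlate.
#' @param var_equal Student (pooled) or Welch t-tests.
#' @return An object of class `hip_cohort_stats` with [tidy()][tidy.hip_cohort_stats],
#'   [glance()][glance.hip_cohort_stats] and `autoplot()` methods.
#' @export
cohort_stats <- function(data, group = "sex",
                         compare_cols = c("ce_angle", "go2d", "ao2d", "fo2d",
                                          "fo3d", "cup_offset3d",
                                          "cup_femoral_diff", "dist_cup_head",
                                          "angle_cup_head", "femoral_anteversion"),
                         corr_pairs = list(c("fo3d", "cup_offset3d"),
                                           c("fo3d", "body_length"),
                                           c("fo2d", "fo3d"),
                                           c("fo_diff_3d_2d", "femoral_anteversion"),
                                           c("cup_femoral_diff", "ao2d"),
                                           c("cup_femoral_diff", "go2d"),
                                           c("cup_femoral_diff", "ce_angle")),
                         var_equal = TRUE) {
  compare_cols <- intersect(compare_cols, names(data))
  corr_pairs <- purrr::keep(corr_pairs, ~ all(.x %in% names(data)))

  summary_tbl <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(compare_cols),
                                   list(mean = mean, sd = stats::sd)),
                     n = dplyr::n(), .groups = "drop")

  # group tests are omitted (not failed) when a group is too small
  ttests <- purrr::map(compare_cols, function(cl) {
    tryCatch(group_compare(data, cl, group, var_equal = var_equal),
             error = function(e) NULL)
  }) |>
    dplyr::bind_rows()

  offset_cmp <- NULL
  if (all(c("fo3d", "cup_offset3d") %in% names(data))) {
    ht <- stats::t.test(data$cup_offset3d, data$fo3d, var.equal = var_equal)
    offset_cmp <- tibble::tibble(
      comparison = "cup_offset3d vs fo3d",
      mean_cup = mean(data$cup_offset3d), mean_fo = mean(data$fo3d),
      mean_diff = mean(data$cup_offset3d) - mean(data$fo3d),
      t = unname(ht$statistic), df = unname(ht$parameter), p_value = ht$p.value)
  }

  correlations <- purrr::map(corr_pairs, \(pr) correlate(data, pr[1], pr[2])) |>
    dplyr::bind_rows()

  structure(list(data = tibble::as_tibble(data), group = group,
                 summary = summary_tbl, ttests = ttests,
                 offset_comparison = offset_cmp,
                 correlations = correlations),
            class = "hip_cohort_stats")
}

#' @export
print.hip_cohort_stats <- function(x, ...) {
  cat(sprintf("<hip_cohort_stats> %d hips\n", nrow(x$data)))
  if (!is.null(x$offset_comparison)) {
    oc <- x$offset_comparison
    cat(sprintf("  mean 3D FO %.1f mm, mean 3D cup offset %.1f mm (diff %.1f mm, p = %.3g)\n",
                oc$mean_fo, oc$mean_cup, oc$mean_diff, oc$p_value))
  }
  if (nrow(x$correlations)) {
    cat("  correlations:\n")
    for (i in seq_len(nrow(x$correlations))) {
      cr <- x$correlations[i, ]
      cat(sprintf("    r(%s, %s) = %.3f (p = %.3g)\n", cr$x, cr$y, cr$r, cr$p_value))
    }
  }
  invisible(x)
}

#' Tidy a cohort statistics report
#'
#' @param x A [cohort_stats()] object.
#' @param ... Unused.
#' @return A [tibble::tibble()] stacking the t-tests and correlations with a
#'   `type` column.
#' @export
tidy.hip_cohort_stats <- function(x, ...) {
  tt <- x$ttests |>
    dplyr::transmute(type = "t_test", term = .data$column,
                     estimate = .data$mean1 - .data$mean2,
                     statistic = .data$t, df = .data$df, p_value = .data$p_value)
  cr <- x$correlations |>
    dplyr::transmute(type = "correlation",
                     term = paste(.data$x, .data$y, sep = ":"),
                     estimate = .data$r, statistic = .data$t, df = .data$df,
                     p_value = .data$p_value)
  dplyr::bind_rows(tt, cr)
}

#' One-row summary of a cohort statistics report
#'
#' @inheritParams tidy.hip_cohort_stats
#' @return A one-row [tibble::tibble()] with the cohort size, mean 3D
#'   femoral and cup offsets, their difference, and the femoral/cup offset
#'   correlation.
#' @export
glance.hip_cohort_stats <- function(x, ...) {
  r_fc <- x$correlations[x$correlations$x == "fo3d" &
                           x$correlations$y == "cup_offset3d", ]
  tibble::tibble(
    n = nrow(x$data),
    mean_fo3d = if (!is.null(x$offset_comparison)) x$offset_comparison$mean_fo else NA_real_,
    mean_cup_offset3d = if (!is.null(x$offset_comparison)) x$offset_comparison$mean_cup else NA_real_,
    mean_cup_femoral_diff = if (!is.null(x$offset_comparison)) x$offset_comparison$mean_diff else NA_real_,
    r_fo_cup = if (nrow(r_fc)) r_fc$r else NA_real_,
    p_fo_cup = if (nrow(r_fc)) r_fc$p_value else NA_real_
  )
}

#' Generic tidy (broom-style)
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic glance (broom-style)
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
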