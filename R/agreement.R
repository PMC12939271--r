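#' Intraclass correlation coefficient from a two-way ANOVA decomposition
#'
#' Single-measures ICC for a complete `n x k` ratings table (n subjects,
#' k raters), computed from the two-way ANOVA mean squares: `MSR` between
#' subjects, `MSC` between raters, `MSE` residual. Two forms are provided:
#'
#' * `two_way_random_2_1` — ICC(2,1), two-way random effects, absolute
#'   agreement: `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'   Appropriate for interchangeable human raters.
#' * `two_way_mixed_3_1` — ICC(3,1), two-way mixed effects, consistency:
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`. Appropriate when one method is
#'   fixed, e.g. comparing an automated measurement against a manual
#'   reference.
#'
#' 95% confidence intervals use the exact F-distribution method
#' (McGraw & Wong). Estimates are labelled with the conventional
#' interpretation bands: below 0.50 poor, 0.50--0.75 moderate, above 0.75
#' up to 0.90 good, above 0.90 excellent.
#'
#' @param table Numeric matrix or data frame, subjects in rows, raters in
#'   columns; complete (no missing cells), `n >= 2`, `k >= 2`.
#' @param model `"two_way_random_2_1"` or `"two_way_mixed_3_1"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An `icc_result`: list with `icc`, `model`, `ci_low`, `ci_high`,
#'   `interpretation`, `msr`, `msc`, `mse`, `n`, `k`.
#' @examples
#' x <- cbind(r1 = c(9, 6, 8, 5), r2 = c(9.2, 6.1, 7.9, 5.3))
#' icc(x, "two_way_mixed_3_1")
#' @export
icc <- function(table, model = c("two_way_random_2_1", "two_way_mixed_3_1"),
                conf_level = 0.95) {
  model <- match.arg(model)
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("ratings must be numeric")
  if (anyNA(x)) stop("ratings table must be complete (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")

  m <- mean(x)
  ri <- rowMeans(x)
  cj <- colMeans(x)
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  mse <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + m)^2) /
    ((n - 1) * (k - 1))

  if (msr + msc + mse < 1e-15 * max(1, m^2)) {
    warning("zero total variance: all ratings identical; ICC reported as 1")
    return(new_icc_result(1, model, 1, 1, msr, msc, mse, n, k))
  }

  alpha <- 1 - conf_level
  if (model == "two_way_mixed_3_1") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      ci <- c(1, 1)
    } else {
      f <- msr / mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      fl <- f / stats::qf(1 - alpha / 2, df1, df2)
      fu <- f * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse <= 0 && msc <= 0) {
      ci <- c(1, 1)
    } else {
      # McGraw & Wong A,1 interval with Satterthwaite df
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(lo, hi)
    }
  }
  new_icc_result(est, model, min(ci[1], est), max(ci[2], est),
                 msr, msc, mse, n, k)
}

new_icc_result <- function(est, model, lo, hi, msr, msc, mse, n, k) {
  structure(list(icc = est, model = model, ci_low = lo, ci_high = hi,
                 interpretation = icc_interpret(est),
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' Interpretation band for an ICC estimate
#'
#' Below 0.50 poor; 0.50 to 0.75 moderate; above 0.75 up to and including
#' 0.90 good; above 0.90 excellent (band boundaries belong to the lower
#' band).
#'
#' @param icc ICC estimate(s).
#' @return Character vector of band labels.
#' @export
icc_interpret <- function(icc) {
  ifelse(icc < 0.50, "poor",
         ifelse(icc <= 0.75, "moderate",
                ifelse(icc <= 0.90, "good", "excellent")))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC [%s] = %.3f (95%% CI %.3f to %.3f): %s agreement\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$interpretation))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity by two methods, computes the
#' mean difference (bias), the sample standard deviation of the differences
#' (`n - 1` denominator), and the 95% limits of agreement
#' `bias +/- 1.96 * sd`. Proportional bias is assessed by ordinary least
#' squares of the differences on the pair means (slope and its two-sided
#' t-test p-value).
#'
#' @param a,b Numeric vectors of paired measurements (degrees); differences
#'   are `a - b`. At least 3 pairs.
#' @return A `bland_altman` object: list with `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `proportional_bias_slope`, `proportional_bias_p`, `n`, and
#'   the per-pair `diffs` and `means` for plotting.
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4), c(0.9, 2.2, 2.8, 4.1))
#' ba$loa_high - ba$bias   # 1.96 * sd of differences
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  slope <- NA_real_; pval <- NA_real_
  if (stats::var(m) > 0 && sdd > 0) {
    fit <- summary(stats::lm(d ~ m))
    slope <- fit$coefficients[2, 1]
    pval <- fit$coefficients[2, 4]
  }
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 proportional_bias_slope = slope,
                 proportional_bias_p = pval,
                 n = n, diffs = d, means = m),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.2f, 95%% LoA [%.2f, %.2f]\n",
    x$n, x$bias, x$loa_low, x$loa_high))
  if (!is.na(x$proportional_bias_p)) {
    cat(sprintf("proportional bias: slope %.3f (p = %.3g)\n",
                x$proportional_bias_slope, x$proportional_bias_p))
  }
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means with horizontal lines at the bias and the
#' 95% limits of agreement.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  df <- data.frame(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (degrees)",
                  y = "Difference between methods (degrees)") +
    ggplot2::theme_minimal()
}

#' Dice similarity coefficient
#'
#' Overlap between two binary masks: `2 |A intersect B| / (|A| + |B|)`.
#' Two empty masks agree vacuously and return 1 with a warning.
#'
#' @param mask_a,mask_b Logical or 0/1 matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shape mismatch")
  a <- mask_a != 0
  b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

#' Grouped agreement between two sets of angulation records
#'
#' Matches records on `(image_id, fdi_code)` (unmatched records are dropped
#' with a message) and summarizes agreement per group: mean absolute error
#' and ICC(3,1) on the paired values.
#'
#' @param ai,ref Tibbles of angulation records (see [measure_image()]);
#'   `ref` is the reference method.
#' @param grouping `"tooth_type"`, `"arch"`, or `"side"`.
#' @param value_col Column compared, default `"angle_deg"`; use
#'   `"angle_abs_deg"` for unsigned comparison.
#' @return Tibble with columns `group`, `mae`, `icc`, `n`.
#' @export
grouped_errors <- function(ai, ref, grouping = c("tooth_type", "arch", "side"),
                           value_col = "angle_deg") {
  grouping <- match.arg(grouping)
  mm <- match_records(ai, ref, value_col)
  grp <- mm$meta[[grouping]]
  out <- lapply(split(seq_len(nrow(mm)), grp), function(i) {
    if (length(i) == 0) return(NULL)
    pair <- cbind(mm$a[i], mm$b[i])
    val <- if (length(i) >= 2) icc(pair, "two_way_mixed_3_1")$icc else NA_real_
    tibble::tibble(group = grp[i][1],
                   mae = mean(abs(mm$a[i] - mm$b[i])),
                   icc = val,
                   n = length(i))
  })
  dplyr::bind_rows(out)
}

# pairwise match on (image_id, fdi_code); returns data frame with a, b and
# the descriptor columns of `ai`
match_records <- function(ai, ref, value_col = "angle_deg") {
  key_a <- paste(ai$image_id, ai$fdi_code)
  key_b <- paste(ref$image_id, ref$fdi_code)
  i <- match(key_a, key_b)
  drop_a <- sum(is.na(i))
  drop_b <- nrow(ref) - sum(!is.na(i))
  if (drop_a > 0 || drop_b > 0) {
    message(sprintf("dropped unmatched records: %d from ai, %d from ref",
                    drop_a, drop_b))
  }
  keep <- !is.na(i)
  if (!any(keep)) stop("no matched records")
  out <- data.frame(a = ai[[value_col]][keep],
                    b = ref[[value_col]][i[keep]])
  out$meta <- ai[keep, intersect(c("tooth_type", "arch", "side"), names(ai))]
  ok <- !is.na(out$a) & !is.na(out$b)
  out[ok, , drop = FALSE]
}

#' Repeat-acquisition sensitivity summary
#'
#' Summarizes absolute tooth-wise differences between angulation
#' measurements from two acquisitions of the same individuals (records
#' matched on `(image_id, fdi_code)`, where `image_id` identifies the
#' patient): mean, empirical 95th percentile, maximum, and the fractions of
#' teeth differing by more than 1 and 2 degrees. This quantifies the
#' measurement variability attributable to head positioning and projection
#' geometry rather than to the algorithm itself.
#'
#' @param run1,run2 Tibbles of angulation records.
#' @param value_col Column compared, default `"angle_deg"`.
#' @return A `sensitivity_report`: list with `mean_abs_diff`,
#'   `p95_abs_diff`, `max_abs_diff`, `frac_gt_1deg`, `frac_gt_2deg`,
#'   `n_teeth`.
#' @export
repeat_sensitivity <- function(run1, run2, value_col = "angle_deg") {
  mm <- match_records(run1, run2, value_col)
  d <- abs(mm$a - mm$b)
  if (length(d) == 0) stop("no matched teeth")
  structure(list(
    mean_abs_diff = mean(d),
    p95_abs_diff = as.numeric(stats::quantile(d, 0.95)),
    max_abs_diff = max(d),
    frac_gt_1deg = mean(d > 1),
    frac_gt_2deg = mean(d > 2),
    n_teeth = length(d)
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    paste0("Repeat-acquisition sensitivity (n = %d teeth):\n",
           "  mean |diff| %.2f deg, 95th pct %.2f deg, max %.2f deg\n",
           "  > 1 deg: %.0f%%   > 2 deg: %.0f%%\n"),
    x$n_teeth, x$mean_abs_diff, x$p95_abs_diff, x$max_abs_diff,
    100 * x$frac_gt_1deg, 100 * x$frac_gt_2deg))
  invisible(x)
}

#' Screening/exclusion accounting
#'
#' Subtracts per-reason exclusion counts from the number of collected
#' images and returns the number remaining. Errors if any count is
#' negative or the exclusions exceed the collected total.
#'
#' @param collected Non-negative integer: images collected before screening.
#' @param exclusion_counts Numeric vector of per-reason counts (optionally
#'   named), or a data frame with a `count` column.
#' @return Integer: images remaining after exclusion.
#' @examples
#' scr <- example_screening_counts()
#' exclusion_accounting(scr$collected, scr$exclusions)  # 214
#' @export
exclusion_accounting <- function(collected, exclusion_counts) {
  if (is.data.frame(exclusion_counts)) {
    exclusion_counts <- exclusion_counts$count
  }
  if (length(exclusion_counts) == 0) return(as.integer(collected))
  if (any(exclusion_counts < 0)) stop("exclusion counts must be non-negative")
  remaining <- collected - sum(exclusion_counts)
  if (remaining < 0) {
    stop("exclusion counts (", sum(exclusion_counts),
         ") exceed collected total (", collected, ")")
  }
  as.integer(remaining)
}

#' Worked example: screening a panoramic radiograph archive
#'
#' A bundled example of retrospective archive screening for a root
#' angulation study: 7751 collected panoramic radiographs and the nine
#' exclusion reasons (primary/mixed dentition, retained primary teeth,
#' impacted teeth other than third molars, missing teeth, severe caries
#' obscuring the long axis, pathologic lesions, dental anomalies of number
#' or morphology, syndromes affecting the dentition, imaging artifacts),
#' leaving 214 images of natural complete permanent dentition.
#'
#' @return List with `collected` (integer) and `exclusions` (tibble with
#'   `reason`, `count`).
#' @export
example_screening_counts <- function() {
  list(
    collected = 7751L,
    exclusions = tibble::tibble(
      reason = c(
        "primary or mixed dentition",
        "retained primary teeth",
        "impacted teeth (except third molars)",
        "missing teeth (one or more)",
        "severe caries preventing long-axis determination",
        "pathologic lesions affecting root position",
        "dental anomalies of tooth number or morphology",
        "syndromes affecting the dentition",
        "imaging artifacts"),
      count = c(3187L, 165L, 539L, 2674L, 81L, 253L, 181L, 4L, 453L)
    )
  )
}

#' Full agreement report between two record sets
#'
#' Convenience wrapper producing the complete validation summary for a pair
#' of angulation record sets: global ICC(3,1), Bland-Altman, and grouped
#' errors by tooth type, arch and side.
#'
#' @param ai,ref Tibbles of angulation records; `ref` is the reference.
#' @param absolute Compare unsigned angles (`angle_abs_deg`) instead of
#'   signed ones.
#' @return List with elements `icc`, `bland_altman`, `by_tooth_type`,
#'   `by_arch`, `by_side`, `n_pairs`.
#' @export
agreement_report <- function(ai, ref, absolute = FALSE) {
  value_col <- if (absolute) "angle_abs_deg" else "angle_deg"
  mm <- match_records(ai, ref, value_col)
  ic <- icc(cbind(mm$a, mm$b), "two_way_mixed_3_1")
  ba <- bland_altman(mm$a, mm$b)
  list(
    icc = ic,
    bland_altman = ba,
    by_tooth_type = grouped_errors(ai, ref, "tooth_type", value_col),
    by_arch = grouped_errors(ai, ref, "arch", value_col),
    by_side = grouped_errors(ai, ref, "side", value_col),
    n_pairs = nrow(mm)
  )
}
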