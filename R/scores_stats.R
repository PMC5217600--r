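# NSS scoring and group statistics: mean +/- SEM, t tests, percent
# differences, per-timepoint series comparison.

validate_nss <- function(records) {
  caps <- nss_category_maxima
  need <- names(caps)
  if (!all(need %in% names(records)))
    stop("NSS records need columns: ", paste(need, collapse = ", "))
  for (cat_i in need) {
    v <- records[[cat_i]]
    if (any(v < 0 | v > caps[[cat_i]] | v != round(v)))
      stop("NSS category '", cat_i, "' out of range 0..", caps[[cat_i]])
  }
  invisible(records)
}

#' Total NSS score for one animal
#'
#' Sums the four category scores per record (examiner x trial) and
#' averages the totals, matching the convention of reporting each rat as
#' the mean over examiners and trials.  Totals are bounded in [0, 18].
#'
#' @param records data.frame of NSS records for a single rat (columns
#'   motor, sensory, beam, reflex; see [make_nss_cohort()]).
#' @return mean total score.
#' @export
nss_total <- function(records) {
  if (nrow(records) < 1) stop("no NSS records supplied")
  validate_nss(records)
  mean(records$motor + records$sensory + records$beam + records$reflex)
}

#' Group summary: mean and standard error of the mean
#'
#' @param values numeric vector, n >= 2.
#' @return list with `mean`, `sem` (sample sd / sqrt(n)) and `n`.
#' @export
group_summary <- function(values) {
  n <- length(values)
  if (n < 2) stop("group summary needs n >= 2")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Two-sample t test between groups
#'
#' Two-sided two-sample t test, Welch (unequal variance) by default with a
#' pooled-variance option.  Degenerate inputs follow fixed conventions:
#' both groups constant with equal means gives t = 0, p = 1; both constant
#' with different means gives |t| = Inf, p = 0.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal use the pooled-variance statistic (default FALSE).
#' @param alpha significance level for the `significant` flag.
#' @return a `group_comparison`: means, SEMs, `t_stat`, `df`, `p_value`,
#'   `significant`, `percent_diff` (a vs b), `method`.
#' @export
ttest_groups <- function(a, b, var_equal = FALSE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  sa <- group_summary(a); sb <- group_summary(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (sa$mean == sb$mean) { tt <- 0; pv <- 1; df <- NA_real_ }
    else { tt <- sign(sa$mean - sb$mean) * Inf; pv <- 0; df <- NA_real_ }
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    tt <- unname(ht$statistic); pv <- ht$p.value
    df <- unname(ht$parameter)
  }
  structure(list(mean_a = sa$mean, mean_b = sb$mean,
                 sem_a = sa$sem, sem_b = sb$sem,
                 n_a = sa$n, n_b = sb$n,
                 t_stat = tt, df = df, p_value = pv,
                 significant = pv < alpha, alpha = alpha,
                 percent_diff = if (sb$mean > 0)
                   round(100 * (sa$mean - sb$mean) / sb$mean, 1)
                 else NA_real_,
                 method = if (var_equal) "pooled t" else "Welch t"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<group_comparison> %s\n",
           "  a: %.3f +/- %.3f (n = %d)   b: %.3f +/- %.3f (n = %d)\n",
           "  t = %.4f, p = %.4g%s\n"),
    x$method, x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
    x$t_stat, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Relative difference between group means, in percent
#'
#' `100 * (mean_a - mean_b) / mean_b`, reported to one decimal: the
#' convention that reproduces published between-group percentages with the
#' anesthetic group as denominator.
#'
#' @param mean_a,mean_b group means; `mean_b` must be positive.
#' @return percent difference rounded to 1 decimal.
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (!is.finite(mean_b) || mean_b <= 0)
    stop("denominator mean must be positive")
  round(100 * (mean_a - mean_b) / mean_b, 1)
}

#' Per-timepoint comparison of area time series between groups
#'
#' Runs one two-sample t test per time bin across the per-animal area
#' series of two groups.  No multiple-testing correction is applied by
#' default (each bin is reported as tested); a Bonferroni toggle is
#' provided.
#'
#' @param group_a,group_b lists of `area_series` (one per animal) with
#'   identical time axes.
#' @param var_equal pooled-variance t test if TRUE.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame (time_min, mean_a, mean_b, t, p, p_adj, significant).
#' @export
timepoint_comparison <- function(group_a, group_b, var_equal = FALSE,
                                 alpha = 0.05,
                                 adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  times <- group_a[[1]]$times
  grab <- function(gr) {
    m <- vapply(gr, function(s) {
      if (!identical(s$times, times))
        stop("area series have misaligned time axes")
      s$areas
    }, numeric(length(times)))
    matrix(m, nrow = length(times))
  }
  ma <- grab(group_a); mb <- grab(group_b)
  res <- lapply(seq_along(times), function(i)
    ttest_groups(ma[i, ], mb[i, ], var_equal = var_equal, alpha = alpha))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  p_adj <- stats::p.adjust(p, method = adjust)
  data.frame(time_min = times,
             mean_a = vapply(res, `[[`, numeric(1), "mean_a"),
             mean_b = vapply(res, `[[`, numeric(1), "mean_b"),
             t = vapply(res, `[[`, numeric(1), "t_stat"),
             p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}
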