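#' Pearson correlation between paired observer measurements
#'
#' Thin, validated wrapper around the sample Pearson correlation, used to
#' quantify inter-observer reproducibility of tracheal measurements.
#'
#' @param x,y numeric vectors of paired measurements (same length, n >= 3).
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("pearson_r requires at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean difference x - y), its 95% confidence interval
#' (t-based CI of the mean difference), and the classical 95% limits of
#' agreement (bias +/- 1.96 sd of the differences). Both intervals are
#' reported because Bland-Altman convention varies: narrow printed
#' intervals around a bias are CIs of the mean, while limits of agreement
#' describe the spread of individual differences.
#'
#' @param x,y numeric vectors of paired measurements (n >= 3).
#' @return An object of class `agreement_stats`: list with `r`, `bias`,
#'   `bias_ci_low`, `bias_ci_high`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("bland_altman requires at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  half_ci <- stats::qt(0.975, df = n - 1) * sdd / sqrt(n)
  res <- list(
    r = if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_,
    bias = bias,
    bias_ci_low = bias - half_ci,
    bias_ci_high = bias + half_ci,
    loa_low = bias - 1.96 * sdd,
    loa_high = bias + 1.96 * sdd,
    sd_diff = sdd,
    n = n
  )
  class(res) <- "agreement_stats"
  res
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement (n = %d): r = %.4f\n", x$n, x$r))
  cat(sprintf("  bias %.4g  95%% CI [%.4g, %.4g]\n",
              x$bias, x$bias_ci_low, x$bias_ci_high))
  cat(sprintf("  95%% limits of agreement [%.4g, %.4g]\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' @param x,y paired numeric vectors.
#' @return list with `t`, `p`, `df`, `mean_diff`, and `degenerate` flag
#'   (TRUE when the differences have zero variance but nonzero mean, in
#'   which case `t`/`p` are NA; zero variance with zero mean yields p = 1
#'   by convention).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(t = 0, p = 1, df = n - 1, mean_diff = 0, degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = n - 1, mean_diff = md,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter),
       mean_diff = md, degenerate = FALSE)
}

#' Significance stars
#'
#' Annotation convention: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p p-value.
#' @return character star annotation.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Per-group summaries and all pairwise between-group comparisons
#'
#' Summarises each metric as mean and SD per group and runs all pairwise
#' between-group comparisons. Groups are distinct animals, so the
#' comparison is an unpaired two-sample Welch t-test; stars follow the
#' usual four-threshold convention (see [significance_stars()]).
#'
#' @param results data.frame with a `group` column and one numeric column
#'   per metric.
#' @param metrics character vector of metric column names.
#' @return list with `summary` (group x metric means/SDs/n) and `pairwise`
#'   (one row per group pair per metric with t, p, stars) data.frames.
#' @export
group_table <- function(results, metrics) {
  stopifnot(is.data.frame(results), "group" %in% names(results),
            all(metrics %in% names(results)))
  groups <- sort(unique(as.character(results$group)))
  if (length(groups) < 2) stop("need at least two groups")
  counts <- table(results$group)
  if (any(counts < 2)) stop("every group needs n >= 2")

  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- results[results$group == g, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(group = g, metric = m, n = nrow(sub),
                 mean = mean(sub[[m]]), sd = stats::sd(sub[[m]]),
                 stringsAsFactors = FALSE)
    }))
  }))

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      xa <- results[results$group == pr[1], m]
      xb <- results[results$group == pr[2], m]
      ht <- stats::t.test(xa, xb, var.equal = FALSE)
      data.frame(metric = m, group1 = pr[1], group2 = pr[2],
                 t = unname(ht$statistic), p = ht$p.value,
                 stars = significance_stars(ht$p.value),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- rownames(pw) <- NULL
  list(summary = summ, pairwise = pw)
}
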