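#' Paired comparison of metric runs with normality gating
#'
#' For each metric, the paired differences between the two run sets are
#' tested for normality (Shapiro-Wilk at 0.05); normal differences take a
#' paired two-tailed t test, non-normal a Wilcoxon signed-rank test.
#' P values receive a Bonferroni correction across the metric family.
#' Zero-variance differences — which do occur when runs converge to
#' identical metric values — make both tests undefined: those metrics are
#' flagged `degenerate` and reported at sign level only. Inputs must share
#' run identifiers; unpaired runs are refused.
#'
#' @param runs_a,runs_b Data frames with a `run_id` column and one column
#'   per metric, one row per run.
#' @param metrics Metric columns to compare (default: all shared,
#'   non-`run_id` columns).
#' @param alpha Significance level (default 0.05).
#' @param family_size Bonferroni family size (default: number of metrics
#'   compared).
#' @return `data.table(metric, mean_diff, test, shapiro_p, p, p_bonferroni,
#'   significant)`.
#' @export
paired_compare <- function(runs_a, runs_b, metrics = NULL, alpha = 0.05,
                           family_size = NULL) {
  a <- data.table::as.data.table(runs_a)
  b <- data.table::as.data.table(runs_b)
  if (!"run_id" %in% names(a) || !"run_id" %in% names(b)) {
    stop("both run sets must carry a run_id column", call. = FALSE)
  }
  if (!setequal(a$run_id, b$run_id) || anyDuplicated(a$run_id) || anyDuplicated(b$run_id)) {
    stop("unpaired input: run_id sets must match one-to-one", call. = FALSE)
  }
  if (nrow(a) < 3L) stop("need at least 3 paired runs", call. = FALSE)
  if (is.null(metrics)) {
    metrics <- setdiff(intersect(names(a), names(b)), "run_id")
  }
  if (is.null(family_size)) family_size <- length(metrics)
  b <- b[match(a$run_id, b$run_id)]
  rows <- lapply(metrics, function(m) {
    d <- a[[m]] - b[[m]]
    if (sd(d) == 0) {
      return(data.table::data.table(
        metric = m, mean_diff = mean(d), test = "degenerate",
        shapiro_p = NA_real_, p = NA_real_, p_bonferroni = NA_real_,
        significant = mean(d) != 0))
    }
    sw <- shapiro.test(d)$p.value
    if (sw >= 0.05) {
      test <- "paired_t"
      p <- t.test(d)$p.value
    } else {
      test <- "wilcoxon"
      p <- suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
    }
    padj <- min(1, p * family_size)
    data.table::data.table(metric = m, mean_diff = mean(d), test = test,
                           shapiro_p = sw, p = p, p_bonferroni = padj,
                           significant = padj < alpha)
  })
  data.table::rbindlist(rows)
}

#' Two one-sided tests (TOST) of equivalence
#'
#' The Schuirmann procedure on paired differences: one-sided t tests of
#' mean > -margin and mean < +margin; the reported p value is the larger of
#' the two, and equivalence is declared when it falls below `alpha`.
#' Zero-variance differences make the t statistics undefined; the
#' documented degenerate rule then declares equivalence iff the (constant)
#' mean lies strictly inside the margin, with p reported as 0 or 1.
#'
#' @param differences Paired metric differences (length >= 3).
#' @param margin Equivalence margin, > 0 (0.02 for AUROC/AUPRC, 0.01 for
#'   accuracy/F1 in the reference configuration).
#' @param alpha Significance level (default 0.05).
#' @return List: `p` (max of the one-sided p values), `p_lower`, `p_upper`,
#'   `mean_diff`, `equivalent`, `degenerate`.
#' @export
tost_equivalence <- function(differences, margin, alpha = 0.05) {
  if (length(differences) < 3L) stop("need at least 3 paired differences", call. = FALSE)
  if (margin <= 0) stop("margin must be positive", call. = FALSE)
  m <- mean(differences)
  s <- sd(differences)
  n <- length(differences)
  if (s == 0) {
    inside <- abs(m) < margin
    p <- if (inside) 0 else 1
    return(list(p = p, p_lower = p, p_upper = p, mean_diff = m,
                equivalent = inside && p < alpha, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  t_lower <- (m + margin) / se   # H0: mean <= -margin
  t_upper <- (m - margin) / se   # H0: mean >= +margin
  p_lower <- pt(t_lower, df = n - 1, lower.tail = FALSE)
  p_upper <- pt(t_upper, df = n - 1, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  list(p = p, p_lower = p_lower, p_upper = p_upper, mean_diff = m,
       equivalent = p < alpha, degenerate = FALSE)
}

#' Seeded percentile bootstrap confidence interval
#'
#' @param values Numeric vector to resample.
#' @param statistic Function of a numeric vector (default `mean`).
#' @param reps Bootstrap replicates (default 5000).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` with the point estimate in the
#'   `estimate` attribute. For statistics that do not respect resample
#'   monotonicity the percentile interval need not contain the estimate.
#' @export
bootstrap_ci <- function(values, statistic = mean, reps = 5000L, seed = 42L,
                         conf = 0.95) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  est <- statistic(values)
  stats <- with_seed(seed, {
    n <- length(values)
    vapply(seq_len(reps), function(i) statistic(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  qs <- quantile(stats, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE, type = 7)
  structure(qs, estimate = est, conf = conf)
}

#' Full equivalence report over paired metric runs
#'
#' Combines [paired_compare()], [tost_equivalence()] per metric at its
#' prespecified margin, and a seeded bootstrap CI of the mean difference.
#'
#' @inheritParams paired_compare
#' @param margins Named margins per metric (default
#'   `c(auroc = .02, auprc = .02, accuracy = .01, f1 = .01)`).
#' @param reps Bootstrap replicates (default 5000).
#' @param seed Bootstrap seed.
#' @return `data.table` with one row per metric: paired-test results, TOST
#'   p value and verdict, and the bootstrap 95% CI of the difference.
#' @export
equivalence_report <- function(runs_a, runs_b,
                               margins = c(auroc = 0.02, auprc = 0.02,
                                           accuracy = 0.01, f1 = 0.01),
                               alpha = 0.05, reps = 5000L, seed = 42L) {
  metrics <- intersect(names(margins),
                       setdiff(intersect(names(runs_a), names(runs_b)), "run_id"))
  cmp <- paired_compare(runs_a, runs_b, metrics = metrics, alpha = alpha)
  a <- data.table::as.data.table(runs_a)
  b <- data.table::as.data.table(runs_b)
  b <- b[match(a$run_id, b$run_id)]
  extra <- lapply(metrics, function(m) {
    d <- a[[m]] - b[[m]]
    tost <- tost_equivalence(d, margins[[m]], alpha)
    ci <- bootstrap_ci(d, mean, reps = reps, seed = seed)
    data.table::data.table(metric = m, margin = margins[[m]],
                           tost_p = tost$p, equivalent = tost$equivalent,
                           tost_degenerate = tost$degenerate,
                           ci_lower = ci[1], ci_upper = ci[2])
  })
  cmp[data.table::rbindlist(extra), on = "metric"]
}
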