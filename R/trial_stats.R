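#' Mean change from baseline with a t-based confidence interval
#'
#' Change is computed as baseline minus follow-up so that improvement on a
#' "higher is worse" disability scale is positive, matching the usual
#' presentation of clinical-effectiveness tables.
#'
#' @param baseline,followup Paired numeric vectors of equal length (n >= 2),
#'   one entry per participant.
#' @param conf Confidence level (default 0.95).
#' @return List with `mean_change`, `ci95` (length 2), `n`.
#' @export
mean_change_from_baseline <- function(baseline, followup, conf = 0.95) {
  if (length(baseline) != length(followup))
    stop("`baseline` and `followup` must be paired (equal length)", call. = FALSE)
  if (length(baseline) < 2L)
    stop("at least 2 paired observations are required", call. = FALSE)
  if (anyNA(baseline) || anyNA(followup))
    stop("missing values are not allowed in paired changes", call. = FALSE)
  change <- baseline - followup
  n <- length(change)
  m <- mean(change)
  se <- stats::sd(change) / sqrt(n)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * se
  list(mean_change = m, ci95 = c(m - half, m + half), n = n)
}

#' Between-arm difference in mean change (Welch)
#'
#' Difference of per-arm mean changes with a Welch-type confidence interval
#' and p-value, for contrasting two arms' improvements at one time point.
#'
#' @param change_x,change_y Numeric vectors of per-participant change scores
#'   in the two arms.
#' @param conf Confidence level.
#' @return List with `difference`, `ci95`, `p_value`.
#' @export
between_arm_difference <- function(change_x, change_y, conf = 0.95) {
  if (length(change_x) < 2L || length(change_y) < 2L)
    stop("each arm needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(change_x, change_y, conf.level = conf)
  list(difference = unname(tt$estimate[1] - tt$estimate[2]),
       ci95 = unname(tt$conf.int),
       p_value = tt$p.value)
}

#' Mann-Whitney U test between two arms
#'
#' Rank-sum comparison of two independent samples with midranks for ties.
#' The U statistic reported is the number of (x, y) pairs with x > y (ties
#' counting one half), so complete separation with every x below every y
#' gives U = 0, and U_x + U_y = n_x * n_y. The p-value is exact (network
#' enumeration) for small tie-free samples and uses the tie-corrected normal
#' approximation otherwise, as in [stats::wilcox.test()], which performs
#' the computation.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U`, `p_value`, `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = !ties && (length(x) + length(y)) <= 12L,
    correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Friedman test across repeated time points
#'
#' Within-participant rank test (midranks for ties) for scores measured at k
#' time points on the same participants; here k = 3 (baseline, week 4,
#' week 8), giving 2 degrees of freedom. Computation is delegated to
#' [stats::friedman.test()]. The statistic is 0 when every participant's
#' scores are constant across time and attains its analytic maximum
#' n * (k - 1) under perfect concordance (every participant ranking the time
#' points identically and strictly).
#'
#' @param scores Numeric matrix or data frame, participants in rows, time
#'   points in columns; no missing cells.
#' @return List with `statistic` (chi-squared), `df`, `p_value`, `n`.
#' @export
friedman <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("at least 2 participants required", call. = FALSE)
  if (ncol(scores) < 2L) stop("at least 2 time points required", call. = FALSE)
  if (anyNA(scores)) stop("missing cells are not allowed", call. = FALSE)
  # fully tied rows carry no rank information: statistic 0 by convention
  # (the tie-corrected denominator would otherwise be 0/0)
  if (all(apply(scores, 1, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, df = ncol(scores) - 1L, p_value = 1,
                n = nrow(scores)))
  ft <- stats::friedman.test(scores)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value, n = nrow(scores))
}

#' Clinical-effectiveness report for a cohort
#'
#' Per-arm mean ODI change from baseline at weeks 4 and 8 with t-based 95%
#' confidence intervals, the between-arm Welch contrast at each week, the
#' Mann-Whitney comparison of change scores between arms, and the Friedman
#' test across the three time points within each arm.
#'
#' @param cohort Cohort data frame with columns `arm`, `odi_baseline`,
#'   `odi_week4`, `odi_week8` (e.g. from [generate_cohort()]).
#' @param file Optional path; when given, the change-score table is also
#'   written as tab-separated text.
#' @return List with `changes` (data frame: arm, timepoint, mean_change,
#'   ci_low, ci_high, n), `contrasts` (per week: difference, CI,
#'   Welch and Mann-Whitney p-values), `friedman` (per arm).
#' @export
effectiveness_report <- function(cohort, file = NULL) {
  need <- c("arm", "odi_baseline", "odi_week4", "odi_week8")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  arms <- unique(cohort$arm)
  weeks <- c(week4 = "odi_week4", week8 = "odi_week8")

  changes <- do.call(rbind, lapply(arms, function(a) {
    d <- cohort[cohort$arm == a, ]
    do.call(rbind, lapply(names(weeks), function(w) {
      cs <- mean_change_from_baseline(d$odi_baseline, d[[weeks[w]]])
      data.frame(arm = a, timepoint = w, mean_change = cs$mean_change,
                 ci_low = cs$ci95[1], ci_high = cs$ci95[2], n = cs$n)
    }))
  }))
  rownames(changes) <- NULL

  contrasts <- NULL
  if (length(arms) == 2L) {
    d1 <- cohort[cohort$arm == arms[1], ]
    d2 <- cohort[cohort$arm == arms[2], ]
    contrasts <- do.call(rbind, lapply(names(weeks), function(w) {
      c1 <- d1$odi_baseline - d1[[weeks[w]]]
      c2 <- d2$odi_baseline - d2[[weeks[w]]]
      bd <- between_arm_difference(c1, c2)
      mw <- mann_whitney(c1, c2)
      data.frame(timepoint = w, arm_new = arms[1], arm_ref = arms[2],
                 difference = bd$difference, ci_low = bd$ci95[1],
                 ci_high = bd$ci95[2], p_welch = bd$p_value,
                 p_mann_whitney = mw$p_value)
    }))
    rownames(contrasts) <- NULL
  }

  fried <- lapply(stats::setNames(arms, arms), function(a) {
    d <- cohort[cohort$arm == a, c("odi_baseline", "odi_week4", "odi_week8")]
    friedman(d)
  })

  if (!is.null(file))
    utils::write.table(changes, file, sep = "\t", quote = FALSE, row.names = FALSE)
  list(changes = changes, contrasts = contrasts, friedman = fried)
}
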