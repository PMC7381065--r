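#' Incremental cost and effect between two arms
#'
#' New intervention minus reference, component-wise, matching the ICER
#' convention (Cost_new - Cost_ref) / (QALY_new - QALY_ref).
#'
#' @param summary_new,summary_ref Lists (or one-row data frames) with
#'   elements `mean_cost_naira` and `mean_qaly`.
#' @return Named numeric vector `c(delta_cost, delta_effect)`.
#' @examples
#' incremental(list(mean_cost_naira = 22200, mean_qaly = 0.085),
#'             list(mean_cost_naira = 38200, mean_qaly = 0.084))
#' @export
incremental <- function(summary_new, summary_ref) {
  need <- c("mean_cost_naira", "mean_qaly")
  if (!all(need %in% names(summary_new)) || !all(need %in% names(summary_ref)))
    stop("summaries need `mean_cost_naira` and `mean_qaly`", call. = FALSE)
  c(delta_cost = unname(summary_new$mean_cost_naira - summary_ref$mean_cost_naira),
    delta_effect = unname(summary_new$mean_qaly - summary_ref$mean_qaly))
}

#' Classify an incremental cost/effect pair (ICER with dominance)
#'
#' Every sign pattern of (delta cost, delta effect) maps to a defined
#' outcome:
#' * `dominant` - cheaper and more effective (no meaningful ratio);
#' * `dominated` - dearer and less effective (no meaningful ratio);
#' * `tradeoff_NE` - dearer and more effective: numeric ICER reported;
#' * `tradeoff_SW` - cheaper and less effective: numeric ICER reported;
#' * `indeterminate` - zero effect difference: no division attempted.
#'
#' Negative ratios from dominance quadrants are never reported as numbers:
#' a ratio like -16,000,000 naira per QALY carries no decision information,
#' while "dominant" does.
#'
#' @param delta_cost Incremental cost (naira).
#' @param delta_effect Incremental effect (QALY).
#' @return List of class `icer_result` with `label`, `icer` (numeric
#'   naira/QALY for the trade-off quadrants, otherwise `NA`), and the inputs.
#' @examples
#' icer(-16000, 0.001)  # dominant
#' icer(1000, 0.01)     # 100000 naira/QALY, tradeoff_NE
#' @export
icer <- function(delta_cost, delta_effect) {
  stopifnot(is.numeric(delta_cost), is.numeric(delta_effect),
            length(delta_cost) == 1L, length(delta_effect) == 1L)
  if (delta_effect == 0) {
    label <- "indeterminate"; ratio <- NA_real_
  } else if (delta_cost < 0 && delta_effect > 0) {
    label <- "dominant"; ratio <- NA_real_
  } else if (delta_cost > 0 && delta_effect < 0) {
    label <- "dominated"; ratio <- NA_real_
  } else if (delta_effect > 0) {
    label <- "tradeoff_NE"; ratio <- delta_cost / delta_effect
  } else {
    label <- "tradeoff_SW"; ratio <- delta_cost / delta_effect
  }
  structure(list(label = label, icer = ratio,
                 delta_cost = delta_cost, delta_effect = delta_effect),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat("Incremental analysis\n")
  cat(sprintf("  delta cost:   %12.2f naira\n", x$delta_cost))
  cat(sprintf("  delta effect: %12.5f QALY\n", x$delta_effect))
  if (is.na(x$icer)) cat(sprintf("  ICER:         %s\n", x$label))
  else cat(sprintf("  ICER:         %.0f naira/QALY (%s)\n", x$icer, x$label))
  invisible(x)
}

#' Quadrant of the cost-effectiveness plane
#'
#' The plane has incremental effect on the horizontal axis and incremental
#' cost on the vertical axis. Quadrants: NE (dearer, more effective), SE
#' (cheaper, more effective: dominant), SW (cheaper, less effective), NW
#' (dearer, less effective: dominated). Points exactly on an axis - a
#' probability-zero event with continuous data - are assigned to the
#' adjacent quadrant in the clockwise direction (the positive cost axis to
#' NE, the positive effect axis to SE, the negative cost axis to SW, the
#' negative effect axis to NW; the origin to NE).
#'
#' @param delta_cost,delta_effect Numeric vectors of equal length.
#' @return Factor with levels NE, SE, SW, NW.
#' @export
ce_quadrant <- function(delta_cost, delta_effect) {
  stopifnot(length(delta_cost) == length(delta_effect))
  q <- ifelse(delta_effect > 0,
              ifelse(delta_cost > 0, "NE", "SE"),
              ifelse(delta_effect < 0,
                     ifelse(delta_cost < 0, "SW", "NW"),
                     # on the cost axis (delta_effect == 0)
                     ifelse(delta_cost >= 0, "NE", "SW")))
  factor(q, levels = c("NE", "SE", "SW", "NW"))
}

#' Nonparametric bootstrap of incremental cost and effect
#'
#' Resamples participants with replacement *within each arm* (arm sizes
#' preserved), recomputes arm mean cost and mean QALY for every replicate,
#' and summarises the resulting cloud of incremental pairs: percentile
#' confidence intervals for the incremental cost and effect, and the
#' proportion of replicates falling in each quadrant of the
#' cost-effectiveness plane. The replicate set is deterministic for a fixed
#' seed.
#'
#' @param participants Data frame with columns `arm`, `cost_naira`, `qaly`
#'   (one row per participant), e.g. from [participant_costs_qalys()].
#' @param new,ref Labels of the new and reference arm (defaults `"TBMT"`
#'   and `"CBMT"`).
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile intervals (default 0.95).
#' @param ci_method `"percentile"` (default) or `"bca"`
#'   (bias-corrected and accelerated, jackknife acceleration).
#' @return A list of class `ce_result`: point estimates (`delta_cost`,
#'   `delta_effect`, `icer`, `label`), `replicates` (a `B` x 2 data frame),
#'   `ci_cost`, `ci_effect`, `quadrant_proportions` (named, sums to 1), and
#'   the per-arm summaries in `arms`.
#' @export
bootstrap_cea <- function(participants, new = "TBMT", ref = "CBMT",
                          B = 1000L, seed = 1L, conf = 0.95,
                          ci_method = c("percentile", "bca")) {
  ci_method <- match.arg(ci_method)
  need <- c("arm", "cost_naira", "qaly")
  if (!is.data.frame(participants) || !all(need %in% names(participants)))
    stop("`participants` needs columns arm, cost_naira, qaly", call. = FALSE)
  if (B < 1) stop("`B` must be at least 1", call. = FALSE)
  dat <- split(participants[, c("cost_naira", "qaly")], participants$arm)
  for (a in c(new, ref))
    if (is.null(dat[[a]]) || nrow(dat[[a]]) == 0L)
      stop(sprintf("arm '%s' has no participants", a), call. = FALSE)
  dn <- dat[[new]]; dr <- dat[[ref]]

  point <- incremental(
    list(mean_cost_naira = mean(dn$cost_naira), mean_qaly = mean(dn$qaly)),
    list(mean_cost_naira = mean(dr$cost_naira), mean_qaly = mean(dr$qaly)))

  reps <- withr_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      i <- sample.int(nrow(dn), replace = TRUE)
      j <- sample.int(nrow(dr), replace = TRUE)
      c(mean(dn$cost_naira[i]) - mean(dr$cost_naira[j]),
        mean(dn$qaly[i]) - mean(dr$qaly[j]))
    }, numeric(2)))
  })
  replicates <- data.frame(delta_cost = reps[, 1], delta_effect = reps[, 2])

  alpha <- 1 - conf
  ci_fun <- switch(ci_method,
    percentile = function(theta, ...)
      unname(stats::quantile(theta, c(alpha / 2, 1 - alpha / 2), type = 6)),
    bca = function(theta, t0, jack)
      bca_interval(theta, t0, jack, conf))
  jack <- if (ci_method == "bca") jackknife_increments(dn, dr) else NULL
  ci_cost <- ci_fun(replicates$delta_cost, point[["delta_cost"]], jack$cost)
  ci_effect <- ci_fun(replicates$delta_effect, point[["delta_effect"]], jack$effect)

  quad <- ce_quadrant(replicates$delta_cost, replicates$delta_effect)
  qp <- table(quad) / B

  structure(list(
    delta_cost = point[["delta_cost"]],
    delta_effect = point[["delta_effect"]],
    icer = icer(point[["delta_cost"]], point[["delta_effect"]]),
    label = icer(point[["delta_cost"]], point[["delta_effect"]])$label,
    replicates = replicates,
    ci_cost = ci_cost, ci_effect = ci_effect,
    quadrant_proportions = stats::setNames(as.numeric(qp), names(qp)),
    conf = conf, B = B, seed = seed, ci_method = ci_method,
    arms = list(new = list(arm = new, n = nrow(dn),
                           mean_cost_naira = mean(dn$cost_naira),
                           mean_qaly = mean(dn$qaly)),
                ref = list(arm = ref, n = nrow(dr),
                           mean_cost_naira = mean(dr$cost_naira),
                           mean_qaly = mean(dr$qaly)))),
    class = "ce_result")
}

# Leave-one-out increments for the BCa acceleration constant.
jackknife_increments <- function(dn, dr) {
  jc <- je <- numeric(nrow(dn) + nrow(dr))
  for (i in seq_len(nrow(dn))) {
    jc[i] <- mean(dn$cost_naira[-i]) - mean(dr$cost_naira)
    je[i] <- mean(dn$qaly[-i]) - mean(dr$qaly)
  }
  for (j in seq_len(nrow(dr))) {
    jc[nrow(dn) + j] <- mean(dn$cost_naira) - mean(dr$cost_naira[-j])
    je[nrow(dn) + j] <- mean(dn$qaly) - mean(dr$qaly[-j])
  }
  list(cost = jc, effect = je)
}

bca_interval <- function(theta, t0, jack, conf) {
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  if (stats::sd(theta) == 0) return(rep(t0, 2))
  z0 <- stats::qnorm(mean(theta < t0))
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  if (!is.finite(z0) || !is.finite(a)) # degenerate resamples: fall back
    return(unname(stats::quantile(theta, alpha, type = 6)))
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  unname(stats::quantile(theta, adj, type = 6))
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Cost-utility bootstrap (B = %d, seed = %d, %s CI)\n",
              x$B, x$seed, x$ci_method))
  cat(sprintf("  %s: mean cost %10.0f naira, mean QALY %.4f (n = %d)\n",
              x$arms$ref$arm, x$arms$ref$mean_cost_naira,
              x$arms$ref$mean_qaly, x$arms$ref$n))
  cat(sprintf("  %s: mean cost %10.0f naira, mean QALY %.4f (n = %d)\n",
              x$arms$new$arm, x$arms$new$mean_cost_naira,
              x$arms$new$mean_qaly, x$arms$new$n))
  cat(sprintf("  delta cost   %.0f naira (%.0f%% CI %.0f to %.0f)\n",
              x$delta_cost, 100 * x$conf, x$ci_cost[1], x$ci_cost[2]))
  cat(sprintf("  delta effect %.4f QALY (%.0f%% CI %.4f to %.4f)\n",
              x$delta_effect, 100 * x$conf, x$ci_effect[1], x$ci_effect[2]))
  cat(sprintf("  conclusion:  %s\n", x$label))
  cat("  quadrant proportions: ",
      paste(sprintf("%s %.3f", names(x$quadrant_proportions),
                    x$quadrant_proportions), collapse = ", "), "\n")
  invisible(x)
}

#' Quadrant summary of a bootstrap replicate cloud
#'
#' @param replicates Data frame with columns `delta_cost`, `delta_effect`
#'   (e.g. the `replicates` element of a [bootstrap_cea()] result).
#' @return Named numeric vector of proportions (NE, SE, SW, NW) summing to 1.
#' @export
ce_plane_summary <- function(replicates) {
  if (!is.data.frame(replicates) || nrow(replicates) == 0L)
    stop("`replicates` must be a non-empty data frame", call. = FALSE)
  q <- ce_quadrant(replicates$delta_cost, replicates$delta_effect)
  stats::setNames(as.numeric(table(q) / nrow(replicates)), levels(q))
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of bootstrap incremental (effect, cost) pairs with the point
#' estimate marked; incremental effect (QALY) on the horizontal axis and
#' incremental cost (naira) on the vertical axis.
#'
#' @param result A `ce_result` from [bootstrap_cea()].
#' @param file Optional path; when given, the plot is also written there
#'   (device chosen from the extension by [ggplot2::ggsave()]).
#' @return A ggplot object, invisibly when `file` is given.
#' @export
plot_ce_plane <- function(result, file = NULL) {
  stopifnot(inherits(result, "ce_result"))
  reps <- result$replicates
  p <- ggplot2::ggplot(reps, ggplot2::aes(x = delta_effect, y = delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue", size = 1) +
    ggplot2::annotate("point", x = result$delta_effect, y = result$delta_cost,
                      colour = "firebrick", size = 3, shape = 18) +
    ggplot2::labs(x = "Incremental effect (QALY)",
                  y = "Incremental cost (naira)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("%d bootstrap replicates; point estimate in red (%s)",
                                     result$B, result$label)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the proportion of bootstrap replicates
#' with positive net monetary benefit (`wtp * delta_effect - delta_cost > 0`).
#' This is an extension beyond a point-estimate dominance ruling, useful
#' when the replicate cloud straddles quadrants.
#'
#' @param result A `ce_result` from [bootstrap_cea()].
#' @param wtp_grid Willingness-to-pay values in naira per QALY.
#' @return Data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 2e6, length.out = 101)) {
  stopifnot(inherits(result, "ce_result"))
  reps <- result$replicates
  prob <- vapply(wtp_grid, function(w)
    mean(w * reps$delta_effect - reps$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}
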