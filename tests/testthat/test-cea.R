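# Small hand-built cohorts for bootstrap behaviour checks.
degenerate_cohort <- function(n_new = 5, n_ref = 6) {
  data.frame(
    arm = c(rep("TBMT", n_new), rep("CBMT", n_ref)),
    cost_naira = c(rep(22200, n_new), rep(38200, n_ref)),
    qaly = c(rep(0.085, n_new), rep(0.084, n_ref))
  )
}

test_that("incremental analysis is new-minus-reference, component-wise", {
  inc <- incremental(list(mean_cost_naira = 22200, mean_qaly = 0.085),
                     list(mean_cost_naira = 38200, mean_qaly = 0.084))
  expect_equal(inc[["delta_cost"]], -16000)
  expect_equal(inc[["delta_effect"]], 0.001)
  same <- list(mean_cost_naira = 100, mean_qaly = 0.05)
  expect_equal(unname(incremental(same, same)), c(0, 0))
  expect_error(incremental(list(mean_qaly = 1), same), "mean_cost_naira")
})

test_that("ICER classification is exhaustive and mutually exclusive", {
  cases <- expand.grid(dc = c(-1000, 0, 1000), de = c(-0.01, 0, 0.01))
  labels <- mapply(function(dc, de) icer(dc, de)$label, cases$dc, cases$de)
  expected <- c(
    "tradeoff_SW", "tradeoff_SW", "dominated",         # de < 0: dc -, 0, +
    "indeterminate", "indeterminate", "indeterminate", # de = 0
    "dominant", "tradeoff_NE", "tradeoff_NE"           # de > 0: dc -, 0, +
  )
  expect_identical(unname(labels), expected)
  valid <- c("dominant", "dominated", "tradeoff_NE", "tradeoff_SW",
             "indeterminate")
  expect_true(all(labels %in% valid))
})

test_that("numeric ICERs appear only in the trade-off quadrants", {
  dom <- icer(-16000, 0.001)
  expect_identical(dom$label, "dominant")
  expect_true(is.na(dom$icer))
  expect_identical(icer(16000, -0.001)$label, "dominated")
  expect_true(is.na(icer(16000, -0.001)$icer))
  ne <- icer(1000, 0.01)
  expect_identical(ne$label, "tradeoff_NE")
  expect_equal(ne$icer, 100000)
  sw <- icer(-1000, -0.01)
  expect_identical(sw$label, "tradeoff_SW")
  expect_equal(sw$icer, 100000)
  ind <- icer(5000, 0)
  expect_identical(ind$label, "indeterminate")
  expect_true(is.na(ind$icer))
})

test_that("plane quadrants follow the clockwise tie convention", {
  expect_identical(as.character(ce_quadrant(10, 0.01)), "NE")
  expect_identical(as.character(ce_quadrant(-10, 0.01)), "SE")
  expect_identical(as.character(ce_quadrant(-10, -0.01)), "SW")
  expect_identical(as.character(ce_quadrant(10, -0.01)), "NW")
  # axis ties: assigned to the clockwise-adjacent quadrant
  expect_identical(as.character(ce_quadrant(10, 0)), "NE")   # +cost axis
  expect_identical(as.character(ce_quadrant(0, 0.01)), "SE") # +effect axis
  expect_identical(as.character(ce_quadrant(-10, 0)), "SW")  # -cost axis
  expect_identical(as.character(ce_quadrant(0, -0.01)), "NW")# -effect axis
  expect_identical(as.character(ce_quadrant(0, 0)), "NE")
})

test_that("a degenerate cohort gives zero-width intervals at the point estimate", {
  res <- bootstrap_cea(degenerate_cohort(), B = 200, seed = 3)
  expect_equal(res$delta_cost, -16000)
  expect_equal(res$delta_effect, 0.001)
  # every replicate equals the point estimate; intervals have zero width
  expect_true(all(res$replicates$delta_cost == res$delta_cost))
  expect_true(all(res$replicates$delta_effect == res$delta_effect))
  expect_equal(unname(res$ci_cost), rep(res$delta_cost, 2))
  expect_equal(unname(res$ci_effect), rep(res$delta_effect, 2))
  expect_equal(diff(res$ci_effect), 0)
  expect_equal(unname(res$quadrant_proportions[["SE"]]), 1)
  expect_identical(res$label, "dominant")
})

test_that("the bootstrap is deterministic for a fixed seed", {
  cohort <- participant_costs_qalys(generate_cohort(cohort_config(), seed = 4))
  a <- bootstrap_cea(cohort, B = 300, seed = 11)
  b <- bootstrap_cea(cohort, B = 300, seed = 11)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$ci_effect, b$ci_effect)
  c_ <- bootstrap_cea(cohort, B = 300, seed = 12)
  expect_false(identical(a$replicates, c_$replicates))
})

test_that("replicate means converge to the point estimates", {
  cohort <- participant_costs_qalys(generate_cohort(cohort_config(), seed = 8))
  res <- bootstrap_cea(cohort, B = 5000, seed = 21)
  mc_se_effect <- stats::sd(res$replicates$delta_effect) / sqrt(res$B)
  expect_lt(abs(mean(res$replicates$delta_effect) - res$delta_effect),
            3 * mc_se_effect)
  # protocol costs are constant within arm, so delta cost is exactly recovered
  expect_equal(mean(res$replicates$delta_cost), res$delta_cost)
  expect_equal(sum(res$quadrant_proportions), 1)
})

test_that("uniform dominance puts every replicate in the south-east quadrant", {
  cohort <- degenerate_cohort(8, 8)
  set.seed(42)
  cohort$qaly <- cohort$qaly + stats::runif(16, 0, 0.001)
  cohort$qaly[cohort$arm == "TBMT"] <- cohort$qaly[cohort$arm == "TBMT"] + 0.05
  cohort$cost_naira[cohort$arm == "TBMT"] <-
    cohort$cost_naira[cohort$arm == "TBMT"] - 20000
  res <- bootstrap_cea(cohort, B = 400, seed = 5)
  expect_equal(unname(res$quadrant_proportions[["SE"]]), 1)
  expect_identical(res$label, "dominant")
})

test_that("scaling all costs scales deltas but not labels or quadrants", {
  cohort <- participant_costs_qalys(generate_cohort(cohort_config(), seed = 6))
  base <- bootstrap_cea(cohort, B = 400, seed = 9)
  scaled_cohort <- cohort
  scaled_cohort$cost_naira <- cohort$cost_naira * 3
  scaled <- bootstrap_cea(scaled_cohort, B = 400, seed = 9)
  expect_equal(scaled$delta_cost, 3 * base$delta_cost)
  expect_equal(scaled$replicates$delta_cost, 3 * base$replicates$delta_cost)
  expect_equal(scaled$replicates$delta_effect, base$replicates$delta_effect)
  expect_identical(scaled$label, base$label)
  expect_identical(scaled$quadrant_proportions, base$quadrant_proportions)
})

test_that("quadrant proportions of a symmetric cloud are near one quarter each", {
  set.seed(99)
  reps <- data.frame(delta_cost = stats::rnorm(20000),
                     delta_effect = stats::rnorm(20000))
  qp <- ce_plane_summary(reps)
  expect_equal(sum(qp), 1)
  # chi-square goodness of fit against the uniform quadrant law
  gof <- stats::chisq.test(qp * 20000, p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.001)
  expect_true(all(abs(qp - 0.25) < 0.02))
  expect_error(ce_plane_summary(data.frame()), "non-empty")
})

test_that("bootstrap validates its inputs", {
  cohort <- degenerate_cohort()
  expect_error(bootstrap_cea(cohort[cohort$arm == "TBMT", ], B = 10, seed = 1),
               "no participants")
  expect_error(bootstrap_cea(cohort, B = 0, seed = 1), "at least 1")
  expect_error(bootstrap_cea(data.frame(x = 1), B = 10, seed = 1), "columns")
})

test_that("BCa intervals are available and sane", {
  cohort <- participant_costs_qalys(generate_cohort(cohort_config(), seed = 10))
  res <- bootstrap_cea(cohort, B = 500, seed = 2, ci_method = "bca")
  expect_lt(res$ci_effect[1], res$ci_effect[2])
  expect_true(all(is.finite(res$ci_effect)))
  # cost is degenerate (protocol-determined): interval collapses to the point
  expect_equal(unname(res$ci_cost), c(-16000, -16000))
})

test_that("the plane plot builds and writes to file", {
  cohort <- participant_costs_qalys(generate_cohort(cohort_config(), seed = 14))
  res <- bootstrap_cea(cohort, B = 100, seed = 3)
  p <- plot_ce_plane(res)
  expect_s3_class(p, "ggplot")
  path <- withr::local_tempfile(fileext = ".png")
  plot_ce_plane(res, file = path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("the acceptability curve is a proportion for every willingness-to-pay", {
  cohort <- participant_costs_qalys(generate_cohort(cohort_config(), seed = 15))
  res <- bootstrap_cea(cohort, B = 300, seed = 4)
  cc <- ceac(res, wtp_grid = c(0, 1e5, 1e6))
  expect_equal(nrow(cc), 3)
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  # at zero willingness-to-pay this is P(cost saving), here 1 by protocol
  expect_equal(cc$prob_cost_effective[1], 1)
})
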