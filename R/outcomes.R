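#' Score the Oswestry Disability Index from item responses
#'
#' The ODI has 10 items, each scored 0 (no disability) to 5 (worst). The
#' total is rescaled to 0--100 as `100 * sum(answered) / (5 * n_answered)`,
#' so skipped items (NA) do not penalise the score.
#'
#' @param item_responses Numeric vector of up to 10 item responses, each an
#'   integer in \[0, 5\]; `NA` marks an unanswered item.
#' @return ODI score in \[0, 100\] (higher = more disabled).
#' @examples
#' odi_score(c(3, 2, 4, 1, 0, 5, 2, 3, 1, 2)) # 46
#' @export
odi_score <- function(item_responses) {
  if (!is.numeric(item_responses) || length(item_responses) < 1L ||
      length(item_responses) > 10L)
    stop("`item_responses` must be a numeric vector of 1-10 items", call. = FALSE)
  answered <- item_responses[!is.na(item_responses)]
  if (length(answered) == 0L)
    stop("cannot score the ODI with zero answered items", call. = FALSE)
  if (any(answered < 0 | answered > 5 | answered != round(answered)))
    stop("item responses must be integers in [0, 5]", call. = FALSE)
  100 * sum(answered) / (5 * length(answered))
}

#' Default ODI to SF-6D mapping coefficients
#'
#' The published linear crosswalk from ODI disability to SF-6D utility:
#' `SF-6D = 0.78275 - 0.00518 * ODI`. Over the full ODI range the mapped
#' utility stays inside (0, 1) (0.78275 at ODI 0, 0.26475 at ODI 100), so
#' no clamping is applied.
#'
#' @param intercept Utility at ODI = 0.
#' @param slope Utility lost per ODI point (entered as a positive number,
#'   applied subtractively).
#' @return A list of class `sf6d_coefficients`.
#' @export
sf6d_coefficients <- function(intercept = 0.78275, slope = 0.00518) {
  stopifnot(is.numeric(intercept), is.numeric(slope), slope > 0)
  if (intercept <= 0 || intercept - slope * 100 <= 0 || intercept >= 1)
    stop("coefficients must map ODI in [0, 100] into (0, 1)", call. = FALSE)
  structure(list(intercept = intercept, slope = slope),
            class = "sf6d_coefficients")
}

#' Map an ODI score to SF-6D utility
#'
#' @param odi ODI score(s) in \[0, 100\].
#' @param coeffs Mapping coefficients from [sf6d_coefficients()].
#' @return SF-6D utility in (0, 1); strictly decreasing in `odi`.
#' @examples
#' map_odi_to_sf6d(0)   # 0.78275
#' map_odi_to_sf6d(100) # 0.26475
#' @export
map_odi_to_sf6d <- function(odi, coeffs = sf6d_coefficients()) {
  stopifnot(inherits(coeffs, "sf6d_coefficients"))
  if (!is.numeric(odi) || any(is.na(odi)) || any(odi < 0 | odi > 100))
    stop("ODI scores must lie in [0, 100]", call. = FALSE)
  coeffs$intercept - coeffs$slope * odi
}

#' Quality-adjusted life years over a short trial horizon
#'
#' QALYs are utility multiplied by time lived at that utility, in years.
#' Two conventions for combining the week-4 and week-8 utilities are
#' supported:
#' \describe{
#'   \item{`"mean_utility"`}{(default) the average of the two utilities is
#'     applied to the whole horizon: `mean(u4, u8) * horizon_weeks / 52`.
#'     This is the convention that reproduces an arm-level QALY of ~0.085
#'     from a utility level of ~0.55 over 8 weeks.}
#'   \item{`"period_qaly"`}{each utility is applied to its own assessment
#'     time (4 and 8 weeks) and the two period QALYs are averaged:
#'     `mean(u4 * 4/52, u8 * 8/52)`.}
#' }
#'
#' @param sf6d_week4,sf6d_week8 Utilities in \[0, 1\] at weeks 4 and 8.
#' @param horizon_weeks Trial horizon in weeks (default 8).
#' @param convention `"mean_utility"` or `"period_qaly"`.
#' @return QALY value(s), bounded by `horizon_weeks / 52`.
#' @examples
#' qaly(0.5526, 0.5526) # 0.0850
#' @export
qaly <- function(sf6d_week4, sf6d_week8, horizon_weeks = 8,
                 convention = c("mean_utility", "period_qaly")) {
  convention <- match.arg(convention)
  u <- c(sf6d_week4, sf6d_week8)
  if (!is.numeric(u) || any(is.na(u)) || any(u < 0 | u > 1))
    stop("utilities must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(horizon_weeks) || horizon_weeks <= 0)
    stop("`horizon_weeks` must be positive", call. = FALSE)
  switch(convention,
    mean_utility = (sf6d_week4 + sf6d_week8) / 2 * horizon_weeks / 52,
    period_qaly = (sf6d_week4 * 4 / 52 + sf6d_week8 * horizon_weeks / 52) / 2
  )
}

#' Arm-level mean QALY with a percentile bootstrap confidence interval
#'
#' @param qalys Numeric vector of participant QALYs for one arm.
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return A list with `mean`, `ci` (length-2 percentile interval) and `n`.
#' @export
arm_mean_qaly <- function(qalys, B = 1000L, seed = 1L, conf = 0.95) {
  if (length(qalys) == 0L || !is.numeric(qalys) || any(is.na(qalys)))
    stop("`qalys` must be a non-empty numeric vector", call. = FALSE)
  reps <- withr_seed(seed, {
    vapply(seq_len(B), function(b) mean(sample(qalys, replace = TRUE)),
           numeric(1))
  })
  alpha <- 1 - conf
  list(mean = mean(qalys),
       ci = unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 6)),
       n = length(qalys))
}
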