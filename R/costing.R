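#' Define one costed resource item
#'
#' A resource item is either recurring (charged `frequency_per_week` times a
#' week for the whole horizon) or one-off (charged once regardless of
#' frequency, e.g. a smartphone supplied at enrolment).
#'
#' @param name Item label.
#' @param unit_cost_naira Unit cost in naira (non-negative).
#' @param frequency_per_week Charges per week for recurring items; ignored
#'   for one-off items.
#' @param one_off Logical; `TRUE` for a single charge at enrolment.
#' @param arms Character vector of arm labels the item applies to.
#' @return A list of class `resource_item`.
#' @export
resource_item <- function(name, unit_cost_naira, frequency_per_week = 0,
                          one_off = FALSE, arms) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(unit_cost_naira) || unit_cost_naira < 0)
    stop("`unit_cost_naira` must be non-negative", call. = FALSE)
  if (!is.numeric(frequency_per_week) || frequency_per_week < 0)
    stop("`frequency_per_week` must be non-negative", call. = FALSE)
  if (missing(arms) || length(arms) == 0L)
    stop("`arms` must name at least one arm", call. = FALSE)
  structure(list(name = name,
                 unit_cost_naira = unit_cost_naira,
                 frequency_per_week = frequency_per_week,
                 one_off = isTRUE(one_off),
                 arms = as.character(arms)),
            class = "resource_item")
}

#' Assemble a cost model
#'
#' @param items List of [resource_item()] objects.
#' @param exchange_rate Naira per US dollar (default 360, the rate implied
#'   by every printed naira/USD pair in the source protocol costs, e.g.
#'   20,000 naira = US$55.56).
#' @param horizon_weeks Costing horizon in weeks (default 8).
#' @return A list of class `cost_model`.
#' @export
cost_model <- function(items, exchange_rate = 360, horizon_weeks = 8) {
  if (!is.list(items) || !all(vapply(items, inherits, logical(1), "resource_item")))
    stop("`items` must be a list of resource_item objects", call. = FALSE)
  if (!is.numeric(exchange_rate) || exchange_rate <= 0)
    stop("`exchange_rate` must be positive", call. = FALSE)
  if (!is.numeric(horizon_weeks) || horizon_weeks <= 0)
    stop("`horizon_weeks` must be positive", call. = FALSE)
  structure(list(items = items, exchange_rate = exchange_rate,
                 horizon_weeks = horizon_weeks),
            class = "cost_model")
}

#' Protocol cost model for the telerehabilitation trial
#'
#' The default direct-implementation cost configuration over an 8-week
#' horizon: SMS/reminder calls (50 naira, 3x/week, both arms), a compatible
#' smartphone for the app (20,000 naira one-off, telerehabilitation arm
#' only), pre-randomization physiotherapy consultation (1,000 naira one-off,
#' both arms), clinic visits (1,000 naira, 3x/week) and transport plus
#' refreshment per visit (500 naira, 3x/week) for the clinic arm only.
#' Medication and indirect/personal costs are excluded. Per-arm totals are
#' 22,200 naira (telerehabilitation) and 38,200 naira (clinic).
#'
#' @param exchange_rate Naira per USD (default 360).
#' @param horizon_weeks Costing horizon (default 8).
#' @return A `cost_model`.
#' @export
default_cost_model <- function(exchange_rate = 360, horizon_weeks = 8) {
  cost_model(list(
    resource_item("SMS messages and reminder calls", 50, 3, FALSE, c("TBMT", "CBMT")),
    resource_item("Compatible phone for the app", 20000, 0, TRUE, "TBMT"),
    resource_item("Clinic visit", 1000, 3, FALSE, "CBMT"),
    resource_item("Consultation fee", 1000, 0, TRUE, c("TBMT", "CBMT")),
    resource_item("Transportation and refreshment", 500, 3, FALSE, "CBMT")
  ), exchange_rate = exchange_rate, horizon_weeks = horizon_weeks)
}

#' Cost of one resource item over the horizon
#'
#' @param item A [resource_item()].
#' @param horizon_weeks Horizon in weeks.
#' @return Cost in naira: the unit cost for one-off items, otherwise
#'   `unit_cost * frequency_per_week * horizon_weeks`.
#' @export
item_cost <- function(item, horizon_weeks) {
  stopifnot(inherits(item, "resource_item"))
  if (!is.numeric(horizon_weeks) || horizon_weeks <= 0)
    stop("`horizon_weeks` must be positive", call. = FALSE)
  if (item$one_off) item$unit_cost_naira
  else item$unit_cost_naira * item$frequency_per_week * horizon_weeks
}

#' Total per-participant cost of an arm, in naira
#'
#' Sums [item_cost()] over the items applicable to the arm. With integer
#' unit costs the arithmetic is exact.
#'
#' @param model A [cost_model()].
#' @param arm Arm label.
#' @return Total cost per participant in naira.
#' @examples
#' arm_total_cost_naira(default_cost_model(), "TBMT") # 22200
#' @export
arm_total_cost_naira <- function(model, arm) {
  stopifnot(inherits(model, "cost_model"), is.character(arm), length(arm) == 1L)
  if (length(model$items) == 0L) return(0)
  known <- unique(unlist(lapply(model$items, `[[`, "arms")))
  if (!arm %in% known)
    stop(sprintf("unknown arm '%s'; cost model covers: %s",
                 arm, paste(known, collapse = ", ")), call. = FALSE)
  applicable <- Filter(function(it) arm %in% it$arms, model$items)
  sum(vapply(applicable, item_cost, numeric(1),
             horizon_weeks = model$horizon_weeks))
}

#' Convert naira to US dollars
#'
#' Conversion is a display step only; all accounting is done in naira.
#'
#' @param amount Amount(s) in naira.
#' @param rate Naira per USD (positive).
#' @param digits Decimal places for display rounding; `NULL` for unrounded.
#' @return Amount in USD.
#' @examples
#' naira_to_usd(22200, 360) # 61.67
#' @export
naira_to_usd <- function(amount, rate = 360, digits = 2) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive naira-per-USD exchange rate", call. = FALSE)
  usd <- amount / rate
  if (is.null(digits)) usd else round(usd, digits)
}

#' Per-arm cost breakdown table
#'
#' Produces an itemised per-participant cost table for each arm, in naira
#' and USD. The USD display follows the convention used in the source cost
#' table: the unit cost is converted and rounded to 2 decimals, multiplied
#' by the number of charges, rounded to 1 decimal, and the USD column total
#' is the sum of those rounded item values (giving 61.8 and 106.3 for the
#' default model, alongside exact naira totals 22,200 and 38,200).
#'
#' @param model A [cost_model()].
#' @param arms Arm labels to tabulate; defaults to every arm in the model.
#' @return A data frame with one row per item per arm plus a total row per
#'   arm: columns `arm`, `item`, `unit_cost_naira`, `n_charges`,
#'   `cost_naira`, `cost_usd`.
#' @export
cost_breakdown <- function(model, arms = NULL) {
  stopifnot(inherits(model, "cost_model"))
  if (is.null(arms))
    arms <- unique(unlist(lapply(model$items, `[[`, "arms")))
  rows <- do.call(rbind, lapply(arms, function(arm) {
    applicable <- Filter(function(it) arm %in% it$arms, model$items)
    item_rows <- do.call(rbind, lapply(applicable, function(it) {
      n_charges <- if (it$one_off) 1 else it$frequency_per_week * model$horizon_weeks
      unit_usd <- round(it$unit_cost_naira / model$exchange_rate, 2)
      data.frame(arm = arm, item = it$name,
                 unit_cost_naira = it$unit_cost_naira,
                 n_charges = n_charges,
                 cost_naira = item_cost(it, model$horizon_weeks),
                 cost_usd = round(unit_usd * n_charges, 1))
    }))
    total <- data.frame(arm = arm, item = "Total",
                        unit_cost_naira = NA_real_, n_charges = NA_real_,
                        cost_naira = sum(item_rows$cost_naira),
                        cost_usd = sum(item_rows$cost_usd))
    rbind(item_rows, total)
  }))
  rownames(rows) <- NULL
  rows
}

#' Read a cost model from a YAML configuration file
#'
#' The file mirrors the protocol cost table: a top-level `exchange_rate`,
#' `horizon_weeks`, and an `items` list in which every entry has `name`,
#' `unit_cost_naira`, `arms`, and either `one_off: true` or a
#' `frequency_per_week`.
#'
#' @param path Path to the YAML file.
#' @return A [cost_model()].
#' @seealso [write_cost_model()]
#' @export
read_cost_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  items <- lapply(cfg$items, function(it) {
    resource_item(name = it$name,
                  unit_cost_naira = it$unit_cost_naira,
                  frequency_per_week = it$frequency_per_week %||% 0,
                  one_off = isTRUE(it$one_off),
                  arms = it$arms)
  })
  cost_model(items,
             exchange_rate = cfg$exchange_rate %||% 360,
             horizon_weeks = cfg$horizon_weeks %||% 8)
}

#' Write a cost model to a YAML configuration file
#'
#' @param model A [cost_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_model <- function(model, path) {
  stopifnot(inherits(model, "cost_model"))
  cfg <- list(exchange_rate = model$exchange_rate,
              horizon_weeks = model$horizon_weeks,
              items = lapply(model$items, function(it) {
                list(name = it$name,
                     unit_cost_naira = it$unit_cost_naira,
                     frequency_per_week = it$frequency_per_week,
                     one_off = it$one_off,
                     arms = as.list(it$arms))
              }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
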