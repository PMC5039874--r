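discount_weights <- function(n_cycles, cycle_length_years, discount_rate) {
  # start-of-cycle discounting; identity at rate 0
  (1 + discount_rate)^(-(seq_len(n_cycles) - 1) * cycle_length_years)
}

#' Life-years accrued by a cohort trace
#'
#' Each cycle contributes its full length for every patient alive at cycle
#' start (no half-cycle correction).
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param cycle_length_years cycle length; defaults to the trace's own.
#' @param discount_rate annual discount rate (0 in the base case).
#' @return undiscounted (or discounted) life-years over the horizon.
#' @export
accrue_life_years <- function(trace, cycle_length_years = NULL,
                              discount_rate = 0) {
  cl <- if (is.null(cycle_length_years)) trace$cycle_length_years
        else cycle_length_years
  alive <- 1 - trace$occupancy[, "dead"]
  w <- discount_weights(nrow(trace$occupancy), cl, discount_rate)
  sum(cl * alive * w)
}

#' QALYs accrued by a cohort trace
#'
#' Time in each angina state, valued at its utility weight; death contributes
#' nothing.
#'
#' @inheritParams accrue_life_years
#' @param utilities QALY weight per angina state.
#' @return quality-adjusted life-years over the horizon.
#' @export
accrue_qalys <- function(trace, utilities, cycle_length_years = NULL,
                         discount_rate = 0) {
  cl <- if (is.null(cycle_length_years)) trace$cycle_length_years
        else cycle_length_years
  u <- named4(utilities, "utilities")
  w <- discount_weights(nrow(trace$occupancy), cl, discount_rate)
  sum(cl * w * (trace$occupancy[, angina_states(), drop = FALSE] %*% u))
}

#' Costs accrued by a cohort trace, by category
#'
#' State-dependent medical costs accrue at one quarter of the annual cost per
#' cycle of state occupancy; drug acquisition accrues at three monthly costs
#' per cycle for every patient alive at cycle start. The dead state accrues
#' nothing.
#'
#' @inheritParams accrue_life_years
#' @param costs category x state matrix of annual costs (see
#'   [cea_parameters()]).
#' @param monthly_drug_cost strategy drug cost, EUR per patient-month.
#' @return named vector: `drug` plus the five [cost_categories()].
#' @export
accrue_costs <- function(trace, costs, monthly_drug_cost,
                         cycle_length_years = NULL, discount_rate = 0) {
  cl <- if (is.null(cycle_length_years)) trace$cycle_length_years
        else cycle_length_years
  occ <- trace$occupancy[, angina_states(), drop = FALSE]
  w <- discount_weights(nrow(occ), cl, discount_rate)
  state_time <- as.vector(t(occ) %*% w)       # discounted cycles per state
  by_cat <- as.vector(costs %*% state_time) * cl
  names(by_cat) <- rownames(costs)
  alive <- 1 - trace$occupancy[, "dead"]
  drug <- monthly_drug_cost * (12 * cl) * sum(alive * w)
  c(drug = drug, by_cat)
}

#' Evaluate one strategy end to end
#'
#' Runs the cohort and accrues life-years, QALYs and per-category costs,
#' applying the configured discount rate (identity at 0).
#'
#' @param params a validated `cea_parameters` object.
#' @param strategy a [strategy_spec()] or `"intervention"`/`"comparator"`.
#' @return an `economic_result`: `strategy`, `total_cost`,
#'   `cost_by_category`, `qalys`, `life_years`.
#' @export
evaluate_strategy <- function(params, strategy) {
  strategy <- resolve_strategy(params, strategy)
  trace <- run_cohort(params, strategy)
  by_cat <- accrue_costs(trace, params$costs, strategy$monthly_drug_cost,
                         discount_rate = params$discount_rate)
  structure(
    list(strategy = strategy$name,
         total_cost = sum(by_cat),
         cost_by_category = by_cat,
         qalys = accrue_qalys(trace, params$utilities,
                              discount_rate = params$discount_rate),
         life_years = accrue_life_years(trace,
                                        discount_rate = params$discount_rate)),
    class = "economic_result")
}

#' @export
print.economic_result <- function(x, ...) {
  cat(sprintf("%s: cost %.2f (drug %.2f), QALYs %.4f, LYs %.4f\n",
              x$strategy, x$total_cost, x$cost_by_category["drug"],
              x$qalys, x$life_years))
  invisible(x)
}

#' Incremental comparison of two evaluated strategies
#'
#' Differences are taken on unrounded totals. The ICER is reported only for a
#' genuine trade-off (non-zero QALY difference with cost and effect moving in
#' the same direction); dominance and equality are flagged instead of forcing
#' a ratio.
#'
#' @param intervention,comparator `economic_result` objects on the same
#'   horizon.
#' @return an `incremental_result`: `delta_cost`, `delta_effect`, `icer`
#'   (`NA` unless classification is `tradeoff_icer`), `classification` (one
#'   of `intervention_dominant`, `comparator_dominant`, `tradeoff_icer`,
#'   `equal`).
#' @export
incremental_analysis <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$qalys - comparator$qalys
  cls <- if (dc == 0 && de == 0) "equal"
    else if (dc <= 0 && de >= 0) "intervention_dominant"
    else if (dc >= 0 && de <= 0) "comparator_dominant"
    else "tradeoff_icer"
  icer <- if (cls == "tradeoff_icer") dc / de else NA_real_
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 classification = cls,
                 intervention = intervention$strategy,
                 comparator = comparator$strategy),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, wtp = NULL, ...) {
  cat(sprintf("%s vs %s: dCost %.2f, dQALY %.4f -> %s",
              x$intervention, x$comparator, x$delta_cost, x$delta_effect,
              x$classification))
  if (!is.na(x$icer)) cat(sprintf(" (ICER %.2f per QALY)", x$icer))
  cat("\n")
  if (!is.null(wtp) && !is.na(x$icer))
    cat(sprintf("  at WTP %s/QALY: %s\n", format(wtp, big.mark = ","),
                if (x$delta_effect > 0 && x$icer <= wtp) "cost-effective"
                else "not cost-effective"))
  invisible(x)
}

#' Net monetary benefit of a strategy
#'
#' `wtp * QALYs - total cost`: the strategy with the higher net monetary
#' benefit at a willingness-to-pay threshold is the preferred one, which
#' sidesteps ratio pathologies near zero QALY differences.
#'
#' @param result an `economic_result`.
#' @param wtp willingness to pay, EUR per QALY (non-negative).
#' @return net monetary benefit in EUR.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$qalys - result$total_cost
}

#' Deterministic base-case analysis
#'
#' Evaluates both strategies and their incremental comparison: the package's
#' headline deterministic result.
#'
#' @param params a validated `cea_parameters` object.
#' @return a `cea_base_case` list: `intervention` and `comparator`
#'   (`economic_result`s), `incremental`, and `wtp_threshold`.
#' @export
base_case <- function(params) {
  int <- evaluate_strategy(params, "intervention")
  comp <- evaluate_strategy(params, "comparator")
  structure(list(intervention = int, comparator = comp,
                 incremental = incremental_analysis(int, comp),
                 wtp_threshold = params$wtp_threshold),
            class = "cea_base_case")
}

#' @export
print.cea_base_case <- function(x, ...) {
  print(base_case_table(x), row.names = FALSE)
  inc <- x$incremental
  if (!is.na(inc$icer)) {
    verdict <- if (inc$delta_effect > 0 && inc$icer <= x$wtp_threshold)
      "cost-effective" else "not cost-effective"
    cat(sprintf("ICER %.2f per QALY gained: %s at WTP %s/QALY\n",
                inc$icer, verdict, format(x$wtp_threshold, big.mark = ",")))
  } else cat("classification:", inc$classification, "\n")
  invisible(x)
}

#' Deterministic results in the published table layout
#'
#' One row per cost category, totals, QALYs, life-years and the ICER;
#' columns: intervention, comparator, incremental.
#'
#' @param x a `cea_base_case` (or a `cea_parameters` object, which is
#'   evaluated first).
#' @return data.frame with columns `quantity`, `intervention`, `comparator`,
#'   `incremental`.
#' @export
base_case_table <- function(x) {
  if (inherits(x, "cea_parameters")) x <- base_case(x)
  stopifnot(inherits(x, "cea_base_case"))
  a <- x$intervention; b <- x$comparator
  cats <- c("drug", cost_categories())
  rows <- data.frame(
    quantity = c("total_cost", paste0("cost_", cats), "qalys", "life_years",
                 "icer"),
    intervention = c(a$total_cost, a$cost_by_category[cats], a$qalys,
                     a$life_years, NA),
    comparator = c(b$total_cost, b$cost_by_category[cats], b$qalys,
                   b$life_years, NA),
    stringsAsFactors = FALSE)
  rows$incremental <- rows$intervention - rows$comparator
  rows$incremental[rows$quantity == "icer"] <- x$incremental$icer
  rows
}
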