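#' Enumerate the scalar parameters entering the tornado analysis
#'
#' The default handle set covers the independent clinical inputs -- every
#' first-cycle transition probability of both strategies other than the
#' stay-in-state cells (which are the residuals completing each row to 1),
#' the four state utilities and the four annual mortality probabilities --
#' and, as cost inputs, every per-state category cost. Clinical handles are
#' varied by +/-10\% and cost handles by +/-20\% in [run_owsa()].
#'
#' Drug acquisition costs are administered prices and are not part of the
#' default tornado; they are examined through [rebate_scenario()] instead
#' (and are likewise held fixed in the PSA). Set `drug_costs = TRUE` (and,
#' if wanted, `stay_cells = TRUE`) to widen the set.
#'
#' @param params a `cea_parameters` object.
#' @param stay_cells include the stay-in-state transition cells as handles.
#' @param drug_costs include the two monthly drug costs as cost handles.
#' @return data.frame with columns `id` and `kind` (`clinical` or `cost`).
#' @export
parameter_handles <- function(params, stay_cells = FALSE,
                              drug_costs = FALSE) {
  ids <- character(); kind <- character()
  for (role in c("intervention", "comparator")) {
    for (i in angina_states()) for (j in angina_states()) {
      if (i == j && !stay_cells) next
      ids <- c(ids, paste("transition", role, i, j, sep = "."))
      kind <- c(kind, "clinical")
    }
  }
  ids <- c(ids, paste0("utility.", angina_states()),
           paste0("mortality.", angina_states()))
  kind <- c(kind, rep("clinical", 8L))
  for (k in cost_categories()) for (st in angina_states()) {
    ids <- c(ids, paste("cost", k, st, sep = "."))
    kind <- c(kind, "cost")
  }
  if (drug_costs) {
    ids <- c(ids, "drug_cost.intervention", "drug_cost.comparator")
    kind <- c(kind, "cost", "cost")
  }
  data.frame(id = ids, kind = kind, stringsAsFactors = FALSE)
}

#' Read one scalar parameter by handle id
#'
#' @param params a `cea_parameters` object.
#' @param id handle id as produced by [parameter_handles()], e.g.
#'   `"transition.intervention.moderate.mild"` or
#'   `"cost.hosp_revasc.minimal"`.
#' @return the scalar value.
#' @export
get_parameter <- function(params, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  bad <- function() stop("unknown parameter handle: ", id, call. = FALSE)
  switch(parts[1],
    transition = {
      if (length(parts) != 4L) bad()
      if (!parts[2] %in% names(params$strategies)) bad()
      tm <- params$strategies[[parts[2]]]$transition
      if (!parts[3] %in% angina_states() || !parts[4] %in% angina_states())
        bad()
      tm[parts[3], parts[4]]
    },
    utility = if (length(parts) == 2L && parts[2] %in% angina_states())
      params$utilities[[parts[2]]] else bad(),
    mortality = if (length(parts) == 2L && parts[2] %in% angina_states())
      params$mortality[[parts[2]]] else bad(),
    cost = if (length(parts) == 3L && parts[2] %in% cost_categories() &&
               parts[3] %in% angina_states())
      params$costs[parts[2], parts[3]] else bad(),
    drug_cost = if (length(parts) == 2L &&
                    parts[2] %in% names(params$strategies))
      params$strategies[[parts[2]]]$monthly_drug_cost else bad(),
    bad())
}

#' Multiply one parameter by a factor, keeping the model coherent
#'
#' Returns a modified copy; the input is never touched. Perturbing a
#' transition probability keeps its row stochastic, in one of two ways:
#' `"proportional"` (default) rescales the other three entries of the row
#' proportionally, while `"stay_state"` absorbs the whole change in the
#' row's stay-in-state cell -- the parameterization in which off-diagonal
#' probabilities are independent inputs and the diagonal is the residual
#' `1 - sum(others)`. Utilities are capped at 1. A perturbation that would
#' push a probability above 1, or that hits a row that cannot absorb the
#' change, is an error.
#'
#' @inheritParams get_parameter
#' @param factor positive multiplier applied to the target scalar.
#' @param balance how a transition row is rebalanced (see above); ignored
#'   for non-transition handles.
#' @return a new `cea_parameters` object.
#' @export
perturb_parameter <- function(params, id, factor,
                              balance = c("proportional", "stay_state")) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  balance <- match.arg(balance)
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  out <- params
  old <- get_parameter(params, id)
  new <- old * factor
  switch(parts[1],
    transition = {
      tm <- out$strategies[[parts[2]]]$transition
      if (new > 1)
        stop("perturbing ", id, " by ", factor,
             " pushes the probability above 1", call. = FALSE)
      from <- parts[3]; to <- parts[4]
      if (balance == "stay_state" && from != to) {
        resid <- tm[from, from] - (new - old)
        if (resid < 0)
          stop("perturbing ", id, " by ", factor,
               " exceeds the row's stay-in-state residual", call. = FALSE)
        tm[from, to] <- new
        tm[from, from] <- resid
      } else {
        row <- tm[from, ]
        rest <- setdiff(angina_states(), to)
        if (sum(row[rest]) == 0 && new != 1)
          stop("cannot renormalize row '", from,
               "': complementary probabilities are all zero", call. = FALSE)
        row[to] <- new
        if (sum(row[rest]) > 0)
          row[rest] <- row[rest] * (1 - new) / sum(row[rest])
        tm[from, ] <- row
      }
      out$strategies[[parts[2]]]$transition <- tm
    },
    utility = out$utilities[parts[2]] <- min(new, 1),
    mortality = {
      if (new >= 1)
        stop("perturbing ", id, " by ", factor,
             " pushes the annual probability to 1 or above", call. = FALSE)
      out$mortality[parts[2]] <- new
    },
    cost = out$costs[parts[2], parts[3]] <- new,
    drug_cost = out$strategies[[parts[2]]]$monthly_drug_cost <- new)
  out
}

#' One-way sensitivity analysis with tornado ranking
#'
#' Each handle is set to its low (`1 - f`) and high (`1 + f`) bound and the
#' full incremental analysis recomputed at each endpoint. Transition handles
#' are rebalanced against their row's stay-in-state cell by default (see
#' [perturb_parameter()]); an increase that would exhaust the residual cell
#' is clamped to the feasible boundary.
#'
#' Handles are ranked by the width of the signed cost-per-QALY interval
#' spanned by the two endpoints: `delta_cost / delta_effect` is taken as the
#' endpoint's position even when the intervention dominates (negative
#' ratio), so dominance widens rather than breaks the bar. Only when an
#' endpoint reverses the sign of the QALY difference -- where a
#' cost-per-QALY scale stops being meaningful -- does the spread fall back
#' to the incremental net-monetary-benefit range at `wtp`, keeping the
#' ordering always defined. Ties break by handle id, so the ranking is
#' invariant to input order.
#'
#' @param params a validated `cea_parameters` object.
#' @param handles data.frame of handles (default [parameter_handles()]).
#' @param cost_factor,clinical_factor half-widths of the relative ranges
#'   (defaults 0.20 for costs, 0.10 for clinical inputs).
#' @param wtp willingness to pay used for the ICER verdicts and the
#'   net-benefit fallback; defaults to the configured threshold.
#' @param balance row-rebalancing rule for transition handles (default
#'   `"stay_state"`).
#' @return an `owsa_result` data.frame: `id`, `kind`, `low_value`,
#'   `high_value`, `icer_low`, `icer_high` (`NA` under dominance),
#'   `classification_low`, `classification_high`, `ratio_low`, `ratio_high`
#'   (signed), `nmb_diff_low`, `nmb_diff_high`, `spread`, `rank`, sorted by
#'   decreasing spread.
#' @export
run_owsa <- function(params, handles = parameter_handles(params),
                     cost_factor = 0.2, clinical_factor = 0.1,
                     wtp = params$wtp_threshold,
                     balance = c("stay_state", "proportional")) {
  balance <- match.arg(balance)
  n <- nrow(handles)
  out <- handles
  num_cols <- c("low_value", "high_value", "icer_low", "icer_high",
                "ratio_low", "ratio_high", "nmb_diff_low", "nmb_diff_high",
                "spread")
  for (cl in num_cols) out[[cl]] <- rep(NA_real_, n)
  out$classification_low <- out$classification_high <- rep(NA_character_, n)
  if (n == 0L) {
    out$rank <- integer(0)
    class(out) <- c("owsa_result", "data.frame")
    return(out)
  }
  endpoint <- function(id, f) {
    # clamp relative increases that are infeasible for probabilities
    old <- get_parameter(params, id)
    if (f > 1 && old > 0 && grepl("^(transition|mortality)\\.", id)) {
      cap <- (1 - 1e-12) / old
      if (balance == "stay_state" && grepl("^transition\\.", id)) {
        parts <- strsplit(id, ".", fixed = TRUE)[[1]]
        if (parts[3] != parts[4]) {
          tm <- params$strategies[[parts[2]]]$transition
          cap <- min(cap, (old + tm[parts[3], parts[3]]) / old)
        }
      }
      f <- min(f, cap)
    }
    p <- perturb_parameter(params, id, f, balance = balance)
    int <- evaluate_strategy(p, "intervention")
    comp <- evaluate_strategy(p, "comparator")
    inc <- incremental_analysis(int, comp)
    list(value = get_parameter(p, id), icer = inc$icer,
         classification = inc$classification,
         ratio = if (inc$delta_effect > 0)
           inc$delta_cost / inc$delta_effect else NA_real_,
         nmb_diff = net_monetary_benefit(int, wtp) -
           net_monetary_benefit(comp, wtp))
  }
  for (i in seq_len(n)) {
    f <- if (out$kind[i] == "cost") cost_factor else clinical_factor
    lo <- endpoint(out$id[i], 1 - f)
    hi <- endpoint(out$id[i], 1 + f)
    out$low_value[i] <- lo$value; out$high_value[i] <- hi$value
    out$icer_low[i] <- lo$icer; out$icer_high[i] <- hi$icer
    out$ratio_low[i] <- lo$ratio; out$ratio_high[i] <- hi$ratio
    out$classification_low[i] <- lo$classification
    out$classification_high[i] <- hi$classification
    out$nmb_diff_low[i] <- lo$nmb_diff; out$nmb_diff_high[i] <- hi$nmb_diff
    out$spread[i] <- if (!is.na(lo$ratio) && !is.na(hi$ratio))
      abs(hi$ratio - lo$ratio) else abs(hi$nmb_diff - lo$nmb_diff)
  }
  out <- out[order(-out$spread, out$id), ]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  class(out) <- c("owsa_result", "data.frame")
  out
}

#' Volume-rebate scenario on drug prices
#'
#' Reduces both strategies' net monthly drug costs by the rebate fraction and
#' recomputes the full incremental analysis. QALYs are untouched, so only the
#' cost difference moves.
#'
#' @param params a validated `cea_parameters` object.
#' @param rebate_fraction rebate in `[0, 1)` applied to both monthly drug
#'   costs.
#' @return an `incremental_result` with the rebate recorded as attribute
#'   `rebate_fraction`.
#' @export
rebate_scenario <- function(params, rebate_fraction) {
  stopifnot(is.numeric(rebate_fraction), length(rebate_fraction) == 1L,
            rebate_fraction >= 0, rebate_fraction < 1)
  p <- params
  for (role in names(p$strategies))
    p$strategies[[role]]$monthly_drug_cost <-
      p$strategies[[role]]$monthly_drug_cost * (1 - rebate_fraction)
  res <- incremental_analysis(evaluate_strategy(p, "intervention"),
                              evaluate_strategy(p, "comparator"))
  attr(res, "rebate_fraction") <- rebate_fraction
  res
}
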