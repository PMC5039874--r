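#' Convert an annual probability to a per-cycle probability
#'
#' Constant-rate conversion: the annual probability is turned into a rate and
#' the rate split evenly over the cycles of the year, so
#' `p_cycle = 1 - exp(log(1 - p_annual) / cycles_per_year)` and
#' `1 - (1 - p_cycle)^cycles_per_year` recovers `p_annual` exactly.
#'
#' @param p_annual annual probability in `[0, 1)`; vectorized.
#' @param cycles_per_year number of equal cycles per year (4 for a 3-month
#'   cycle).
#' @return per-cycle probability, in `[0, p_annual]`.
#' @export
annual_to_cycle_probability <- function(p_annual, cycles_per_year = 4L) {
  if (any(cycles_per_year < 1)) stop("cycles_per_year must be >= 1",
                                     call. = FALSE)
  if (any(is.na(p_annual)) || any(p_annual < 0) || any(p_annual >= 1))
    stop("p_annual must lie in [0, 1): the rate is undefined at 1",
         call. = FALSE)
  1 - exp(log(1 - p_annual) / cycles_per_year)
}

resolve_strategy <- function(params, strategy) {
  if (inherits(strategy, "strategy_spec")) return(strategy)
  if (is.character(strategy) && length(strategy) == 1L &&
      strategy %in% names(params$strategies))
    return(params$strategies[[strategy]])
  stop("strategy must be a strategy_spec or one of ",
       paste(sQuote(names(params$strategies)), collapse = ", "),
       call. = FALSE)
}

cycle_death_probs <- function(params) {
  annual_to_cycle_probability(params$mortality,
                              round(1 / params$cycle_length_years))
}

#' Full per-cycle transition matrix including death
#'
#' Builds the 5x5 row-stochastic matrix governing one model cycle. Death is
#' state-dependent but strategy-independent and acts at the end of the cycle
#' on the state occupied during it; survivors change angina state at the end
#' of cycle 1 only (treatment effect observed over the first 3 months), and
#' remain in their state from cycle 2 onward.
#'
#' @param params a `cea_parameters` object.
#' @param strategy a [strategy_spec()] or `"intervention"`/`"comparator"`.
#' @param cycle_index cycle number, 1-based, at most `params$n_cycles`.
#' @return 5x5 matrix with rows/columns [health_states()], rows summing to 1.
#' @export
cycle_transition_matrix <- function(params, strategy, cycle_index) {
  if (length(cycle_index) != 1L || is.na(cycle_index) ||
      cycle_index < 1 || cycle_index > params$n_cycles)
    stop("cycle_index must be in 1..", params$n_cycles, call. = FALSE)
  strategy <- resolve_strategy(params, strategy)
  d <- cycle_death_probs(params)
  P <- matrix(0, 5, 5, dimnames = list(health_states(), health_states()))
  if (cycle_index == 1) {
    P[1:4, 1:4] <- (1 - d) * unclass(strategy$transition)[, ]
  } else {
    diag(P)[1:4] <- 1 - d
  }
  P[1:4, 5] <- d
  P[5, 5] <- 1
  P
}

#' Propagate the cohort through the model
#'
#' Starts the full cohort in the baseline angina distribution (no deaths at
#' entry) and applies [cycle_transition_matrix()] cycle by cycle. Occupancy is
#' recorded at the start of each cycle -- the convention under which rewards
#' accrue -- with the end-of-horizon distribution kept separately.
#'
#' @param params a validated `cea_parameters` object.
#' @param strategy a [strategy_spec()] or `"intervention"`/`"comparator"`.
#' @return a `cohort_trace`: list with `occupancy` (`n_cycles` x 5 matrix of
#'   start-of-cycle proportions), `final_distribution` (state distribution
#'   after the last cycle), `strategy`, and `cycle_length_years`.
#' @export
run_cohort <- function(params, strategy) {
  viol <- validate_parameters(params)
  if (length(viol))
    stop("invalid parameters:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  strategy <- resolve_strategy(params, strategy)
  n <- params$n_cycles
  occ <- matrix(0, n, 5, dimnames = list(paste0("cycle_", seq_len(n)),
                                         health_states()))
  state <- c(params$baseline, dead = 0)
  for (cyc in seq_len(n)) {
    occ[cyc, ] <- state
    state <- as.vector(state %*% cycle_transition_matrix(params, strategy, cyc))
    names(state) <- health_states()
  }
  stopifnot(all(abs(rowSums(occ) - 1) < ROW_SUM_TOL))
  structure(list(occupancy = occ,
                 final_distribution = state,
                 strategy = strategy$name,
                 cycle_length_years = params$cycle_length_years),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", x$strategy, "\n")
  print(round(x$occupancy, 4))
  cat("final:", paste(sprintf("%s %.4f", names(x$final_distribution),
                              x$final_distribution), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy export of a cohort trace
#'
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @return data.frame with columns `cycle`, `state`, `occupancy`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  data.frame(cycle = rep(seq_len(n), times = 5L),
             state = rep(health_states(), each = n),
             occupancy = as.vector(x$occupancy),
             stringsAsFactors = FALSE)
}
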