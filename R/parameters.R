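#' Health states of the angina model
#'
#' The model distinguishes four living states ordered by angina severity
#' (defined by the frequency of angina episodes: less than weekly, weekly,
#' several times per week, several times per day) plus an absorbing death
#' state.
#'
#' @format `angina_states()` returns the four living states in severity
#'   order; `health_states()` appends `"dead"`.
#' @export
angina_states <- function() c("minimal", "mild", "moderate", "severe")

#' @rdname angina_states
#' @export
health_states <- function() c(angina_states(), "dead")

#' Cost categories tracked by the model
#'
#' Five state-dependent medical cost categories (annual EUR per patient-year)
#' plus drug acquisition, which is handled separately as a monthly cost per
#' strategy.
#' @export
cost_categories <- function() {
  c("outpatient_visits", "diagnostic_tests", "laboratory_tests",
    "hosp_no_revasc", "hosp_revasc")
}

# row-sum slack accepted before renormalization fails: printed transition
# tables carry 2-decimal rounding, so rows may sum to e.g. 0.9999 or 1.0001
ROW_SUM_SLACK <- 0.005
ROW_SUM_TOL <- 1e-9

#' Construct a 4x4 angina transition matrix
#'
#' Rows are origin states, columns destination states, both in severity order;
#' entries are 3-month transition probabilities conditional on surviving the
#' cycle. Rows whose sums deviate from 1 by at most 0.5\% (printed-table
#' rounding) are renormalized proportionally; larger deviations are errors.
#'
#' @param x numeric 4x4 matrix (or object coercible to one) of probabilities
#'   in `[0, 1]`, expressed as fractions (0.5272, not 52.72).
#' @param row_ess optional numeric vector of length 4 giving the sample size
#'   behind each row (used as Dirichlet concentration in the PSA when the
#'   uncertainty specification asks for observed row denominators).
#' @return matrix with state dimnames, rows summing to 1 within 1e-9,
#'   carrying `row_ess` as an attribute when supplied.
#' @export
transition_matrix <- function(x, row_ess = NULL) {
  m <- as.matrix(x)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    stop("transition matrix must be a numeric 4x4 matrix", call. = FALSE)
  if (anyNA(m)) stop("transition matrix contains missing values", call. = FALSE)
  if (any(m < 0) || any(m > 1))
    stop("transition probabilities must lie in [0, 1]; ",
         "percentages must be given as fractions (0.5272, not 52.72)",
         call. = FALSE)
  rs <- rowSums(m)
  bad <- abs(rs - 1) > ROW_SUM_SLACK
  if (any(bad))
    stop("transition matrix row(s) ", paste(which(bad), collapse = ", "),
         " sum to ", paste(signif(rs[bad], 6), collapse = ", "),
         "; rows must sum to 1 within 0.5%", call. = FALSE)
  m <- m / rs
  dimnames(m) <- list(angina_states(), angina_states())
  if (!is.null(row_ess)) {
    stopifnot(is.numeric(row_ess), length(row_ess) == 4L, all(row_ess > 0))
    attr(m, "row_ess") <- as.numeric(row_ess)
  }
  m
}

#' Define a treatment strategy
#'
#' @param name label for the strategy.
#' @param transition 4x4 [transition_matrix()] of first-cycle angina
#'   transitions conditional on survival.
#' @param monthly_drug_cost net drug acquisition cost to the payer, EUR per
#'   patient-month.
#' @return a `strategy_spec` list.
#' @export
strategy_spec <- function(name, transition, monthly_drug_cost) {
  if (!is.character(name) || length(name) != 1L)
    stop("strategy name must be a single string", call. = FALSE)
  if (!is.numeric(monthly_drug_cost) || length(monthly_drug_cost) != 1L ||
      is.na(monthly_drug_cost) || monthly_drug_cost < 0)
    stop("monthly_drug_cost for strategy '", name,
         "' must be a single non-negative number", call. = FALSE)
  structure(
    list(name = name,
         transition = transition_matrix(transition,
                                        row_ess = attr(transition, "row_ess")),
         monthly_drug_cost = as.numeric(monthly_drug_cost)),
    class = "strategy_spec")
}

named4 <- function(x, what) {
  x <- unlist(x)
  if (length(x) != 4L || anyNA(x))
    stop(what, " must supply one value per angina state (minimal, mild, ",
         "moderate, severe)", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), angina_states()))
      stop(what, " has unexpected state names: ",
           paste(setdiff(names(x), angina_states()), collapse = ", "),
           call. = FALSE)
    x <- x[angina_states()]
  }
  v <- as.numeric(x)
  names(v) <- angina_states()
  v
}

#' Assemble a complete, validated parameter set
#'
#' Bundles the two strategies with the shared clinical and cost inputs into a
#' single `cea_parameters` object, the unit of work for every analysis in the
#' package. Mortality is strategy-independent.
#'
#' @param intervention,comparator [strategy_spec()] objects.
#' @param mortality annual death probability per angina state (unitless).
#' @param utilities QALY weight per angina state in `[0, 1]`; death is 0.
#' @param baseline cohort distribution over angina states at model entry;
#'   must sum to 1.
#' @param costs numeric matrix, rows = [cost_categories()], columns = angina
#'   states: annual EUR per patient-year in that state.
#' @param n_cycles number of model cycles (default 4).
#' @param cycle_length_years cycle length in years (default 0.25).
#' @param wtp_threshold willingness-to-pay benchmark, EUR per QALY.
#' @param discount_rate annual discount rate; 0 for a 1-year horizon.
#' @param currency,price_year metadata tags for reporting.
#' @return a `cea_parameters` list; [validate_parameters()] reports any
#'   violated invariant.
#' @export
cea_parameters <- function(intervention, comparator, mortality, utilities,
                           baseline, costs, n_cycles = 4L,
                           cycle_length_years = 0.25, wtp_threshold = 34000,
                           discount_rate = 0, currency = "EUR",
                           price_year = 2016L) {
  stopifnot(inherits(intervention, "strategy_spec"),
            inherits(comparator, "strategy_spec"))
  cm <- as.matrix(costs)
  if (!identical(dim(cm), c(5L, 4L))) {
    if (identical(dim(cm), c(4L, 5L))) cm <- t(cm)
    else stop("costs must be a 5 category x 4 state matrix", call. = FALSE)
  }
  if (!is.null(rownames(cm))) {
    if (!setequal(rownames(cm), cost_categories()))
      stop("cost categories must be: ",
           paste(cost_categories(), collapse = ", "), call. = FALSE)
    cm <- cm[cost_categories(), ]
  } else rownames(cm) <- cost_categories()
  if (!is.null(colnames(cm))) cm <- cm[, angina_states()]
  else colnames(cm) <- angina_states()
  p <- structure(
    list(strategies = list(intervention = intervention,
                           comparator = comparator),
         mortality = named4(mortality, "mortality"),
         utilities = named4(utilities, "utilities"),
         baseline = named4(baseline, "baseline"),
         costs = cm,
         n_cycles = as.integer(n_cycles),
         cycle_length_years = as.numeric(cycle_length_years),
         wtp_threshold = as.numeric(wtp_threshold),
         discount_rate = as.numeric(discount_rate),
         meta = list(currency = currency, price_year = price_year)),
    class = "cea_parameters")
  p
}

#' Check every model invariant and report violations
#'
#' Reports rather than raises: an empty character vector means the parameter
#' set satisfies all structural invariants (probabilities in range,
#' row-stochastic transitions, baseline summing to 1, utilities in `[0, 1]`,
#' non-negative costs, horizon consistency).
#'
#' @param params a `cea_parameters` object.
#' @return character vector of human-readable violation descriptions.
#' @export
validate_parameters <- function(params) {
  v <- character()
  if (!inherits(params, "cea_parameters"))
    return("not a cea_parameters object")
  for (role in c("intervention", "comparator")) {
    tm <- params$strategies[[role]]$transition
    if (any(tm < 0 | tm > 1))
      v <- c(v, paste0(role, ": transition probabilities outside [0, 1]"))
    bad <- abs(rowSums(tm) - 1) > ROW_SUM_TOL
    if (any(bad))
      v <- c(v, paste0(role, ": transition row(s) not summing to 1: ",
                       paste(angina_states()[bad], collapse = ", ")))
    if (params$strategies[[role]]$monthly_drug_cost < 0)
      v <- c(v, paste0(role, ": negative monthly drug cost"))
  }
  m <- params$mortality
  bad <- m < 0 | m >= 1
  if (any(bad))
    v <- c(v, paste0("mortality outside [0, 1) for state(s): ",
                     paste(names(m)[bad], collapse = ", ")))
  u <- params$utilities
  bad <- u < 0 | u > 1
  if (any(bad))
    v <- c(v, paste0("utility outside [0, 1] for state(s): ",
                     paste(names(u)[bad], collapse = ", ")))
  b <- params$baseline
  if (any(b < 0))
    v <- c(v, "baseline distribution has negative shares")
  if (abs(sum(b) - 1) > 1e-6)
    v <- c(v, paste0("baseline distribution sums to ", signif(sum(b), 6),
                     ", not 1"))
  if (any(params$costs < 0))
    v <- c(v, "negative entries in the state cost table")
  if (params$n_cycles < 1L)
    v <- c(v, "n_cycles must be at least 1")
  if (params$cycle_length_years <= 0)
    v <- c(v, "cycle_length_years must be positive")
  horizon <- params$n_cycles * params$cycle_length_years
  if (horizon <= 1 && params$discount_rate != 0)
    v <- c(v, "discount_rate must be 0 for a horizon of at most 1 year")
  v
}

#' Parameter set of the Greek chronic stable angina evaluation
#'
#' The built-in fixture: trimetazidine (TMZ) 70 mg/d added to standard of
#' care (SoC) versus SoC alone, 3-month cycles over a 1-year horizon,
#' third-party payer perspective, prices in EUR 2016.
#'
#' The published transition tables and baseline distribution are percentages
#' rounded to two decimals; every one of them is the rounding of an exact
#' trial fraction, and those fractions (with their per-row denominators) are
#' what this fixture carries. Probabilities are therefore stored at full
#' precision -- e.g. the mild-to-minimal probability under TMZ is 97/184 =
#' 0.527174, printed as 52.72\% -- and the row denominators double as
#' Dirichlet sample sizes for the probabilistic sensitivity analysis. The
#' deterministic results computed from these inputs agree with the published
#' ones to their printed precision; see the package vignette for the
#' reconstruction.
#'
#' @return a validated `cea_parameters` object.
#' @export
angina_parameters <- function() {
  # first-cycle transition counts by origin state (rows) and destination
  tmz_counts <- rbind(minimal  = c(248, 11,  3,  0),
                      mild     = c(97,  76, 10,  1),
                      moderate = c(20,  63, 16,  4),
                      severe   = c(15,  19, 26, 45))
  soc_counts <- rbind(minimal  = c(164, 17,  0,  0),
                      mild     = c(89,  80, 18,  4),
                      moderate = c(23,  39, 21,  6),
                      severe   = c(15,  34, 20, 59))
  tm <- function(k) transition_matrix(k / rowSums(k), row_ess = rowSums(k))
  # symptomatic patients only: baseline shares are the TMZ-arm state counts
  baseline <- c(minimal = 0, mild = 184, moderate = 103, severe = 105) / 392
  costs <- rbind(
    outpatient_visits = c(8.00,   15.75,  39.88,   76.50),
    diagnostic_tests  = c(41.62,  62.05,  101.00,  122.37),
    laboratory_tests  = c(20.41,  25.63,  45.31,   61.24),
    hosp_no_revasc    = c(4.67,   35.03,  331.06,  1428.63),
    hosp_revasc       = c(586.24, 683.62, 1583.23, 1972.77))
  colnames(costs) <- angina_states()
  cea_parameters(
    intervention = strategy_spec("TMZ + SoC", tm(tmz_counts), 29.18),
    comparator   = strategy_spec("SoC",       tm(soc_counts), 23.40),
    mortality = c(0.046, 0.048, 0.081, 0.109),
    utilities = c(0.81, 0.75, 0.60, 0.39),
    baseline  = baseline,
    costs     = costs,
    n_cycles = 4L, cycle_length_years = 0.25,
    wtp_threshold = 34000, discount_rate = 0)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Cost-utility model parameters (", x$meta$currency, " ",
      x$meta$price_year, ")\n", sep = "")
  cat("  strategies : ", x$strategies$intervention$name, " (",
      format(x$strategies$intervention$monthly_drug_cost), "/month) vs ",
      x$strategies$comparator$name, " (",
      format(x$strategies$comparator$monthly_drug_cost), "/month)\n", sep = "")
  cat("  horizon    : ", x$n_cycles, " cycles x ",
      x$cycle_length_years, " years\n", sep = "")
  cat("  WTP        : ", format(x$wtp_threshold, big.mark = ","),
      " per QALY\n", sep = "")
  viol <- validate_parameters(x)
  cat("  validation : ",
      if (length(viol)) paste(length(viol), "violation(s)") else "ok",
      "\n", sep = "")
  invisible(x)
}

#' Read a parameter configuration from JSON
#'
#' The configuration is a single JSON document with keys `strategies`
#' (`intervention` / `comparator`, each with `name`, `transition_matrix` and
#' `monthly_drug_cost`), `mortality`, `utilities`, `baseline`, `costs`, and
#' `settings`. All probabilities are fractions; values above 1 in probability
#' fields are rejected to prevent percent/fraction mix-ups. Transition rows
#' off 1 by at most 0.5\% (printed rounding) are renormalized.
#'
#' @param path file path to a JSON document, or an already-parsed list with
#'   the same structure.
#' @return a validated `cea_parameters` object.
#' @export
read_parameters <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) path
  else stop("read_parameters() expects a file path or a list", call. = FALSE)

  need <- function(x, key, where) {
    if (is.null(x[[key]]))
      stop("configuration is missing required key '", where, key, "'",
           call. = FALSE)
    x[[key]]
  }
  strat <- need(cfg, "strategies", "")
  build_strategy <- function(role) {
    s <- need(strat, role, "strategies.")
    tmx <- need(s, "transition_matrix", paste0("strategies.", role, "."))
    tmx <- as.matrix(tmx)
    if (any(tmx > 1))
      stop("strategies.", role, ".transition_matrix contains values above 1; ",
           "probabilities must be fractions, not percentages", call. = FALSE)
    strategy_spec(need(s, "name", paste0("strategies.", role, ".")),
                  transition_matrix(tmx, row_ess = s$row_ess),
                  need(s, "monthly_drug_cost",
                       paste0("strategies.", role, ".")))
  }
  prob_field <- function(key) {
    x <- named4(need(cfg, key, ""), key)
    if (any(x > 1))
      stop("'", key, "' contains values above 1; probabilities must be ",
           "fractions, not percentages", call. = FALSE)
    x
  }
  costs <- need(cfg, "costs", "")
  cm <- do.call(rbind, lapply(cost_categories(), function(k)
    named4(need(costs, k, "costs."), paste0("costs.", k))))
  rownames(cm) <- cost_categories()
  st <- if (is.null(cfg$settings)) list() else cfg$settings
  defaults <- list(n_cycles = 4L, cycle_length_years = 0.25,
                   wtp_threshold = 34000, discount_rate = 0,
                   currency = "EUR", price_year = 2016L)
  st <- utils::modifyList(defaults, st[!vapply(st, is.null, logical(1))])
  p <- cea_parameters(
    intervention = build_strategy("intervention"),
    comparator = build_strategy("comparator"),
    mortality = prob_field("mortality"),
    utilities = prob_field("utilities"),
    baseline = prob_field("baseline"),
    costs = cm,
    n_cycles = st$n_cycles, cycle_length_years = st$cycle_length_years,
    wtp_threshold = st$wtp_threshold, discount_rate = st$discount_rate,
    currency = st$currency, price_year = st$price_year)
  viol <- validate_parameters(p)
  if (length(viol))
    stop("invalid parameter configuration:\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  p
}

#' Serialize a parameter set to JSON
#'
#' Writes the configuration format read by [read_parameters()]; a
#' write/read round trip reproduces the parameter set to full double
#' precision.
#'
#' @param params a `cea_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  strat <- function(role) {
    s <- params$strategies[[role]]
    out <- list(name = s$name,
                transition_matrix = matrix(as.numeric(s$transition), 4, 4),
                monthly_drug_cost = s$monthly_drug_cost)
    ess <- attr(s$transition, "row_ess")
    if (!is.null(ess)) out$row_ess <- ess
    out
  }
  cfg <- list(
    strategies = list(intervention = strat("intervention"),
                      comparator = strat("comparator")),
    mortality = as.list(params$mortality),
    utilities = as.list(params$utilities),
    baseline = as.list(params$baseline),
    costs = lapply(cost_categories(), function(k)
      as.list(params$costs[k, ])),
    settings = list(n_cycles = params$n_cycles,
                    cycle_length_years = params$cycle_length_years,
                    wtp_threshold = params$wtp_threshold,
                    discount_rate = params$discount_rate,
                    currency = params$meta$currency,
                    price_year = params$meta$price_year))
  names(cfg$costs) <- cost_categories()
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Flat table of every scalar parameter
#'
#' One row per scalar with its identity, units and value -- the CSV export
#' format for audit trails.
#'
#' @param params a `cea_parameters` object.
#' @return data.frame with columns `id`, `strategy`, `state`, `category`,
#'   `value`, `units`.
#' @export
parameter_table <- function(params) {
  rows <- list()
  add <- function(id, strategy, state, category, value, units)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, strategy = strategy, state = state, category = category,
      value = value, units = units, stringsAsFactors = FALSE)
  for (role in c("intervention", "comparator")) {
    s <- params$strategies[[role]]
    tm <- s$transition
    for (i in angina_states()) for (j in angina_states())
      add(paste("transition", role, i, j, sep = "."), s$name, i, j,
          tm[i, j], "probability/cycle")
    add(paste0("drug_cost.", role), s$name, "", "drug",
        s$monthly_drug_cost, paste0(params$meta$currency, "/month"))
  }
  for (st in angina_states()) {
    add(paste0("mortality.", st), "", st, "", params$mortality[st],
        "probability/year")
    add(paste0("utility.", st), "", st, "", params$utilities[st], "QALY weight")
    add(paste0("baseline.", st), "", st, "", params$baseline[st], "proportion")
    for (k in cost_categories())
      add(paste("cost", k, st, sep = "."), "", st, k, params$costs[k, st],
          paste0(params$meta$currency, "/year"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
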