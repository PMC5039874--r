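# shared fixtures for the suite; everything is built in code

# published deterministic results (Table 4 of the source evaluation) with the
# reproduction tolerances used by the acceptance tests
published <- list(
  total_cost = c(intervention = 1755.57, comparator = 1751.76),
  qalys = c(intervention = 0.6650, comparator = 0.6562),
  life_years = c(intervention = 0.9747, comparator = 0.9743),
  drug_cost = c(intervention = 341.36, comparator = 273.61),
  delta_cost = 3.82, delta_qalys = 0.0088, icer = 430.67,
  wtp = 34000,
  tol = list(total_cost = 1.5, qalys = 1e-3, life_years = 5e-4,
             drug_cost = 1, delta_cost = 0.2, delta_qalys = 5e-4,
             icer_rel = 0.03))

# minimal hand-checkable parameter set: identity transitions, no deaths,
# perfect health, known costs
simple_params <- function(utilities = c(1, 1, 1, 1),
                          mortality = c(0, 0, 0, 0),
                          transition = diag(4),
                          baseline = c(0, 0.5, 0.25, 0.25),
                          costs = matrix(0, 5, 4,
                                         dimnames = list(cost_categories(),
                                                         angina_states())),
                          drug = c(0, 0), ...) {
  cea_parameters(
    intervention = strategy_spec("A", transition_matrix(transition), drug[1]),
    comparator = strategy_spec("B", transition_matrix(transition), drug[2]),
    mortality = mortality, utilities = utilities, baseline = baseline,
    costs = costs, ...)
}
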