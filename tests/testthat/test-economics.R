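test_that("accruals reduce to closed forms in degenerate models", {
  # zero mortality, identity transitions, perfect health: 1 life-year and
  # 1 QALY over the 1-year horizon; zero costs stay zero
  p0 <- simple_params()
  tr <- run_cohort(p0, "intervention")
  expect_equal(accrue_life_years(tr), 1)
  expect_equal(accrue_qalys(tr, p0$utilities), 1)
  costs <- accrue_costs(tr, p0$costs, 0)
  expect_equal(unname(costs), rep(0, 6))
  expect_named(costs, c("drug", cost_categories()))

  # flat utility u gives u QALYs; a single cost cell accrues
  # annual/4 * occupancy summed over cycles
  p1 <- simple_params(utilities = c(0.5, 0.5, 0.5, 0.5))
  p1$costs["hosp_revasc", "mild"] <- 100
  tr <- run_cohort(p1, "intervention")
  expect_equal(accrue_qalys(tr, p1$utilities), 0.5)
  got <- accrue_costs(tr, p1$costs, 10)
  expect_equal(got[["hosp_revasc"]], 4 * (100 / 4) * 0.5)
  expect_equal(got[["drug"]], 10 * 12)   # alive all year
})

test_that("deterministic pipeline reproduces the published strategy table", {
  p <- angina_parameters()
  bc <- base_case(p)
  res <- list(intervention = bc$intervention, comparator = bc$comparator)
  for (arm in names(res)) {
    expect_equal(res[[arm]]$total_cost, published$total_cost[[arm]],
                 tolerance = published$tol$total_cost / published$total_cost[[arm]])
    expect_equal(res[[arm]]$qalys, published$qalys[[arm]],
                 tolerance = published$tol$qalys / published$qalys[[arm]])
    expect_equal(res[[arm]]$life_years, published$life_years[[arm]],
                 tolerance = published$tol$life_years / published$life_years[[arm]])
    expect_equal(res[[arm]]$cost_by_category[["drug"]],
                 published$drug_cost[[arm]],
                 tolerance = published$tol$drug_cost / published$drug_cost[[arm]])
  }
  inc <- bc$incremental
  expect_equal(inc$classification, "tradeoff_icer")
  expect_equal(inc$icer, published$icer,
               tolerance = published$tol$icer_rel)
})

test_that("category costs add up to the total", {
  for (params in list(angina_parameters(), synthetic_parameters(4))) {
    for (role in c("intervention", "comparator")) {
      r <- evaluate_strategy(params, role)
      expect_equal(r$total_cost, sum(r$cost_by_category), tolerance = 1e-6)
      expect_lte(r$qalys, r$life_years)
      expect_lte(r$life_years,
                 params$n_cycles * params$cycle_length_years + 1e-12)
    }
  }
})

test_that("incremental classification covers all quadrants", {
  mk <- function(cost, q) structure(list(strategy = "x", total_cost = cost,
                                         qalys = q, life_years = 1),
                                    class = "economic_result")
  eq <- incremental_analysis(mk(100, 0.5), mk(100, 0.5))
  expect_identical(eq$classification, "equal")
  expect_true(is.na(eq$icer))

  dom <- incremental_analysis(mk(99, 0.51), mk(100, 0.5))
  expect_identical(dom$classification, "intervention_dominant")
  expect_true(is.na(dom$icer))

  dom2 <- incremental_analysis(mk(101, 0.49), mk(100, 0.5))
  expect_identical(dom2$classification, "comparator_dominant")

  tr <- incremental_analysis(mk(110, 0.52), mk(100, 0.5))
  expect_identical(tr$classification, "tradeoff_icer")
  expect_equal(tr$icer, 10 / 0.02)

  # zero effect difference never divides by zero
  flat <- incremental_analysis(mk(110, 0.5), mk(100, 0.5))
  expect_true(is.na(flat$icer))
  expect_identical(flat$classification, "comparator_dominant")
})

test_that("net monetary benefit is consistent with the ICER", {
  p <- angina_parameters()
  bc <- base_case(p)
  expect_equal(net_monetary_benefit(bc$intervention, 0),
               -bc$intervention$total_cost)
  zero_q <- bc$intervention; zero_q$qalys <- 0
  expect_equal(net_monetary_benefit(zero_q, 50000), -zero_q$total_cost)

  # the incremental NMB changes sign exactly at the ICER
  icer <- bc$incremental$icer
  nmb_diff <- function(wtp)
    net_monetary_benefit(bc$intervention, wtp) -
      net_monetary_benefit(bc$comparator, wtp)
  expect_lt(nmb_diff(icer * 0.999), 0)
  expect_gt(nmb_diff(icer * 1.001), 0)
  expect_equal(nmb_diff(icer), 0, tolerance = 1e-9)
  expect_gt(nmb_diff(published$wtp), 0)
})

test_that("raising a utility weakly increases QALYs on a fixed trace", {
  p <- angina_parameters()
  tr <- run_cohort(p, "intervention")
  base_q <- accrue_qalys(tr, p$utilities)
  for (st in angina_states()) {
    u <- p$utilities
    u[st] <- min(1, u[st] + 0.05)
    expect_gte(accrue_qalys(tr, u), base_q)
  }
})

test_that("discounting is the identity at rate zero and contracts otherwise", {
  p <- angina_parameters()
  r0 <- evaluate_strategy(p, "intervention")
  p_explicit <- p; p_explicit$discount_rate <- 0
  expect_equal(evaluate_strategy(p_explicit, "intervention")$total_cost,
               r0$total_cost)
  # on a 2-year horizon a positive rate shrinks all accruals
  p2 <- simple_params(utilities = c(0.8, 0.7, 0.6, 0.5), n_cycles = 8L)
  p2$costs["hosp_revasc", ] <- 100
  p2d <- p2; p2d$discount_rate <- 0.035
  a <- evaluate_strategy(p2, "intervention")
  b <- evaluate_strategy(p2d, "intervention")
  expect_lt(b$total_cost, a$total_cost)
  expect_lt(b$qalys, a$qalys)
  expect_lt(b$life_years, a$life_years)
})

test_that("base-case table mirrors the published layout", {
  tab <- base_case_table(angina_parameters())
  expect_identical(tab$quantity[1], "total_cost")
  expect_identical(tab$quantity[nrow(tab)], "icer")
  expect_equal(tab$incremental[tab$quantity == "total_cost"],
               tab$intervention[1] - tab$comparator[1])
  expect_false(anyNA(tab$intervention[-nrow(tab)]))
})
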