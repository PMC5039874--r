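test_that("built-in fixture carries the published inputs and validates", {
  p <- angina_parameters()
  expect_length(validate_parameters(p), 0)

  # transition probabilities agree with the published 2-decimal percentages
  tmz_printed <- rbind(c(94.66, 4.20, 1.15, 0.00),
                       c(52.72, 41.30, 5.43, 0.54),
                       c(19.42, 61.17, 15.53, 3.88),
                       c(14.29, 18.10, 24.76, 42.86)) / 100
  soc_printed <- rbind(c(90.61, 9.39, 0.00, 0.00),
                       c(46.60, 41.88, 9.42, 2.09),
                       c(25.84, 43.82, 23.60, 6.74),
                       c(11.72, 26.56, 15.63, 46.09)) / 100
  # each stored fraction rounds to the published 2-decimal percentage
  expect_lt(max(abs(unclass(p$strategies$intervention$transition)[, ] -
                      tmz_printed)), 6e-5)
  expect_lt(max(abs(unclass(p$strategies$comparator$transition)[, ] -
                      soc_printed)), 6e-5)
  expect_equal(p$strategies$intervention$transition["mild", "minimal"],
               0.5272, tolerance = 1e-4)

  expect_equal(unname(p$mortality), c(0.046, 0.048, 0.081, 0.109))
  expect_equal(p$mortality[["severe"]], 0.109)
  expect_equal(unname(p$utilities), c(0.81, 0.75, 0.60, 0.39))
  expect_equal(unname(round(p$baseline, 2)), c(0, 0.47, 0.26, 0.27))
  expect_equal(p$costs["hosp_revasc", "minimal"], 586.24)
  expect_equal(p$costs["hosp_no_revasc", "severe"], 1428.63)
  expect_equal(p$strategies$intervention$monthly_drug_cost, 29.18)
  expect_equal(p$strategies$comparator$monthly_drug_cost, 23.40)
  expect_identical(p$n_cycles, 4L)
  expect_equal(p$cycle_length_years, 0.25)
  expect_equal(p$wtp_threshold, 34000)
  expect_equal(p$discount_rate, 0)

  # rows are exact trial fractions with their denominators attached
  expect_equal(attr(p$strategies$intervention$transition, "row_ess"),
               c(262, 184, 103, 105), ignore_attr = TRUE)
  expect_equal(attr(p$strategies$comparator$transition, "row_ess"),
               c(181, 191, 89, 128), ignore_attr = TRUE)
})

test_that("serialization round-trips an arbitrary valid parameter set", {
  for (seed in c(1, 2)) {
    p <- synthetic_parameters(seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_parameters(p, path)
    q <- read_parameters(path)
    expect_equal(q$strategies$intervention$transition,
                 p$strategies$intervention$transition, ignore_attr = TRUE)
    expect_equal(q$strategies$comparator$monthly_drug_cost,
                 p$strategies$comparator$monthly_drug_cost)
    expect_equal(q$mortality, p$mortality)
    expect_equal(q$utilities, p$utilities)
    expect_equal(q$baseline, p$baseline)
    expect_equal(q$costs, p$costs)
  }
  # the shipped config file parses to the built-in fixture
  shipped <- read_parameters(angina_config_path())
  p <- angina_parameters()
  expect_equal(shipped$strategies$intervention$transition,
               p$strategies$intervention$transition, ignore_attr = TRUE)
  expect_equal(shipped$costs, p$costs)
  expect_equal(shipped$wtp_threshold, p$wtp_threshold)
})

test_that("loader renormalizes printed rounding but rejects bad input", {
  p <- angina_parameters()
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(p, path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)

  # a row carrying printed 2-decimal rounding (sums to 99.99%) is accepted
  # and renormalized to sum exactly 1
  cfg$strategies$intervention$transition_matrix[2, ] <-
    c(0.5272, 0.4130, 0.0543, 0.0054)
  q <- read_parameters(cfg)
  expect_equal(sum(q$strategies$intervention$transition["mild", ]), 1)

  # a row off by more than 0.5% is an error
  cfg_bad <- cfg
  cfg_bad$strategies$intervention$transition_matrix[2, ] <-
    c(0.5, 0.3, 0.05, 0.05)
  expect_error(read_parameters(cfg_bad), "sum")

  # percent-style probabilities are rejected, naming the field
  cfg_pct <- cfg
  cfg_pct$mortality$severe <- 10.9
  expect_error(read_parameters(cfg_pct), "mortality")

  # missing keys are reported by name
  cfg_missing <- cfg
  cfg_missing$utilities <- NULL
  expect_error(read_parameters(cfg_missing), "utilities")
  expect_error(read_parameters(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("validate_parameters reports violations without raising", {
  p <- angina_parameters()
  expect_length(validate_parameters(p), 0)

  q <- p; q$utilities["moderate"] <- 1.2
  v <- validate_parameters(q)
  expect_length(v, 1)
  expect_match(v, "moderate")

  q <- p; q$baseline <- q$baseline * 0.9
  v <- validate_parameters(q)
  expect_length(v, 1)
  expect_match(v, "baseline")

  q <- p; q$mortality["severe"] <- 1
  expect_match(validate_parameters(q), "severe")

  q <- p; q$costs["hosp_revasc", "mild"] <- -5
  expect_match(validate_parameters(q), "cost")
})

test_that("transition_matrix enforces its invariants", {
  expect_error(transition_matrix(matrix(0.25, 3, 3)), "4x4")
  m <- diag(4); m[1, 1] <- 1.5; m[1, 2] <- -0.5
  expect_error(transition_matrix(m), "\\[0, 1\\]")
  m <- diag(4); m[2, 2] <- 0.9   # row sums to 0.9
  expect_error(transition_matrix(m), "0.5%")
  # slight deviation renormalizes
  m <- diag(4) * 0.9999; m[1, 2] <- 1e-4; m[2, 1] <- 1e-4
  m[3, 4] <- 1e-4; m[4, 3] <- 1e-4
  expect_equal(rowSums(transition_matrix(m)), rep(1, 4), ignore_attr = TRUE)
})

test_that("parameter_table flattens every scalar with units", {
  p <- angina_parameters()
  tab <- parameter_table(p)
  # 2 x (16 transitions + 1 drug cost) + 4 x (mortality, utility, baseline)
  # + 20 category costs
  expect_identical(nrow(tab), 2L * 17L + 12L + 20L)
  expect_setequal(names(tab),
                  c("id", "strategy", "state", "category", "value", "units"))
  row <- tab[tab$id == "cost.hosp_revasc.minimal", ]
  expect_equal(row$value, 586.24)
  expect_match(row$units, "EUR")
  expect_false(anyNA(tab$value))
})
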