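test_that("maintenance drug cost per cycle follows the dosing rules", {
  co <- mini_spec()$costs  # niraparib $0.24/mg, p200 = 0.75
  expect_equal(drug_cost_per_cycle(co, "niraparib", "FSD"),
               28 * 300 * 0.24)                      # $2,016.00
  co$p200 <- 1
  expect_equal(drug_cost_per_cycle(co, "niraparib", "ISD"),
               28 * 200 * 0.24)                      # $1,344.00
  expect_equal(drug_cost_per_cycle(co, "routine_surveillance", "ISD"), 0)
  expect_error(drug_cost_per_cycle(co, "chemo", "ISD"), "unknown strategy")
})

test_that("chemotherapy doses use BSA, weight and the Calvert formula", {
  co <- mini_spec()$costs  # 61 kg, 1.64 m2, AUC 5, GFR 100
  expect_equal(chemo_dose("paclitaxel", co), 175 * 1.64)    # 287 mg
  expect_equal(chemo_dose("bevacizumab", co), 15 * 61)      # 915 mg
  expect_equal(chemo_dose("carboplatin", co), 5 * (100 + 25))  # 625 mg
  co$patient[["gfr"]] <- NA
  expect_error(chemo_dose("carboplatin", co), "GFR")
  expect_error(chemo_dose("unknown_drug", co), "dosing rule")
})

test_that("zero prices with full utilities make cost 0 and QALY equal LY", {
  spec <- mini_spec(horizon_years = 3, discount_rate = 0)
  zero <- cost_inputs(
    drug_prices = spec$costs$drug_prices * 0,
    sae_costs = c(anemia = 0), gbrca_test = 0, terminal_care = 0,
    followup_per_cycle = 0, iv_admin = 0)
  spec$costs <- zero
  for (a in names(spec$arms)) spec$arms[[a]]$utilities <- c(pfs = 1, pd = 1)
  out <- accumulate_outcomes(markov_trace(spec, "niraparib"), spec, "niraparib")
  expect_equal(out$cost, 0)
  expect_equal(out$qaly, out$ly)
})

test_that("terminal care is charged exactly once per cohort member", {
  spec <- mini_spec(lambda_pfs = 5, lambda_os = 0.5, horizon_years = 5,
                    discount_rate = 0)
  tr <- markov_trace(spec, "niraparib")
  out <- accumulate_outcomes(tr, spec, "niraparib")
  expect_equal(unname(out$breakdown["terminal"]),
               spec$costs$terminal_care * tr$death[nrow(tr)],
               tolerance = 1e-9)
  expect_gt(tr$death[nrow(tr)], 1 - 1e-6)
})

test_that("a 3-cycle model matches the hand-built spreadsheet to the cent", {
  cm <- 28 / (365.25 / 12)
  spec <- mini_spec(lambda_pfs = 0.1, lambda_os = 0.02,
                    horizon_years = 3 * 28 / 365.25)
  out <- accumulate_outcomes(markov_trace(spec, "niraparib"), spec,
                             "niraparib")
  # --- independent spreadsheet arithmetic -------------------------------
  p_death <- 1 - exp(-0.02 * cm)
  p_exit <- 1 - exp(-0.1 * cm)
  p_prog <- p_exit - p_death
  pfs <- c(1, 0, 0, 0); pd <- c(0, 0, 0, 0); dead <- c(0, 0, 0, 0)
  pd_in <- death_in <- numeric(3)
  for (j in 1:3) {
    pd_in[j] <- pfs[j] * p_prog
    death_in[j] <- (pfs[j] + pd[j]) * p_death
    pfs[j + 1] <- pfs[j] * (1 - p_death - p_prog)
    pd[j + 1] <- pd[j] * (1 - p_death) + pd_in[j]
    dead[j + 1] <- dead[j] + death_in[j]
  }
  cy <- cm / 12
  disc <- (1.05)^(-((1:3) - 0.5) * cy)
  pfs_m <- (pfs[1:3] + pfs[2:4]) / 2
  pd_m <- (pd[1:3] + pd[2:4]) / 2
  tx <- 28 * (0.75 * 200 + 0.25 * 300) * 0.24          # $1,512 / cycle
  sub_once <- (2.5 * 28 * 0.40) * 6                    # letrozole x 6 cycles
  cost <- sum(tx * pfs_m * disc) +
    sum(50 * (pfs_m + pd_m) * disc) +
    sum(sub_once * pd_in * disc) +
    sum(1000 * death_in * disc) +
    100                                                # gBRCA test at entry
  qaly <- sum((0.8 * pfs_m + 0.6 * pd_m) * cy * disc)
  # ----------------------------------------------------------------------
  expect_equal(out$cost, cost, tolerance = 1e-10)
  expect_lt(abs(out$cost - cost), 0.01)
  expect_equal(out$qaly, qaly, tolerance = 1e-10)
})

test_that("incremental ratios use unrounded deltas and flag dominance", {
  a <- list(cost = 33509.01, qaly = 3.39, ly = 4.15)
  b <- list(cost = 22648.22, qaly = 2.80, ly = 3.59)
  r <- icer(a, b)
  expect_equal(r$d_cost, 10860.79)
  expect_equal(r$icer_per_qaly, r$d_cost / r$d_qaly)
  expect_equal(r$dominance, "none")
  tie <- icer(a, a)
  expect_equal(tie$dominance, "tie")
  expect_true(is.na(tie$icer_per_qaly))
  dom <- icer(list(cost = -1, qaly = 1, ly = 1),
              list(cost = 0, qaly = 0, ly = 0))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer_per_qaly))
})

test_that("discounting never increases costs, QALYs or life-years", {
  spec <- mini_spec()
  for (a in names(spec$arms)) {
    out <- accumulate_outcomes(markov_trace(spec, a), spec, a)
    expect_lte(out$cost, out$cost_undisc)
    expect_lte(out$qaly, out$qaly_undisc)
    expect_lte(out$ly, out$ly_undisc)
  }
})

test_that("total cost is linear in prices and the ICER is currency-homogeneous", {
  spec <- mini_spec()
  dbl <- spec
  dbl$costs$drug_prices <- dbl$costs$drug_prices * 2
  dbl$costs$sae_costs <- dbl$costs$sae_costs * 2
  dbl$costs$gbrca_test <- dbl$costs$gbrca_test * 2
  dbl$costs$terminal_care <- dbl$costs$terminal_care * 2
  dbl$costs$followup_per_cycle <- dbl$costs$followup_per_cycle * 2
  dbl$costs$iv_admin <- dbl$costs$iv_admin * 2
  r1 <- run_cea(spec); r2 <- run_cea(dbl)
  expect_equal(r2$arms$niraparib$cost, 2 * r1$arms$niraparib$cost)
  expect_equal(r2$d_cost, 2 * r1$d_cost)
  expect_equal(r2$d_qaly, r1$d_qaly)  # effects untouched by currency
  expect_equal(r2$icer_per_qaly, 2 * r1$icer_per_qaly)
})

test_that("threshold price is a fixed point and matches a grid-search oracle", {
  spec <- mini_spec()
  base <- run_cea(spec)
  tp <- threshold_price(spec, wtp = base$icer_per_qaly)
  expect_equal(tp, 0.24, tolerance = 1e-4)

  wtp <- 37488
  tp2 <- threshold_price(spec, wtp)
  grid <- seq(0, 2.4, length.out = 1000)
  dev <- vapply(grid, function(p) {
    s <- spec_set(spec, "costs.drug_prices.niraparib", p)
    abs(run_cea(s)$icer_per_qaly - wtp)
  }, numeric(1))
  expect_lt(abs(tp2 - grid[which.min(dev)]), 0.0005 + 2.4 / 999)
  # unreachable thresholds are refused rather than extrapolated
  expect_error(threshold_price(spec, wtp = 1e9), "no threshold price")
})

test_that("CE results serialize to the published table layout", {
  r <- run_cea(mini_spec())
  f <- tempfile()
  write_ce_result(r, f)
  tab <- read.csv(paste0(f, ".csv"))
  expect_named(tab, c("strategy", "cost", "qalys", "lys",
                      "icer_per_qaly", "icer_per_ly"))
  j <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(j$d_cost, r$d_cost, tolerance = 1e-9)
})
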