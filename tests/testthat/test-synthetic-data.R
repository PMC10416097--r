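test_that("simulated trials honour the generating distribution and the seed", {
  sc <- trial_scenario(arms = list(e = exp_curve(0.05)), n = 10000,
                       follow_up = 1000, grid = 20, seed = 5)
  ipd <- simulate_trial(sc)$e
  # closed-form exponential median ln2 / lambda = 13.86 months
  expect_equal(median(ipd$data$time), log(2) / 0.05, tolerance = 0.02)
  expect_identical(simulate_trial(sc)$e$data, ipd$data)
  # censor-everyone scheme
  sc0 <- trial_scenario(arms = list(e = exp_curve(0.05)), n = 100,
                        follow_up = 0.001, grid = 20, seed = 5)
  expect_lte(sum(simulate_trial(sc0)$e$data$event), 1)
  expect_error(trial_scenario(arms = list(e = exp_curve(1)), n = 5), "10")
  expect_error(trial_scenario(arms = list(e = exp_curve(1)), grid = 3), "5")
})

test_that("the digitizer reads the exact KM at grid times; jitter stays valid", {
  sc <- trial_scenario(arms = list(e = exp_curve(0.08)), n = 120,
                       follow_up = 30, grid = 25, seed = 6)
  ipd <- simulate_trial(sc)$e
  g <- seq(0, 30, length.out = 25)
  cur <- digitize(ipd, g)
  expect_equal(cur$points$survival, km_survival(ipd, g))
  expect_equal(cur$risk_table$n_at_risk[1], 120)
  noisy <- digitize(ipd, g, jitter = 0.02, seed = 7)
  expect_true(all(diff(noisy$points$survival) <= 1e-12))
  expect_true(all(noisy$points$survival >= 0 & noisy$points$survival <= 1))
  expect_equal(noisy$points$survival[1], 1)
})

test_that("digitize -> reconstruct -> fit recovers the generating parameters", {
  truth <- c(shape = 1.3, scale = 20)
  sc <- trial_scenario(arms = list(w = parsurv("weibull", truth)),
                       n = 2000, follow_up = 60, grid = 60, seed = 13)
  ipd <- simulate_trial(sc)$w
  cur <- digitize(ipd, seq(0, 60, length.out = 60))
  rec <- reconstruct_ipd(cur)
  fit <- fit_parametric(rec, "weibull")
  expect_lt(abs(coef(fit)[["shape"]] - truth["shape"]) / truth["shape"], 0.15)
  expect_lt(abs(coef(fit)[["scale"]] - truth["scale"]) / truth["scale"], 0.15)
})

test_that("the fixture encodes the trial-reported quantities", {
  spec <- nora_fixture("non_gBRCAm")
  # printed medians: PFS 3.9 vs 11.1 months, OS 38.41 vs 43.10 months
  expect_equal(median_time(spec$arms$niraparib$pfs), 11.1, tolerance = 1e-9)
  expect_equal(median_time(spec$arms$routine_surveillance$pfs), 3.9,
               tolerance = 1e-9)
  expect_equal(median_time(spec$arms$niraparib$os), 43.10, tolerance = 1e-9)
  expect_equal(median_time(spec$arms$routine_surveillance$os), 38.41,
               tolerance = 1e-9)
  g <- nora_fixture("gBRCAm")
  expect_equal(median_time(g$arms$routine_surveillance$pfs), 5.5,
               tolerance = 1e-9)
  expect_equal(median_time(g$arms$routine_surveillance$os), 47.61,
               tolerance = 1e-9)
  # "not reached" medians must exceed the surveillance-arm medians
  expect_gt(median_time(g$arms$niraparib$pfs), 16)
  expect_gt(median_time(g$arms$niraparib$os), 47.61)
  # utilities, discontinuation, price, insurance fractions as printed
  expect_equal(unname(spec$arms$niraparib$utilities), c(0.849, 0.793))
  expect_equal(unname(spec$arms$routine_surveillance$utilities),
               c(0.820, 0.775))
  expect_equal(spec$arms$niraparib$ae_discontinuation, 0.04)
  expect_equal(spec$arms$routine_surveillance$ae_discontinuation, 0.057)
  expect_equal(spec$costs$drug_prices[["niraparib"]], 0.24)
  expect_equal(unname(spec$costs$insurance_fractions),
               c(0.20, 0, 0, 0.30, 0.20, 0.30, 0.05))
  expect_equal(unname(spec$costs$patient[c("weight_kg", "bsa_m2",
                                           "carboplatin_auc")]),
               c(61, 1.64, 5))
  # structural settings
  expect_equal(spec$cycle_length_days, 28)
  expect_equal(spec$horizon_years, 21.3)
  expect_equal(spec$discount_rate, 0.05)
})

test_that("every fixture probability and utility is a valid probability", {
  for (cohort in c("gBRCAm", "non_gBRCAm")) {
    spec <- nora_fixture(cohort)
    for (a in names(spec$arms)) {
      arm <- spec$arms[[a]]
      vals <- c(arm$utilities, arm$ae_discontinuation, arm$sae_incidence,
                arm$subsequent_mix$proportion)
      expect_true(all(vals >= 0 & vals <= 1))
      expect_equal(sum(arm$subsequent_mix$proportion), 1)
    }
    expect_true(all(spec$costs$oop_fractions >= 0 &
                    spec$costs$oop_fractions <= 1))
    # assumptions are flagged
    prov <- attr(spec, "provenance")
    expect_true(all(c("trial", "assumed") %in% prov$source))
  }
})

test_that("both cohorts run end-to-end to finite positive ICERs", {
  for (cohort in c("gBRCAm", "non_gBRCAm")) {
    r <- run_cea(nora_fixture(cohort))
    expect_true(is.finite(r$icer_per_qaly))
    expect_gt(r$icer_per_qaly, 0)
    expect_gt(r$d_qaly, 0)
  }
})

test_that("the spec config round-trips through YAML", {
  spec <- nora_fixture("gBRCAm")
  f <- tempfile(fileext = ".yaml")
  write_spec_config(spec, f)
  back <- read_spec_config(f)
  expect_equal(back$arms$niraparib$pfs$params,
               spec$arms$niraparib$pfs$params, tolerance = 1e-9)
  expect_equal(back$costs$drug_prices, spec$costs$drug_prices,
               tolerance = 1e-12)
  expect_equal(back$costs$insurance_fractions,
               spec$costs$insurance_fractions, tolerance = 1e-12)
  expect_equal(back$arms$routine_surveillance$subsequent_mix,
               spec$arms$routine_surveillance$subsequent_mix)
  expect_equal(back$horizon_years, spec$horizon_years)
  # the rebuilt spec is functionally identical
  expect_equal(run_cea(back)$icer_per_qaly, run_cea(spec)$icer_per_qaly,
               tolerance = 1e-9)
  expect_equal(attr(back, "provenance"), attr(spec, "provenance"))
})
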