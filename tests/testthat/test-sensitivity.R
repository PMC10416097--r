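test_that("spec paths address nested values, named vectors and errors", {
  spec <- mini_spec()
  expect_equal(spec_get(spec, "costs.drug_prices.niraparib"), 0.24)
  expect_equal(spec_get(spec, "arms.niraparib.utilities.pfs"), 0.8)
  s2 <- spec_set(spec, "costs.p200", 0.5)
  expect_equal(spec_get(s2, "costs.p200"), 0.5)
  expect_equal(spec_get(spec, "costs.p200"), 0.75)  # copy semantics
  expect_error(spec_get(spec, "costs.nope"), "not found")
  expect_error(spec_set(spec, "costs.nope.x", 1), "not found")
})

test_that("tornado bounds default to +/-20% and rank by ICER width", {
  p <- sa_parameter("x", "costs.p200", 100)
  expect_equal(c(p$low, p$high), c(80, 120))
  spec <- mini_spec()
  params <- rbind(
    sa_parameter("niraparib price", "costs.drug_prices.niraparib", 0.24),
    # identical cost in both arms at entry: zero effect on the ICER
    sa_parameter("gBRCA test cost", "costs.gbrca_test", 100),
    # lowering niraparib's PD utility far enough flips dQALY negative:
    # must surface as a dominance warning, not a spurious ratio
    sa_parameter("utility PD (niraparib)", "arms.niraparib.utilities.pd",
                 0.6, psa_family = "beta"))
  expect_warning(tor <- one_way(spec, params), "dominance")
  expect_equal(nrow(tor), 3)
  expect_equal(tor$width[tor$name == "gBRCA test cost"], 0)
  expect_equal(tor$name[1], "niraparib price")
  # zero-width ranked after real widths; dominance (NA width) ranked last
  expect_equal(tor$name[2], "gBRCA test cost")
  expect_true(is.na(tor$width[3]))
  # bounds actually evaluated at 0.8x / 1.2x
  pr <- params[params$name == "niraparib price", ]
  expect_equal(c(pr$low, pr$high), c(0.8 * 0.24, 1.2 * 0.24))
})

test_that("tornado output is invariant to parameter order", {
  spec <- mini_spec()
  params <- rbind(
    sa_parameter("a", "costs.drug_prices.niraparib", 0.24),
    sa_parameter("b", "costs.followup_per_cycle", 50),
    sa_parameter("c", "costs.terminal_care", 1000))
  t1 <- one_way(spec, params)
  t2 <- one_way(spec, params[c(3, 1, 2), ])
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2, ignore_attr = TRUE)
})

test_that("moment matching reproduces the textbook gamma and beta solutions", {
  set.seed(1)
  g <- niracea:::.psa_draw(200000, "gamma", 100, 20, "g")
  # k = (m/s)^2 = 25, theta = s^2/m = 4
  expect_equal(mean(g), 100, tolerance = 0.01)
  expect_equal(sd(g), 20, tolerance = 0.02)
  b <- niracea:::.psa_draw(200000, "beta", 0.8, 0.05, "b")
  # alpha + beta = 0.8*0.2/0.0025 - 1 = 63, alpha = 50.4
  expect_equal(mean(b), 0.8, tolerance = 0.01)
  expect_equal(sd(b), 0.05, tolerance = 0.02)
  expect_error(niracea:::.psa_draw(10, "beta", 0.8, 0.5, "bad"),
               "infeasible.*bad")
})

test_that("degenerate PSA (sd = 0) reproduces the base case every iteration", {
  spec <- mini_spec(horizon_years = 3)
  params <- rbind(
    sa_parameter("price", "costs.drug_prices.niraparib", 0.24, sd = 0),
    sa_parameter("u", "arms.niraparib.utilities.pfs", 0.8,
                 psa_family = "beta", sd = 0))
  pr <- psa(spec, params, n_iter = 5, seed = 1)
  base <- run_cea(spec)
  expect_true(all(abs(pr$iterations$d_cost - base$d_cost) < 1e-9))
  expect_true(all(abs(pr$iterations$d_qaly - base$d_qaly) < 1e-9))
})

test_that("PSA is reproducible under a fixed seed", {
  spec <- mini_spec(horizon_years = 3)
  params <- nora_parameters(nora_fixture("gBRCAm"))[1:3, ]
  params$base <- vapply(params$path, function(p) spec_get(spec, p), numeric(1))
  params$low <- 0.8 * params$base; params$high <- 1.2 * params$base
  params$sd <- 0.2 * params$base
  a <- psa(spec, params, n_iter = 20, seed = 42)
  b <- psa(spec, params, n_iter = 20, seed = 42)
  expect_identical(a$iterations, b$iterations)
})

test_that("CEAC edges and monotonicity behave as net-benefit logic requires", {
  fake <- structure(list(iterations = data.frame(
    d_cost = c(-5, -1, -2), d_qaly = c(1, 2, 0.5)),
    n_iter = 3, seed = 1, cohort = "x"), class = "psa_result")
  cc <- ceac(fake, c(0, 1000, 1e6))
  expect_true(all(cc$prob_ce == 1))  # cheaper and better everywhere
  mixed <- structure(list(iterations = data.frame(
    d_cost = c(-5, 3, 10), d_qaly = c(0.1, 0.2, 0.3)),
    n_iter = 3, seed = 1, cohort = "x"), class = "psa_result")
  expect_equal(ceac(mixed, 0)$prob_ce, 1 / 3)  # fraction with d_cost < 0
  # monotone nondecreasing in WTP whenever all dQALY >= 0
  set.seed(8)
  rnd <- structure(list(iterations = data.frame(
    d_cost = rnorm(500, 5000, 4000), d_qaly = runif(500, 0, 1)),
    n_iter = 500, seed = 8, cohort = "x"), class = "psa_result")
  curve <- ceac(rnd, seq(0, 50000, length.out = 40))
  expect_true(all(diff(curve$prob_ce) >= 0))
  expect_true(all(curve$prob_ce >= 0 & curve$prob_ce <= 1))
})

test_that("PSA means are stable between 300 and 1500 iterations", {
  spec <- mini_spec(horizon_years = 5)
  params <- rbind(
    sa_parameter("price", "costs.drug_prices.niraparib", 0.24),
    sa_parameter("fu", "costs.followup_per_cycle", 50),
    sa_parameter("u", "arms.niraparib.utilities.pfs", 0.8,
                 psa_family = "beta", sd = 0.05))
  small <- psa(spec, params, n_iter = 300, seed = 1)
  large <- psa(spec, params, n_iter = 1500, seed = 2)
  se <- sd(small$iterations$d_cost) / sqrt(300)
  expect_lt(abs(mean(small$iterations$d_cost) -
                mean(large$iterations$d_cost)), 4 * se)
})

test_that("scenario machinery: FSD dominates ISD cost; unit fractions = base", {
  spec <- mini_spec()
  sc <- run_scenarios(spec, scenarios = c("fsd", "insurance"))
  # p200 > 0 makes the fixed 300 mg dose strictly costlier
  expect_gt(sc$fsd$arms$niraparib$cost, sc$base$arms$niraparib$cost)
  # insurance scenario with all fractions = 1 reproduces the base case
  s1 <- spec
  s1$costs$insurance_fractions[] <- 1
  sc1 <- run_scenarios(s1, scenarios = "insurance")
  expect_equal(sc1$insurance$arms$niraparib$cost,
               sc1$base$arms$niraparib$cost, tolerance = 1e-12)
  expect_equal(sc1$insurance$icer_per_qaly, sc1$base$icer_per_qaly,
               tolerance = 1e-12)
  # zero out-of-pocket for every drug: only non-drug costs remain in d_cost
  s0 <- spec
  s0$costs$insurance_fractions[] <- 0
  sc0 <- run_scenarios(s0, scenarios = "insurance")
  nodrug <- spec
  nodrug$costs$drug_prices[] <- 0
  expect_equal(sc0$insurance$d_cost, run_cea(nodrug)$d_cost,
               tolerance = 1e-9)
  expect_error(run_scenarios(spec, scenarios = "nope"))
})

test_that("regional WTP scenario reads an ordered acceptability curve", {
  spec <- mini_spec()
  params <- rbind(
    sa_parameter("price", "costs.drug_prices.niraparib", 0.24),
    sa_parameter("u", "arms.niraparib.utilities.pfs", 0.8,
                 psa_family = "beta", sd = 0.05))
  sc <- run_scenarios(spec, params, scenarios = "wtp", n_iter = 200, seed = 9)
  expect_equal(sc$wtp$wtp, c(19002, 37488, 85176))
  # with nonnegative dQALY draws the curve is nondecreasing across thresholds
  if (all(sc$psa$iterations$d_qaly >= 0))
    expect_true(all(diff(sc$wtp$prob_ce) >= 0))
})
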