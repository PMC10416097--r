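# Shared in-code fixtures: everything is generated, nothing read from disk.

exp_curve <- function(rate, label = "exp")
  parsurv("exponential", c(rate = rate), label = label)

# A minimal runnable spec with exponential curves and round-number costs;
# short horizon keeps per-test model runs cheap.
mini_spec <- function(lambda_pfs = 0.10, lambda_os = 0.02,
                      horizon_years = 5, discount_rate = 0.05,
                      engine = "transition", ...) {
  arm <- function(lp, lo) list(
    pfs = exp_curve(lp), os = exp_curve(lo),
    ae_discontinuation = 0,
    utilities = c(pfs = 0.8, pd = 0.6),
    sae_incidence = c(anemia = 0),
    subsequent_mix = data.frame(regimen = "endocrine", proportion = 1))
  costs <- cost_inputs(
    drug_prices = c(niraparib = 0.24, paclitaxel = 0.06, carboplatin = 0.02,
                    bevacizumab = 0.35, nab_paclitaxel = 0.90,
                    olaparib = 0.07, letrozole = 0.40),
    p200 = 0.75,
    sae_costs = c(anemia = 500),
    gbrca_test = 100, terminal_care = 1000, followup_per_cycle = 50,
    iv_admin = 10,
    insurance_fractions = c(niraparib = 0.20, paclitaxel = 0,
                            carboplatin = 0, bevacizumab = 0.30,
                            nab_paclitaxel = 0.20, olaparib = 0.30,
                            letrozole = 0.05))
  cea_spec(
    arms = list(niraparib = arm(lambda_pfs, lambda_os),
                routine_surveillance = arm(lambda_pfs * 1.6, lambda_os * 1.2)),
    costs = costs, horizon_years = horizon_years,
    discount_rate = discount_rate, engine = engine, cohort = "mini", ...)
}

# Ground-truth parameter sets used for simulation-based checks, one per family
family_truth <- list(
  exponential = c(rate = 0.06),
  weibull = c(shape = 1.3, scale = 20),
  log_logistic = c(shape = 1.8, scale = 15),
  lognormal = c(meanlog = 2.6, sdlog = 0.7),
  generalized_gamma = c(mu = 2.7, sigma = 0.6, Q = 0.8),
  gamma = c(shape = 1.6, rate = 0.09),
  gompertz = c(shape = 0.05, rate = 0.03)
)
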