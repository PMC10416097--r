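#' Direct medical cost inputs
#'
#' All prices in 2021 US dollars. Only direct medical costs enter the model:
#' drug acquisition, intravenous administration, serious-adverse-event (SAE)
#' management, gBRCA mutation testing, routine follow-up and terminal care.
#'
#' @param drug_prices named $/mg vector for `niraparib`, `paclitaxel`,
#'   `carboplatin`, `bevacizumab`, `nab_paclitaxel`, `olaparib`, `letrozole`.
#' @param p200 proportion of niraparib patients on 200 mg/day under the
#'   individualized starting dose (the rest take 300 mg/day).
#' @param patient named vector `weight_kg`, `bsa_m2`, `carboplatin_auc`,
#'   `gfr` (mL/min, for the Calvert formula).
#' @param dosing per-drug dosing rules: list of `list(basis, rate)` where
#'   `basis` is `"bsa"` (mg/m2 per administration), `"weight"` (mg/kg per
#'   administration), `"auc"` (Calvert: dose = AUC x (GFR + 25)) or
#'   `"daily"` (mg/day oral).
#' @param regimens named list of subsequent-therapy regimens:
#'   `list(drugs = c(...), infusions = <IV administrations per cycle>)`.
#' @param sae_costs named one-time management cost per SAE type.
#' @param gbrca_test one-time gBRCA mutation test cost at model entry.
#' @param terminal_care one-time terminal-care cost charged on death.
#' @param followup_per_cycle follow-up cost per model cycle while alive.
#' @param iv_admin cost per intravenous administration.
#' @param oop_fractions named out-of-pocket multipliers on drug prices
#'   (1 = payer-perspective full price; the insurance scenario replaces them
#'   with reimbursed fractions).
#' @param insurance_fractions named out-of-pocket shares after National
#'   Basic Medical Insurance reimbursement, used by the insurance scenario
#'   (e.g. 0.20 for niraparib: the patient pays 20% of the list price).
#' @param subsequent_cycles number of cycles of subsequent therapy charged
#'   to each patient entering the progressed state.
#' @return object of class `cost_inputs`.
#' @export
cost_inputs <- function(drug_prices, p200 = 0.75,
                        patient = c(weight_kg = 61, bsa_m2 = 1.64,
                                    carboplatin_auc = 5, gfr = 100),
                        dosing = default_dosing(),
                        regimens = default_regimens(),
                        sae_costs = numeric(0),
                        gbrca_test = 0, terminal_care = 0,
                        followup_per_cycle = 0, iv_admin = 0,
                        oop_fractions = NULL,
                        insurance_fractions = NULL,
                        subsequent_cycles = 6) {
  drug_prices <- unlist(drug_prices)
  if (any(drug_prices < 0)) stop("drug prices must be non-negative")
  if (p200 < 0 || p200 > 1) stop("p200 must be a proportion")
  if (is.null(oop_fractions))
    oop_fractions <- stats::setNames(rep(1, length(drug_prices)),
                                     names(drug_prices))
  oop_fractions <- oop_fractions[names(drug_prices)]
  if (any(is.na(oop_fractions) | oop_fractions < 0 | oop_fractions > 1))
    stop("out-of-pocket fractions must be probabilities for every priced drug")
  if (any(c(gbrca_test, terminal_care, followup_per_cycle, iv_admin,
            unlist(sae_costs)) < 0))
    stop("costs must be non-negative")
  structure(list(drug_prices = drug_prices, p200 = p200,
                 patient = unlist(patient), dosing = dosing,
                 regimens = regimens, sae_costs = unlist(sae_costs),
                 gbrca_test = gbrca_test, terminal_care = terminal_care,
                 followup_per_cycle = followup_per_cycle,
                 iv_admin = iv_admin, oop_fractions = oop_fractions,
                 insurance_fractions = insurance_fractions,
                 subsequent_cycles = subsequent_cycles),
            class = "cost_inputs")
}

#' Default dosing rules for the drugs in the model
#'
#' Conventional regimens: paclitaxel 175 mg/m2, bevacizumab 15 mg/kg,
#' carboplatin by Calvert formula at the configured AUC, albumin-bound
#' paclitaxel 260 mg/m2, olaparib 600 mg/day, letrozole 2.5 mg/day.
#' @return named list of dosing rules.
#' @export
default_dosing <- function() list(
  paclitaxel = list(basis = "bsa", rate = 175),
  bevacizumab = list(basis = "weight", rate = 15),
  carboplatin = list(basis = "auc", rate = NA),
  nab_paclitaxel = list(basis = "bsa", rate = 260),
  olaparib = list(basis = "daily", rate = 600),
  letrozole = list(basis = "daily", rate = 2.5))

#' Default subsequent-therapy regimens
#' @return named list of regimen definitions (drugs + IV administrations per
#'   4-week cycle; one administration per cycle for each IV drug).
#' @export
default_regimens <- function() list(
  platinum_paclitaxel = list(drugs = c("carboplatin", "paclitaxel"),
                             infusions = 2),
  platinum_bevacizumab = list(drugs = c("carboplatin", "paclitaxel",
                                        "bevacizumab"), infusions = 3),
  nab_paclitaxel = list(drugs = "nab_paclitaxel", infusions = 1),
  parpi = list(drugs = "olaparib", infusions = 0),
  endocrine = list(drugs = "letrozole", infusions = 0))

# effective (out-of-pocket) price per mg
.price <- function(costs, drug) {
  p <- costs$drug_prices[[drug]]
  if (is.null(p)) stop("no price configured for drug ", drug)
  p * costs$oop_fractions[[drug]]
}

#' Maintenance drug cost per model cycle
#'
#' Individualized starting dose (ISD): a blend of 200 and 300 mg/day by the
#' configured proportion `p200`; fixed starting dose (FSD): 300 mg/day for
#' everyone; routine surveillance carries no maintenance drug cost.
#'
#' @param costs a [cost_inputs()].
#' @param strategy `"niraparib"` or `"routine_surveillance"`.
#' @param dosing_mode `"ISD"` or `"FSD"`.
#' @return dollars per 28-day cycle.
#' @export
drug_cost_per_cycle <- function(costs, strategy, dosing_mode = c("ISD", "FSD")) {
  dosing_mode <- match.arg(dosing_mode)
  if (strategy == "routine_surveillance") return(0)
  if (strategy != "niraparib") stop("unknown strategy ", strategy)
  mg_day <- if (dosing_mode == "FSD") 300
  else costs$p200 * 200 + (1 - costs$p200) * 300
  28 * mg_day * .price(costs, "niraparib")
}

#' Chemotherapy dose per administration (or per day for orals)
#'
#' Body-surface-area drugs use the standard 1.64 m2 female BSA, weight-based
#' drugs the 61 kg standard weight, and carboplatin the Calvert formula
#' dose = AUC x (GFR + 25).
#'
#' @param drug drug id present in `costs$dosing`.
#' @param costs a [cost_inputs()].
#' @return dose in mg.
#' @export
chemo_dose <- function(drug, costs) {
  rule <- costs$dosing[[drug]]
  if (is.null(rule)) stop("no dosing rule for drug ", drug)
  switch(rule$basis,
         bsa = rule$rate * costs$patient[["bsa_m2"]],
         weight = rule$rate * costs$patient[["weight_kg"]],
         auc = {
           gfr <- costs$patient[["gfr"]]
           if (is.null(gfr) || is.na(gfr))
             stop("carboplatin dosing requires a GFR value")
           costs$patient[["carboplatin_auc"]] * (gfr + 25)
         },
         daily = rule$rate,
         stop("unknown dosing basis ", rule$basis))
}

#' Cost of one cycle of a subsequent-therapy regimen
#'
#' Drug acquisition at effective prices plus intravenous administration fees.
#' Oral (daily) drugs are dosed for the full 28-day cycle; IV drugs once per
#' cycle per administration listed in the regimen.
#'
#' @param regimen regimen id in `costs$regimens`.
#' @param costs a [cost_inputs()].
#' @return dollars per cycle.
#' @export
regimen_cycle_cost <- function(regimen, costs) {
  reg <- costs$regimens[[regimen]]
  if (is.null(reg)) stop("unknown regimen ", regimen)
  drug_cost <- sum(vapply(reg$drugs, function(d) {
    rule <- costs$dosing[[d]]
    mg <- chemo_dose(d, costs)
    if (identical(rule$basis, "daily")) mg <- mg * 28
    mg * .price(costs, d)
  }, numeric(1)))
  drug_cost + reg$infusions * costs$iv_admin
}

# expected one-time subsequent-therapy cost per patient entering PD
.subsequent_onetime <- function(costs, mix) {
  if (is.null(mix) || nrow(mix) == 0) return(0)
  per_cycle <- sum(vapply(seq_len(nrow(mix)), function(i)
    mix$proportion[i] * regimen_cycle_cost(mix$regimen[i], costs), numeric(1)))
  per_cycle * costs$subsequent_cycles
}

#' Attach costs and utilities to a cohort trace
#'
#' Half-cycle-corrected state occupancies accrue per-cycle quantities
#' (follow-up cost, maintenance drug cost on the on-treatment
#' progression-free fraction, utility-weighted time), discounted at the
#' cycle midpoint. One-time costs: gBRCA testing at entry; SAE management in
#' the first cycle only; subsequent therapy on each progression increment;
#' terminal care on each death increment.
#'
#' @param trace a [markov_trace()] result.
#' @param spec the [cea_spec()] that produced it.
#' @param arm arm id matching the trace.
#' @return list with discounted `cost`, `qaly`, `ly`, their undiscounted
#'   counterparts, and a per-component cost `breakdown`.
#' @export
accumulate_outcomes <- function(trace, spec, arm) {
  a <- spec$arms[[arm]]
  costs <- spec$costs
  cm <- attr(trace, "cycle_months")
  n <- nrow(trace) - 1
  cyc_years <- cm / 12
  t_mid <- ((0:(n - 1)) + 0.5) * cyc_years
  disc <- (1 + spec$discount_rate)^(-t_mid)

  mean_of <- function(x) (x[-1] + x[-(n + 1)]) / 2
  pfs_m <- mean_of(trace$pfs)
  pd_m <- mean_of(trace$pd)
  alive_m <- pfs_m + pd_m
  pd_in <- trace$pd_inflow[seq_len(n)]
  death_in <- trace$death_inflow[seq_len(n)]

  u_pfs <- a$utilities[["pfs"]]
  u_pd <- a$utilities[["pd"]]
  qaly_cyc <- (pfs_m * u_pfs + pd_m * u_pd) * cyc_years

  tx_cycle <- drug_cost_per_cycle(costs, arm, spec$dosing_mode) *
    (1 - a$ae_discontinuation)
  sub_once <- .subsequent_onetime(costs, a$subsequent_mix)
  sae_once <- if (length(costs$sae_costs) && length(a$sae_incidence))
    sum(costs$sae_costs[names(a$sae_incidence)] * a$sae_incidence)
  else 0

  comp <- function(w) c(sum(w), sum(w * disc))
  treatment <- comp(tx_cycle * pfs_m)
  followup <- comp(costs$followup_per_cycle * alive_m)
  subsequent <- comp(sub_once * pd_in)
  terminal <- comp(costs$terminal_care * death_in)
  entry <- c(costs$gbrca_test + sae_once, costs$gbrca_test + sae_once)

  cost <- treatment + followup + subsequent + terminal + entry
  ly <- c(sum(alive_m), sum(alive_m * disc)) * cyc_years
  qaly <- c(sum(qaly_cyc), sum(qaly_cyc * disc))

  list(cost = cost[2], qaly = qaly[2], ly = ly[2],
       cost_undisc = cost[1], qaly_undisc = qaly[1], ly_undisc = ly[1],
       breakdown = c(treatment = treatment[2], followup = followup[2],
                     subsequent = subsequent[2], terminal = terminal[2],
                     entry = entry[2]))
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' All deltas use unrounded inputs. When the intervention saves money and
#' gains effect it is flagged `dominant`; when it costs more and loses
#' effect, `dominated`; identical arms are a `tie`. Ratios are reported only
#' where they are meaningful.
#'
#' @param intervention,comparator lists with `cost`, `qaly`, `ly` (as
#'   returned by [accumulate_outcomes()]).
#' @return list with `d_cost`, `d_qaly`, `d_ly`, `icer_per_qaly`,
#'   `icer_per_ly`, `dominance` (`"none"`, `"dominant"`, `"dominated"`,
#'   `"tie"`).
#' @export
icer <- function(intervention, comparator) {
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qaly - comparator$qaly
  d_ly <- intervention$ly - comparator$ly
  dominance <- "none"
  if (d_cost == 0 && d_qaly == 0) dominance <- "tie"
  else if (d_cost <= 0 && d_qaly >= 0) dominance <- "dominant"
  else if (d_cost >= 0 && d_qaly <= 0) dominance <- "dominated"
  ratio <- function(eff) if (dominance == "none" && eff != 0)
    d_cost / eff else NA_real_
  list(d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
       icer_per_qaly = ratio(d_qaly), icer_per_ly = ratio(d_ly),
       dominance = dominance)
}

#' Run the full cost-effectiveness comparison for one model spec
#'
#' Traces both arms through the cohort model, attaches costs and utilities,
#' and summarizes discounted cost, QALYs, life-years and the incremental
#' ratios of niraparib maintenance over routine surveillance.
#'
#' @param spec a [cea_spec()].
#' @return object of class `cea_result` with per-arm outcomes, deltas and
#'   ICERs.
#' @export
run_cea <- function(spec) {
  arms <- c("niraparib", "routine_surveillance")
  out <- lapply(arms, function(a)
    accumulate_outcomes(markov_trace(spec, a), spec, a))
  names(out) <- arms
  inc <- icer(out$niraparib, out$routine_surveillance)
  structure(c(list(cohort = spec$cohort, arms = out), inc,
              list(wtp = NULL, spec = spec)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness results [", x$cohort, "]\n", sep = "")
  tab <- data.frame(
    strategy = c("niraparib", "routine surveillance"),
    cost = sprintf("%.2f", c(x$arms$niraparib$cost,
                             x$arms$routine_surveillance$cost)),
    QALYs = sprintf("%.2f", c(x$arms$niraparib$qaly,
                              x$arms$routine_surveillance$qaly)),
    LYs = sprintf("%.2f", c(x$arms$niraparib$ly,
                            x$arms$routine_surveillance$ly)))
  print(tab, row.names = FALSE)
  cat(sprintf("incremental cost %.2f, QALY %.3f, LY %.3f\n",
              x$d_cost, x$d_qaly, x$d_ly))
  if (x$dominance == "none")
    cat(sprintf("ICER %.2f $/QALY, %.2f $/LY\n",
                x$icer_per_qaly, x$icer_per_ly))
  else cat("dominance:", x$dominance, "\n")
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  print(object)
  cat("\nDiscounted cost breakdown ($):\n")
  b <- rbind(niraparib = object$arms$niraparib$breakdown,
             routine_surveillance = object$arms$routine_surveillance$breakdown)
  colnames(b) <- sub("\\d+$", "", colnames(b))
  print(round(b, 2))
  invisible(object)
}

#' Write a cost-effectiveness summary as CSV and JSON
#' @param result a `cea_result`.
#' @param file output path without extension; writes `<file>.csv` and
#'   `<file>.json`.
#' @export
write_ce_result <- function(result, file) {
  tab <- data.frame(
    strategy = c("niraparib", "routine_surveillance"),
    cost = c(result$arms$niraparib$cost, result$arms$routine_surveillance$cost),
    qalys = c(result$arms$niraparib$qaly, result$arms$routine_surveillance$qaly),
    lys = c(result$arms$niraparib$ly, result$arms$routine_surveillance$ly),
    icer_per_qaly = c(result$icer_per_qaly, NA),
    icer_per_ly = c(result$icer_per_ly, NA))
  utils::write.csv(tab, paste0(file, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(cohort = result$cohort, strategies = tab,
         d_cost = result$d_cost, d_qaly = result$d_qaly, d_ly = result$d_ly,
         dominance = result$dominance),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file)
}

#' Niraparib price at which the ICER equals a willingness-to-pay threshold
#'
#' Bisection on the niraparib $/mg price. The ICER is linear and increasing
#' in the price (incremental cost is linear in it; effects are unchanged),
#' which is asserted numerically on a coarse grid before searching.
#'
#' @param spec a [cea_spec()].
#' @param wtp willingness-to-pay threshold in $/QALY.
#' @param price_range search interval in $/mg; defaults to 0 to 10x the
#'   configured price.
#' @param tol stop when the ICER is within this many $/QALY of `wtp`.
#' @return threshold price in $/mg.
#' @export
threshold_price <- function(spec, wtp, price_range = NULL, tol = 0.01) {
  base <- spec$costs$drug_prices[["niraparib"]]
  if (is.null(price_range)) price_range <- c(0, 10 * base)
  at_price <- function(p) {
    s <- spec
    s$costs$drug_prices[["niraparib"]] <- p
    run_cea(s)
  }
  # net benefit at wtp: zero exactly at the threshold price
  g <- function(r) r$d_cost - wtp * r$d_qaly
  grid <- seq(price_range[1], price_range[2], length.out = 5)
  gv <- vapply(grid, function(p) g(at_price(p)), numeric(1))
  if (is.unsorted(gv)) stop("ICER is not monotone increasing in price")
  lo <- price_range[1]; hi <- price_range[2]
  if (gv[1] > 0 || gv[5] < 0)
    stop("no threshold price in [", lo, ", ", hi, "] $/mg at WTP ", wtp)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    r <- at_price(mid)
    if (g(r) > 0) hi <- mid else lo <- mid
    ic <- r$icer_per_qaly
    if (!is.na(ic) && abs(ic - wtp) < tol) return(mid)
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}
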