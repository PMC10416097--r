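# One-way (tornado), probabilistic (PSA + CEAC) and scenario sensitivity
# analyses over a cea_spec. Parameters are addressed by dot-separated paths
# into the spec (e.g. "costs.drug_prices.niraparib",
# "arms.niraparib.utilities.pfs", "discount_rate").

#' Read a value from a model spec by path
#' @param spec a [cea_spec()].
#' @param path dot-separated path, e.g. `"costs.drug_prices.niraparib"`.
#' @return the addressed value.
#' @export
spec_get <- function(spec, path) {
  cur <- spec
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(cur)) stop("no element '", key, "' along path ", path)
    cur <- cur[[key]]
  }
  if (is.null(cur)) stop("path not found: ", path)
  cur
}

#' Return a copy of a model spec with one value replaced
#' @inheritParams spec_get
#' @param value replacement value.
#' @return modified `cea_spec`.
#' @export
spec_set <- function(spec, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(obj, parts) {
    key <- parts[1]
    if (is.null(obj) || !(key %in% names(obj)))
      stop("path not found: ", path)
    if (length(parts) == 1) {
      obj[[key]] <- value
      return(obj)
    }
    if (!is.list(obj)) stop("path not found: ", path)
    obj[[key]] <- rec(obj[[key]], parts[-1])
    obj
  }
  rec(spec, parts)
}

#' Define a parameter for sensitivity analysis
#'
#' Bounds default to +/-20% of the base value when no interval (confidence
#' interval or market range) is supplied. For probabilistic analysis, cost
#' parameters follow a gamma distribution and probability/utility parameters
#' a beta distribution, both matched by moments to `(base, sd)`; `sd`
#' defaults to 20% of the base.
#'
#' @param name display name.
#' @param path spec path (see [spec_get()]).
#' @param base base-case value.
#' @param low,high one-way bounds; default `0.8 * base` / `1.2 * base`.
#' @param psa_family `"gamma"`, `"beta"` or `"fixed"` (excluded from PSA).
#' @param sd standard deviation for the PSA draw; default `0.2 * base`.
#' @return one-row data.frame.
#' @export
sa_parameter <- function(name, path, base, low = 0.8 * base,
                         high = 1.2 * base,
                         psa_family = c("gamma", "beta", "fixed"),
                         sd = 0.2 * base) {
  psa_family <- match.arg(psa_family)
  if (!(low <= base && base <= high))
    stop("need low <= base <= high for parameter ", name)
  if (psa_family == "beta" && (base < 0 || base > 1))
    stop("beta-distributed parameter ", name, " must lie in [0, 1]")
  data.frame(name = name, path = path, base = base, low = low, high = high,
             psa_family = psa_family, sd = sd, stringsAsFactors = FALSE)
}

.check_params <- function(spec, params) {
  for (i in seq_len(nrow(params))) {
    v <- spec_get(spec, params$path[i])
    if (abs(v - params$base[i]) > 1e-8 * max(1, abs(v)))
      warning("base value of '", params$name[i],
              "' differs from the spec value")
  }
  invisible(params)
}

# ICER of the spec after setting several paths; NA on dominance
.icer_at <- function(spec, paths, values) {
  for (i in seq_along(paths)) spec <- spec_set(spec, paths[i], values[i])
  r <- run_cea(spec)
  list(icer = r$icer_per_qaly, d_cost = r$d_cost, d_qaly = r$d_qaly,
       dominance = r$dominance)
}

#' One-way sensitivity analysis (tornado table)
#'
#' Evaluates the ICER at each parameter's low and high bound, holding all
#' other parameters at base, and ranks parameters by the width of the
#' resulting ICER interval. A bound yielding dominance (no meaningful ratio)
#' is recorded as `NA` with a warning and the parameter is ranked last.
#'
#' @param spec a [cea_spec()].
#' @param params data.frame of [sa_parameter()] rows.
#' @return data.frame `name, low, high, icer_low, icer_high, width`, sorted
#'   by decreasing width; attribute `base_icer` carries the base-case ICER.
#' @export
one_way <- function(spec, params) {
  .check_params(spec, params)
  base_icer <- run_cea(spec)$icer_per_qaly
  rows <- lapply(seq_len(nrow(params)), function(i) {
    lo <- .icer_at(spec, params$path[i], params$low[i])
    hi <- .icer_at(spec, params$path[i], params$high[i])
    if (lo$dominance != "none" || hi$dominance != "none")
      warning("parameter '", params$name[i],
              "' yields dominance at a bound; excluded from ranking width")
    data.frame(name = params$name[i], low = params$low[i],
               high = params$high[i], icer_low = lo$icer, icer_high = hi$icer,
               width = abs(hi$icer - lo$icer))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$name, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

# gamma / beta draws matched by moments; degenerate sd -> constant
.psa_draw <- function(n, family, mean, sd, name) {
  if (sd <= 0 || family == "fixed" || mean == 0)
    return(rep(mean, n))
  switch(family,
    gamma = {
      shape <- (mean / sd)^2
      stats::rgamma(n, shape = shape, scale = sd^2 / mean)
    },
    beta = {
      v <- sd^2
      if (v >= mean * (1 - mean))
        stop("beta moment matching infeasible for parameter ", name)
      s <- mean * (1 - mean) / v - 1
      stats::rbeta(n, shape1 = mean * s, shape2 = (1 - mean) * s)
    },
    stop("unknown PSA family ", family))
}

# redraw a fitted curve's parameters from their asymptotic normal
# distribution on the estimation scale (identity for constructed curves
# without a covariance matrix)
.draw_parsurv <- function(fit) {
  if (is.null(fit$cov) || is.null(fit$params_t)) return(fit)
  L <- tryCatch(chol(fit$cov), error = function(e) NULL)
  if (is.null(L)) return(fit)
  z <- stats::rnorm(length(fit$params_t))
  pt <- fit$params_t + as.numeric(crossprod(L, z))
  nat <- vapply(seq_along(pt), function(i) fit$transforms[[i]](pt[i]),
                numeric(1))
  fit$params <- stats::setNames(nat, names(fit$params))
  fit
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters jointly and independently from their assigned
#' distributions (gamma for costs, beta for probabilities and utilities,
#' moment-matched) and reruns the full model per iteration, recording the
#' incremental cost and QALYs of niraparib over routine surveillance.
#'
#' @inheritParams one_way
#' @param n_iter number of Monte Carlo iterations (10,000 in the base
#'   analysis; smaller values give proportionally faster, noisier curves).
#' @param seed RNG seed; identical seeds reproduce the iteration set.
#' @param vary_survival also redraw fitted survival-curve parameters from
#'   their asymptotic standard errors (only possible for curves that carry a
#'   covariance matrix, i.e. actual fits); off by default.
#' @return object of class `psa_result`: `iterations` data.frame with
#'   per-arm cost/QALY and `d_cost`, `d_qaly`; fields `n_iter`, `seed`.
#' @export
psa <- function(spec, params, n_iter = 10000, seed = NULL,
                vary_survival = FALSE) {
  .check_params(spec, params)
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(params)
  draws <- matrix(NA_real_, n_iter, P)
  for (j in seq_len(P))
    draws[, j] <- .psa_draw(n_iter, params$psa_family[j], params$base[j],
                            params$sd[j], params$name[j])
  it <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    s <- spec
    for (j in seq_len(P)) s <- spec_set(s, params$path[j], draws[i, j])
    if (vary_survival) {
      for (a in names(s$arms)) {
        s$arms[[a]]$pfs <- .draw_parsurv(s$arms[[a]]$pfs)
        s$arms[[a]]$os <- .draw_parsurv(s$arms[[a]]$os)
      }
    }
    r <- run_cea(s)
    it[[i]] <- c(cost_nir = r$arms$niraparib$cost,
                 qaly_nir = r$arms$niraparib$qaly,
                 cost_rs = r$arms$routine_surveillance$cost,
                 qaly_rs = r$arms$routine_surveillance$qaly,
                 d_cost = r$d_cost, d_qaly = r$d_qaly)
  }
  iterations <- as.data.frame(do.call(rbind, it))
  structure(list(iterations = iterations, n_iter = n_iter, seed = seed,
                 cohort = spec$cohort),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA [", x$cohort, "]: ", x$n_iter, " iterations\n", sep = "")
  cat(sprintf("mean incremental cost %.2f, mean incremental QALY %.4f\n",
              mean(x$iterations$d_cost), mean(x$iterations$d_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA iterations in which
#' the intervention has positive incremental net monetary benefit,
#' `wtp * dQALY - dCost > 0`. All grid points are evaluated on the same
#' iteration set.
#'
#' @param psa_result a [psa()] result.
#' @param wtp_grid numeric vector of willingness-to-pay values ($/QALY).
#' @return data.frame `wtp`, `prob_ce`.
#' @export
ceac <- function(psa_result, wtp_grid) {
  stopifnot(inherits(psa_result, "psa_result"))
  it <- psa_result$iterations
  data.frame(wtp = wtp_grid,
             prob_ce = vapply(wtp_grid, function(w)
               mean(w * it$d_qaly - it$d_cost > 0), numeric(1)))
}

#' Scenario analyses
#'
#' Three policy scenarios around the base case:
#' \describe{
#'   \item{fsd}{every patient starts at the fixed 300 mg/day dose instead of
#'     the individualized 200/300 mg split.}
#'   \item{wtp}{the acceptability curve is read at regional
#'     willingness-to-pay thresholds spanning the lowest- and highest-GDP
#'     regions, in addition to the national threshold.}
#'   \item{insurance}{drug prices are replaced by out-of-pocket prices after
#'     National Basic Medical Insurance reimbursement
#'     (`costs$insurance_fractions`).}
#' }
#'
#' @inheritParams psa
#' @param scenarios subset of `c("fsd", "wtp", "insurance")`.
#' @param wtp national willingness-to-pay threshold ($/QALY).
#' @param wtp_range low/high regional thresholds ($/QALY).
#' @param n_iter PSA iterations backing the `wtp` scenario.
#' @return object of class `cea_scenarios` (named list of scenario results,
#'   plus the base-case comparison).
#' @export
run_scenarios <- function(spec, params = NULL,
                          scenarios = c("fsd", "wtp", "insurance"),
                          wtp = 37488, wtp_range = c(19002, 85176),
                          n_iter = 1000, seed = NULL) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  base <- run_cea(spec)
  out <- list(base = base)
  if ("fsd" %in% scenarios) {
    s <- spec
    s$dosing_mode <- "FSD"
    out$fsd <- run_cea(s)
  }
  if ("wtp" %in% scenarios) {
    if (is.null(params)) stop("the WTP scenario needs a PSA parameter table")
    pr <- psa(spec, params, n_iter = n_iter, seed = seed)
    out$wtp <- ceac(pr, sort(unique(c(wtp_range[1], wtp, wtp_range[2]))))
    out$psa <- pr
  }
  if ("insurance" %in% scenarios) {
    fr <- spec$costs$insurance_fractions
    if (is.null(fr)) stop("spec carries no insurance_fractions")
    s <- spec
    s$costs$oop_fractions[names(fr)] <- fr
    out$insurance <- run_cea(s)
  }
  structure(out, class = "cea_scenarios")
}

#' @export
print.cea_scenarios <- function(x, ...) {
  fmt <- function(r) if (r$dominance == "none")
    sprintf("ICER %.2f $/QALY (d_cost %.2f)", r$icer_per_qaly, r$d_cost)
  else sprintf("%s (d_cost %.2f)", r$dominance, r$d_cost)
  cat("Base case:      ", fmt(x$base), "\n")
  if (!is.null(x$fsd)) cat("Fixed dose:     ", fmt(x$fsd), "\n")
  if (!is.null(x$insurance)) cat("Insurance OOP:  ", fmt(x$insurance), "\n")
  if (!is.null(x$wtp)) {
    cat("P(cost-effective) by WTP threshold:\n")
    print(x$wtp, row.names = FALSE)
  }
  invisible(x)
}

#' Write sensitivity-analysis artifacts to CSV
#'
#' @param tornado a [one_way()] table (or NULL).
#' @param psa_result a [psa()] result (or NULL).
#' @param ceac_tab a [ceac()] table (or NULL).
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the directory.
#' @export
write_sensitivity <- function(tornado = NULL, psa_result = NULL,
                              ceac_tab = NULL, dir = ".", prefix = "sa") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(tornado))
    utils::write.csv(tornado, file.path(dir, paste0(prefix, "_tornado.csv")),
                     row.names = FALSE)
  if (!is.null(psa_result))
    utils::write.csv(psa_result$iterations,
                     file.path(dir, paste0(prefix, "_psa_iterations.csv")),
                     row.names = FALSE)
  if (!is.null(ceac_tab))
    utils::write.csv(ceac_tab, file.path(dir, paste0(prefix, "_ceac.csv")),
                     row.names = FALSE)
  invisible(dir)
}
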