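#' Run a configured analysis and write its artifacts
#'
#' The package's batch entry point: takes a run configuration (an R list or
#' the path of a YAML file with the same fields), runs the requested
#' analyses on the fixture or on a user-supplied spec config, and writes
#' tabular artifacts plus a run manifest to the output directory.
#'
#' Config fields: `cohort` (`"gBRCAm"` or `"non_gBRCAm"`), `spec_config`
#' (optional path to a [write_spec_config()] YAML; default is the built-in
#' fixture for the cohort), `analyses` (subset of `"base"`, `"owsa"`,
#' `"psa"`, `"scenarios"`, `"threshold_price"`), `seed` (required when the
#' PSA runs), `n_iter`, `wtp`, `wtp_range`.
#'
#' @param config list or YAML file path.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a character vector of the files written.
#' @export
run_analysis <- function(config, out_dir = "cea-output") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(cohort = "gBRCAm", spec_config = NULL, analyses = "base",
         seed = NULL, n_iter = 10000, wtp = 37488,
         wtp_range = c(19002, 85176)),
    config)
  bad <- setdiff(cfg$analyses,
                 c("base", "owsa", "psa", "scenarios", "threshold_price"))
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (any(cfg$analyses %in% c("psa", "scenarios")) && is.null(cfg$seed))
    stop("a seed is required for probabilistic analyses")

  spec <- if (is.null(cfg$spec_config)) nora_fixture(cfg$cohort)
  else read_spec_config(cfg$spec_config)
  params <- nora_parameters(spec)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(f) written <<- c(written, f)

  spec_file <- file.path(out_dir, "spec.yaml")
  write_spec_config(spec, spec_file)
  emit(spec_file)

  for (arm in names(spec$arms)) {
    f <- file.path(out_dir, paste0("trace_", arm, ".csv"))
    write_trace(markov_trace(spec, arm), f)
    emit(f)
  }
  if ("base" %in% cfg$analyses) {
    res <- run_cea(spec)
    write_ce_result(res, file.path(out_dir, "base_case"))
    emit(file.path(out_dir, c("base_case.csv", "base_case.json")))
  }
  if ("owsa" %in% cfg$analyses) {
    tor <- one_way(spec, params)
    f <- file.path(out_dir, "tornado.csv")
    utils::write.csv(tor, f, row.names = FALSE)
    emit(f)
  }
  if ("psa" %in% cfg$analyses) {
    pr <- psa(spec, params, n_iter = cfg$n_iter, seed = cfg$seed)
    grid <- seq(0, max(cfg$wtp_range), length.out = 101)
    write_sensitivity(psa_result = pr, ceac_tab = ceac(pr, grid),
                      dir = out_dir, prefix = "psa")
    emit(file.path(out_dir, c("psa_psa_iterations.csv", "psa_ceac.csv")))
  }
  if ("scenarios" %in% cfg$analyses) {
    sc <- run_scenarios(spec, params, wtp = cfg$wtp,
                        wtp_range = cfg$wtp_range,
                        n_iter = min(cfg$n_iter, 1000), seed = cfg$seed)
    f <- file.path(out_dir, "scenarios.csv")
    utils::write.csv(scenario_table(sc), f, row.names = FALSE)
    emit(f)
  }
  if ("threshold_price" %in% cfg$analyses) {
    tp <- threshold_price(spec, cfg$wtp)
    f <- file.path(out_dir, "threshold_price.csv")
    utils::write.csv(data.frame(wtp = cfg$wtp, threshold_price_per_mg = tp),
                     f, row.names = FALSE)
    emit(f)
  }
  manifest <- list(
    package = "niracea",
    version = as.character(utils::packageVersion("niracea")),
    cohort = cfg$cohort,
    analyses = cfg$analyses,
    seed = cfg$seed,
    n_iter = cfg$n_iter,
    spec_md5 = unname(tools::md5sum(spec_file)))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  emit(mf)
  invisible(written)
}

#' Flatten scenario results into a summary table
#' @param sc a [run_scenarios()] result.
#' @return data.frame with one row per scenario quantity.
#' @export
scenario_table <- function(sc) {
  stopifnot(inherits(sc, "cea_scenarios"))
  rows <- list()
  add <- function(scenario, quantity, value)
    rows[[length(rows) + 1]] <<- data.frame(scenario = scenario,
                                            quantity = quantity,
                                            value = value)
  ce_rows <- function(tag, r) {
    add(tag, "d_cost", r$d_cost)
    add(tag, "d_qaly", r$d_qaly)
    add(tag, "icer_per_qaly", r$icer_per_qaly)
  }
  ce_rows("base", sc$base)
  if (!is.null(sc$fsd)) ce_rows("fsd", sc$fsd)
  if (!is.null(sc$insurance)) ce_rows("insurance", sc$insurance)
  if (!is.null(sc$wtp))
    for (i in seq_len(nrow(sc$wtp)))
      add("wtp", paste0("prob_ce_at_", sc$wtp$wtp[i]), sc$wtp$prob_ce[i])
  do.call(rbind, rows)
}
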