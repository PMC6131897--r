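#' Run a reproducible simulate/map/evaluate workflow
#'
#' Executes a configured workflow end to end and writes all artifacts plus a
#' JSON manifest (package version, seed, configuration, output files) to
#' `out_dir`. Two modes:
#'
#' * **Simulation mode** (`config$simulate` present): simulates a cohort,
#'   scans it with the requested models (the interaction model uses
#'   noise-added measured purity), and scores each scan against the
#'   simulated truth.
#' * **File mode**: reads expression/genotype/purity/pairs/covariate TSVs
#'   named in the config and runs the requested scans.
#'
#' Identical configuration and seed reproduce byte-identical result tables.
#'
#' @param config A named list or the path of a YAML file. Recognized fields:
#'   `out_dir` (required), `seed`, `models` (character subset of
#'   `c("conventional", "interaction")`), `fdr` (default 0.05),
#'   `purity_noise_sd` (simulation mode; default from the sim config),
#'   `simulate` (list of [sim_config()] arguments), and in file mode
#'   `expression`, `genotypes`, `purity`, `pairs`, `covariates`, `truth`
#'   (file paths).
#' @return A named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) abort("config must name `out_dir`.")
  models <- config$models %||% c("conventional", "interaction")
  bad <- setdiff(models, c("conventional", "interaction"))
  if (length(bad))
    abort(paste0("unknown model(s): ", paste(bad, collapse = ", ")))
  fdr <- config$fdr %||% 0.05
  seed <- config$seed
  sim_mode <- !is.null(config$simulate)

  # validate before any computation
  if (!sim_mode) {
    for (f in c("expression", "genotypes"))
      if (is.null(config[[f]]))
        abort(sprintf("file mode requires `%s` in the config.", f))
    if ("interaction" %in% models && is.null(config$purity))
      abort("the interaction model requires a `purity` file.")
  }

  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  outputs <- list()

  if (sim_mode) {
    cfg <- do.call(sim_config, config$simulate %||% list())
    cohort <- tryCatch(simulate_cohort(cfg, seed = seed),
                       error = function(e) abort(paste0("simulate stage: ",
                                                        conditionMessage(e))))
    write_cohort(cohort, out_dir)
    outputs$cohort_dir <- out_dir
    noise_sd <- config$purity_noise_sd %||% cfg$purity_noise_sd
    measured <- add_purity_noise(cohort$purity, noise_sd = noise_sd,
                                 seed = if (!is.null(seed)) seed + 1L)
    write_purity(measured, p("purity_measured.tsv"), seed)
    for (m in models) {
      res <- eqtl_scan(cohort, model = m,
                       purity = if (m == "interaction") measured)
      rf <- p(sprintf("results_%s.tsv", m))
      write_eqtl_results(res, rf, seed)
      outputs[[paste0("results_", m)]] <- rf
      perf <- classify_performance(res, cohort$truth, fdr_threshold = fdr)
      pf <- p(sprintf("performance_%s.tsv", m))
      write_with_header(glance(perf), pf, paste0(m, " performance"), seed)
      outputs[[paste0("performance_", m)]] <- pf
    }
  } else {
    run_stage <- function(stage, code)
      tryCatch(code, error = function(e)
        abort(sprintf("%s stage: %s", stage, conditionMessage(e))))
    expr <- run_stage("read expression", read_matrix_tsv(config$expression))
    geno <- run_stage("read genotypes", read_genotypes(config$genotypes))
    purity <- if (!is.null(config$purity))
      run_stage("read purity", read_purity(config$purity))
    pairs <- if (!is.null(config$pairs))
      run_stage("read pairs", read_checked_tsv(config$pairs))
    covars <- if (!is.null(config$covariates))
      run_stage("read covariates", read_matrix_tsv(config$covariates))
    for (m in models) {
      res <- run_stage(paste0("map (", m, ")"),
                       eqtl_scan(expr, geno, pairs = pairs,
                                 purity = if (m == "interaction") purity,
                                 covariates = covars, model = m))
      rf <- p(sprintf("results_%s.tsv", m))
      write_eqtl_results(res, rf, seed)
      outputs[[paste0("results_", m)]] <- rf
      if (!is.null(config$truth)) {
        truth <- read_checked_tsv(config$truth)
        perf <- classify_performance(res, truth, fdr_threshold = fdr)
        pf <- p(sprintf("performance_%s.tsv", m))
        write_with_header(glance(perf), pf, paste0(m, " performance"), seed)
        outputs[[paste0("performance_", m)]] <- pf
      }
    }
  }

  manifest <- list(package = "tumoreqtl", version = pkg_version(),
                   seed = seed, fdr = fdr, models = models,
                   mode = if (sim_mode) "simulate" else "files",
                   config = config[setdiff(names(config), "out_dir")],
                   outputs = outputs)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  outputs$manifest <- p("manifest.json")
  inform(sprintf("pipeline complete: %d artifact(s) in %s",
                 length(outputs), out_dir))
  invisible(outputs)
}
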