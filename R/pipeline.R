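#' Run the full karyotype-evolution pipeline
#'
#' Orchestrates synthesize -> call -> karyotype -> E_X/A -> cohesion ->
#' model on a synthetic panel, writing plain-text outputs and a manifest.
#' Outputs are deterministic given `seed`; re-running with the same config
#' reproduces them byte for byte.
#'
#' @param config A named list or path to a YAML file with (all optional
#'   except `outdir`):
#' \describe{
#'   \item{`outdir`}{output directory.}
#'   \item{`seed`}{integer master seed (default 1); the panel uses `seed`,
#'     the sublines `seed + 1`.}
#'   \item{`stages`}{subset of `c("synth", "call", "karyotype", "exa",
#'     "cohesion", "model")` (default all, in order).}
#'   \item{`panel`}{[panel_config()] arguments.}
#'   \item{`sublines`}{[subline_config()] arguments.}
#'   \item{`model`}{`u`, `v`, `a`, `b`, `c` plus optional `observed` (a
#'     4-vector overriding the tally from the karyotype stage).}
#'   \item{`write_panel`}{write the synthetic panel TSVs under
#'     `outdir/panel/` (default `FALSE`; the downstream stages use the
#'     in-memory panel either way).}
#' }
#' @return The output directory, invisibly. Files written: `states.tsv`,
#'   `karyotypes.tsv`, `tally.json`, `exa.tsv`, `sublines.tsv`,
#'   `cohesion.json`, `fit.json`, `manifest.json` (config hash, package
#'   version, seed), subject to the stages selected.
#' @export
#' @examples
#' \donttest{
#' dir <- run_pipeline(list(
#'   outdir = tempfile("kev_run_"),
#'   seed = 7,
#'   panel = list(n_lines = 40, n_female = 20, n_male = 20,
#'                probes_per_chromosome = 80)
#' ))
#' list.files(dir)
#' }
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$outdir)) stopf("run_pipeline: config$outdir is required")
  stages_all <- c("synth", "call", "karyotype", "exa", "cohesion", "model")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stopf("run_pipeline: unknown stage(s): %s", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  fail <- function(stage, msg) stopf("pipeline stage '%s' failed: %s", stage, msg)

  panel <- NULL
  states <- NULL
  karyo <- NULL
  tally <- NULL

  if ("synth" %in% stages) {
    pargs <- config$panel %||% list()
    pargs$seed <- pargs$seed %||% seed
    if (!is.null(pargs$genotype_freqs)) pargs$genotype_freqs <- unlist(pargs$genotype_freqs)
    panel <- generate_panel(do.call(panel_config, pargs))
    if (isTRUE(config$write_panel)) write_panel(panel, file.path(outdir, "panel"))
  }

  if ("call" %in% stages) {
    if (is.null(panel)) {
      pd <- file.path(outdir, "panel")
      if (!dir.exists(pd)) fail("call", sprintf("no panel available; run the 'synth' stage or place one under %s", pd))
      panel <- read_panel(pd)
    }
    states <- call_states(panel)
    write_tsv(states, file.path(outdir, "states.tsv"))
  }

  if ("karyotype" %in% stages) {
    if (is.null(states)) fail("karyotype", "no chromosome states; run the 'call' stage first")
    karyo <- karyotype_panel(states, panel$expression, panel$truth$lines[c("line", "sex")])
    write_tsv(karyo, file.path(outdir, "karyotypes.tsv"))
    tally <- tally_clusters(karyo)
    jsonlite::write_json(
      c(as.list(tally_vector(tally, residual = TRUE)), list(n = tally$n_classified)),
      file.path(outdir, "tally.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("exa" %in% stages) {
    if (is.null(panel)) fail("exa", "no panel available; run the 'synth' stage first")
    exa <- exa_panel(panel$expression, panel$genes, platform = "array")
    write_tsv(exa, file.path(outdir, "exa.tsv"))
  }

  if ("cohesion" %in% stages) {
    sargs <- config$sublines %||% list()
    sargs$seed <- sargs$seed %||% (seed + 1L)
    sub <- generate_sublines(do.call(subline_config, sargs))
    write_tsv(sub, file.path(outdir, "sublines.tsv"))
    res <- poisson_chisq(sub, pooled = TRUE)
    jsonlite::write_json(
      list(observed = as.list(res$observed), expected = as.list(res$expected),
           lambda_hat = res$lambda_hat, statistic = res$statistic,
           df = res$df, p_value = res$p_value, verdict = res$verdict),
      file.path(outdir, "cohesion.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("model" %in% stages) {
    margs <- config$model %||% list()
    obs <- margs$observed %||% (if (!is.null(tally)) tally_vector(tally) else NULL)
    if (is.null(obs)) fail("model", "no observed cluster frequencies; run the 'karyotype' stage or set model$observed")
    fit <- fit_selection(unlist(obs),
                         u = margs$u %||% 0.1, v = margs$v %||% 0.01,
                         a = margs$a %||% 2, b = margs$b %||% 1.5,
                         c = margs$c %||% margs$b %||% 1.5,
                         grid_step = margs$grid_step %||% 0.05)
    ntest <- neutrality_test(unlist(obs)[1:3] / sum(unlist(obs)[1:3]))
    jsonlite::write_json(
      list(s_hat = fit$s_hat, t_hat = fit$t_hat, loss = fit$loss,
           fitted = as.list(fit$fitted), observed = as.list(fit$observed),
           neutrality_rejected = ntest$rejected,
           max_neutral_x3 = ntest$max_neutral_x3),
      file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA)
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("karyoevolve")),
    r_version = R.version.string,
    stages = stages
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
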