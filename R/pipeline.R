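#' Assemble a pipeline configuration
#'
#' Builds the configuration consumed by [run_pipeline()]: input source,
#' stage parameter blocks and seeds.  Defaults are desk-scale (small
#' MCMC and reference tables, suitable for interactive use); set
#' `scale = "full"` for production-scale admixture chains and ABC
#' tables.
#'
#' @param input either a file path (GenePop or delimited table) or a
#'   list `list(synthetic = "paperlike", seed = ...)` to analyse the
#'   built-in synthetic preset.
#' @param output_dir directory for all stage outputs (created).
#' @param format `"genepop"` or `"table"` for file inputs.
#' @param dialect optional [table_dialect()] for table inputs.
#' @param qc,stats,dapc,admixture,abc named lists overriding stage
#'   defaults; set a stage to `FALSE` to skip it.
#' @param seed master seed; stage seeds derive from it.
#' @param scale `"desk"` or `"full"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir, format = "genepop",
                            dialect = NULL, qc = list(), stats = list(),
                            dapc = list(), admixture = list(),
                            abc = list(), seed = 1L, scale = "desk") {
  full <- identical(scale, "full")
  def <- list(
    qc = list(max_missing = 0.10, drop_monomorphic = TRUE),
    stats = list(n_permutations = if (full) 999 else 199),
    dapc = list(n_pcs = NULL, folds = 5),
    admixture = list(k_values = 1:6, n_runs = if (full) 10 else 3,
                     burnin = if (full) 200000 else 2000,
                     iters = if (full) 200000 else 4000,
                     thin = if (full) 100 else 10),
    abc = list(enabled = FALSE, n_per_scenario = if (full) 1e6 else 1e4,
               n_closest = 500, fraction = 0.01, step2 = FALSE,
               n_loci = NULL))
  merge_stage <- function(name, user) {
    if (isFALSE(user)) return(FALSE)
    modifyList(def[[name]], user)
  }
  structure(list(
    input = input, output_dir = output_dir, format = format,
    dialect = dialect,
    qc = merge_stage("qc", qc), stats = merge_stage("stats", stats),
    dapc = merge_stage("dapc", dapc),
    admixture = merge_stage("admixture", admixture),
    abc = merge_stage("abc", abc),
    seed = as.integer(seed), scale = scale), class = "pipeline_config")
}

.validate_pipeline_config <- function(cfg) {
  if (is.character(cfg$input) && !file.exists(cfg$input))
    stop("pipeline validation: input file does not exist: ", cfg$input)
  if (is.list(cfg$input) && !identical(cfg$input$synthetic, "paperlike"))
    stop("pipeline validation: unknown synthetic input")
  if (!cfg$format %in% c("genepop", "table"))
    stop("pipeline validation: unknown format ", cfg$format)
  invisible(TRUE)
}

#' Run the full outbreak-genetics workflow
#'
#' QC (missingness filter, monomorphic-locus drop), per-population
#' diversity summaries and pairwise F_ST, DAPC, admixture clustering
#' over a K grid with Evanno diagnostics, and (optionally, when the
#' dataset carries Marly-style spot metadata) the coalescent-ABC
#' demographic reconstruction.  Every stage writes its tables (CSV) and
#' a machine report (JSON) into `output_dir` as soon as it completes, so
#' a later failure never destroys earlier outputs; the manifest records
#' config, seeds and per-stage status/runtimes.
#'
#' @param config a [pipeline_config()] (or a YAML file path whose
#'   content maps onto its arguments).
#' @return (invisibly) the report list: per-stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg)
  }
  .validate_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "outbreakgen",
                   version = as.character(utils::packageVersion("outbreakgen")),
                   seed = config$seed, scale = config$scale,
                   started = format(Sys.time()), stages = list())
  report <- list()
  jwrite <- function(x, f)
    jsonlite::write_json(x, file.path(out, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) e)
    el <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed", seconds = el,
      error = if (ok) NULL else conditionMessage(res))
    jwrite(manifest, "manifest.json")
    if (!ok) {
      warning("stage '", name, "' failed: ", conditionMessage(res))
      return(NULL)
    }
    res
  }

  # ---- input + QC
  ds0 <- stage("input", function() {
    if (is.list(config$input))
      make_paperlike_dataset(config$input$seed %||% config$seed)$dataset
    else if (config$format == "genepop") read_genepop(config$input)
    else read_genotype_table(config$input,
                             config$dialect %||% table_dialect())
  })
  if (is.null(ds0)) stop("pipeline aborted: input stage failed")

  ds <- ds0
  if (!isFALSE(config$qc)) {
    qc <- stage("qc", function()
      qc_dataset(ds0, config$qc$max_missing, config$qc$drop_monomorphic))
    if (!is.null(qc)) {
      ds <- qc$dataset
      report$qc <- qc$report
      jwrite(qc$report, "qc.json")
    }
  }

  # ---- diversity + differentiation
  if (!isFALSE(config$stats)) {
    st <- stage("stats", function() {
      su <- summarize_populations(ds, config$stats$n_permutations,
                                  seed = config$seed)
      fm <- fst_matrix(ds, n_permutations = config$stats$n_permutations,
                       seed = config$seed + 100L)
      list(summary = su, fst = fm)
    })
    if (!is.null(st)) {
      report$stats <- st
      write.csv(st$summary, file.path(out, "population_summary.csv"),
                row.names = FALSE)
      write.csv(st$fst, file.path(out, "fst_pairwise.csv"),
                row.names = FALSE)
      jwrite(st, "stats.json")
    }
  }

  # ---- DAPC
  if (!isFALSE(config$dapc)) {
    dp <- stage("dapc", function()
      dapc_populations(ds, n_pcs = config$dapc$n_pcs,
                       folds = config$dapc$folds,
                       seed = config$seed + 200L))
    if (!is.null(dp)) {
      report$dapc <- list(n_pcs = dp$n_pcs_retained,
                          groups = dp$group_labels,
                          mean_self_posterior = mean(vapply(
                            seq_len(nrow(dp$posterior)), function(i)
                              dp$posterior[i, dp$assigned[i]], numeric(1))))
      jwrite(c(report$dapc,
               list(coords = as.data.frame(dp$specimen_coords))),
             "dapc.json")
    }
  }

  # ---- admixture
  if (!isFALSE(config$admixture)) {
    ad <- stage("admixture", function() {
      a <- config$admixture
      structure_kscan(ds, k_values = a$k_values, n_runs = a$n_runs,
                      seed = config$seed + 300L, burnin = a$burnin,
                      iters = a$iters, thin = a$thin)
    })
    if (!is.null(ad)) {
      report$admixture <- list(
        lnpk = lapply(ad$lnpk, unname),
        best_k = if (!is.null(ad$evanno)) attr(ad$evanno, "best_k"),
        assignment_diagnostic = ad$assignment_diagnostic)
      if (!is.null(ad$evanno))
        write.csv(as.data.frame(ad$evanno),
                  file.path(out, "evanno.csv"), row.names = FALSE)
      for (K in names(ad$q_aligned))
        write.csv(as.data.frame(ad$q_aligned[[K]]),
                  file.path(out, paste0("qmatrix_K", K, ".csv")))
      jwrite(report$admixture, "admixture.json")
    }
  }

  # ---- ABC demographic reconstruction
  if (!isFALSE(config$abc) && isTRUE(config$abc$enabled)) {
    abr <- stage("abc", function() {
      md <- marly_demes(ds)
      sizes <- table(md$metadata$population)
      sample_config <- stats::setNames(as.integer(sizes), names(sizes))
      sample_config <- sample_config[c("Ma1", "Ma2", "Br")]
      n_loci <- config$abc$n_loci %||% n_loci(md)
      scs <- default_scenarios()
      pr <- default_priors(step2 = config$abc$step2)
      tab <- build_reference_table(scs, pr, config$abc$n_per_scenario,
                                   sample_config, n_loci = n_loci,
                                   seed = config$seed + 400L)
      obs <- compute_sumstats(md, c("Ma1", "Ma2", "Br"))
      direct <- select_scenario_direct(obs, tab, config$abc$n_closest)
      lda <- select_scenario_lda_logistic(obs, tab, config$abc$fraction)
      best <- lda$best
      sub <- tab
      keep <- tab$scenario == best
      sub$scenario <- droplevels(tab$scenario[keep])
      sub$params <- tab$params[keep, , drop = FALSE]
      sub$stats <- tab$stats[keep, , drop = FALSE]
      est <- estimate_parameters(obs, sub,
                                 fraction = max(config$abc$fraction,
                                                60 / sum(keep)))
      list(observed = obs, direct = direct, lda = lda, best = best,
           estimate = est$summary, sample_config = sample_config)
    })
    if (!is.null(abr)) {
      report$abc <- abr
      jwrite(list(direct = abr$direct$posterior,
                  lda = abr$lda$posterior, best = abr$best,
                  estimate = abr$estimate,
                  observed = as.list(abr$observed)), "abc.json")
    }
  }

  manifest$finished <- format(Sys.time())
  manifest$config <- list(
    seed = config$seed, scale = config$scale,
    input = if (is.character(config$input)) config$input else "synthetic")
  jwrite(manifest, "manifest.json")
  report$manifest <- manifest
  invisible(report)
}
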