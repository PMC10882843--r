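# End-to-end orchestration: simulate or ingest, normalize, diversity,
# enterotypes, maturation, differential abundance, AMR trends and qPCR
# models, driven by one config with per-stage sub-seeds and a JSON manifest.

default_pipeline_config <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    simulation = NULL,
    inputs = NULL,
    normalization = list(quantile = 0.5, scale_constant = 1000),
    dmm = list(k_range = 1:7, n_restarts = 3),
    permanova = list(terms = c("age_weeks", "cohort"), strata = "pig_id",
                     n_permutations = 999),
    maturation = list(ra_threshold = 0.005, n_permutations = 1000),
    da = list(min_mean_ra = 1e-4, alpha_p = 0.05, alpha_q = 0.25),
    amr = list(n_knots = 9, degree = 3, penalty_order = 2, grid_length = 101)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- data (simulate from a config or
#' read from input paths), CSS normalization, alpha diversity, Bray-Curtis +
#' PERMANOVA, enterotype selection and trajectories, maturation scores,
#' differential abundance, AMR spline trends with significance windows, and
#' qPCR models -- writing each stage's TSV outputs under `output_dir` and a
#' JSON manifest of files, seed and stage status. A stage failure halts the
#' stages that depend on it and is recorded in the manifest. All randomness
#' derives from the global seed via per-stage sub-seeds, so reruns with the
#' same config are identical.
#'
#' @param config a config list (see Details) or the path to a YAML file with
#'   the same structure. Exactly one of `simulation` (a list of
#'   [cohort_config()] overrides) or `inputs` (paths `counts`, `metadata`,
#'   and optionally `amr`, `qpcr`) must be given.
#' @return a `pipeline_report`: list with `results` (in-memory stage
#'   outputs), `manifest` (stage status + files), `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  if (is.null(cfg$simulation) == is.null(cfg$inputs)) {
    abort("exactly one of `simulation` or `inputs` must be configured")
  }
  outdir <- cfg$output_dir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  manifest <- list(seed = seed, stages = list(), files = character(0))
  results <- list()
  failed <- FALSE

  write_out <- function(tbl, name) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    manifest$files <<- c(manifest$files, path)
  }
  run_stage <- function(name, expr) {
    if (failed) {
      manifest$stages[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) {
      failed <<- TRUE
      manifest$stages[[name]] <<- paste0("failed: ", conditionMessage(e))
      NULL
    })
    if (!failed) manifest$stages[[name]] <<- "ok"
    res
  }

  results$data <- run_stage("data", {
    if (!is.null(cfg$simulation)) {
      sim_cfg <- do.call(cohort_config,
                         modifyList(cfg$simulation,
                                    list(seed = stage_seed(seed, "simulate"))))
      sim <- simulate_cohort(sim_cfg)
      list(dataset = sim$dataset, truth = sim$truth,
           fungal_counts = sim$fungal_counts)
    } else {
      paths <- cfg$inputs
      if (is.null(paths$counts) || is.null(paths$metadata)) {
        abort("inputs must provide `counts` and `metadata` paths")
      }
      for (pp in unlist(paths)) {
        if (!file.exists(pp)) abort(paste0("missing input file: ", pp))
      }
      ds <- assemble_dataset(
        read_count_table(paths$counts),
        read_metadata(paths$metadata),
        amr = if (!is.null(paths$amr)) read_amr_table(paths$amr),
        qpcr = if (!is.null(paths$qpcr)) read_qpcr_table(paths$qpcr)
      )
      list(dataset = ds, truth = NULL)
    }
  })

  ds <- results$data$dataset
  results$normalized <- run_stage("normalize", {
    norm <- css_normalize(ds$counts, quantile = cfg$normalization$quantile,
                          scale_constant = cfg$normalization$scale_constant)
    write_out(norm, "normalized_counts.tsv")
    norm
  })
  results$alpha <- run_stage("alpha_diversity", {
    a <- alpha_diversity(ds$counts) %>%
      left_join(ds$metadata, by = "sample_id")
    write_out(a, "alpha_diversity.tsv")
    a
  })
  results$permanova <- run_stage("permanova", {
    bc <- bray_curtis(results$normalized)
    fit <- permanova(bc, ds$metadata, terms = cfg$permanova$terms,
                     strata = cfg$permanova$strata,
                     n_permutations = cfg$permanova$n_permutations,
                     seed = stage_seed(seed, "permanova"))
    write_out(tidy(fit), "permanova.tsv")
    fit
  })
  results$enterotypes <- run_stage("enterotypes", {
    sel <- select_k(ds$counts, k_range = cfg$dmm$k_range,
                    n_restarts = cfg$dmm$n_restarts,
                    seed = stage_seed(seed, "dmm"))
    assign <- assign_enterotypes(sel$models[[as.character(sel$selected_k)]],
                                 ds$counts)
    traj <- enterotype_trajectories(assign, ds$metadata)
    write_out(sel$scores, "model_scores.tsv")
    write_out(assign, "assignments.tsv")
    write_out(traj$proportions, "enterotype_proportions.tsv")
    list(selection = sel, assignments = assign, trajectories = traj)
  })
  results$maturation <- run_stage("maturation", {
    ranks <- first_appearance_ranks(ds$counts, ds$metadata,
                                    ra_threshold = cfg$maturation$ra_threshold)
    cons <- consensus_order(ranks,
                            n_permutations = cfg$maturation$n_permutations,
                            seed = stage_seed(seed, "maturation"))
    scores <- maturation_scores(cons, ds$counts, ds$metadata,
                                ra_threshold = cfg$maturation$ra_threshold)
    write_out(scores, "maturation_scores.tsv")
    list(consensus = cons, scores = scores)
  })
  results$differential_abundance <- run_stage("differential_abundance", {
    da <- differential_abundance_scan(results$normalized, ds$metadata,
                                      min_mean_ra = cfg$da$min_mean_ra,
                                      alpha_p = cfg$da$alpha_p,
                                      alpha_q = cfg$da$alpha_q)
    write_out(da, "differential_abundance.tsv")
    da
  })
  results$amr_trends <- run_stage("amr_trends", {
    if (is.null(ds$amr)) return(NULL)
    dat <- ds$amr %>% left_join(ds$metadata, by = "sample_id")
    series <- dat %>% distinct(.data$bacterium, .data$drug_class)
    wins <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
      sub <- dat %>% filter(.data$bacterium == series$bacterium[i],
                            .data$drug_class == series$drug_class[i])
      fit <- fit_penalized_spline_ar1(sub, n_knots = cfg$amr$n_knots,
                                      degree = cfg$amr$degree,
                                      penalty_order = cfg$amr$penalty_order)
      grid <- seq(fit$age_range[1], fit$age_range[2],
                  length.out = cfg$amr$grid_length)
      sw <- significance_windows(derivative_band(fit, grid))
      if (!nrow(sw)) return(NULL)
      sw$bacterium <- series$bacterium[i]
      sw$drug_class <- series$drug_class[i]
      sw
    })
    write_out(wins, "amr_significance_windows.tsv")
    wins
  })
  results$qpcr <- run_stage("qpcr", {
    if (is.null(ds$qpcr)) return(NULL)
    qm <- qpcr_age_models(ds$qpcr, ds$metadata)
    write_out(qm, "qpcr_models.tsv")
    qm
  })

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(results = results, manifest = manifest, config = cfg),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed =", x$manifest$seed, "\n")
  for (nm in names(x$manifest$stages)) {
    cat(sprintf("  %-24s %s\n", nm, x$manifest$stages[[nm]]))
  }
  invisible(x)
}
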