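#' Run an end-to-end workflow
#'
#' Orchestrates the pipeline's two measurement workflows plus a pure
#' simulation mode. Configuration is a named list (or a YAML file path with
#' the same structure):
#'
#' * `workflow = "simulate"`: generates a petite time series, a set of
#'   growth curves, a colony-area table and a screen count table, writing
#'   each as TSV/CSV under `out_dir`.
#' * `workflow = "loss_rate"`: reads (or takes) a petite series, estimates
#'   the mtDNA loss rate with bootstrap CI, and writes a JSON report.
#' * `workflow = "screen"`: reads (or takes) a count table, runs the
#'   requested contrast, selects hits, and writes results TSV + JSON
#'   report.
#'
#' Every stochastic stage receives a sub-seed derived deterministically
#' from the global `seed`, and the report logs them; rerunning an identical
#' config gives byte-identical outputs.
#'
#' @param config Named list or YAML path. Top-level fields: `workflow`,
#'   `seed`, plus one parameter block per stage (see the vignette for the
#'   full schema). Data may be passed in-memory via `config$data` instead
#'   of file paths.
#' @param out_dir Output directory; created if missing. `NULL` (default)
#'   skips file output and just returns the report.
#' @return A report list (estimates, hit tables, diagnostics, seeds),
#'   invisibly when `out_dir` is set.
#' @export
run_workflow <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$workflow)) {
    stop_validation("`config` must be a list (or YAML path) with a `workflow` field.")
  }
  workflow <- match.arg(config$workflow, c("simulate", "loss_rate", "screen"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- switch(workflow,
    simulate = workflow_simulate(config, seed, out_dir),
    loss_rate = workflow_loss_rate(config, seed, out_dir),
    screen = workflow_screen(config, seed, out_dir)
  )
  report$workflow <- workflow
  report$seed <- seed
  report$package_version <- as.character(utils::packageVersion("rhozero"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_for_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

report_for_json <- function(x) {
  # tibbles -> data frames for stable json; drop bulky raw data
  rapply(x, function(el) el, how = "replace")
}

cfg_get <- function(config, block, name, default) {
  v <- config[[block]][[name]]
  if (is.null(v)) default else v
}

workflow_simulate <- function(config, seed, out_dir) {
  seeds <- derive_seeds(seed, 4)
  mp <- config$model
  params <- two_state_params(
    g_wt = if (is.null(mp$g_wt)) 0.4 else mp$g_wt,
    g_mut = if (is.null(mp$g_mut)) 0.4 else mp$g_mut,
    r = if (is.null(mp$r)) 0.15 else mp$r
  )
  series <- generate_petite_time_series(
    params,
    sampling_times = cfg_get(config, "petite", "sampling_times", c(0, 3, 6, 9)),
    colonies_per_plate = cfg_get(config, "petite", "colonies_per_plate", 150),
    n_replicates = cfg_get(config, "petite", "n_replicates", 8),
    baseline_fraction = cfg_get(config, "petite", "baseline_fraction", 0.02),
    seed = seeds[1]
  )
  rates <- cfg_get(config, "growth", "rates", c(0.2, 0.3, 0.4))
  curve_seeds <- derive_seeds(seeds[2], length(rates))
  curves <- purrr::map2_dfr(rates, seq_along(rates), function(rt, i) {
    generate_growth_curve(rate = rt, curve_id = sprintf("well%02d", i),
                          seed = curve_seeds[i])
  })
  colonies <- generate_colony_areas(
    n = cfg_get(config, "colonies", "n", 300),
    petite_fraction = cfg_get(config, "colonies", "petite_fraction", 0.3),
    label_noise = cfg_get(config, "colonies", "label_noise", 0),
    seed = seeds[3]
  )
  spikes <- config$screen$spikes
  if (!is.null(spikes)) spikes <- as_tibble(spikes)
  counts <- generate_screen_counts(
    n_genes = cfg_get(config, "screen", "n_genes", 1000),
    n_reps = cfg_get(config, "screen", "n_reps", 3),
    library_size = cfg_get(config, "screen", "library_size", 2e5),
    spikes = spikes,
    dispersion = cfg_get(config, "screen", "dispersion", 0.05),
    seed = seeds[4]
  )
  if (!is.null(out_dir)) {
    readr::write_tsv(series, file.path(out_dir, "petite_series.tsv"))
    write_plate_csv(curves, file.path(out_dir, "plate.csv"))
    readr::write_csv(colonies, file.path(out_dir, "colonies.csv"))
    write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))
  }
  list(
    stage_seeds = as.list(setNames(seeds, c("petite", "growth", "colonies", "screen"))),
    n_series_rows = nrow(series), n_curves = length(rates),
    n_colonies = nrow(colonies),
    n_genes = cfg_get(config, "screen", "n_genes", 1000),
    data = list(series = series, curves = curves, colonies = colonies,
                counts = counts)
  )
}

workflow_loss_rate <- function(config, seed, out_dir) {
  series <- if (!is.null(config$data$series)) {
    as_tibble(config$data$series)
  } else if (!is.null(config$loss_rate$series_tsv)) {
    read_petite_series_tsv(config$loss_rate$series_tsv)
  } else {
    stop_validation("loss_rate workflow needs `data$series` or `loss_rate$series_tsv`.")
  }
  fit <- estimate_loss_rate(
    series,
    g_wt = cfg_get(config, "loss_rate", "g_wt", 0.4),
    g_mut = cfg_get(config, "loss_rate", "g_mut", 0.2),
    fit_f0 = cfg_get(config, "loss_rate", "fit_f0", TRUE),
    method = cfg_get(config, "loss_rate", "method", "wls"),
    n_boot = cfg_get(config, "loss_rate", "n_boot", 1000),
    conf_level = cfg_get(config, "loss_rate", "conf_level", 0.90),
    seed = derive_seeds(seed, 1)
  )
  summary_tbl <- petite_fraction_summary(
    if ("genotype" %in% names(series)) series else
      dplyr::mutate(series, genotype = "unknown")
  )
  if (!is.null(out_dir)) {
    readr::write_tsv(summary_tbl, file.path(out_dir, "petite_summary.tsv"))
  }
  list(
    estimate = as.list(glance(fit)),
    summary = summary_tbl
  )
}

workflow_screen <- function(config, seed, out_dir) {
  counts <- if (!is.null(config$data$counts)) {
    as_tibble(config$data$counts)
  } else if (!is.null(config$screen$counts_tsv)) {
    sample_info <- NULL
    if (!is.null(config$screen$sample_indexes_tsv)) {
      sample_info <- read_sample_index_tsv(config$screen$sample_indexes_tsv)
    }
    read_counts_tsv(config$screen$counts_tsv, sample_info = sample_info)
  } else {
    stop_validation("screen workflow needs `data$counts` or `screen$counts_tsv`.")
  }
  contrast <- cfg_get(config, "screen", "contrast", c("etbr", "control"))
  fdr <- cfg_get(config, "screen", "fdr", 0.05)
  res <- run_contrast(counts, contrast, fdr = fdr)
  hits <- select_hits(res, mode = "fdr", fdr = fdr)
  if (!is.null(out_dir)) {
    readr::write_tsv(res, file.path(out_dir, "enrichment_results.tsv"))
    readr::write_tsv(hits, file.path(out_dir, "hits.tsv"))
  }
  list(
    contrast = contrast, fdr = fdr,
    n_genes = nrow(res), n_hits = nrow(hits),
    hits = hits, results = res
  )
}
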