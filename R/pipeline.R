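#' Run the full analysis pipeline on a replicate table
#'
#' Orchestrates the analysis stages over one replicate table: per-isolate
#' bootstrap effect sizes for both responses with the gradual-vs-abrupt
#' contrast; per-isolate Tukey HSD on biomass; isolate-level Pearson
#' correlations (biomass effect vs control biomass per arm, contrast vs
#' control biomass, biomass effect vs accumulation effect per arm);
#' reaction-pattern and strategy calls; and, when a tree is supplied, the
#' phylogenetic-signal table.  Every stage's table is written as CSV to
#' `config$out_dir` together with a run log recording seeds and settings.
#'
#' @param config a [run_config()].
#' @param table a replicate table (e.g. from [simulate_experiment()] or
#'   [read_replicate_table()]).
#' @param tree optional [ape::phylo] tree over the isolates; if omitted the
#'   phylogenetic-signal stage is skipped with a logged notice.
#' @return (invisibly) a list of tibbles:
#'   `es_biomass`, `es_copper`, `tukey`, `correlations`, `calls`,
#'   `phylo_signal` (NULL when no tree), plus `paths` of the written files.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(n_isolates = 4, n_boot = 1999)
#' tab <- simulate_experiment(
#'   experiment_design(isolate_ids = sprintf("ISO%02d", 1:4)),
#'   generate_isolate_panel(4, seed = 1), seed = 1)
#' res <- run_pipeline(cfg, tab)
#' }
run_pipeline <- function(config, table, tree = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("rampulse %s", as.character(utils::packageVersion("rampulse"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d  n_boot %d  alpha %g  n_perm %d",
            config$seed, config$n_boot, config$alpha, config$n_perm),
    sprintf("isolates %d  rows %d", length(unique(table$isolate)),
            nrow(table))
  )
  note <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  note("stage: effect sizes (biomass)")
  es_bio <- effect_size_table(table, "biomass_g", config$n_boot,
                              config$alpha, config$seed)
  note("stage: effect sizes (copper accumulation)")
  es_cu <- effect_size_table(table, "cu_mg_per_g", config$n_boot,
                             config$alpha, config$seed + 10000L)
  note("stage: Tukey HSD per isolate (biomass)")
  tukey <- tukey_table(table, "biomass_g")
  note("stage: correlations on isolate means")
  correlations <- .correlation_stage(table, es_bio, es_cu, config$alpha)
  note("stage: pattern and strategy calls")
  calls <- classify_panel(table, config$n_boot, config$alpha, config$seed)

  phylo <- NULL
  if (is.null(tree)) {
    note("no tree supplied: phylogenetic-signal stage skipped")
  } else {
    note("stage: phylogenetic signal (Blomberg's K, 6 responses)")
    phylo <- phylo_signal_table(table, tree, config$n_perm,
                                config$seed + 20000L)
  }

  paths <- c(
    es_biomass = .write_stage(es_bio, config$out_dir, "effect_sizes_biomass.csv"),
    es_copper = .write_stage(es_cu, config$out_dir, "effect_sizes_copper.csv"),
    tukey = .write_stage(tukey, config$out_dir, "tukey_biomass.csv"),
    correlations = .write_stage(correlations, config$out_dir,
                                "correlations.csv"),
    calls = .write_stage(calls, config$out_dir, "pattern_strategy_calls.csv")
  )
  if (!is.null(phylo)) {
    paths <- c(paths, phylo_signal = .write_stage(phylo, config$out_dir,
                                                  "phylo_signal.csv"))
  }
  note("note: no multiplicity correction across isolates is applied")
  writeLines(log_lines, log_path)
  paths <- c(paths, run_log = log_path)

  invisible(list(es_biomass = es_bio, es_copper = es_cu, tukey = tukey,
                 correlations = correlations, calls = calls,
                 phylo_signal = phylo, paths = paths))
}

.write_stage <- function(tab, dir, name) {
  path <- file.path(dir, name)
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 15,
                                                   format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

# isolate-level correlations mirroring the study's Figs 3-4 structure
.correlation_stage <- function(table, es_bio, es_cu, alpha) {
  ctrl <- table[table$treatment == "control", ]
  ctrl_mean <- tapply(ctrl$biomass_g, ctrl$isolate, mean)
  ord <- es_bio$isolate
  cb <- as.numeric(ctrl_mean[ord])
  rows <- list(
    list("es_biomass_vs_control_biomass", "gradual", es_bio$es_gradual, cb),
    list("es_biomass_vs_control_biomass", "abrupt", es_bio$es_abrupt, cb),
    list("delta_es_vs_control_biomass", "abrupt-gradual", es_bio$delta, cb),
    list("es_biomass_vs_es_copper", "gradual", es_bio$es_gradual,
         es_cu$es_gradual[match(ord, es_cu$isolate)]),
    list("es_biomass_vs_es_copper", "abrupt", es_bio$es_abrupt,
         es_cu$es_abrupt[match(ord, es_cu$isolate)])
  )
  do.call(rbind, lapply(rows, function(r) {
    ct <- pearson_ci(r[[3]], r[[4]], alpha)
    tibble::tibble(comparison = r[[1]], arm = r[[2]], r = ct$r, p = ct$p,
                   ci_low = ct$ci_low, ci_high = ct$ci_high, n = ct$n)
  }))
}
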