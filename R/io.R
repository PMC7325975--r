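#' Read a replicate measurement table
#'
#' Reads and validates the long-format CSV with header
#' `isolate,treatment,replicate,biomass_g,cu_mg_per_g`.  Unknown treatment
#' labels, non-numeric responses and duplicate
#' (isolate, treatment, replicate) keys are rejected; incomplete design
#' cells are reported as a warning.
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_replicate_table <- function(path) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot read '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  required <- c("isolate", "treatment", "replicate", "biomass_g",
                "cu_mg_per_g")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty replicate table", call. = FALSE)
  bad_trt <- !tab$treatment %in% c("control", "gradual", "abrupt")
  if (any(bad_trt)) {
    stop("unknown treatment label(s) in row(s) ",
         paste(utils::head(which(bad_trt), 10), collapse = ", "), ": ",
         paste(unique(tab$treatment[bad_trt]), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("replicate", "biomass_g", "cu_mg_per_g")) {
    if (!is.numeric(tab[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (anyNA(tab[[col]])) {
      stop("column '", col, "' contains missing values", call. = FALSE)
    }
  }
  key <- paste(tab$isolate, tab$treatment, tab$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (isolate, treatment, replicate) keys, e.g. ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  cells <- table(tab$isolate, tab$treatment)
  if (length(unique(as.vector(cells))) > 1L) {
    warning("incomplete design: cell counts range from ", min(cells), " to ",
            max(cells), call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' Write a replicate table as CSV
#'
#' Numeric columns are written at full double precision (15 significant
#' digits), so a write/read round trip is lossless to at least 12
#' significant digits.
#'
#' @param table a replicate table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_replicate_table <- function(table, path) {
  out <- as.data.frame(table)
  for (col in c("biomass_g", "cu_mg_per_g")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every tunable setting of the pipeline.  The defaults are the
#' reference study conditions: a 17 x 3 x 5 design (255 units), 5-day
#' pre-incubation, 9 treatment days with a 1 mM final concentration and the
#' abrupt step on day 5, 9999 bootstrap iterations, 95% intervals, and 999
#' tip permutations.
#'
#' @param n_isolates number of isolates (used when simulating).
#' @param n_replicates replicates per cell.
#' @param pre_incubation_days,treatment_days,final_conc,step_day schedule
#'   settings, see [experiment_design()].
#' @param n_boot bootstrap iterations.
#' @param alpha significance / CI level.
#' @param n_perm tip permutations for the phylogenetic-signal test.
#' @param seed master seed; all pipeline randomness derives from it.
#' @param out_dir output directory for [run_pipeline()] tables.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_isolates = 17, n_replicates = 5,
                       pre_incubation_days = 5, treatment_days = 9,
                       final_conc = 1, step_day = 5,
                       n_boot = 9999, alpha = 0.05, n_perm = 999,
                       seed = 1L, out_dir = tempfile("rampulse_run_")) {
  stopifnot(n_boot >= 1000, alpha > 0, alpha < 1, n_perm >= 99)
  structure(
    list(n_isolates = as.integer(n_isolates),
         n_replicates = as.integer(n_replicates),
         pre_incubation_days = as.integer(pre_incubation_days),
         treatment_days = as.integer(treatment_days),
         final_conc = final_conc, step_day = as.integer(step_day),
         n_boot = as.integer(n_boot), alpha = alpha,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Read/write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a [run_config()] (unknown keys are rejected).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(unclass(x)), "out_dir")) {
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-20s %s\n", "out_dir", x$out_dir))
  invisible(x)
}
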