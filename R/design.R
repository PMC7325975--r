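#' Experimental design of a gradual-vs-abrupt stress assay
#'
#' Captures the factorial layout of the liquid-culture experiment: a panel of
#' isolates, the three treatment arms (control, gradual, abrupt), a number of
#' replicates per cell, a stressor-free pre-incubation phase, and the shared
#' schedule parameters of the treatment phase.  The defaults reproduce the
#' reference layout: 17 isolates x 3 treatments x 5 replicates = 255
#' experimental units, 5 days of pre-incubation, a 9-day treatment phase, a
#' 1 mM final copper concentration, and the abrupt step on treatment day 5.
#'
#' @param isolate_ids character vector of unique isolate identifiers.
#' @param n_replicates replicates per isolate x treatment cell.
#' @param pre_incubation_days stressor-free days before the treatment phase.
#' @param treatment_days length of the treatment phase (days).
#' @param final_conc final stressor concentration (mM).
#' @param step_day day of the abrupt step within the treatment phase.
#' @param inoculum_g initial biomass per culture (g dry weight).
#'
#' @return an object of class `experiment_design`.
#' @export
#' @examples
#' d <- experiment_design()
#' n_units(d) # 255
experiment_design <- function(isolate_ids = sprintf("ISO%02d", 1:17),
                              n_replicates = 5,
                              pre_incubation_days = 5,
                              treatment_days = 9,
                              final_conc = 1,
                              step_day = 5,
                              inoculum_g = 0.002) {
  isolate_ids <- as.character(isolate_ids)
  if (anyDuplicated(isolate_ids)) {
    stop("isolate ids must be unique", call. = FALSE)
  }
  stopifnot(
    n_replicates >= 0, n_replicates == round(n_replicates),
    pre_incubation_days >= 0, treatment_days >= 1,
    final_conc > 0, step_day >= 1, step_day <= treatment_days,
    inoculum_g > 0
  )
  structure(
    list(isolate_ids = isolate_ids,
         treatments = c("control", "gradual", "abrupt"),
         n_replicates = as.integer(n_replicates),
         pre_incubation_days = as.integer(pre_incubation_days),
         treatment_days = as.integer(treatment_days),
         final_conc = final_conc,
         step_day = as.integer(step_day),
         inoculum_g = inoculum_g),
    class = "experiment_design"
  )
}

#' Total number of experimental units in a design
#'
#' @param design an [experiment_design()].
#' @return integer: isolates x treatments x replicates.
#' @export
n_units <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  length(design$isolate_ids) * length(design$treatments) * design$n_replicates
}

#' The three treatment-arm schedules implied by a design
#'
#' @param design an [experiment_design()].
#' @return named list of [treatment_schedule()] objects
#'   (`control`, `gradual`, `abrupt`).
#' @export
design_schedules <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  list(
    control = control_schedule(design$treatment_days),
    gradual = build_gradual_schedule(design$final_conc, design$treatment_days),
    abrupt  = build_abrupt_schedule(design$final_conc, design$treatment_days,
                                    design$step_day)
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_design> %d isolates x %d treatments x %d replicates",
    " = %d units\n  pre-incubation %d d, treatment %d d,",
    " final %.3g mM, abrupt step day %d\n"),
    length(x$isolate_ids), length(x$treatments), x$n_replicates, n_units(x),
    x$pre_incubation_days, x$treatment_days, x$final_conc, x$step_day))
  invisible(x)
}
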