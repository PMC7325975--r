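#' Treatment schedules for gradual and abrupt stressor delivery
#'
#' A `treatment_schedule` records the stressor concentration (mM) prevailing
#' in the growth medium during each day of the treatment phase.  Days are
#' 1-based; the concentration of day *i* applies for exactly one day after
#' that day's addition.  Because the stressor is only ever added, the
#' concentration trajectory must be non-decreasing.
#'
#' @param label one of `"control"`, `"gradual"`, `"abrupt"`.
#' @param conc numeric vector of daily concentrations (mM), one per day.
#'
#' @return An object of class `treatment_schedule`: a list with elements
#'   `label`, `n_days` and `conc`.
#' @seealso [build_gradual_schedule()], [build_abrupt_schedule()],
#'   [dose_days()], [check_equivalence()]
#' @export
#' @examples
#' treatment_schedule("abrupt", c(0, 0, 1, 1))
treatment_schedule <- function(label, conc) {
  label <- match.arg(label, c("control", "gradual", "abrupt"))
  conc <- as.numeric(conc)
  if (length(conc) < 1L || anyNA(conc)) {
    stop("'conc' must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  if (any(conc < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (is.unsorted(conc)) {
    stop("concentrations must be non-decreasing (stressor is only added)",
         call. = FALSE)
  }
  if (label == "control" && any(conc != 0)) {
    stop("a control schedule must be all zeros", call. = FALSE)
  }
  structure(
    list(label = label, n_days = length(conc), conc = conc),
    class = "treatment_schedule"
  )
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("<treatment_schedule> %s, %d day(s), final %.4g mM, %.4g mM*day\n",
              x$label, x$n_days, x$conc[x$n_days], dose_days(x)))
  invisible(x)
}

#' Linear-ramp (gradual) schedule
#'
#' Builds the gradual arm: the concentration is raised every 24 h by equal
#' increments, reaching `final_conc` on the last treatment day, i.e.
#' `conc[i] = final_conc * i / n_days`.
#'
#' @param final_conc final concentration (mM), > 0.
#' @param n_days number of treatment days, >= 1.
#' @return a [treatment_schedule()] with label `"gradual"`.
#' @export
#' @examples
#' build_gradual_schedule(1, 9)
build_gradual_schedule <- function(final_conc, n_days) {
  if (!is.numeric(final_conc) || length(final_conc) != 1L || final_conc <= 0) {
    stop("'final_conc' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1 ||
      n_days != round(n_days)) {
    stop("'n_days' must be a positive integer", call. = FALSE)
  }
  treatment_schedule("gradual", final_conc * seq_len(n_days) / n_days)
}

#' Step (abrupt) schedule
#'
#' Builds the abrupt arm: zero concentration until `step_day`, on which the
#' medium is raised directly to `final_conc` and held there.
#'
#' @inheritParams build_gradual_schedule
#' @param step_day day of the single step, in `[1, n_days]`.
#' @return a [treatment_schedule()] with label `"abrupt"`.
#' @export
#' @examples
#' build_abrupt_schedule(1, 9, step_day = 5)
build_abrupt_schedule <- function(final_conc, n_days, step_day) {
  if (!is.numeric(final_conc) || length(final_conc) != 1L || final_conc <= 0) {
    stop("'final_conc' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_days) || length(n_days) != 1L || n_days < 1 ||
      n_days != round(n_days)) {
    stop("'n_days' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(step_day) || length(step_day) != 1L ||
      step_day != round(step_day) || step_day < 1 || step_day > n_days) {
    stop("'step_day' must be an integer in [1, n_days]", call. = FALSE)
  }
  treatment_schedule("abrupt", ifelse(seq_len(n_days) >= step_day, final_conc, 0))
}

#' All-zero control schedule
#'
#' @param n_days number of treatment days.
#' @return a [treatment_schedule()] with label `"control"`.
#' @export
control_schedule <- function(n_days) {
  treatment_schedule("control", rep(0, n_days))
}

#' Dose-days of a schedule
#'
#' The discrete area under the concentration-time curve: each daily
#' concentration is held for exactly one day, so the area is the plain sum of
#' the daily concentrations, in mM*day.  Under this convention the default
#' 9-day ramp and the default step-on-day-5 schedule deliver exactly equal
#' dose-days (5 mM*day at a 1 mM final concentration).
#'
#' @param schedule a [treatment_schedule()].
#' @return numeric scalar, mM*day.
#' @export
#' @examples
#' dose_days(build_gradual_schedule(1, 9)) # 5
dose_days <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  sum(schedule$conc)
}

#' Audit dose-day and final-concentration equivalence of two schedules
#'
#' Two schedules are "equivalent" in the dose-day design sense when their
#' discrete areas under the curve agree within relative tolerance `tol` and
#' their final concentrations match.  Both conditions must hold.
#'
#' @param a,b [treatment_schedule()] objects with equal `n_days`.
#' @param tol relative tolerance on the dose-day comparison.
#' @return a list of class `schedule_equivalence` with elements `equivalent`,
#'   `dose_days_equal`, `final_equal`, `dose_days_a`, `dose_days_b`,
#'   `final_a`, `final_b`, `tol`.
#' @export
#' @examples
#' check_equivalence(build_gradual_schedule(1, 9),
#'                   build_abrupt_schedule(1, 9, 5))
check_equivalence <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "treatment_schedule"), inherits(b, "treatment_schedule"))
  if (a$n_days != b$n_days) {
    stop("schedules have unequal n_days and cannot be compared", call. = FALSE)
  }
  dda <- dose_days(a)
  ddb <- dose_days(b)
  fa <- a$conc[a$n_days]
  fb <- b$conc[b$n_days]
  dd_equal <- abs(dda - ddb) <= tol * max(dda, ddb, 1e-300)
  f_equal <- abs(fa - fb) <= tol * max(fa, fb, 1e-300)
  structure(
    list(equivalent = dd_equal && f_equal,
         dose_days_equal = dd_equal, final_equal = f_equal,
         dose_days_a = dda, dose_days_b = ddb,
         final_a = fa, final_b = fb, tol = tol),
    class = "schedule_equivalence"
  )
}

#' @export
print.schedule_equivalence <- function(x, ...) {
  cat(sprintf("<schedule_equivalence> %s\n",
              if (x$equivalent) "EQUIVALENT" else "NOT equivalent"))
  cat(sprintf("  dose-days: %.6g vs %.6g (%s)\n", x$dose_days_a, x$dose_days_b,
              if (x$dose_days_equal) "equal" else "differ"))
  cat(sprintf("  final conc: %.6g vs %.6g mM (%s)\n", x$final_a, x$final_b,
              if (x$final_equal) "equal" else "differ"))
  invisible(x)
}

#' Read/write a schedule as a two-column plain-text table
#'
#' The on-disk format is CSV with header `day,concentration_mM`.
#'
#' @param schedule a [treatment_schedule()].
#' @param path file path.
#' @param label schedule label to attach on read.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a [treatment_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  utils::write.csv(
    data.frame(day = seq_len(schedule$n_days),
               concentration_mM = schedule$conc),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, label = c("control", "gradual", "abrupt")) {
  label <- match.arg(label)
  tab <- utils::read.csv(path)
  if (!all(c("day", "concentration_mM") %in% names(tab))) {
    stop("schedule file must have columns 'day' and 'concentration_mM'",
         call. = FALSE)
  }
  treatment_schedule(label, tab$concentration_mM[order(tab$day)])
}
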