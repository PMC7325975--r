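#' Growth, sensitivity and uptake parameters of one simulated isolate
#'
#' Parameters of the mechanistic single-culture model used by
#' [simulate_replicate()].  Growth is logistic with a Hill-type concentration
#' inhibition and an accrued-damage penalty; the stressor load follows
#' saturable (Langmuir-type) biosorption with metabolism-dependent efflux.
#'
#' @param r_max intrinsic growth rate (per day).
#' @param K_cap carrying capacity (g dry weight).
#' @param ec50 concentration halving the growth rate (mM); > 0.
#' @param hill Hill exponent of the inhibition curve; >= 1.
#' @param damage_rate chronic damage accrual per unit exposure (per mM*day).
#' @param shock_sens biomass penalty per mM of single-day concentration jump
#'   above `jump_thresh` (dimensionless).
#' @param jump_thresh single-day concentration jump tolerated without an
#'   osmotic/toxic shock (mM).
#' @param uptake_passive maximal biosorption rate
#'   (mg stressor per g biomass per day at saturating concentration).
#' @param uptake_km half-saturation concentration of biosorption (mM).
#' @param efflux_rate baseline efflux rate of accumulated stressor (per day);
#'   attenuated by accrued damage.
#' @param noise_sigma lognormal standard deviation of the multiplicative
#'   replicate noise applied to each endpoint.
#'
#' @return an object of class `isolate_params`.
#' @export
isolate_params <- function(r_max = 0.45, K_cap = 5, ec50 = 0.66, hill = 2,
                           damage_rate = 0, shock_sens = 0, jump_thresh = 0.3,
                           uptake_passive = 1.2, uptake_km = 0.15,
                           efflux_rate = 0.3, noise_sigma = 0.05) {
  p <- list(r_max = r_max, K_cap = K_cap, ec50 = ec50, hill = hill,
            damage_rate = damage_rate, shock_sens = shock_sens,
            jump_thresh = jump_thresh, uptake_passive = uptake_passive,
            uptake_km = uptake_km, efflux_rate = efflux_rate,
            noise_sigma = noise_sigma)
  bad <- vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("non-negative finite scalar required for: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  }
  if (ec50 <= 0) stop("'ec50' must be > 0", call. = FALSE)
  if (hill < 1) stop("'hill' must be >= 1", call. = FALSE)
  structure(p, class = "isolate_params")
}

#' @export
print.isolate_params <- function(x, ...) {
  cat("<isolate_params>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-14s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

# ec50 floor above which an isolate is effectively insensitive at a 1 mM
# final concentration (growth-rate reduction < 1%)
.no_effect_ec50_floor <- 5

#' Delivery-neutral ec50 for a gradual/abrupt schedule pair
#'
#' In the exponential growth phase the endpoint biomass depends on the
#' schedule only through the cumulative inhibition
#' `sum_i 1 / (1 + (conc_i / ec50)^hill)`.  This solves for the `ec50` at
#' which that sum is identical under the linear ramp and the step schedule,
#' so the two delivery modes are exactly matched in expectation and any
#' remaining asymmetry must come from damage accrual or shock sensitivity.
#'
#' @param hill Hill exponent of the inhibition curve.
#' @param final_conc final concentration (mM).
#' @param n_days treatment days.
#' @param step_day abrupt step day.
#' @return the balancing ec50 (mM).
#' @export
#' @examples
#' balanced_ec50(hill = 2) # ~0.66 mM for the default 9-day/step-5 pair
balanced_ec50 <- function(hill = 2, final_conc = 1, n_days = 9, step_day = 5) {
  grad <- build_gradual_schedule(final_conc, n_days)$conc
  abr <- build_abrupt_schedule(final_conc, n_days, step_day)$conc
  gap <- function(e) {
    f <- function(conc) 1 / (1 + (conc / e)^hill)
    sum(f(grad)) - sum(f(abr))
  }
  stats::uniroot(gap, c(1e-3 * final_conc, 10 * final_conc),
                 tol = 1e-12)$root
}

# largest-remainder apportionment of n units to proportions p (sums to n)
.apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' Generate a panel of isolates from the four reaction-pattern presets
#'
#' Draws `n` parameter sets from regions of parameter space chosen so that,
#' under the default schedule pair, an isolate's expected response falls into
#' one of the four qualitative reaction patterns:
#'
#' * `no_effect` - ec50 far above the final concentration; growth is
#'   essentially uninhibited in either arm.
#' * `uniform_reduction` - delivery-neutral ec50 (see [balanced_ec50()]),
#'   no damage accrual, no shock sensitivity: both arms reduce biomass
#'   equally.
#' * `gradual_worse` - delivery-neutral ec50 plus chronic damage accrual;
#'   the longer low-level exposure of the ramp hurts more.
#' * `abrupt_worse` - delivery-neutral ec50 plus shock sensitivity; the
#'   single large concentration jump of the step hurts more.
#'
#' Within each region the remaining parameters are jittered uniformly.
#'
#' @param n number of isolates.
#' @param preset_mix named proportions over the four presets; must sum to 1.
#'   Counts are assigned by largest-remainder apportionment, so exact
#'   proportions (e.g. 4 isolates at an equal mix) give exact counts.
#' @param seed integer seed.
#' @param noise_sigma replicate noise level passed to every isolate.
#' @return a named list of [isolate_params()]; each element carries its
#'   preset in `attr(, "preset")`, and the list the vector
#'   `attr(, "presets")`.
#' @export
#' @examples
#' panel <- generate_isolate_panel(4, seed = 1)
#' table(attr(panel, "presets"))
generate_isolate_panel <- function(n,
                                   preset_mix = c(no_effect = 0.25,
                                                  uniform_reduction = 0.25,
                                                  gradual_worse = 0.25,
                                                  abrupt_worse = 0.25),
                                   seed = 1L,
                                   noise_sigma = 0.05) {
  presets <- c("no_effect", "uniform_reduction", "gradual_worse",
               "abrupt_worse")
  if (is.null(names(preset_mix)) || !all(names(preset_mix) %in% presets)) {
    stop("'preset_mix' must be named with the four reaction presets",
         call. = FALSE)
  }
  mix <- stats::setNames(numeric(4), presets)
  mix[names(preset_mix)] <- preset_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("'preset_mix' proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  counts <- .apportion(n, mix)
  labels <- rep(presets, counts)
  set.seed(as.integer(seed))
  panel <- lapply(labels, function(preset) {
    hill <- stats::runif(1, 1.5, 2.5)
    base <- list(
      r_max = stats::runif(1, 0.3, 0.6),
      K_cap = stats::runif(1, 3, 8),
      hill = hill,
      damage_rate = 0, shock_sens = 0, jump_thresh = 0.3,
      uptake_passive = stats::runif(1, 0.6, 2.0),
      uptake_km = stats::runif(1, 0.1, 0.3),
      efflux_rate = stats::runif(1, 0.1, 0.5),
      noise_sigma = noise_sigma
    )
    base$ec50 <- switch(preset,
      no_effect = stats::runif(1, 10, 30),
      balanced_ec50(hill = hill)
    )
    if (preset == "gradual_worse") base$damage_rate <- stats::runif(1, 0.25, 0.5)
    if (preset == "abrupt_worse") base$shock_sens <- stats::runif(1, 0.8, 1.6)
    out <- do.call(isolate_params, base)
    attr(out, "preset") <- preset
    out
  })
  names(panel) <- sprintf("ISO%02d", seq_len(n))
  attr(panel, "presets") <- labels
  panel
}

#' Write/read a parameter panel as CSV
#'
#' @param panel a list of [isolate_params()] as returned by
#'   [generate_isolate_panel()].
#' @param path file path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` a panel
#'   list.
#' @export
write_panel <- function(panel, path) {
  rows <- lapply(names(panel), function(id) {
    data.frame(isolate = id,
               preset = attr(panel[[id]], "preset") %||% NA_character_,
               as.data.frame(unclass(panel[[id]])))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  tab <- utils::read.csv(path)
  fields <- setdiff(names(tab), c("isolate", "preset"))
  panel <- lapply(seq_len(nrow(tab)), function(i) {
    p <- do.call(isolate_params, as.list(tab[i, fields]))
    if ("preset" %in% names(tab) && !is.na(tab$preset[i])) {
      attr(p, "preset") <- tab$preset[i]
    }
    p
  })
  names(panel) <- tab$isolate
  attr(panel, "presets") <- if ("preset" %in% names(tab)) tab$preset else NULL
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a
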