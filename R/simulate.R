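# Deterministic endpoint of one culture under a schedule.
#
# State (B, D, Q): biomass (g), accrued damage (dimensionless exposure
# integral x damage_rate), total stressor load (mg).  Within each day the
# medium concentration is constant; integration is classical RK4 at step
# `dt` days.  At each day boundary whose concentration jump exceeds
# `jump_thresh` the biomass takes an instantaneous shock penalty.
.simulate_endpoint <- function(params, schedule, pre_days, inoculum_g,
                               dt = 0.01) {
  days <- c(rep(0, pre_days), schedule$conc)
  B <- inoculum_g; D <- 0; Q <- 0
  c_prev <- 0
  steps <- round(1 / dt)
  for (conc in days) {
    jump <- conc - c_prev
    if (jump > params$jump_thresh) {
      B <- B * exp(-params$shock_sens * (jump - params$jump_thresh))
    }
    c_prev <- conc
    f_inh <- 1 / (1 + (conc / params$ec50)^params$hill)
    upt <- params$uptake_passive * conc / (conc + params$uptake_km)
    dD <- params$damage_rate * conc
    deriv <- function(s) {
      c(params$r_max * s[1] * (1 - s[1] / params$K_cap) * f_inh * exp(-s[2]),
        dD,
        upt * s[1] - params$efflux_rate * exp(-s[2]) * s[3])
    }
    s <- c(B, D, Q)
    for (i in seq_len(steps)) {
      k1 <- deriv(s)
      k2 <- deriv(s + dt / 2 * k1)
      k3 <- deriv(s + dt / 2 * k2)
      k4 <- deriv(s + dt * k3)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!all(is.finite(s))) {
      stop("simulation diverged (non-finite trajectory); check parameters",
           call. = FALSE)
    }
    B <- s[1]; D <- s[2]; Q <- s[3]
  }
  c(biomass = B, cu_accum = if (B > 0) Q / B else 0)
}

#' Simulate one replicate culture
#'
#' Integrates the mechanistic growth/uptake model over the stressor-free
#' pre-incubation phase followed by the treatment phase of `schedule`, then
#' applies one multiplicative lognormal noise draw to each endpoint
#' (biomass, accumulation).  Deterministic given `seed`.
#'
#' Model: logistic growth `dB/dt = r_max B (1 - B/K_cap)` modulated by a
#' Hill inhibition term `1/(1 + (c/ec50)^hill)` and a chronic-damage factor
#' `exp(-damage)` with `d(damage)/dt = damage_rate * c(t)`; at each day
#' boundary with a concentration jump above `jump_thresh`, biomass is cut by
#' `exp(-shock_sens * (jump - jump_thresh))`.  Stressor load follows
#' `dQ/dt = uptake_passive * c/(c + uptake_km) * B - efflux_rate * exp(-damage) * Q`;
#' the reported accumulation is `Q(T)/B(T)` (mg per g dry weight).
#'
#' @param params an [isolate_params()].
#' @param schedule a [treatment_schedule()].
#' @param design an [experiment_design()] (supplies pre-incubation length and
#'   inoculum size).
#' @param seed integer seed for the replicate's noise draw.
#' @param dt integration step (days).
#' @return named numeric vector `c(biomass, cu_accum)`:
#'   g dry weight and mg per g dry weight.
#' @export
#' @examples
#' d <- experiment_design()
#' simulate_replicate(isolate_params(), design_schedules(d)$gradual, d, seed = 1)
simulate_replicate <- function(params, schedule, design, seed, dt = 0.01) {
  stopifnot(inherits(params, "isolate_params"),
            inherits(schedule, "treatment_schedule"),
            inherits(design, "experiment_design"))
  end <- .simulate_endpoint(params, schedule, design$pre_incubation_days,
                            design$inoculum_g, dt = dt)
  if (params$noise_sigma > 0) {
    set.seed(as.integer(seed))
    z <- stats::rnorm(2)
    end <- end * exp(params$noise_sigma * z)
  }
  end
}

# stable sub-seed for cell (isolate i, treatment t, replicate r)
.replicate_seed <- function(master, i, t, r, n_rep) {
  id <- ((i - 1) * 3 + (t - 1)) * max(n_rep, 1L) + (r - 1)
  as.integer((as.double(master) + 104729 * id) %% 2147483629)
}

#' Simulate a full replicate table for a design and panel
#'
#' Runs the deterministic model once per isolate x treatment cell and applies
#' independent replicate noise draws, with per-replicate seeds derived
#' stably from the master seed and the cell coordinates, so the full table is
#' reproducible bit-for-bit under a fixed seed.
#'
#' @param design an [experiment_design()].
#' @param panel list of [isolate_params()], one per isolate id in the design.
#' @param seed master integer seed.
#' @param dt integration step (days).
#' @return a tibble with columns
#'   `isolate, treatment, replicate, biomass_g, cu_mg_per_g`, one row per
#'   experimental unit ([n_units()] rows).
#' @export
#' @examples
#' d <- experiment_design(isolate_ids = c("A", "B"), n_replicates = 2)
#' simulate_experiment(d, generate_isolate_panel(2, seed = 1), seed = 1)
simulate_experiment <- function(design, panel, seed = 1L, dt = 0.01) {
  stopifnot(inherits(design, "experiment_design"))
  n_iso <- length(design$isolate_ids)
  if (length(panel) != n_iso) {
    stop("panel length (", length(panel), ") does not match design isolates (",
         n_iso, ")", call. = FALSE)
  }
  schedules <- design_schedules(design)
  rows <- vector("list", n_iso * 3L)
  k <- 0L
  for (i in seq_len(n_iso)) {
    params <- panel[[i]]
    for (t in seq_along(design$treatments)) {
      trt <- design$treatments[t]
      k <- k + 1L
      if (design$n_replicates == 0L) {
        rows[[k]] <- NULL
        next
      }
      end <- .simulate_endpoint(params, schedules[[trt]],
                                design$pre_incubation_days,
                                design$inoculum_g, dt = dt)
      bio <- cu <- numeric(design$n_replicates)
      for (r in seq_len(design$n_replicates)) {
        if (params$noise_sigma > 0) {
          set.seed(.replicate_seed(seed, i, t, r, design$n_replicates))
          z <- stats::rnorm(2)
          bio[r] <- end[1] * exp(params$noise_sigma * z[1])
          cu[r] <- end[2] * exp(params$noise_sigma * z[2])
        } else {
          bio[r] <- end[1]
          cu[r] <- end[2]
        }
      }
      rows[[k]] <- tibble::tibble(
        isolate = design$isolate_ids[i], treatment = trt,
        replicate = seq_len(design$n_replicates),
        biomass_g = bio, cu_mg_per_g = cu
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(tibble::tibble(isolate = character(), treatment = character(),
                          replicate = integer(), biomass_g = numeric(),
                          cu_mg_per_g = numeric()))
  }
  do.call(rbind, rows)
}

#' Random phylogeny and tip traits for the isolate panel
#'
#' Draws a pure-birth (Yule) tree over the given tips and a trait vector
#' either independent of the tree (i.i.d. normal; no phylogenetic signal) or
#' evolved by Brownian motion along its branches (signal present).
#'
#' @param tip_ids character vector of >= 3 tip labels.
#' @param seed integer seed.
#' @param trait_mode `"independent"` or `"brownian"`.
#' @param sigma trait standard deviation (independent mode) or Brownian
#'   rate parameter per unit branch length.
#' @return list with elements `tree` (an [ape::phylo] object) and `traits`
#'   (named numeric vector over tips).
#' @export
#' @examples
#' gp <- generate_phylogeny(letters[1:5], seed = 1, trait_mode = "brownian")
generate_phylogeny <- function(tip_ids, seed = 1L,
                               trait_mode = c("independent", "brownian"),
                               sigma = 1) {
  trait_mode <- match.arg(trait_mode)
  tip_ids <- as.character(tip_ids)
  n <- length(tip_ids)
  if (n < 3L) stop("at least 3 tips are required", call. = FALSE)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- tip_ids
  traits <- switch(trait_mode,
    independent = stats::setNames(stats::rnorm(n, sd = sigma), tip_ids),
    brownian = {
      x <- ape::rTraitCont(tree, model = "BM", sigma = sigma)
      stats::setNames(as.numeric(x), names(x))
    }
  )
  list(tree = tree, traits = traits)
}
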