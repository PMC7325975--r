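#' Classify an isolate's reaction pattern
#'
#' Formalises the four qualitative reaction patterns as an ordered decision
#' rule over the bootstrap evidence:
#'
#' 1. if neither arm's effect-size CI excludes 0 -> `no_effect`;
#' 2. else if the gradual-vs-abrupt contrast has `p_boot >= alpha` ->
#'    `uniform_reduction`;
#' 3. else if the gradual point effect is below the abrupt one ->
#'    `gradual_worse`;
#' 4. else -> `abrupt_worse`.
#'
#' All three pieces of evidence must have been computed at the same `alpha`
#' so the call rests on one coherent inferential basis.
#'
#' @param es_g,es_a [bootstrap_ci()] results for the gradual and abrupt arms.
#' @param contrast a [compare_es()] result for the same isolate.
#' @param alpha significance level; must match the evidence.
#' @return an object of class `pattern_call`: list with `label` (one of
#'   `no_effect`, `uniform_reduction`, `gradual_worse`, `abrupt_worse`) and
#'   `evidence`.
#' @export
classify_pattern <- function(es_g, es_a, contrast, alpha = 0.05) {
  stopifnot(inherits(es_g, "effect_size_ci"), inherits(es_a, "effect_size_ci"),
            inherits(contrast, "es_comparison"))
  if (es_g$alpha != alpha || es_a$alpha != alpha || contrast$alpha != alpha) {
    stop("configuration error: CIs and contrast must share 'alpha' = ", alpha,
         call. = FALSE)
  }
  excludes0 <- function(es) es$ci_low > 0 || es$ci_high < 0
  label <- if (!excludes0(es_g) && !excludes0(es_a)) {
    "no_effect"
  } else if (contrast$p_boot >= alpha) {
    "uniform_reduction"
  } else if (es_g$point < es_a$point) {
    "gradual_worse"
  } else {
    "abrupt_worse"
  }
  structure(
    list(label = label,
         evidence = list(es_gradual = es_g, es_abrupt = es_a,
                         contrast = contrast, alpha = alpha)),
    class = "pattern_call"
  )
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> %s (alpha = %g)\n", x$label,
              x$evidence$alpha))
  invisible(x)
}

#' Classify an isolate's stress-response strategy quadrant
#'
#' Places one isolate x treatment combination in the growth/accumulation
#' plane split at the panel medians: isolates whose biomass effect lies
#' above the panel median are "growing", those whose accumulation effect
#' lies above the median are "accumulating".  Quadrants:
#' `a_grow_accumulate`, `b_grow_exclude`, `c_inhibited_accumulate`,
#' `d_inhibited_exclude`.  Values exactly at a median are assigned to the
#' lower half (so an isolate at both medians is called `d`).
#'
#' @param es_biomass,es_cu [bootstrap_ci()] results (or any objects with a
#'   `point` element) for the biomass and accumulation responses of one
#'   isolate under one treatment.
#' @param panel_medians named numeric vector with elements `biomass` and
#'   `cu`: medians of the point effects over all isolates for the same
#'   treatment.
#' @return an object of class `strategy_call`: list with `label` and
#'   `thresholds`.
#' @export
classify_strategy <- function(es_biomass, es_cu, panel_medians) {
  if (length(panel_medians) == 0 ||
      !all(c("biomass", "cu") %in% names(panel_medians)) ||
      anyNA(panel_medians[c("biomass", "cu")])) {
    stop("'panel_medians' must supply non-missing 'biomass' and 'cu' medians",
         call. = FALSE)
  }
  grow <- es_biomass$point > panel_medians[["biomass"]]
  accum <- es_cu$point > panel_medians[["cu"]]
  label <- if (grow && accum) "a_grow_accumulate"
  else if (grow) "b_grow_exclude"
  else if (accum) "c_inhibited_accumulate"
  else "d_inhibited_exclude"
  structure(
    list(label = label,
         thresholds = c(biomass = panel_medians[["biomass"]],
                        cu = panel_medians[["cu"]])),
    class = "strategy_call"
  )
}

#' @export
print.strategy_call <- function(x, ...) {
  cat(sprintf("<strategy_call> %s (medians: biomass %.4g, cu %.4g)\n",
              x$label, x$thresholds["biomass"], x$thresholds["cu"]))
  invisible(x)
}

#' Pattern and strategy calls for every isolate of a replicate table
#'
#' Computes per-isolate bootstrap effect sizes for both responses, the
#' gradual-vs-abrupt biomass contrast, the reaction-pattern call, and the
#' strategy quadrant of each treatment arm (split at the panel medians of
#' that arm's point effects).
#'
#' @inheritParams effect_size_table
#' @return a tibble with columns
#'   `isolate, pattern, strategy_gradual, strategy_abrupt, alpha`.
#' @export
classify_panel <- function(table, n_boot = 9999, alpha = 0.05, seed = 1L) {
  isolates <- unique(table$isolate)
  per_iso <- lapply(seq_along(isolates), function(i) {
    sub <- table[table$isolate == isolates[i], ]
    bio <- split(sub$biomass_g, sub$treatment)
    cu <- split(sub$cu_mg_per_g, sub$treatment)
    list(
      es_bio_g = bootstrap_ci(bio$gradual, bio$control, n_boot, alpha, seed + i),
      es_bio_a = bootstrap_ci(bio$abrupt, bio$control, n_boot, alpha, seed + i),
      es_cu_g = bootstrap_ci(cu$gradual, cu$control, n_boot, alpha, seed + i),
      es_cu_a = bootstrap_ci(cu$abrupt, cu$control, n_boot, alpha, seed + i),
      contrast = compare_es(bio$gradual, bio$abrupt, bio$control, n_boot,
                            alpha, seed + i)
    )
  })
  med <- function(field) {
    stats::median(vapply(per_iso, function(z) z[[field]]$point, numeric(1)))
  }
  med_g <- c(biomass = med("es_bio_g"), cu = med("es_cu_g"))
  med_a <- c(biomass = med("es_bio_a"), cu = med("es_cu_a"))
  rows <- lapply(seq_along(isolates), function(i) {
    z <- per_iso[[i]]
    tibble::tibble(
      isolate = isolates[i],
      pattern = classify_pattern(z$es_bio_g, z$es_bio_a, z$contrast,
                                 alpha)$label,
      strategy_gradual = classify_strategy(z$es_bio_g, z$es_cu_g,
                                           med_g)$label,
      strategy_abrupt = classify_strategy(z$es_bio_a, z$es_cu_a,
                                          med_a)$label,
      alpha = alpha
    )
  })
  do.call(rbind, rows)
}
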