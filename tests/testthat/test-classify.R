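# build bootstrap-evidence stubs with prescribed CIs / p-values
fake_es <- function(point, lo, hi, alpha = 0.05) {
  structure(list(point = point, ci_low = lo, ci_high = hi, n_treated = 5,
                 n_control = 5, alpha = alpha, n_boot = 1999),
            class = "effect_size_ci")
}
fake_cmp <- function(p, alpha = 0.05) {
  structure(list(delta = 0, ci_low = -1, ci_high = 1, p_boot = p,
                 n_boot = 1999, alpha = alpha),
            class = "es_comparison")
}

test_that("pattern rules fire in their documented order", {
  expect_equal(classify_pattern(fake_es(0, -0.5, 0.4), fake_es(0.1, -0.3, 0.6),
                                fake_cmp(0.001))$label, "no_effect")
  expect_equal(classify_pattern(fake_es(-4, -5, -3), fake_es(-3.5, -4.5, -2.5),
                                fake_cmp(0.7))$label, "uniform_reduction")
  expect_equal(classify_pattern(fake_es(-5, -6, -4), fake_es(-1, -1.5, -0.5),
                                fake_cmp(0.001))$label, "gradual_worse")
  expect_equal(classify_pattern(fake_es(-1, -1.5, -0.5), fake_es(-5, -6, -4),
                                fake_cmp(0.001))$label, "abrupt_worse")
  expect_error(classify_pattern(fake_es(0, -1, 1, alpha = 0.10),
                                fake_es(0, -1, 1), fake_cmp(0.5)),
               "configuration error")
})

test_that("every evidence combination yields exactly one pattern label", {
  labels <- c("no_effect", "uniform_reduction", "gradual_worse",
              "abrupt_worse")
  set.seed(51)
  for (i in 1:100) {
    pt_g <- rnorm(1); pt_a <- rnorm(1); w <- abs(rnorm(2, 0, 1))
    call <- classify_pattern(fake_es(pt_g, pt_g - w[1], pt_g + w[1]),
                             fake_es(pt_a, pt_a - w[2], pt_a + w[2]),
                             fake_cmp(runif(1)))
    expect_length(call$label, 1)
    expect_true(call$label %in% labels)
  }
})

test_that("strategy quadrants split at panel medians with lower-side ties", {
  med <- c(biomass = -1, cu = 2)
  expect_equal(classify_strategy(fake_es(-0.5, -1, 0), fake_es(3, 2, 4),
                                 med)$label, "a_grow_accumulate")
  expect_equal(classify_strategy(fake_es(-0.5, -1, 0), fake_es(1, 0, 2),
                                 med)$label, "b_grow_exclude")
  expect_equal(classify_strategy(fake_es(-2, -3, -1), fake_es(3, 2, 4),
                                 med)$label, "c_inhibited_accumulate")
  # exact ties on both axes fall to the lower half
  expect_equal(classify_strategy(fake_es(-1, -2, 0), fake_es(2, 1, 3),
                                 med)$label, "d_inhibited_exclude")
  expect_error(classify_strategy(fake_es(0, -1, 1), fake_es(0, -1, 1),
                                 numeric(0)), "panel_medians")
})

test_that("strategy presets are recovered from simulated panels at low noise", {
  # four parameter groups spanning the growth x accumulation plane
  combos <- expand.grid(grow = c(TRUE, FALSE), accum = c(TRUE, FALSE))
  want <- c("a_grow_accumulate", "c_inhibited_accumulate",
            "b_grow_exclude", "d_inhibited_exclude")
  panel <- list()
  set.seed(52)
  for (i in seq_len(nrow(combos))) {
    for (j in 1:5) {
      panel[[length(panel) + 1]] <- isolate_params(
        r_max = runif(1, 0.4, 0.5),
        ec50 = if (combos$grow[i]) runif(1, 10, 20) else runif(1, 0.5, 0.7),
        uptake_passive = if (combos$accum[i]) runif(1, 2.5, 3.5)
                         else runif(1, 0.2, 0.5),
        noise_sigma = 0.02)
    }
  }
  names(panel) <- sprintf("ISO%02d", seq_along(panel))
  truth <- rep(want, each = 5)
  d <- experiment_design(isolate_ids = names(panel))
  tab <- simulate_experiment(d, panel, seed = 53)
  calls <- classify_panel(tab, n_boot = 1999, alpha = 0.05, seed = 54)
  expect_gte(mean(calls$strategy_gradual == truth), 0.9)
  expect_gte(mean(calls$strategy_abrupt == truth), 0.9)
})

test_that("noise-free panels with large separation are recovered perfectly", {
  for (preset in c("gradual_worse", "abrupt_worse")) {
    tab <- sim_preset_table(preset, 6, seed = 55, noise_sigma = 0)
    # jitter-free measurement: add minimal noise through resampling only
    calls <- classify_panel(tab, n_boot = 1999, alpha = 0.05, seed = 56)
    expect_true(all(calls$pattern == preset))
  }
})
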