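test_that("control-arm endpoint matches the closed-form logistic solution", {
  d <- quick_design(1)
  sched <- control_schedule(d$treatment_days)
  total_days <- d$pre_incubation_days + d$treatment_days
  for (r in c(0.3, 0.45, 0.6)) {
    p <- isolate_params(r_max = r, K_cap = 5, noise_sigma = 0)
    got <- simulate_replicate(p, sched, d, seed = 1)[["biomass"]]
    b0 <- d$inoculum_g
    want <- 5 / (1 + ((5 - b0) / b0) * exp(-r * total_days))
    expect_lt(abs(got - want) / want, 1e-3)
  }
})

test_that("with no inhibition, damage or shock, treatment equals control", {
  d <- quick_design(1)
  s <- design_schedules(d)
  p <- isolate_params(ec50 = 1e6, damage_rate = 0, shock_sens = 0,
                      noise_sigma = 0)
  ctrl <- simulate_replicate(p, s$control, d, 1)[["biomass"]]
  expect_equal(simulate_replicate(p, s$gradual, d, 1)[["biomass"]], ctrl,
               tolerance = 1e-8)
  expect_equal(simulate_replicate(p, s$abrupt, d, 1)[["biomass"]], ctrl,
               tolerance = 1e-8)
})

test_that("no uptake means zero accumulation; zero schedule means zero load", {
  d <- quick_design(1)
  s <- design_schedules(d)
  p <- isolate_params(uptake_passive = 0, noise_sigma = 0)
  expect_equal(simulate_replicate(p, s$gradual, d, 1)[["cu_accum"]], 0)
  expect_equal(simulate_replicate(p, s$abrupt, d, 1)[["cu_accum"]], 0)
  p2 <- isolate_params(uptake_passive = 2, noise_sigma = 0)
  expect_equal(simulate_replicate(p2, s$control, d, 1)[["cu_accum"]], 0)
})

test_that("treated biomass is monotone non-increasing in the final dose", {
  d0 <- quick_design(1)
  p <- isolate_params(noise_sigma = 0)
  bio <- vapply(c(0.25, 0.5, 1, 2, 4), function(conc) {
    d <- experiment_design(isolate_ids = "A", final_conc = conc)
    simulate_replicate(p, design_schedules(d)$gradual, d, 1)[["biomass"]]
  }, numeric(1))
  expect_true(all(diff(bio) <= 1e-12))
})

test_that("damage accrual penalises the ramp and shocks penalise the step", {
  d <- quick_design(1)
  s <- design_schedules(d)
  set.seed(21)
  for (i in 1:20) {
    base <- list(r_max = runif(1, 0.3, 0.6), K_cap = runif(1, 3, 8),
                 ec50 = balanced_ec50(hill = 2), hill = 2,
                 jump_thresh = 0.3, noise_sigma = 0)
    p_dam <- do.call(isolate_params,
                     c(base, damage_rate = runif(1, 0.1, 0.6), shock_sens = 0))
    expect_lte(simulate_replicate(p_dam, s$gradual, d, 1)[["biomass"]],
               simulate_replicate(p_dam, s$abrupt, d, 1)[["biomass"]])
    p_shk <- do.call(isolate_params,
                     c(base, damage_rate = 0, shock_sens = runif(1, 0.2, 2)))
    expect_gte(simulate_replicate(p_shk, s$gradual, d, 1)[["biomass"]],
               simulate_replicate(p_shk, s$abrupt, d, 1)[["biomass"]])
  }
})

test_that("a full default-design run yields 255 units and is deterministic", {
  panel <- generate_isolate_panel(17, seed = 4)
  d <- experiment_design(isolate_ids = names(panel))
  tab1 <- simulate_experiment(d, panel, seed = 9)
  expect_equal(nrow(tab1), 255)
  expect_equal(nrow(tab1), n_units(d))
  expect_equal(nrow(unique(tab1[, c("isolate", "treatment", "replicate")])),
               255)
  expect_true(all(tab1$biomass_g > 0))
  expect_true(all(tab1$cu_mg_per_g >= 0))
  tab2 <- simulate_experiment(d, panel, seed = 9)
  expect_identical(tab1, tab2)
})

test_that("zero replicates give an empty table; panel mismatch errors", {
  panel <- generate_isolate_panel(2, seed = 1)
  d <- experiment_design(isolate_ids = names(panel), n_replicates = 0)
  expect_equal(nrow(simulate_experiment(d, panel, seed = 1)), 0)
  d3 <- quick_design(3)
  expect_error(simulate_experiment(d3, panel, seed = 1), "does not match")
})

test_that("panel presets land in their parameter regions with exact counts", {
  panel <- generate_isolate_panel(4, seed = 2)
  expect_equal(sort(attr(panel, "presets")),
               sort(c("no_effect", "uniform_reduction", "gradual_worse",
                      "abrupt_worse")))
  none <- single_preset_panel("no_effect", 17, seed = 3)
  expect_true(all(vapply(none, `[[`, numeric(1), "ec50") > 5))
  gw <- single_preset_panel("gradual_worse", 5, seed = 3)
  expect_true(all(vapply(gw, `[[`, numeric(1), "damage_rate") > 0))
  expect_true(all(vapply(gw, `[[`, numeric(1), "shock_sens") == 0))
  expect_error(generate_isolate_panel(4, c(no_effect = 0.9)), "sum to 1")
})

test_that("panels round-trip through CSV", {
  panel <- generate_isolate_panel(3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(names(back), names(panel))
  expect_equal(vapply(back, `[[`, numeric(1), "ec50"),
               vapply(panel, `[[`, numeric(1), "ec50"), tolerance = 1e-5)
  expect_equal(attr(back, "presets"), attr(panel, "presets"))
})

test_that("generated phylogenies are valid and traits follow the mode", {
  gp <- generate_phylogeny(sprintf("ISO%02d", 1:17), seed = 1)
  expect_s3_class(gp$tree, "phylo")
  expect_equal(length(gp$tree$tip.label), 17)
  expect_equal(sort(names(gp$traits)), sort(gp$tree$tip.label))
  # newick round trip
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(gp$tree, path)
  expect_equal(sort(ape::read.tree(path)$tip.label), sort(gp$tree$tip.label))
  # zero branch lengths under Brownian motion give identical traits
  gp2 <- generate_phylogeny(letters[1:6], seed = 2, trait_mode = "brownian")
  tree0 <- gp2$tree
  tree0$edge.length[] <- 0
  set.seed(3)
  x <- ape::rTraitCont(tree0, model = "BM")
  expect_equal(diff(range(x)), 0)
  expect_error(generate_phylogeny(c("a", "b"), seed = 1), "3 tips")
})
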