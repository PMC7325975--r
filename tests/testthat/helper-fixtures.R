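# shared fixtures, built in code at test time

default_schedule_pair <- function() {
  list(gradual = build_gradual_schedule(1, 9),
       abrupt = build_abrupt_schedule(1, 9, step_day = 5))
}

quick_design <- function(n_iso, n_rep = 5) {
  experiment_design(isolate_ids = sprintf("ISO%02d", seq_len(n_iso)),
                    n_replicates = n_rep)
}

# panel drawn 100% from one reaction preset
single_preset_panel <- function(preset, n, seed, noise_sigma = 0.05) {
  mix <- stats::setNames(rep(0, 4), c("no_effect", "uniform_reduction",
                                      "gradual_worse", "abrupt_worse"))
  mix[preset] <- 1
  generate_isolate_panel(n, mix, seed = seed, noise_sigma = noise_sigma)
}

sim_preset_table <- function(preset, n, seed, noise_sigma = 0.05) {
  panel <- single_preset_panel(preset, n, seed, noise_sigma)
  d <- experiment_design(isolate_ids = names(panel))
  simulate_experiment(d, panel, seed = seed + 1)
}

# hand-readable 3-taxon fixture: ((A:1,B:1):1,C:2)
three_taxon_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
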