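test_that("tree covariance encodes shared ancestry", {
  # star tree: no shared history off-diagonal
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  Cs <- vcv_from_tree(star)
  expect_equal(unname(Cs), diag(2, 4))
  C <- vcv_from_tree(three_taxon_tree())
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  # diagonal equals root-to-tip path lengths on a random tree
  gp <- generate_phylogeny(letters[1:9], seed = 6)
  Cr <- vcv_from_tree(gp$tree)
  depths <- ape::node.depth.edgelength(gp$tree)[seq_len(9)]
  expect_equal(unname(diag(Cr)),
               depths[match(rownames(Cr), gp$tree$tip.label)],
               tolerance = 1e-12)
})

test_that("zero terminal branches are perturbed with a warning", {
  tr <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  expect_warning(C <- vcv_from_tree(tr), "perturbed")
  expect_true(rcond(C) > 0)
})

test_that("K on the three-taxon fixture matches a hand-inverted matrix oracle", {
  tree <- three_taxon_tree()
  x <- c(A = 1, B = 2, C = 4)
  # oracle: C = [[2,1,0],[1,2,0],[0,0,2]], inverted by hand (block 2x2 + scalar)
  Cinv <- rbind(c(2 / 3, -1 / 3, 0), c(-1 / 3, 2 / 3, 0), c(0, 0, 1 / 2))
  one <- rep(1, 3)
  a_hat <- sum(Cinv %*% x) / sum(Cinv)
  r <- x - a_hat
  mse0 <- sum(r^2) / 2
  mse <- drop(r %*% Cinv %*% r) / 2
  expected_ratio <- (6 - 3 / sum(Cinv)) / 2   # tr(C) = 6
  k_oracle <- (mse0 / mse) / expected_ratio
  expect_equal(blomberg_k(tree, x), k_oracle, tolerance = 1e-10)
})

test_that("K agrees with an independent reference implementation", {
  skip_if_not_installed("phytools")
  gp <- generate_phylogeny(sprintf("t%02d", 1:20), seed = 8,
                           trait_mode = "brownian")
  expect_equal(blomberg_k(gp$tree, gp$traits),
               as.numeric(phytools::phylosig(gp$tree, gp$traits,
                                             method = "K")),
               tolerance = 1e-8)
})

test_that("K is invariant to trait affine maps and branch rescaling", {
  gp <- generate_phylogeny(letters[1:12], seed = 9, trait_mode = "brownian")
  k0 <- blomberg_k(gp$tree, gp$traits)
  expect_equal(blomberg_k(gp$tree, 5 - 3 * gp$traits), k0, tolerance = 1e-10)
  scaled <- gp$tree
  scaled$edge.length <- scaled$edge.length * 17.3
  expect_equal(blomberg_k(scaled, gp$traits), k0, tolerance = 1e-10)
  expect_error(blomberg_k(gp$tree, setNames(rep(1, 12), letters[1:12])),
               "constant")
})

test_that("permutation p is deterministic, bounded below, and detects signal", {
  gp <- generate_phylogeny(sprintf("t%02d", 1:16), seed = 10,
                           trait_mode = "brownian")
  r1 <- perm_test_k(gp$tree, gp$traits, n_perm = 199, seed = 2)
  r2 <- perm_test_k(gp$tree, gp$traits, n_perm = 199, seed = 2)
  expect_identical(r1, r2)
  expect_gte(r1$p_perm, 1 / 200)
  # strong Brownian signal on a deep tree is usually detected
  ps <- vapply(1:20, function(i) {
    g <- generate_phylogeny(sprintf("t%02d", 1:32), seed = 100 + i,
                            trait_mode = "brownian")
    perm_test_k(g$tree, g$traits, n_perm = 199, seed = i)$p_perm
  }, numeric(1))
  expect_lte(median(ps), 0.05)
})

test_that("the six-response signal table runs on simulated data", {
  tab <- sim_preset_table("uniform_reduction", 8, seed = 71)
  gp <- generate_phylogeny(unique(tab$isolate), seed = 3)
  out <- phylo_signal_table(tab, gp$tree, n_perm = 99, seed = 4)
  expect_equal(nrow(out), 6)
  # accumulation is constant (zero) in the unexposed control arm: K undefined
  const_row <- out$response == "cu_mg_per_g" & out$treatment == "control"
  expect_true(all(is.na(out$K[const_row])))
  ok <- out[!const_row, ]
  expect_true(all(ok$p_perm > 0 & ok$p_perm <= 1))
  expect_true(all(ok$K >= 0))
})
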