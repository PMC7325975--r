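#' Tip variance-covariance matrix of a phylogeny
#'
#' `C[i, j]` is the branch length shared between the root and the most
#' recent common ancestor of tips *i* and *j*; the diagonal holds
#' root-to-tip distances.  Terminal branches of length zero (which would
#' make `C` singular) are perturbed to `1e-8` times the tree depth, with a
#' warning.
#'
#' @param tree an [ape::phylo] tree with >= 3 uniquely labelled tips and
#'   branch lengths.
#' @return symmetric positive-definite matrix with tip labels as dimnames.
#' @export
#' @examples
#' vcv_from_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
vcv_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (length(tree$tip.label) < 3L) stop("need >= 3 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  terminal <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[terminal] == 0)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length[terminal & tree$edge.length == 0] <- 1e-8 * depth
    warning("zero-length terminal branches perturbed by 1e-8 * tree depth ",
            "to keep the covariance invertible", call. = FALSE)
  }
  C <- ape::vcv.phylo(tree)
  if (rcond(C) < .Machine$double.eps * 100) {
    stop("singular tip covariance matrix (degenerate branch lengths)",
         call. = FALSE)
  }
  C
}

# core K statistic given precomputed covariance pieces; x is a plain
# numeric vector ordered as the rows of Cinv
.kstat <- function(x, Cinv, expected_ratio) {
  n <- length(x)
  s <- sum(Cinv)
  a_hat <- sum(Cinv %*% x) / s
  r <- x - a_hat
  mse0 <- sum(r * r) / (n - 1)
  mse <- sum(r * (Cinv %*% r)) / (n - 1)
  (mse0 / mse) / expected_ratio
}

.k_pieces <- function(C) {
  n <- nrow(C)
  Cinv <- solve(C)
  list(Cinv = Cinv,
       expected_ratio = (sum(diag(C)) - n / sum(Cinv)) / (n - 1))
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of the trait's ordinary mean squared error
#' (about the phylogenetically weighted GLS mean) to its phylogenetically
#' corrected mean squared error, against the expectation of that ratio under
#' Brownian-motion evolution on the same tree.  K near 1 indicates
#' Brownian-like signal; K near 0 indicates trait values independent of the
#' phylogeny.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits named numeric vector; names must match the tip labels and
#'   the values must not be constant.
#' @return numeric scalar K >= 0.
#' @export
#' @examples
#' gp <- generate_phylogeny(letters[1:8], seed = 1, trait_mode = "brownian")
#' blomberg_k(gp$tree, gp$traits)
blomberg_k <- function(tree, traits) {
  x <- .match_traits(tree, traits)
  C <- vcv_from_tree(tree)
  pieces <- .k_pieces(C)
  .kstat(x[rownames(C)], pieces$Cinv, pieces$expected_ratio)
}

.match_traits <- function(tree, traits) {
  if (is.null(names(traits))) {
    stop("'traits' must be named by tip label", call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing)) {
    stop("traits missing for tips: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- traits[tree$tip.label]
  if (anyNA(x)) stop("traits contain missing values", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("undefined statistic: traits are constant", call. = FALSE)
  }
  x
}

#' Permutation test of Blomberg's K
#'
#' The null distribution is built by shuffling the trait values across the
#' tips of the fixed tree; significance is
#' `p = (1 + #\{K_perm >= K_obs\}) / (n_perm + 1)`, so `p` is bounded below
#' by `1/(n_perm + 1)`.
#'
#' @inheritParams blomberg_k
#' @param n_perm number of tip permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return an object of class `phylo_signal_result`: list with `K`,
#'   `p_perm`, `n_perm`.
#' @export
#' @examples
#' gp <- generate_phylogeny(letters[1:8], seed = 1)
#' perm_test_k(gp$tree, gp$traits, n_perm = 199, seed = 1)
perm_test_k <- function(tree, traits, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop("'n_perm' must be >= 99", call. = FALSE)
  x <- .match_traits(tree, traits)
  C <- vcv_from_tree(tree)
  pieces <- .k_pieces(C)
  x <- x[rownames(C)]
  k_obs <- .kstat(x, pieces$Cinv, pieces$expected_ratio)
  set.seed(as.integer(seed))
  n <- length(x)
  # vectorised over permutations: columns of X are tip-shuffled traits
  X <- vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
  s <- sum(pieces$Cinv)
  a_hat <- colSums(pieces$Cinv %*% X) / s
  R <- sweep(X, 2, a_hat)
  mse0 <- colSums(R * R) / (n - 1)
  mse <- colSums(R * (pieces$Cinv %*% R)) / (n - 1)
  k_perm <- (mse0 / mse) / pieces$expected_ratio
  p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  structure(list(K = k_obs, p_perm = p, n_perm = n_perm),
            class = "phylo_signal_result")
}

#' @export
print.phylo_signal_result <- function(x, ...) {
  cat(sprintf("<phylo_signal_result> K = %.4g, p_perm = %.4g (%d permutations)\n",
              x$K, x$p_perm, x$n_perm))
  invisible(x)
}

#' Phylogenetic-signal table for the six response variables
#'
#' Tests the isolate-mean biomass and accumulation of each treatment arm
#' (2 responses x 3 arms) for phylogenetic signal with [perm_test_k()],
#' reporting unadjusted permutation p-values.  A response that is constant
#' across isolates (e.g. accumulation in an unexposed control arm) has no
#' defined K and is reported as `NA`.
#'
#' @param table a replicate table.
#' @param tree an [ape::phylo] tree whose tip labels are the isolate ids.
#' @param n_perm,seed permutation settings.
#' @return a tibble with columns `response, treatment, K, p_perm, n_perm`.
#' @export
phylo_signal_table <- function(table, tree, n_perm = 999, seed = 1L) {
  rows <- list()
  k <- 0L
  for (resp in c("biomass_g", "cu_mg_per_g")) {
    for (trt in c("control", "gradual", "abrupt")) {
      sub <- table[table$treatment == trt, ]
      means <- tapply(sub[[resp]], sub$isolate, mean)
      traits <- stats::setNames(as.numeric(means), names(means))
      res <- if (stats::sd(traits) == 0) {
        list(K = NA_real_, p_perm = NA_real_)
      } else {
        perm_test_k(tree, traits, n_perm = n_perm, seed = seed + k)
      }
      k <- k + 1L
      rows[[k]] <- tibble::tibble(response = resp, treatment = trt,
                                  K = res$K, p_perm = res$p_perm,
                                  n_perm = n_perm)
    }
  }
  do.call(rbind, rows)
}
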