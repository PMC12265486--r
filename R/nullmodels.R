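# Seeded random generation of Yule and uniform bifurcating trees. Hot loops
# live in C++ but draw from R's RNG, so set.seed() (or the `seed` argument)
# fully determines every sample stream, identically across platforms
# (Mersenne-Twister, R's default generator).

rtree_from_parents <- function(par, leafy = TRUE) {
  par[par == 0L] <- NA_integer_
  is_leaf <- !(seq_along(par) %in% par)
  rtree(par, size = if (leafy) as.numeric(is_leaf) else rep(1, length(par)))
}

sample_parents <- function(model = c("yule", "uniform"), n, reps) {
  model <- match.arg(model)
  if (n < 2) stop("sampling requires n >= 2")
  if (model == "yule") cpp_yule_parents(as.integer(n), as.integer(reps))
  else cpp_remy_parents(as.integer(n), as.integer(reps))
}

#' Sample random bifurcating trees under a null model
#'
#' `sample_yule()` grows a tree from a cherry by `n - 2` uniform leaf
#' replacements; `sample_uniform()` draws uniformly over leaf-labelled
#' bifurcating topologies by Remy-style edge insertion (equivalent in
#' distribution to the random bracket-sequence construction). Both return
#' unit-leaf leafy trees. Use `set.seed()` (or [sample_trees()] with a
#' `seed`) for reproducibility.
#'
#' @param n leaf count, `>= 2`.
#' @return An [rtree()].
#' @examples
#' set.seed(1)
#' j_one(sample_yule(8))
#' @export
sample_yule <- function(n) rtree_from_parents(sample_parents("yule", n, 1L)[, 1L])

#' @rdname sample_yule
#' @export
sample_uniform <- function(n) rtree_from_parents(sample_parents("uniform", n, 1L)[, 1L])

#' Batch-sample trees under a null model
#'
#' @param model `"yule"` or `"uniform"`.
#' @param n leaf count, `>= 2`.
#' @param reps number of trees.
#' @param seed integer seed; if supplied, the sample stream is fully
#'   reproducible.
#' @return A list of [rtree()] objects.
#' @export
sample_trees <- function(model, n, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  par <- sample_parents(model, n, reps)
  lapply(seq_len(reps), function(r) rtree_from_parents(par[, r]))
}

#' Sampled shape frequencies
#'
#' Samples `reps` trees and tallies canonical shape keys; the workhorse
#' behind sampler-versus-exact total-variation checks.
#'
#' @inheritParams sample_trees
#' @return A named numeric vector of relative frequencies by shape key.
#' @export
sample_shape_frequencies <- function(model, n, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keys <- cpp_parent_shape_keys(sample_parents(model, n, reps))
  tab <- table(keys)
  structure(as.numeric(tab) / reps, names = names(tab))
}

#' Monte Carlo moments of J1 and the Sackin index
#'
#' Samples `reps` unit-leaf leafy trees under the chosen model and
#' estimates the mean of J1 (through the leafy tree identity
#' \eqn{J_1 = n \log_2 n / I_S}) with its standard error, and the mean and
#' variance of the Sackin index.
#'
#' @inheritParams sample_trees
#' @return A list of class `moment_estimate` with `model`, `n`, `reps`,
#'   `mean_j1`, `se_j1`, `mean_IS`, `var_IS`, `seed`.
#' @examples
#' monte_carlo_moments("yule", 8, reps = 1000, seed = 1)
#' @export
monte_carlo_moments <- function(model, n, reps = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  IS <- cpp_parent_sackin(sample_parents(model, n, reps))
  j1 <- n * log2(n) / IS
  structure(list(model = model, n = n, reps = reps,
                 mean_j1 = mean(j1), se_j1 = stats::sd(j1) / sqrt(reps),
                 mean_IS = mean(IS), var_IS = stats::var(IS),
                 seed = seed),
            class = "moment_estimate")
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat(sprintf(
    "%s model, n = %d, reps = %d%s\n  mean J1 = %.6g (SE %.2g)  mean IS = %.6g  var IS = %.6g\n",
    x$model, x$n, x$reps,
    if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed),
    x$mean_j1, x$se_j1, x$mean_IS, x$var_IS))
  invisible(x)
}
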