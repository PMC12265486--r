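# The index is a weighted mean of per-node balance scores. For an internal
# node i with outdegree d+(i) > 1 and descendant magnitude S_i* > 0, the
# balance score is the Shannon entropy, base d+(i), of the child subtree
# magnitudes S_j / S_i*; outdegree-1 nodes score 0. Node weights are
# g_i = S_i*, and the sum runs over V~(T): internal nodes whose descendants
# are not all of zero size. Convention 0*log(0) := 0 throughout.

# Internal: V~ membership and balance scores from precomputed magnitudes.
balance_scores <- function(tree, mag = compute_magnitudes(tree)) {
  n <- n_nodes(tree)
  W <- rep(NA_real_, n)
  in_vt <- logical(n)
  for (v in internal_nodes(tree)) {
    s_star <- mag$S_star[v]
    if (s_star <= 0) next
    in_vt[v] <- TRUE
    kids <- tree$children[[v]]
    d <- length(kids)
    if (d == 1L) { W[v] <- 0; next }
    f <- mag$S[kids] / s_star
    f <- f[f > 0]
    W[v] <- -sum(f * log(f)) / log(d)
  }
  list(W = W, in_vt = in_vt)
}

#' Node balance score
#'
#' The balance score \eqn{W_i} of an internal node is the normalized
#' Shannon entropy (base = outdegree) of its child subtree magnitudes,
#' or 0 for outdegree-1 nodes. Zero-magnitude children contribute 0.
#'
#' @param tree an [rtree()].
#' @param node node index; must be internal with \eqn{S_i^* > 0}.
#' @return A number in \eqn{[0, 1]}.
#' @examples
#' node_balance(parse_newick("((A,B),C);"), 1)
#' @export
node_balance <- function(tree, node) {
  stopifnot(node >= 1L, node <= n_nodes(tree))
  if (length(tree$children[[node]]) == 0L)
    stop("node ", node, " is a leaf; balance scores are defined for internal nodes")
  bs <- balance_scores(tree)
  if (!bs$in_vt[node])
    stop("node ", node, " has zero descendant magnitude; its balance score is undefined")
  bs$W[node]
}

#' The universal tree balance index J1
#'
#' \deqn{J_1(T) = \frac{1}{\sum_{i \in \tilde V} S_i^*}
#'   \sum_{i \in \tilde V(T)} S_i^* W_i,}
#' the weighted mean of node balance scores over internal nodes with
#' positively sized descendants, with weights \eqn{g_i = S_i^*}. The
#' normalizing factor is the generalized Sackin index. J1 ranges over
#' \eqn{[0, 1]}; it is 0 exactly on linear (chain) trees, because
#' outdegree-1 nodes retain their weight \eqn{S_i^*} while scoring 0, and
#' 1 exactly when every node of \eqn{\tilde V} splits its descendants
#' into at least two equal-magnitude subtrees.
#'
#' @param tree an [rtree()] with at least one internal node whose
#'   descendants have positive total size.
#' @return J1, a number in \eqn{[0, 1]}.
#' @examples
#' j_one(build_fixture("caterpillar", 4)) # 8/9
#' @export
j_one <- function(tree) {
  mag <- compute_magnitudes(tree)
  bs <- balance_scores(tree, mag)
  if (!any(bs$in_vt))
    stop("J1 is undefined: no internal node has positively sized descendants")
  g <- mag$S_star[bs$in_vt]
  sum(g * bs$W[bs$in_vt]) / sum(g)
}

#' Sackin and generalized Sackin indices
#'
#' `sackin()` is the sum of leaf depths (external path length);
#' `generalized_sackin()` is the weighted path length
#' \eqn{\sum_i w_i \nu(i) = \sum_{i \in \tilde V} S_i^*}, which reduces
#' to the Sackin index on leafy trees with unit-size leaves.
#'
#' @param tree an [rtree()].
#' @return `sackin()`: an integer; `generalized_sackin()`: a number.
#' @examples
#' sackin(build_fixture("caterpillar", 4)) # 9
#' @export
sackin <- function(tree) {
  dep <- compute_depths(tree)
  sum(dep$depth[leaves(tree)])
}

#' @rdname sackin
#' @export
generalized_sackin <- function(tree) {
  dep <- compute_depths(tree)
  sum(tree$size * dep$depth)
}

#' Full balance report for a tree
#'
#' Computes J1 together with its ingredients: per-node balance scores
#' \eqn{W_i}, weights \eqn{g_i = S_i^*}, the Sackin and generalized
#' Sackin indices, and the Shannon entropy of the leaf size distribution.
#'
#' @param tree an [rtree()].
#' @param m logarithm base for the leaf-size entropy (default 2).
#' @return A list of class `balance_report` with elements `j1`, `sackin`,
#'   `generalized_sackin`, `W`, `g`, `in_vtilde`, `entropy`.
#' @export
balance_report <- function(tree, m = 2) {
  mag <- compute_magnitudes(tree)
  bs <- balance_scores(tree, mag)
  dep <- compute_depths(tree)
  lf <- leaves(tree)
  f <- tree$size[lf]
  f <- f[f > 0] / sum(tree$size)
  structure(list(
    j1 = if (any(bs$in_vt)) sum(mag$S_star[bs$in_vt] * bs$W[bs$in_vt]) /
           sum(mag$S_star[bs$in_vt]) else NA_real_,
    sackin = sum(dep$depth[lf]),
    generalized_sackin = sum(tree$size * dep$depth),
    W = bs$W, g = ifelse(bs$in_vt, mag$S_star, NA_real_),
    in_vtilde = bs$in_vt,
    entropy = -sum(f * log(f)) / log(m)
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("J1 = %.6g  Sackin = %g  generalized Sackin = %.6g\n",
              x$j1, x$sackin, x$generalized_sackin))
  invisible(x)
}

#' Residual of the leafy tree identity
#'
#' For leafy full m-ary trees, J1 equals \eqn{H_m(T) S(T) / I_{S,gen}(T)},
#' where \eqn{H_m} is the base-m Shannon entropy of the relative leaf
#' sizes; with equal leaves this reduces to \eqn{n \log_m n / I_S}. This
#' returns the absolute difference between `j_one(tree)` and the identity's
#' right-hand side, which should vanish to numerical precision (< 1e-10).
#'
#' @param tree a leafy full m-ary [rtree()].
#' @param m the common outdegree (> 1).
#' @return Absolute gap between the two sides of the identity.
#' @export
leafy_identity_gap <- function(tree, m = 2) {
  deg <- outdegree(tree)
  if (any(deg[internal_nodes(tree)] != m))
    stop("tree is not full m-ary with m = ", m)
  if (any(tree$size[internal_nodes(tree)] > 0))
    stop("tree is not leafy (internal nodes must have size zero)")
  if (m <= 1) stop("m must exceed 1")
  S_T <- sum(tree$size)
  f <- tree$size[leaves(tree)]
  f <- f[f > 0] / S_T
  H_m <- -sum(f * log(f)) / log(m)
  abs(j_one(tree) - H_m * S_T / generalized_sackin(tree))
}
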