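#' Rooted trees with node sizes
#'
#' An `rtree` is a rooted tree in which every node carries a non-negative
#' size \eqn{w_i}. Sizes typically represent population sizes of biological
#' types; a *leafy* tree is one whose internal nodes all have size zero (the
#' cladogram convention). All balance quantities computed from an `rtree`
#' are invariant under permutation of any node's child list.
#'
#' @param parent integer vector; `parent[i]` is the parent of node `i`,
#'   `NA` for the root. Exactly one root is required and the parent map
#'   must be acyclic.
#' @param size numeric vector of non-negative node sizes, one per node.
#' @param label optional character vector of node names (`NA` allowed).
#' @return An object of class `rtree`: a list with elements `parent`,
#'   `children` (ordered integer child lists), `size`, `label` and `root`.
#' @examples
#' ch <- rtree(parent = c(NA, 1L, 1L), size = c(0, 1, 1))
#' j_one(ch)
#' @export
rtree <- function(parent, size, label = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (n < 1L) stop("tree must have at least one node")
  size <- as.numeric(size)
  if (length(size) != n) stop("`size` must have one entry per node")
  if (any(is.na(size)) || any(size < 0)) stop("node sizes must be non-negative")
  if (is.null(label)) label <- rep(NA_character_, n)
  label <- as.character(label)
  if (length(label) != n) stop("`label` must have one entry per node")
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (any(parent[-root] < 1L | parent[-root] > n)) stop("parent index out of range")
  children <- vector("list", n)
  nonroot <- setdiff(seq_len(n), root)
  for (i in nonroot) children[[parent[i]]] <- c(children[[parent[i]]], i)
  tr <- structure(
    list(parent = parent, children = children, size = size,
         label = label, root = root),
    class = "rtree")
  # acyclicity / connectivity: a topological order must reach every node
  if (length(postorder(tr)) != n) stop("parent map contains a cycle")
  tr
}

#' @export
print.rtree <- function(x, ...) {
  cat(sprintf("rtree with %d nodes (%d leaves), magnitude %g\n",
              n_nodes(x), length(leaves(x)), sum(x$size)))
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Number of nodes of a tree
#' @param tree an `rtree`.
#' @return Integer node count.
#' @export
n_nodes <- function(tree) length(tree$parent)

#' Leaf and internal node indices
#'
#' Leaves are nodes without children, irrespective of their size.
#' @param tree an `rtree`.
#' @return Integer vector of node indices.
#' @export
leaves <- function(tree) {
  which(vapply(tree$children, length, 1L) == 0L)
}

#' @rdname leaves
#' @export
internal_nodes <- function(tree) {
  which(vapply(tree$children, length, 1L) > 0L)
}

#' Outdegrees of all nodes
#' @param tree an `rtree`.
#' @return Integer vector of child counts.
#' @export
outdegree <- function(tree) vapply(tree$children, length, 1L)

# Post-order (children before parents); also serves as the cycle check.
postorder <- function(tree) {
  n <- n_nodes(tree)
  ord <- integer(n)
  stack <- integer(n)
  state <- integer(n) # next child slot to visit
  top <- 1L
  stack[1L] <- tree$root
  k <- 0L
  while (top > 0L) {
    v <- stack[top]
    kids <- tree$children[[v]]
    s <- state[v] + 1L
    if (s <= length(kids)) {
      state[v] <- s
      top <- top + 1L
      if (top > n) return(integer(0)) # cycle
      stack[top] <- kids[s]
    } else {
      k <- k + 1L
      ord[k] <- v
      top <- top - 1L
    }
  }
  ord[seq_len(k)]
}

#' Subtree magnitudes
#'
#' The magnitude of a tree is the sum of its node sizes. For every node
#' `i` this computes \eqn{S_i} (magnitude of the subtree rooted at `i`,
#' including `i`) and \eqn{S_i^*} (the same, excluding `i`), by a single
#' post-order pass, so that \eqn{S_i = w_i + S_i^*} and
#' \eqn{S_i^* = \sum_{j \in C(i)} S_j}.
#'
#' @param tree an `rtree`.
#' @return A list with numeric vectors `S`, `S_star` and the scalar total
#'   `S_T` (equal to `S` at the root).
#' @export
compute_magnitudes <- function(tree) {
  n <- n_nodes(tree)
  S <- numeric(n)
  S_star <- numeric(n)
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    S_star[v] <- if (length(kids)) sum(S[kids]) else 0
    S[v] <- tree$size[v] + S_star[v]
  }
  list(S = S, S_star = S_star, S_T = S[tree$root])
}

#' Node depths and tree height
#'
#' Depth is the number of edges on the path from the root; the height of
#' the tree is the maximum node depth.
#'
#' @param tree an `rtree`.
#' @return A list with integer vector `depth` and scalar `height`.
#' @export
compute_depths <- function(tree) {
  n <- n_nodes(tree)
  depth <- integer(n)
  for (v in rev(postorder(tree))) { # parents before children
    p <- tree$parent[v]
    depth[v] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  list(depth = depth, height = max(depth))
}

# ---- fixture builders -------------------------------------------------------

#' Build standard tree topologies
#'
#' Constructs the leafy fixtures used throughout: caterpillars, brooms,
#' stars, perfect m-ary trees and linear chains. All are leafy (internal
#' sizes zero); leaves have size 1 except broom head leaves, which have
#' size `p`.
#'
#' A broom tree has every internal node of outdegree 2 except the one most
#' distant from the root, whose subtree (the *head*) is a star on `k`
#' leaves of size `p` each; the remaining caterpillar-like part is the
#' *handle*, with `n - k` leaves of size 1.
#'
#' @param kind one of `"caterpillar"`, `"broom"`, `"star"`,
#'   `"perfect_mary"`, `"linear"`.
#' @param n leaf count (node count for `"linear"`); `n >= 2`
#'   (`n >= 3` for brooms, and for `"perfect_mary"` `n` must be a power
#'   of `m`).
#' @param k broom head size, `2 <= k <= n`.
#' @param p broom head leaf size, `> 0`.
#' @param m arity for `"perfect_mary"`.
#' @return An `rtree`.
#' @examples
#' build_fixture("broom", n = 9, k = 5)
#' @export
build_fixture <- function(kind = c("caterpillar", "broom", "star",
                                   "perfect_mary", "linear"),
                          n, k = NULL, p = 1, m = 2L) {
  kind <- match.arg(kind)
  switch(kind,
    caterpillar = tree_caterpillar(n),
    broom = tree_broom(n, k, p),
    star = tree_star(n),
    perfect_mary = tree_perfect_mary(n, m),
    linear = tree_linear(n))
}

tree_star <- function(n, p = 1) {
  if (n < 2) stop("star needs n >= 2 leaves")
  rtree(parent = c(NA, rep(1L, n)), size = c(0, rep(p, n)),
        label = c(NA, paste0("t", seq_len(n))))
}

tree_caterpillar <- function(n) {
  if (n < 2) stop("caterpillar needs n >= 2 leaves")
  # internal chain 1..n-1; internal i has child leaf and child internal i+1
  parent <- integer(2L * n - 1L)
  size <- numeric(2L * n - 1L)
  parent[1L] <- NA
  for (i in seq_len(n - 1L)) {
    leaf <- n - 1L + i
    parent[leaf] <- i
    size[leaf] <- 1
    if (i < n - 1L) parent[i + 1L] <- i
  }
  last <- 2L * n - 1L
  parent[last] <- n - 1L
  size[last] <- 1
  rtree(parent, size, label = c(rep(NA, n - 1L), paste0("t", seq_len(n))))
}

tree_broom <- function(n, k, p = 1) {
  if (is.null(k)) stop("broom needs a head size k")
  if (n < 3 || k < 2 || k > n) stop("broom needs n >= 3 and 2 <= k <= n")
  if (p <= 0) stop("broom head leaf size p must be positive")
  if (k == n) return(tree_star(n, p))
  # handle: chain of n-k internal nodes, each with one unit leaf; the
  # deepest chain node's second child is the star head on k leaves of size p
  h <- n - k # handle internal nodes
  total <- h + (n - k) + 1L + k # chain + handle leaves + head root + head leaves
  parent <- rep(NA_integer_, total)
  size <- numeric(total)
  for (i in seq_len(h)) {
    if (i > 1L) parent[i] <- i - 1L
    leaf <- h + i
    parent[leaf] <- i
    size[leaf] <- 1
  }
  head_root <- 2L * h + 1L
  parent[head_root] <- h
  for (j in seq_len(k)) {
    parent[head_root + j] <- head_root
    size[head_root + j] <- p
  }
  rtree(parent, size)
}

tree_perfect_mary <- function(n, m = 2L) {
  if (m < 2) stop("perfect m-ary tree needs m >= 2")
  d <- round(log(n) / log(m))
  if (m^d != n) stop("n must be a power of m for a perfect m-ary tree")
  parent <- NA_integer_
  size <- 0
  level <- 1L # node ids of current deepest level
  for (dep in seq_len(d)) {
    new <- integer(0)
    for (v in level) {
      ids <- length(parent) + seq_len(m)
      parent <- c(parent, rep(v, m))
      size <- c(size, rep(if (dep == d) 1 else 0, m))
      new <- c(new, ids)
    }
    level <- new
  }
  rtree(parent, size)
}

tree_linear <- function(n) {
  if (n < 2) stop("linear tree needs n >= 2 nodes")
  rtree(parent = c(NA, seq_len(n - 1L)),
        size = c(rep(0, n - 1L), 1))
}
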