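# Independent oracles used across the suite: counting recurrences for shape
# catalogues, a brute-force rooted-tree isomorphism check, and random tree
# generators. These deliberately share no code with the package internals.

# Wedderburn-Etherington numbers: unlabelled bifurcating shapes on n leaves.
we_number <- function(n) {
  memo <- numeric(max(n, 1)); memo[1] <- 1
  for (m in seq_len(max(n, 1))[-1]) {
    tot <- 0
    for (a in 1:(m %/% 2)) {
      b <- m - a
      tot <- tot + if (a < b) memo[a] * memo[b] else memo[a] * (memo[a] + 1) / 2
    }
    memo[m] <- tot
  }
  memo[n]
}

# Series-reduced (no outdegree-1) rooted shapes on n leaves, counted by the
# multiset recurrence over child leaf-count partitions.
series_reduced_count <- function(n) {
  memo <- numeric(n); memo[1] <- 1
  part_rec <- function(rem, maxv) {
    # partitions of rem into parts <= maxv, as nonincreasing vectors
    if (rem == 0) return(list(integer(0)))
    out <- list()
    for (v in seq_len(min(rem, maxv)))
      for (rest in part_rec(rem - v, v))
        out[[length(out) + 1L]] <- c(v, rest)
    out
  }
  for (m in seq_len(n)[-1]) {
    tot <- 0
    for (part in part_rec(m, m - 1L)) {
      if (length(part) < 2L) next
      tab <- table(part)
      tot <- tot + prod(choose(memo[as.integer(names(tab))] + tab - 1, tab))
    }
    memo[m] <- tot
  }
  memo[n]
}

# Brute-force unlabelled rooted-tree isomorphism by backtracking child
# matching; exponential, fine for the <= 7-leaf catalogues it is used on.
iso_oracle <- function(t1, t2) {
  rec <- function(v1, v2) {
    k1 <- t1$children[[v1]]; k2 <- t2$children[[v2]]
    if (length(k1) != length(k2)) return(FALSE)
    if (length(k1) == 0L) return(TRUE)
    match_rec <- function(rem1, rem2) {
      if (!length(rem1)) return(TRUE)
      for (j in seq_along(rem2))
        if (rec(rem1[1L], rem2[j]) && match_rec(rem1[-1L], rem2[-j])) return(TRUE)
      FALSE
    }
    match_rec(k1, k2)
  }
  n_nodes(t1) == n_nodes(t2) && rec(t1$root, t2$root)
}

# Random rooted tree with arbitrary outdegrees, random sizes and labels.
random_any_tree <- function(n_nodes = sample(3:20, 1)) {
  parent <- NA_integer_
  for (i in seq_len(n_nodes - 1L)) parent <- c(parent, sample(i, 1))
  size <- round(runif(n_nodes, 0, 5), 3)
  labs <- ifelse(runif(n_nodes) < 0.5, paste0("n", seq_len(n_nodes)), NA)
  rtree(parent, size, labs)
}

# Random leafy full m-ary tree: expand a uniformly chosen leaf into m
# children `n_exp` times, then give leaves positive sizes.
random_full_mary <- function(m = 2L, n_exp = sample(2:6, 1),
                             unit_leaves = FALSE) {
  parent <- NA_integer_
  leaves_ <- 1L
  for (i in seq_len(n_exp)) {
    v <- leaves_[sample(length(leaves_), 1)]
    ids <- length(parent) + seq_len(m)
    parent <- c(parent, rep(v, m))
    leaves_ <- c(setdiff(leaves_, v), ids)
  }
  size <- numeric(length(parent))
  size[leaves_] <- if (unit_leaves) 1 else round(runif(length(leaves_), 0.1, 5), 3)
  rtree(parent, size)
}

# All permutations of seq_len(n), for the exhaustive Huffman cross-check.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# Shape key of the n-leaf caterpillar, for catalogue assertions.
caterpillar_key <- function(n) canonical_shape(build_fixture("caterpillar", n))
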