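#' Canonical shape key of a tree
#'
#' Encodes the unlabelled shape of a rooted tree as a string: a leaf is
#' `"L"` and an internal node is `"(k1,k2,...)"` where `k1 <= k2 <= ...`
#' are the children's keys sorted lexicographically (C locale). Two trees
#' receive equal keys if and only if they are isomorphic as unlabelled
#' rooted trees, and the key is invariant under permutation of child
#' lists. Node sizes and labels are ignored.
#'
#' @param tree an [rtree()].
#' @return A character scalar shape key.
#' @examples
#' canonical_shape(build_fixture("caterpillar", 4))
#' @export
canonical_shape <- function(tree) {
  n <- n_nodes(tree)
  key <- character(n)
  for (v in postorder(tree)) {
    kids <- tree$children[[v]]
    key[v] <- if (length(kids) == 0L) "L" else
      paste0("(", paste(sort(key[kids], method = "radix"), collapse = ","), ")")
  }
  key[tree$root]
}

# ---- internal shape-string machinery ---------------------------------------
# Shapes module operations work directly on canonical key strings; these
# helpers parse, canonicalize and summarize them without building rtrees.

# Parse a shape string into a nested list (leaf = "L").
shape_parse <- function(key) {
  pos <- 1L
  n <- nchar(key)
  rec <- function() {
    ch <- substr(key, pos, pos)
    if (ch == "L") { pos <<- pos + 1L; return("L") }
    if (ch != "(") stop("malformed shape key: ", key)
    pos <<- pos + 1L
    kids <- list()
    repeat {
      kids[[length(kids) + 1L]] <- rec()
      ch <- substr(key, pos, pos)
      pos <<- pos + 1L
      if (ch == ")") break
      if (ch != ",") stop("malformed shape key: ", key)
    }
    kids
  }
  out <- rec()
  if (pos != n + 1L) stop("malformed shape key: ", key)
  out
}

shape_unparse_canonical <- function(node) {
  if (identical(node, "L")) return("L")
  keys <- vapply(node, shape_unparse_canonical, "")
  paste0("(", paste(sort(keys, method = "radix"), collapse = ","), ")")
}

# Canonicalize an arbitrary (possibly non-sorted) shape string.
shape_canonicalize <- function(key) shape_unparse_canonical(shape_parse(key))

# Leaf count of a shape string.
shape_n_leaves <- function(key) {
  lengths(regmatches(key, gregexpr("L", key, fixed = TRUE)))
}

# Per-shape summary for unit-leaf leafy trees: leaf count, Sackin index,
# number of symmetric internal nodes (two isomorphic child subtrees, for
# bifurcating shapes), and leaf counts lambda_v of all internal subtrees.
shape_stats <- function(key) {
  chars <- strsplit(key, "")[[1]]
  depth <- 0L
  sackin <- 0L
  n_leaf <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "L") { n_leaf <- n_leaf + 1L; sackin <- sackin + depth }
  }
  node <- shape_parse(key)
  lambda <- integer(0)
  n_sym <- 0L
  count <- function(nd) {
    if (identical(nd, "L")) return(1L)
    sub <- vapply(nd, count, 1L)
    if (length(nd) == 2L &&
        identical(shape_unparse_canonical(nd[[1]]), shape_unparse_canonical(nd[[2]])))
      n_sym <<- n_sym + 1L
    tot <- sum(sub)
    lambda[length(lambda) + 1L] <<- tot
    tot
  }
  count(node)
  list(n_leaves = n_leaf, sackin = sackin, n_sym = n_sym, lambda = lambda)
}

# Replace the i-th leaf (in string order) of a shape with a cherry and
# return the canonicalized result. Used by the Yule growth dynamic program.
shape_replace_leaf <- function(key, i) {
  idx <- gregexpr("L", key, fixed = TRUE)[[1]][i]
  shape_canonicalize(paste0(substr(key, 1L, idx - 1L), "(L,L)",
                            substr(key, idx + 1L, nchar(key))))
}

# Materialize a shape key as a unit-leaf leafy rtree.
shape_to_rtree <- function(key) {
  node <- shape_parse(key)
  parent <- integer(0)
  size <- numeric(0)
  build <- function(nd, par) {
    parent[length(parent) + 1L] <<- par
    id <- length(parent)
    if (identical(nd, "L")) {
      size[id] <<- 1
    } else {
      size[id] <<- 0
      for (k in nd) build(k, id)
    }
    id
  }
  build(node, NA_integer_)
  rtree(parent, size)
}
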