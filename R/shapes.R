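# Exact enumeration of unlabelled tree shapes and exact shape distributions
# under the Yule and uniform models. All probabilities are exact rationals:
# integer numerators over a model-specific common denominator, both held in
# doubles (every integer involved stays far below 2^53 within the caps, so
# the arithmetic is exact). E[1/IS] is accumulated as a double sum of exact
# rationals; its ~1e-15 relative error is negligible against the 1e-3 scale
# of the Jensen gaps.

.j1b_cache <- new.env(parent = emptyenv())

cache_get <- function(key) .j1b_cache[[key]]
cache_set <- function(key, value) { assign(key, value, envir = .j1b_cache); value }

catalan_number <- function(n) round(choose(2 * n, n) / (n + 1))

#' Enumerate unlabelled bifurcating tree shapes
#'
#' Lists every unlabelled bifurcating (full binary) shape on `n` leaves
#' exactly once, as canonical shape keys (see [canonical_shape()]). The
#' counts follow the Wedderburn--Etherington numbers.
#'
#' @param n leaf count, `1 <= n <= cap`.
#' @param cap resource cap on `n` (default 16).
#' @return Character vector of canonical shape keys.
#' @examples
#' enumerate_bifurcating_shapes(4) # two shapes
#' @export
enumerate_bifurcating_shapes <- function(n, cap = 16L) {
  stopifnot(n >= 1)
  if (n > cap) stop("n = ", n, " exceeds the enumeration cap (", cap, ")")
  ck <- paste0("bif", n)
  hit <- cache_get(ck)
  if (!is.null(hit)) return(hit)
  if (n == 1L) return(cache_set(ck, "L"))
  res <- character(0)
  for (a in seq_len(n %/% 2L)) {
    A <- enumerate_bifurcating_shapes(a, cap = cap)
    B <- enumerate_bifurcating_shapes(n - a, cap = cap)
    if (a < n - a) {
      for (x in A) for (y in B) {
        pr <- sort(c(x, y), method = "radix")
        res <- c(res, paste0("(", pr[1L], ",", pr[2L], ")"))
      }
    } else {
      m <- length(A)
      A <- sort(A, method = "radix")
      for (i in seq_len(m)) for (j in i:m)
        res <- c(res, paste0("(", A[i], ",", A[j], ")"))
    }
  }
  cache_set(ck, res)
}

# Per-shape unit-leaf statistics, cached by key.
shape_stats_cached <- function(key) {
  ck <- paste0("st:", key)
  hit <- cache_get(ck)
  if (!is.null(hit)) return(hit)
  cache_set(ck, shape_stats(key))
}

#' Enumerate shapes with no outdegree-1 nodes
#'
#' Lists every unlabelled rooted tree shape on `n` leaves in which each
#' internal node has at least two children (series-reduced shapes), as
#' canonical keys. These are the candidate topologies in the minimal
#' balance search.
#'
#' @param n leaf count, `1 <= n <= cap`.
#' @param cap resource cap on `n` (default 12).
#' @return Character vector of canonical shape keys.
#' @examples
#' length(enumerate_shapes_min_outdeg2(4)) # 5
#' @export
enumerate_shapes_min_outdeg2 <- function(n, cap = 12L) {
  stopifnot(n >= 1)
  if (n > cap) stop("n = ", n, " exceeds the enumeration cap (", cap, ")")
  ck <- paste0("mo2:", n)
  hit <- cache_get(ck)
  if (!is.null(hit)) return(hit)
  if (n == 1L) return(cache_set(ck, "L"))
  groups <- lapply(seq_len(n - 1L), enumerate_shapes_min_outdeg2, cap = cap)
  res <- character(0)
  # every tree is a multiset of >= 2 child subtrees; enumerate by the
  # partition of n into child leaf counts, then by multisets within groups
  for (part in integer_partitions(n, max_parts_value = n - 1L, min_parts = 2L)) {
    tab <- table(part)
    sizes <- as.integer(names(tab))
    picks_per_size <- lapply(seq_along(sizes), function(si) {
      multiset_combinations(groups[[sizes[si]]], as.integer(tab[si]))
    })
    combos <- Reduce(function(acc, picks) {
      out <- list()
      for (a in acc) for (p in picks) out[[length(out) + 1L]] <- c(a, p)
      out
    }, picks_per_size, accumulate = FALSE, right = FALSE)
    for (kids in combos)
      res <- c(res, paste0("(", paste(sort(kids, method = "radix"),
                                      collapse = ","), ")"))
  }
  cache_set(ck, res)
}

# Partitions of n into parts within [1, max_parts_value], at least min_parts
# parts, returned as nonincreasing integer vectors.
integer_partitions <- function(n, max_parts_value = n, min_parts = 1L) {
  out <- list()
  rec <- function(rem, maxv, acc) {
    if (rem == 0L) {
      if (length(acc) >= min_parts) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (v in seq_len(min(rem, maxv))) rec(rem - v, v, c(acc, v))
  }
  rec(n, max_parts_value, integer(0))
  out
}

# Multisets of size m drawn from `items` (with repetition), as a list of
# character vectors; items chosen in nondecreasing index order.
multiset_combinations <- function(items, m) {
  out <- list()
  rec <- function(start, left, acc) {
    if (left == 0L) { out[[length(out) + 1L]] <<- items[acc]; return(invisible()) }
    for (i in start:length(items)) rec(i, left - 1L, c(acc, i))
  }
  if (length(items) > 0L) rec(1L, m, integer(0))
  out
}

# ---- exact shape distributions ---------------------------------------------

new_shape_distribution <- function(model, n, key, num, den) {
  stats <- lapply(key, shape_stats_cached)
  df <- data.frame(
    key = key,
    num = num,
    prob = num / den,
    sackin = vapply(stats, `[[`, 1L, "sackin"),
    n_sym = vapply(stats, `[[`, 1L, "n_sym"),
    stringsAsFactors = FALSE)
  structure(list(model = model, n = n, den = den, shapes = df),
            class = "shape_distribution")
}

#' @export
print.shape_distribution <- function(x, ...) {
  cat(sprintf("%s shape distribution, n = %d: %d shapes, common denominator %g\n",
              x$model, x$n, nrow(x$shapes), x$den))
  print(utils::head(x$shapes, 10L))
  invisible(x)
}

#' @export
as.data.frame.shape_distribution <- function(x, ...) {
  cbind(model = x$model, n = x$n, x$shapes)
}

#' Exact Yule shape distribution
#'
#' Probabilities of every unlabelled bifurcating shape on `n` leaves under
#' the Yule (pure birth) model, computed by an exact dynamic program over
#' the growth process: starting from the cherry, each step replaces a leaf
#' chosen uniformly at random with a cherry. Probabilities are exact
#' rationals with common denominator \eqn{2 \cdot 3 \cdots (n-1)};
#' replacement of automorphism-equivalent leaves is grouped by the
#' canonical key of the resulting shape.
#'
#' @param n leaf count, `2 <= n <= cap`.
#' @param cap resource cap (default 16).
#' @return A `shape_distribution`: list with `model`, `n`, common
#'   denominator `den`, and data frame `shapes` (columns `key`, exact
#'   numerator `num`, `prob`, `sackin`, `n_sym`).
#' @examples
#' yule_shape_distribution(4)$shapes$prob # 1/3 and 2/3
#' @export
yule_shape_distribution <- function(n, cap = 16L) {
  stopifnot(n >= 2)
  if (n > cap) stop("n = ", n, " exceeds the enumeration cap (", cap, ")")
  ck <- paste0("yule:", n)
  hit <- cache_get(ck)
  if (!is.null(hit)) return(hit)
  num <- c("(L,L)" = 1)
  den <- 1
  j <- 2L
  while (j < n) {
    nxt <- new.env(parent = emptyenv())
    for (key in names(num)) {
      c0 <- num[[key]]
      for (i in seq_len(j)) {
        nk <- shape_replace_leaf(key, i)
        prev <- nxt[[nk]]
        nxt[[nk]] <- if (is.null(prev)) c0 else prev + c0
      }
    }
    keys <- sort(names(nxt), method = "radix")
    num <- vapply(keys, function(k) nxt[[k]], 0)
    den <- den * j
    j <- j + 1L
  }
  cache_set(ck, new_shape_distribution("yule", n, names(num), unname(num), den))
}

#' Exact uniform (PDA) shape distribution
#'
#' Under the uniform model every labelled bifurcating topology on `n`
#' leaves is equally likely; summing over labellings, a shape with `s`
#' symmetric internal nodes (two isomorphic child subtrees) has
#' probability \eqn{2^{n-1-s} / C_{n-1}} with \eqn{C} the Catalan numbers
#' -- equivalently \eqn{(n!/2^s)/(2n-3)!!} over labelled topologies; the
#' two weightings agree shape by shape.
#'
#' @inheritParams yule_shape_distribution
#' @return A `shape_distribution` (see [yule_shape_distribution()]).
#' @examples
#' uniform_shape_distribution(4)$shapes$prob # 1/5 and 4/5
#' @export
uniform_shape_distribution <- function(n, cap = 16L) {
  stopifnot(n >= 2)
  if (n > cap) stop("n = ", n, " exceeds the enumeration cap (", cap, ")")
  ck <- paste0("unif:", n)
  hit <- cache_get(ck)
  if (!is.null(hit)) return(hit)
  keys <- sort(enumerate_bifurcating_shapes(n, cap = cap), method = "radix")
  s <- vapply(keys, function(k) shape_stats_cached(k)$n_sym, 1L)
  cache_set(ck, new_shape_distribution("uniform", n, keys,
                                       2^(n - 1L - s), catalan_number(n - 1L)))
}

shape_distribution_for <- function(model = c("yule", "uniform"), n, cap = 16L) {
  model <- match.arg(model)
  if (model == "yule") yule_shape_distribution(n, cap) else
    uniform_shape_distribution(n, cap)
}

#' Exact moments of the Sackin index under a null model
#'
#' Mean, variance and mean reciprocal of the Sackin index over the exact
#' shape distribution.
#'
#' @param model `"yule"` or `"uniform"`.
#' @param n leaf count.
#' @return A list with `mean`, `var`, `mean_inv` and `n`.
#' @export
exact_moments_IS <- function(model, n) {
  d <- shape_distribution_for(model, n)
  IS <- d$shapes$sackin
  num <- d$shapes$num
  m1 <- sum(num * IS) / d$den
  m2 <- sum(num * IS^2) / d$den
  list(n = n, mean = m1, var = m2 - m1^2,
       mean_inv = sum(num / IS) / d$den)
}

#' Exact expected J1 under a null model
#'
#' For unit-leaf leafy bifurcating trees the leafy tree identity gives
#' \eqn{J_1 = n \log_2 n / I_S} per shape, so
#' \eqn{E[J_1] = n \log_2 n \cdot E[1/I_S]} with the expectation taken
#' over the exact shape distribution.
#'
#' @inheritParams exact_moments_IS
#' @return The exact expected value of J1 (a double).
#' @examples
#' exact_expected_j1("yule", 4) # 25/27
#' @export
exact_expected_j1 <- function(model, n) {
  if (n == 2) return(1)
  n * log2(n) * exact_moments_IS(model, n)$mean_inv
}

#' Jensen gap of the first-order expectation approximation
#'
#' Approximating the harmonic mean of the Sackin index by its arithmetic
#' mean gives \eqn{E[J_1] \approx n \log_2 n / E[I_S]}. The error is the
#' Jensen gap \eqn{J(n) = E[J_1] - n \log_2 n / E[I_S] \ge 0} (by
#' convexity of \eqn{x \mapsto 1/x}). The exact term uses shape
#' enumeration; \eqn{E[I_S]} uses the closed forms in
#' [expected_sackin()].
#'
#' @inheritParams exact_moments_IS
#' @return A list of class `gap_report` with `n`, `model`, `exact_e_j1`,
#'   `approx_e_j1` and `gap`.
#' @examples
#' jensen_gap("yule", 4)$gap # 1/351
#' @export
jensen_gap <- function(model, n) {
  exact <- exact_expected_j1(model, n)
  approx <- first_order_j1(model, n)
  structure(list(n = n, model = model, exact_e_j1 = exact,
                 approx_e_j1 = approx, gap = exact - approx),
            class = "gap_report")
}

#' Jensen gap table over a range of leaf counts
#'
#' @param model `"yule"` or `"uniform"`.
#' @param n_range integer vector of leaf counts.
#' @return A data frame with columns `n`, `model`, `e_j1_exact`,
#'   `e_j1_approx1`, `gap`.
#' @export
jensen_gap_table <- function(model, n_range) {
  rows <- lapply(n_range, function(n) {
    g <- jensen_gap(model, n)
    data.frame(n = n, model = model, e_j1_exact = g$exact_e_j1,
               e_j1_approx1 = g$approx_e_j1, gap = g$gap)
  })
  do.call(rbind, rows)
}

# ---- minimal balance over series-reduced shapes ----------------------------

# J1 of a unit-leaf leafy shape, by memoized recursion on canonical keys:
# for a node with children of leaf counts n_c, the J1 numerator satisfies
# Jnum = sum(child Jnum) + n * W_root with W_root the normalized entropy of
# n_c / n, and IS = sum(child IS + n_c); J1 = Jnum / IS.
shape_j1_stats <- function(key) {
  ck <- paste0("j1:", key)
  hit <- cache_get(ck)
  if (!is.null(hit)) return(hit)
  if (key == "L") return(cache_set(ck, c(n = 1, IS = 0, Jnum = 0)))
  node <- shape_parse(key)
  kids <- vapply(node, shape_unparse_canonical, "")
  st <- vapply(kids, shape_j1_stats, c(n = 0, IS = 0, Jnum = 0))
  nc <- st["n", ]
  n <- sum(nc)
  m <- length(kids)
  f <- nc / n
  W <- if (m > 1L) -sum(f * log(f)) / log(m) else 0
  cache_set(ck, c(n = n, IS = sum(st["IS", ] + nc), Jnum = sum(st["Jnum", ]) + n * W))
}

#' J1 of an unlabelled shape with unit leaves
#'
#' @param key a canonical shape key (see [canonical_shape()]).
#' @return J1 of the corresponding unit-leaf leafy tree.
#' @export
shape_j1 <- function(key) {
  st <- shape_j1_stats(key)
  if (st["IS"] == 0) stop("J1 undefined for a single-node shape")
  unname(st["Jnum"] / st["IS"])
}

#' Exhaustive minimal-balance search
#'
#' Finds the least balanced unit-leaf leafy shape(s) on `n` leaves among
#' all shapes with no outdegree-1 nodes, by exhaustive enumeration. For
#' `n <= 4` the minimizer is the caterpillar; beyond that it is a broom
#' tree (verified exhaustively for all `n` within the cap).
#'
#' @param n leaf count, `2 <= n <= cap`.
#' @param cap resource cap (default 12).
#' @return A list with `key` (smallest canonical key among minimizers),
#'   `j1` (the minimum), and `ties` (all minimizing keys).
#' @examples
#' min_balance_search(6)
#' @export
min_balance_search <- function(n, cap = 12L) {
  stopifnot(n >= 2)
  if (n > cap) stop("n = ", n, " exceeds the enumeration cap (", cap, ")")
  keys <- enumerate_shapes_min_outdeg2(n, cap = cap)
  j1 <- vapply(keys, shape_j1, 0)
  jmin <- min(j1)
  ties <- sort(keys[j1 == jmin], method = "radix")
  list(key = ties[1L], j1 = jmin, ties = ties)
}
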