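test_that("Newick parsing honours size annotations and default modes", {
  t1 <- parse_newick("((A,B),C);")
  expect_equal(n_nodes(t1), 5L)
  expect_equal(sort(t1$size[leaves(t1)]), c(1, 1, 1))
  expect_equal(t1$size[internal_nodes(t1)], c(0, 0))

  t2 <- parse_newick("((A[&&NHX:size=4],B[&&NHX:size=2]),C);")
  expect_equal(t2$size[match(c("A", "B", "C"), t2$label)], c(4, 2, 1))

  t3 <- parse_newick("(A,B);", default_sizes = "unit")
  expect_equal(t3$size, c(1, 1, 1))
  t4 <- parse_newick("(A[&&NHX:size=3],B);", default_sizes = "explicit")
  expect_equal(sort(t4$size), c(0, 0, 3))

  # branch lengths parsed but ignored
  t5 <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
  expect_equal(sort(t5$size), c(0, 0, 1, 1, 1))
})

test_that("malformed or invalid Newick is rejected with a position", {
  expect_error(parse_newick("((A,B,C);"), "position")
  expect_error(parse_newick("(A,B)) extra;"), "position")
  expect_error(parse_newick("(A[&&NHX:size=-2],B);"), "negative")
})

test_that("write/parse round trip preserves topology and sizes", {
  set.seed(41)
  for (i in 1:100) {
    tr <- random_any_tree()
    back <- parse_newick(write_newick(tr))
    expect_true(iso_oracle(tr, back))
    expect_equal(sort(back$size), sort(tr$size))
  }
  # explicit fractional size is serialized
  tr <- tree_star <- build_fixture("star", 3)
  tr$size[leaves(tr)[1]] <- 2.5
  expect_match(write_newick(tr), "size=2.5", fixed = TRUE)
  expect_equal(sort(parse_newick(write_newick(tr))$size), c(0, 1, 1, 2.5))
})

test_that("Newick output of plain bifurcating trees agrees with ape", {
  skip_if_not_installed("ape")
  set.seed(5)
  for (i in 1:10) {
    tr <- sample_yule(7)
    tr$label[leaves(tr)] <- paste0("t", seq_len(7))
    ph <- ape::read.tree(text = write_newick(tr))
    expect_equal(ape::Ntip(ph), 7L)
    # rebuild an rtree from ape's edge matrix; shapes must agree
    par <- rep(NA_integer_, max(ph$edge))
    par[ph$edge[, 2]] <- ph$edge[, 1]
    tr2 <- rtree(par, as.numeric(seq_along(par) <= ape::Ntip(ph)))
    expect_identical(canonical_shape(tr2), canonical_shape(tr))
  }
})

test_that("magnitudes satisfy the subtree recursions", {
  ch <- parse_newick("(A,B);")
  m <- compute_magnitudes(ch)
  expect_equal(m$S[ch$root], 2)
  expect_equal(m$S_star[ch$root], 2)

  cat4 <- build_fixture("caterpillar", 4)
  m4 <- compute_magnitudes(cat4)
  expect_equal(sort(m4$S_star[internal_nodes(cat4)], decreasing = TRUE), c(4, 3, 2))

  # weighted caterpillar with leaf sizes 4,2,1,1 from deepest to shallowest:
  # every split is equal-magnitude, so S* opposite the size-4 leaf is 4
  w <- build_fixture("caterpillar", 4)
  dep <- compute_depths(w)$depth[leaves(w)]
  w$size[leaves(w)[order(dep)]] <- c(4, 2, 1, 1)
  mw <- compute_magnitudes(w)
  expect_equal(mw$S_star[w$root], 8)
  expect_equal(sort(mw$S_star[internal_nodes(w)], decreasing = TRUE), c(8, 4, 2))

  set.seed(11)
  for (i in 1:20) {
    tr <- random_any_tree()
    m <- compute_magnitudes(tr)
    expect_equal(m$S_T, sum(tr$size), tolerance = 1e-12)
    expect_equal(m$S, tr$size + m$S_star, tolerance = 1e-12)
  }
})

test_that("depths and heights follow the edge-count definition", {
  ch <- parse_newick("(A,B);")
  expect_equal(compute_depths(ch)$depth[leaves(ch)], c(1L, 1L))
  expect_equal(compute_depths(ch)$height, 1L)
  for (n in c(4, 7, 10))
    expect_equal(compute_depths(build_fixture("caterpillar", n))$height, n - 1L)
  for (k in c(2, 5, 8)) # head leaves sit at depth n - k + 1
    expect_equal(compute_depths(build_fixture("broom", 9, k))$height, 9 - k + 1L)
})

test_that("canonical shape keys agree with brute-force isomorphism", {
  # symmetry: child order never matters
  a <- parse_newick("((A,B),C);")
  b <- parse_newick("(C,(B,A));")
  expect_identical(canonical_shape(a), canonical_shape(b))
  expect_false(canonical_shape(build_fixture("caterpillar", 4)) ==
                 canonical_shape(parse_newick("((A,B),(C,D));")))

  # full catalogue (arbitrary outdegrees) up to 7 leaves: equal keys iff
  # isomorphic, pairwise within each leaf count
  for (n in 2:7) {
    keys <- enumerate_shapes_min_outdeg2(n)
    trees <- lapply(keys, j1balance:::shape_to_rtree)
    expect_equal(length(unique(keys)), length(keys))
    for (i in seq_along(trees)) for (j in seq_len(i - 1L))
      expect_false(iso_oracle(trees[[i]], trees[[j]]))
    # key is reconstructed from the materialized tree
    expect_identical(vapply(trees, canonical_shape, ""), keys)
  }
  expect_equal(length(unique(enumerate_bifurcating_shapes(7))), 11L)
})

test_that("fixture builders produce the documented topologies", {
  cat4 <- build_fixture("caterpillar", 4)
  expect_true(all(outdegree(cat4)[internal_nodes(cat4)] == 2L))
  expect_equal(length(internal_nodes(cat4)), 3L)
  expect_equal(compute_depths(cat4)$height, 3L)

  br <- build_fixture("broom", 9, 5)
  deg <- outdegree(br)[internal_nodes(br)]
  expect_equal(sum(deg == 2L), 4L)
  expect_equal(sum(deg == 5L), 1L)

  expect_true(iso_oracle(build_fixture("broom", 6, 6), build_fixture("star", 6)))
  br_p <- build_fixture("broom", 5, 3, p = 2)
  expect_equal(sort(br_p$size[leaves(br_p)]), c(1, 1, 2, 2, 2))
  expect_error(build_fixture("broom", 5, 1), "k")
  expect_error(build_fixture("broom", 5, 3, p = 0), "p")

  lin <- build_fixture("linear", 4)
  expect_true(all(outdegree(lin)[internal_nodes(lin)] == 1L))

  pm <- build_fixture("perfect_mary", 8, m = 2)
  expect_equal(length(leaves(pm)), 8L)
  expect_equal(compute_depths(pm)$height, 3L)
})
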