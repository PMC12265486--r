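test_that("node balance scores follow the normalized entropy", {
  ch <- parse_newick("(A,B);")
  expect_equal(node_balance(ch, ch$root), 1)

  # child magnitudes 1 and 3
  tr <- parse_newick("(A[&&NHX:size=1],B[&&NHX:size=3]);")
  expect_equal(node_balance(tr, tr$root),
               -(1/4) * log2(1/4) - (3/4) * log2(3/4), tolerance = 1e-12)

  # outdegree-1 nodes score 0
  lin <- build_fixture("linear", 3)
  expect_equal(node_balance(lin, lin$root), 0)

  # zero-magnitude descendants: undefined
  z <- parse_newick("(A[&&NHX:size=0],B[&&NHX:size=0]);", default_sizes = "explicit")
  expect_error(node_balance(z, z$root), "undefined")
  expect_error(node_balance(ch, leaves(ch)[1]), "leaf")
})

test_that("j_one matches hand-computed and closed-form values", {
  expect_equal(j_one(build_fixture("caterpillar", 4)), 8 / 9, tolerance = 1e-12)
  expect_equal(j_one(parse_newick("((A,B),C);")), 3 * log2(3) / 5, tolerance = 1e-12)
  for (n in c(3, 6, 9)) {
    expect_equal(j_one(build_fixture("linear", n)), 0)
    expect_equal(j_one(build_fixture("star", n)), 1)
  }
  # weighted caterpillar 4,2,1,1: every split equal-magnitude, maximal balance
  w <- build_fixture("caterpillar", 4)
  dep <- compute_depths(w)$depth[leaves(w)]
  w$size[leaves(w)[order(dep)]] <- c(4, 2, 1, 1)
  expect_equal(j_one(w), 1, tolerance = 1e-12)
  expect_error(j_one(rtree(NA_integer_, 1)), "undefined")
})

test_that("Sackin indices and their generalization agree on unit-leaf leafy trees", {
  expect_equal(sackin(parse_newick("(A,B);")), 2L)
  expect_equal(sackin(build_fixture("caterpillar", 4)), 9L)
  st <- build_fixture("star", 6)
  expect_equal(sackin(st), 6L)
  expect_equal(generalized_sackin(st), 6)
  set.seed(21)
  for (i in 1:20) {
    tr <- random_full_mary(sample(2:3, 1), unit_leaves = TRUE)
    expect_equal(generalized_sackin(tr), sackin(tr))
    # identity I_S,gen = sum over V~ of S_i*
    m <- compute_magnitudes(tr)
    vt <- intersect(internal_nodes(tr), which(m$S_star > 0))
    expect_equal(generalized_sackin(tr), sum(m$S_star[vt]), tolerance = 1e-12)
  }
  # weighted caterpillar: weighted path length 4*1+2*2+1*3+1*3 = 14
  w <- build_fixture("caterpillar", 4)
  dep <- compute_depths(w)$depth[leaves(w)]
  w$size[leaves(w)[order(dep)]] <- c(4, 2, 1, 1)
  expect_equal(generalized_sackin(w), 14)
})

test_that("the leafy tree identity holds on random full m-ary trees", {
  expect_equal(leafy_identity_gap(build_fixture("caterpillar", 4)), 0, tolerance = 1e-12)
  pm <- build_fixture("perfect_mary", 8)
  expect_equal(leafy_identity_gap(pm), 0, tolerance = 1e-12)
  expect_equal(j_one(pm), 1, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    m <- sample(2:4, 1)
    tr <- random_full_mary(m)
    expect_lt(leafy_identity_gap(tr, m), 1e-10)
  }
  expect_error(leafy_identity_gap(build_fixture("star", 5), 2), "m-ary")
})

test_that("unit-leaf full-binary J1 equals n*log2(n)/IS", {
  set.seed(32)
  for (i in 1:50) {
    tr <- random_full_mary(2, unit_leaves = TRUE)
    n <- length(leaves(tr))
    expect_equal(j_one(tr), n * log2(n) / sackin(tr), tolerance = 1e-12)
  }
})

test_that("J1 is bounded, child-order invariant, and extremal exactly as characterized", {
  set.seed(51)
  shuffle_children <- function(tr) {
    tr$children <- lapply(tr$children, function(k) if (length(k) > 1) sample(k) else k)
    tr
  }
  for (i in 1:50) {
    tr <- random_any_tree()
    m <- compute_magnitudes(tr)
    if (!any(m$S_star[internal_nodes(tr)] > 0)) next
    j <- j_one(tr)
    expect_gte(j, 0); expect_lte(j, 1)
    sh <- shuffle_children(tr)
    expect_equal(j_one(sh), j, tolerance = 1e-12)
    expect_equal(sackin(sh), sackin(tr))
    expect_equal(generalized_sackin(sh), generalized_sackin(tr), tolerance = 1e-12)
  }
  # over the full unit-leaf catalogue with n <= 7: J1 = 0 iff linear (no such
  # shape here), J1 = 1 iff every internal node splits its descendants into
  # equal-magnitude subtrees
  for (n in 3:7) {
    for (key in enumerate_shapes_min_outdeg2(n)) {
      tr <- j1balance:::shape_to_rtree(key)
      j <- j_one(tr)
      expect_gt(j, 0)
      m <- compute_magnitudes(tr)
      all_even <- all(vapply(internal_nodes(tr), function(v) {
        s <- m$S[tr$children[[v]]]
        length(s) >= 2 && diff(range(s)) < 1e-12
      }, TRUE))
      expect_equal(abs(j - 1) < 1e-12, all_even)
    }
  }
})

test_that("balance_report assembles the index from its parts", {
  tr <- parse_newick("((A,B),C);")
  rep <- balance_report(tr)
  vt <- which(rep$in_vtilde)
  expect_equal(rep$j1, sum(rep$g[vt] * rep$W[vt]) / sum(rep$g[vt]), tolerance = 1e-12)
  expect_equal(rep$sackin, 5L)
  expect_equal(rep$generalized_sackin, 5)
  expect_equal(rep$entropy, log2(3), tolerance = 1e-12)
})
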