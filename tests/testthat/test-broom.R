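test_that("the closed-form broom J1 matches tree evaluation", {
  expect_equal(jb1(4, 2, 1), 8 / 9, tolerance = 1e-12)
  expect_equal(jb1(9, 5, 1), 0.62628, tolerance = 1e-4)
  for (n in c(3, 5, 9)) for (p in c(0.3, 1, 4))
    expect_equal(jb1(n, n, p), 1, tolerance = 1e-12) # star
  # p = 1 reduces to the equal-leaf form
  for (n in 4:12) for (k in 2:(n - 1))
    expect_equal(jb1(n, k, 1),
                 2 * (n * log2(n) - k * log2(k) + k) / ((n + k) * (n - k + 1)),
                 tolerance = 1e-12)
  expect_error(jb1(2, 2, 1), "n >= 3")
  expect_error(jb1(5, 6, 1), "k")
  expect_error(jb1(5, 3, 0), "p")

  set.seed(9)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    k <- sample(2:n, 1)
    p <- exp(stats::runif(1, log(1e-3), log(1e3)))
    expect_lt(abs(jb1(n, k, p) - j_one(build_fixture("broom", n, k, p))), 1e-10)
  }
})

test_that("kstar scans the closed form and matches the exhaustive shape search", {
  expect_equal(kstar(9, 1)$k_star, 5L)
  expect_equal(kstar(4, 1)$k_star, 2L)
  expect_equal(kstar(3, 1)$k_star, 2L)
  for (n in 3:200) expect_equal(kstar(n, 1 / 2)$k_star, 2L)
  for (n in 4:200) expect_gte(kstar(n, 1)$r_star, 1 / 2)
  # p = 1, n within the exhaustive cap: broom minimum equals the global one
  for (n in 5:12)
    expect_equal(kstar(n, 1)$jb1_min, min_balance_search(n)$j1, tolerance = 1e-10)
})

test_that("the caterpillar/broom crossover sits between n=4 and n=5", {
  root <- caterpillar_crossover()
  expect_gt(root, 4); expect_lt(root, 5)
  expect_lt(jb1(root - 1e-6, 2, 1) - jb1(root - 1e-6, 3, 1), 0)
  expect_gt(jb1(root + 1e-6, 2, 1) - jb1(root + 1e-6, 3, 1), 0)
  expect_true(jb1(4, 2, 1) < jb1(4, 3, 1))
  expect_true(jb1(5, 2, 1) > jb1(5, 3, 1))
  expect_equal(jb1(4, 3, 1), 0.8922, tolerance = 1e-4)
  expect_equal(jb1(5, 3, 1), 0.8212, tolerance = 1e-4)
})

test_that("theta governs the sign of the p-derivative", {
  expect_equal(theta(2, 1), 1)
  expect_equal(theta(2, 1 / 2), 3)
  expect_equal(theta(2, 0.25), 1 / 0.25 + 2 * 0.75)
  set.seed(1)
  for (i in 1:500) {
    n <- sample(4:100, 1)
    k <- sample(2:(n - 1), 1)
    p <- exp(stats::runif(1, -5, 5))
    if (abs(theta(k, p) - n) < 1e-3) next
    eps <- 1e-6 * p
    fd <- jb1(n, k, p + eps) - jb1(n, k, p - eps)
    expect_equal(sign(fd), sign(theta(k, p) - n))
  }
})

test_that("min over k is maximized in p exactly at n = theta(2, p)", {
  expect_equal(max_min_over_p(3)$p_star, 1 / 2, tolerance = 1e-12)
  for (n in c(5, 10, 50)) {
    ps <- max_min_over_p(n)$p_star
    expect_equal(theta(2, ps), n, tolerance = 1e-9)
    v <- vapply(c(0.5, 0.8, 1, 1.2, 2) * ps,
                function(p) kstar(n, p)$jb1_min, 0)
    expect_true(all(diff(v[1:3]) > 0)) # increasing below p*
    expect_true(all(diff(v[3:5]) < 0)) # decreasing above p*
  }
  # grid scan confirms the maximizer for n = 6
  ps <- max_min_over_p(6)$p_star
  grid <- exp(seq(log(ps / 4), log(ps * 4), length.out = 401))
  vals <- vapply(grid, function(p) kstar(6, p)$jb1_min, 0)
  expect_lt(abs(grid[which.max(vals)] - ps), 1e-2)
  expect_gte(max_min_over_p(6)$value + 1e-12, max(vals))
})

test_that("regions classify as caterpillar, interior, or height-2 cases", {
  expect_identical(classify_region(7, 0.04), "R4")
  expect_identical(classify_region(7, 1), "R2")
  expect_identical(classify_region(7, 200), "R1")
  expect_identical(classify_region(7, 0.5), "R3")
  expect_identical(classify_region(3, 2), "R1")  # k* = 2 for all p at n = 3
  expect_identical(classify_region(3, 0.1), "R3")
  expect_true(classify_region(4, 0.01) %in% c("R4"))
  grid <- broom_grid(5:8, c(0.1, 1, 10))
  expect_true(all(grid$region %in% c("R1", "R2", "R3", "R4")))
  expect_true(all(grid$jb1_min <= 1 & grid$jb1_min > 0))
})

test_that("extreme-p and large-n asymptotics hold at the documented rates", {
  chk <- asymptotic_checks(p = 1, n_grid = c(100, 1000, 1e4, 1e5), n_fixed = 7L)
  expect_lt(abs(chk$large_p_ratio - 1), 0.01)   # jb1 * (n-1) -> 1 as p -> Inf
  expect_lt(abs(chk$small_p_ratio - 1), 0.01)   # jb1 / (p (1-n) log2 p) -> 1
  # p = 1 > 1/2: large heads; convergence of the min to log2(n)/(n p) carries
  # slowly vanishing corrections, so assert monotone decay toward 1 and that
  # the head fraction r* climbs toward 1 like 1 - O(1/sqrt(log2 n))
  expect_true(all(chk$large_n$r_star > 1 / 2))
  expect_true(all(diff(chk$large_n$r_star) > 0))
  expect_true(all(chk$large_n$ratio > 1))
  expect_true(all(diff(chk$large_n$ratio) < 0))
  shrink <- (1 - chk$large_n$r_star) * sqrt(log2(chk$large_n$n))
  expect_lt(max(shrink) / min(shrink), 2)
  # p <= 1/2: caterpillar regime, min ~ 2 log2(n)/n
  chk2 <- asymptotic_checks(p = 0.4, n_grid = c(100, 1000, 1e4, 1e5))
  expect_true(all(chk2$large_n$k_star == 2L))
  expect_lt(abs(chk2$large_n$ratio[4] - 1), 0.05)
  # boundary traces: switch point is genuine and tracks the asymptote loosely
  b <- broom_region_boundary(7, "R1R2")
  expect_equal(kstar(7, b * 0.99)$k_star, 3L)
  expect_equal(kstar(7, b * 1.01)$k_star, 2L)
  b2 <- broom_region_boundary(7, "R3R4")
  expect_equal(kstar(7, b2 * 0.99)$k_star, 6L)
  expect_lt(kstar(7, b2 * 1.01)$k_star, 6L)
  for (n in c(20, 50, 100)) {
    expect_lt(abs(log(broom_region_boundary(n, "R1R2") / (n^2 * log2(n) / 3))),
              log(1.5))
    expect_lt(abs(log(broom_region_boundary(n, "R3R4") / (2 / n^2))), log(1.5))
  }
})
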