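# Closed-form analysis of leafy broom trees: n leaves of which k form the
# star head (each of size p relative to the handle leaves), the remaining
# n - k hang one per internal node along a bifurcating handle.

#' J1 of a leafy broom tree, closed form
#'
#' \deqn{J_1^B(n,k,p) = \frac{2\,[kp + (kp+n-k)\log_2(kp+n-k) -
#'   kp\log_2(kp)]}{(2kp+n-k)(n-k+1)}.}
#' With `p = 1` this reduces to
#' \eqn{2\,[n\log_2 n - k\log_2 k + k] / ((n+k)(n-k+1))}. Real-valued `n`
#' and `k` are admitted for root finding; the formula agrees with
#' [j_one()] evaluated on [build_fixture()] brooms at integer arguments.
#'
#' @param n total leaf count (`>= 3`; real values allowed).
#' @param k head leaf count, `2 <= k <= n` (real values allowed).
#' @param p head leaf size relative to handle leaf size, `> 0`.
#' @return J1 of the broom tree.
#' @examples
#' jb1(9, 5, 1) # about 0.6263
#' @export
jb1 <- function(n, k, p = 1) {
  if (any(n < 3)) stop("broom formula requires n >= 3")
  if (any(k < 2) || any(k > n)) stop("head size k must satisfy 2 <= k <= n")
  if (any(p <= 0)) stop("head leaf size p must be positive")
  kp <- k * p
  h <- n - k
  num <- 2 * (kp + ifelse(h > 0, (kp + h) * log2(kp + h), kp * log2(kp)) -
                kp * log2(kp))
  num / ((2 * kp + h) * (h + 1))
}

#' Minimizing head size of a broom tree
#'
#' Scans `k = 2, ..., n - 1` for the head size minimizing
#' \eqn{J_1^B(n, k, p)} (the star `k = n` has \eqn{J_1^B = 1}, the
#' maximum, and is excluded). Ties go to the smallest `k`; all tying `k`
#' are reported.
#'
#' @param n total leaf count, integer `>= 3`.
#' @param p head leaf size, `> 0`.
#' @return A list with `k_star`, `r_star = k_star/n`, `jb1_min`, `ties`,
#'   and the region label from [classify_region()] (`NA` for `n <= 4`).
#' @examples
#' kstar(9, 1)$k_star # 5
#' @export
kstar <- function(n, p = 1) {
  stopifnot(n >= 3, p > 0)
  ks <- 2:max(2L, n - 1L)
  vals <- jb1(n, ks, p)
  jmin <- min(vals)
  ties <- ks[vals == jmin]
  k_star <- ties[1L]
  list(k_star = k_star, r_star = k_star / n, jb1_min = jmin, ties = ties,
       region = if (n > 4) region_label(n, p, k_star) else NA_character_)
}

region_label <- function(n, p, k_star) {
  if (k_star == 2L) { if (p > 1) "R1" else "R3" }
  else if (k_star == n - 1L) "R4"
  else "R2"
}

#' Region classification of the least balanced broom
#'
#' For `n > 4` the minimizing head size falls into one of four regions of
#' (n, p) space: `R1` (`k* = 2`, `p > 1`) and `R3` (`k* = 2`, `p <= 1`),
#' where the least balanced broom is a caterpillar; `R2`
#' (`2 < k* < n - 1`: long handle and large head); and `R4`
#' (`k* = n - 1`: height-2 trees). For `n = 3`, `k* = 2` for all `p`; for
#' `n = 4` only `k* = 2` and `k* = 3 = n - 1` occur; these small cases are
#' labelled with the same rules.
#'
#' @param n total leaf count, integer `>= 3`.
#' @param p head leaf size, `> 0`.
#' @return A region label, one of `"R1"`, `"R2"`, `"R3"`, `"R4"`.
#' @examples
#' classify_region(7, 0.04) # "R4"
#' @export
classify_region <- function(n, p) {
  stopifnot(n >= 3, p > 0)
  region_label(n, p, kstar(n, p)$k_star)
}

#' Crossover leaf count between caterpillar and k = 3 broom
#'
#' The caterpillar (`k = 2`) is strictly less balanced than the `k = 3`
#' broom, \eqn{J_1^B(n,2,1) < J_1^B(n,3,1)}, only below a crossover leaf
#' count: this returns the real root \eqn{n^*} of
#' \eqn{J_1^B(n,2,1) = J_1^B(n,3,1)} in `(3, 10)`, located by bisection.
#' The unique integer `n > 3` below the root is 4, which is why the
#' caterpillar minimizes J1 over series-reduced shapes exactly when
#' `n <= 4`.
#'
#' @param tol bisection tolerance on `n`.
#' @return The crossover root (about 4.19).
#' @export
caterpillar_crossover <- function(tol = 1e-9) {
  f <- function(n) jb1(n, 2, 1) - jb1(n, 3, 1)
  lo <- 3 + 1e-9; hi <- 10
  if (f(lo) >= 0 || f(hi) <= 0) stop("no sign change on (3, 10)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Threshold governing the p-monotonicity of broom J1
#'
#' \eqn{\theta(k,p) = 2/(kp) + k(1-p)}: for fixed `k`,
#' \eqn{J_1^B(n,k,p)} is strictly decreasing in `p` when
#' \eqn{n > \theta(k,p)} and strictly increasing when
#' \eqn{n < \theta(k,p)}. The same threshold at `k = 2`,
#' \eqn{\theta(2,p) = 1/p + 2(1-p)}, governs the minimum over `k`.
#'
#' @param k head size, `>= 2` (real allowed).
#' @param p head leaf size, `> 0`.
#' @return \eqn{\theta(k,p)}.
#' @examples
#' theta(2, 1/2) # 3
#' @export
theta <- function(k, p) {
  stopifnot(k >= 2, p > 0)
  2 / (k * p) + k * (1 - p)
}

#' Head-leaf size maximizing the minimal broom balance
#'
#' Over `p`, the least balanced broom's J1, \eqn{\min_k J_1^B(n,k,p)},
#' increases while \eqn{n < \theta(2,p)} and decreases while
#' \eqn{n > \theta(2,p)}; its maximum is at the unique positive root of
#' \eqn{n = \theta(2,p)}, i.e. of \eqn{2p^2 + (n-2)p - 1 = 0}.
#'
#' @param n total leaf count, integer `>= 3`.
#' @return A list with `p_star` (the quadratic root) and `value`
#'   (\eqn{\min_k J_1^B(n, k, p^*)}).
#' @examples
#' max_min_over_p(3)$p_star # 1/2
#' @export
max_min_over_p <- function(n) {
  stopifnot(n >= 3)
  p_star <- (-(n - 2) + sqrt((n - 2)^2 + 8)) / 4
  list(p_star = p_star, value = kstar(n, p_star)$jb1_min)
}

#' Locate a region boundary in p for fixed n
#'
#' Bisection in `log p` on the integer-valued switch of the minimizing
#' head size: the `R1`--`R2` boundary is where `k*` drops to 2 as `p`
#' grows (asymptotically \eqn{p = n^2 \log_2 n / 3}); the `R3`--`R4`
#' boundary is where `k*` leaves `n - 1` as `p` grows (asymptotically
#' \eqn{p = 2/n^2}).
#'
#' @param n total leaf count, integer `> 4`.
#' @param boundary `"R1R2"` or `"R3R4"`.
#' @param tol relative tolerance on `p`.
#' @return The boundary value of `p`.
#' @export
broom_region_boundary <- function(n, boundary = c("R1R2", "R3R4"), tol = 1e-6) {
  boundary <- match.arg(boundary)
  stopifnot(n > 4)
  at <- function(p) kstar(n, p)$k_star
  if (boundary == "R1R2") {
    lo <- log(1); hi <- log(n^2 * log2(n)) # k* > 2 at p=1; k* = 2 far right
    cond <- function(p) at(p) == 2L
  } else {
    lo <- log(1e-8 / n^2); hi <- log(1)
    cond <- function(p) at(p) < n - 1L
  }
  if (cond(exp(lo)) || !cond(exp(hi))) stop("boundary not bracketed")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cond(exp(mid))) hi <- mid else lo <- mid
  }
  exp((lo + hi) / 2)
}

#' Numerical checks of the broom asymptotics
#'
#' Evaluates, from the closed form alone, the empirical ratios behind the
#' large-`n` and extreme-`p` behaviour of the least balanced broom:
#' \itemize{
#'   \item `p <= 1/2`: `k*` and the ratio of \eqn{\min_k J_1^B} to its
#'     caterpillar asymptote \eqn{2\log_2(n)/n} over `n_grid`;
#'   \item `p > 1/2`: `r* = k*/n` and the ratio to the large-head
#'     asymptote \eqn{\log_2(n)/(np)};
#'   \item fixed `n`: \eqn{J_1^B(n,k^*,p)(n-1)} as `p` grows large and
#'     \eqn{J_1^B(n,k^*,p)/(p(1-n)\log_2 p)} as `p` vanishes;
#'   \item boundary traces compared against \eqn{2/n^2} and
#'     \eqn{n^2\log_2(n)/3}.
#' }
#'
#' @param p head leaf size for the large-`n` ratios.
#' @param n_grid integer leaf counts for the large-`n` ratios.
#' @param n_fixed leaf count for the extreme-`p` and boundary checks.
#' @param p_large,p_small extreme head-leaf sizes.
#' @return A list with data frame `large_n` (columns `n`, `k_star`,
#'   `r_star`, `jb1_min`, `ratio`) and scalars `large_p_ratio`,
#'   `small_p_ratio`, `boundary_R1R2`, `boundary_R1R2_ref`,
#'   `boundary_R3R4`, `boundary_R3R4_ref`.
#' @export
asymptotic_checks <- function(p = 1, n_grid = c(10, 100, 1000, 1e4, 1e5),
                              n_fixed = 7L, p_large = 1e6, p_small = 1e-8) {
  rows <- lapply(n_grid, function(n) {
    ks <- kstar(n, p)
    ref <- if (p <= 1/2) 2 * log2(n) / n else log2(n) / (n * p)
    data.frame(n = n, k_star = ks$k_star, r_star = ks$r_star,
               jb1_min = ks$jb1_min, ratio = ks$jb1_min / ref)
  })
  list(
    large_n = do.call(rbind, rows),
    large_p_ratio = kstar(n_fixed, p_large)$jb1_min * (n_fixed - 1),
    small_p_ratio = kstar(n_fixed, p_small)$jb1_min /
      (p_small * (1 - n_fixed) * log2(p_small)),
    boundary_R1R2 = broom_region_boundary(n_fixed, "R1R2"),
    boundary_R1R2_ref = n_fixed^2 * log2(n_fixed) / 3,
    boundary_R3R4 = broom_region_boundary(n_fixed, "R3R4"),
    boundary_R3R4_ref = 2 / n_fixed^2)
}

#' Grid of least balanced brooms over (n, p)
#'
#' @param n_range integer leaf counts.
#' @param p_values head leaf sizes.
#' @return A data frame with columns `n`, `p`, `k_star`, `r_star`,
#'   `jb1_min`, `region`.
#' @export
broom_grid <- function(n_range, p_values) {
  rows <- list()
  for (n in n_range) for (p in p_values) {
    ks <- kstar(n, p)
    rows[[length(rows) + 1L]] <- data.frame(
      n = n, p = p, k_star = ks$k_star, r_star = ks$r_star,
      jb1_min = ks$jb1_min,
      region = if (n > 4) ks$region else NA_character_)
  }
  do.call(rbind, rows)
}
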