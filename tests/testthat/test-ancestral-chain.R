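test_that("single-lineage matrix has the forced backward structure", {
  lh <- life_history(p = c(0, 0, 0.1, 0.2, 0.7),
                     c = c(0, 0, 0.05, 0.05, 0.1), N = 1000)
  xi <- build_xi(lh)
  expect_equal(xi[1, ], lh$p, ignore_attr = TRUE)
  for (i in 2:5) {
    expect_equal(unname(xi[i, i - 1]), 1)
    expect_equal(sum(xi[i, ]), 1)
  }
  expect_equal(unname(rowSums(xi)), rep(1, 5))
  # single parental age: the chain is the 5-cycle 1 -> 5 -> 4 -> ... -> 1
  xi1 <- build_xi(lh_single())
  expect_equal(unname(xi1[1, 5]), 1)
  expect_equal(unname(diag(xi1 %*% xi1 %*% xi1 %*% xi1 %*% xi1)), rep(1, 5))
})

test_that("stationary ages match the closed form and the eigen oracle", {
  expect_equal(stationary_ages(lh_single()), rep(0.2, 5))
  lh <- life_history(p = c(0, 0, 0.1, 0.2, 0.7),
                     c = c(0, 0, 0.05, 0.05, 0.1), N = 1000)
  pi1 <- stationary_ages(lh)
  expect_equal(pi1, c(1, 1, 1, 0.9, 0.7) / 4.6)
  expect_equal(pi1, stationary_eigen(build_xi(lh)), tolerance = 1e-12)
  # pi_1 = 1 / g across a panel of generated life histories
  for (seed in 1:10) {
    lhr <- generate_fixture(seed, mode = "strict")
    pir <- stationary_ages(lhr)
    expect_equal(pir[1], 1 / generation_length(lhr), tolerance = 1e-12)
    expect_equal(pir, stationary_eigen(build_xi(lhr)), tolerance = 1e-10)
  }
  # a reducible chain has no unique stationary distribution
  xi_red <- diag(3)
  expect_error(stationary_ages(xi_red), "reducible")
})

test_that("Kronecker product has the block structure and mixed-product law", {
  expect_equal(kron_product(diag(2), diag(2)), diag(4))
  withr::with_seed(42, {
    U <- matrix(runif(9), 3)
    V <- matrix(runif(9), 3)
    W <- matrix(runif(9), 3)
    X <- matrix(runif(9), 3)
    expect_equal(kron_product(U, V) %*% kron_product(W, X),
                 kron_product(U %*% W, V %*% X), tolerance = 1e-12)
    # n-step two-lineage movement is the Kronecker square of the n-step
    # single-lineage matrix
    xi <- matrix(rexp(25), 5)
    xi <- xi / rowSums(xi)
    xi3 <- xi %*% xi %*% xi
    K <- kron_product(xi, xi)
    expect_equal(K %*% K %*% K, kron_product(xi3, xi3), tolerance = 1e-12)
    expect_equal(unname(rowSums(K)), rep(1, 25))
  })
})

test_that("two-lineage chain has exact finite-N coalescence entries", {
  # both lineages in the single spawning class: 1/D_5 chance of one parent
  ch1 <- two_lineage_chain(lh_single(1000))
  expect_equal(unname(ch1$Pi_N["(1,1)", "C"]), 1 / 200)
  # chinook death counts with explicit contributions (0.1, 0.2, 0.7)
  lh <- lh_chinook(p = c(0, 0, 0.1, 0.2, 0.7))
  ch <- two_lineage_chain(lh)
  expect_equal(unname(ch$Pi_N["(1,1)", "C"]),
               0.01 / 160 + 0.04 / 128 + 0.49 / 512)
  # deterministic joint aging backward
  expect_equal(unname(ch$Pi_N["(3,5)", "(2,4)"]), 1)
  expect_equal(sum(ch$Pi_N["(3,5)", ]), 1)
  # structural invariants: stochastic rows, absorbing C, A = xi (x) xi,
  # B supported on the (1,1) row with zero row sum
  expect_equal(unname(rowSums(ch$Pi_N)), rep(1, 26), tolerance = 1e-12)
  expect_equal(unname(rowSums(ch$A)), rep(1, 26), tolerance = 1e-12)
  expect_equal(unname(ch$Pi_N["C", ]), c(rep(0, 25), 1))
  expect_equal(ch$A[1:25, 1:25],
               kron_product(build_xi(lh), build_xi(lh)), ignore_attr = TRUE)
  expect_equal(unname(rowSums(ch$B)), rep(0, 26), tolerance = 1e-12)
  expect_true(all(ch$B[-1, ] == 0))
  expect_equal(unname(ch$B["(1,1)", "C"]), sum_p2_over_c(lh))
  # a reproductive class with no deaths at this N errors
  tiny <- life_history(p = c(0, 0, 0.5, 0.3, 0.2),
                       c = c(0, 0, 0.001, 0.1, 0.1), N = 100)
  expect_error(two_lineage_chain(tiny), "D_m < 1")
})

test_that("decomposition residual N (Pi_N - A) - B vanishes as O(1/N)", {
  lh <- generate_fixture(7, mode = "strict")
  norms <- sapply(c(1e3, 1e4, 1e5), function(N) {
    ch <- two_lineage_chain(lh, N)
    max(abs(N * (ch$Pi_N - ch$A) - ch$B))
  })
  # rounding D to integers perturbs 1/D by at most 1/(2 c^2 N^2)
  K <- sum(lh$p[lh$p > 0]^2 / lh$c[lh$p > 0]^2)
  expect_lt(norms[1], K / 1e3)
  expect_lt(norms[3], norms[1])
  # at sizes where every c_m N is an integer the decomposition is exact
  ch <- two_lineage_chain(lh_pub_strict(1e4))
  expect_equal(max(abs(1e4 * (ch$Pi_N - ch$A) - ch$B)), 0, tolerance = 1e-9)
})

test_that("fast-process limit rows are the product stationary distribution", {
  fixtures <- list(lh_pub_strict(), lh_chinook(),
                   generate_fixture(1, mode = "strict"),
                   generate_fixture(2, mode = "strict"),
                   generate_fixture(3, mode = "lax"))
  for (lh in fixtures) {
    ch <- two_lineage_chain(lh, 1e4)
    ml <- mohle_limit(ch)
    pi1 <- stationary_ages(lh)
    expect_equal(unname(ml$P[1, 1:25]),
                 as.vector(t(outer(pi1, pi1))), tolerance = 1e-12)
    expect_equal(unname(ml$P[1, 26]), 0)
    num <- limit_matrix_numeric(ch)
    expect_equal(num$method, "power")
    expect_lt(max(abs(num$limit - ml$P)), 1e-8)
    # generator rows sum to zero; last column constant across transient
    # rows at (1/g^2) sum p^2/c
    expect_lt(max(abs(rowSums(ml$G))), 1e-10)
    g <- generation_length(lh)
    expect_equal(unname(ml$G[1:25, 26]),
                 rep(sum_p2_over_c(lh) / g^2, 25), tolerance = 1e-10)
  }
})

test_that("periodic lineage chains use the Cesaro construction", {
  ch <- two_lineage_chain(lh_single(1000))
  ml <- mohle_limit(ch)
  num <- limit_matrix_numeric(ch, n = 4000)
  expect_equal(num$method, "cesaro")
  # the row-wise Cesaro limit keeps phase structure: rows are uniform on
  # the 5-state orbit of each start, not on all 25 states ...
  expect_equal(sort(unique(round(num$limit[1, 1:25], 9))), c(0, 0.2))
  # ... but its pi (x) pi weighted average recovers the analytic projection
  w <- as.vector(t(outer(rep(0.2, 5), rep(0.2, 5))))
  expect_equal(unname(as.vector(w %*% num$limit[1:25, 1:25])),
               unname(ml$P[1, 1:25]), tolerance = 1e-9)
  # the generator still carries the closed-form rate
  expect_equal(unname(ml$G[1, 26]), sum_p2_over_c(ch$lh) / 25,
               tolerance = 1e-12)
})

test_that("closed-form effective size agrees with the numeric generator", {
  lh <- lh_pub(1e5)
  ml <- mohle_limit(two_lineage_chain(lh, 1e5))
  g <- generation_length(lh)
  # 1 / (Ne g) in N-year units equals the generator's coalescence rate / g
  expect_equal(ces(lh), lh$N * g / (ml$ces_rate * g^2), tolerance = 1e-12)
  expect_equal(ces(lh), 1e5 * 4.67 / sum_p2_over_c(lh))
  expect_equal(ces(lh), 97889.9, tolerance = 1e-5)
})

test_that("effective size scales linearly and is not class-symmetric", {
  lh <- lh_pub(1e4)
  expect_equal(ces(life_history(lh$p, lh$c, 7 * lh$N)), 7 * ces(lh))
  # swapping the (p, c) pairs of ages 4 and 5 changes Ne: the age weights
  # in g do not follow the swap
  sw <- life_history(p = lh$p[c(1, 2, 3, 5, 4)], c = lh$c[c(1, 2, 3, 5, 4)],
                     N = lh$N)
  expect_false(isTRUE(all.equal(ces(sw), ces(lh))))
  # with p4 = p5 and c4 = c5 the swap is a no-op
  sym <- life_history(p = c(0, 0, 0.2, 0.4, 0.4), c = c(0, 0, .05, .1, .1),
                      N = 1e4)
  sym_sw <- life_history(p = sym$p[c(1, 2, 3, 5, 4)],
                         c = sym$c[c(1, 2, 3, 5, 4)], N = 1e4)
  expect_equal(ces(sym_sw), ces(sym))
})

test_that("absorption oracle converges to Ne g at rate O(1/N)", {
  lh <- lh_pub_strict()
  g <- generation_length(lh)
  rel <- sapply(c(1e3, 1e4), function(N) {
    th <- ces(life_history(lh$p, lh$c, N)) * g
    abs(mean_absorption_time(lh, N, "stationary") - th) / th
  })
  expect_lt(rel[2], rel[1] / 5)    # a decade of N buys ~10x accuracy
  expect_lt(rel[1], 1e-2)
  # from the coalescence-active state the band is much tighter
  th3 <- ces(life_history(lh$p, lh$c, 1e3)) * g
  expect_lt(abs(mean_absorption_time(lh, 1e3, c(1, 1)) - th3) / th3, 2e-3)
})

test_that("periodic out-of-phase pairs never coalesce", {
  lh <- lh_single(1000)
  expect_warning(m <- mean_absorption_time(lh, 1000, "stationary"),
                 "unreachable")
  expect_identical(m, Inf)
  # in-phase start: exact mean is 1 + g (D_5 - 1) years
  expect_equal(mean_absorption_time(lh, 1000, c(1, 1)), 1 + 5 * 199)
})

test_that("CES surface is monotone in c5 but not in p5", {
  surf <- ces_surface(p5 = seq(0, 0.95, by = 0.05),
                      c5 = c(0.05, 0.10), N = 1000)
  expect_s3_class(surf, "salmon_ces_surface")
  # infeasible p5 > 0.9 rows are flagged, not dropped
  expect_true(any(!surf$feasible))
  expect_true(all(is.na(surf$Ne[!surf$feasible])))
  # raising c5 raises Ne at every feasible p5 with p5 > 0 (and leaves it
  # untouched at p5 = 0, where the last class contributes nothing)
  wide <- tidyr::pivot_wider(dplyr::filter(surf, surf$feasible),
                             names_from = "c5", values_from = "Ne",
                             names_prefix = "c")
  expect_true(all(wide$c0.1[wide$p5 > 0] > wide$c0.05[wide$p5 > 0]))
  expect_equal(wide$c0.1[wide$p5 == 0], wide$c0.05[wide$p5 == 0])
  # the p5 profile peaks strictly inside (0, 0.9)
  prof <- dplyr::filter(surf, surf$feasible, surf$c5 == 0.05)
  peak <- which.max(prof$Ne)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(prof))
  single <- ces_surface(p5 = 0.7, c5 = 0.05, N = 1000)
  expect_equal(nrow(single), 1)
})
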