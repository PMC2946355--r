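#' Single-lineage backward transition matrix
#'
#' Backward in time, a lineage in age class \eqn{i \ge 2} was in class
#' `i - 1` the year before; a lineage in the first age class descends from a
#' parent in class `m` with probability `p[m]`. Row 1 of the matrix is
#' therefore the contribution vector `p` and every other row is a shifted
#' unit vector.
#'
#' @param lh A [life_history()].
#' @return A `k x k` row-stochastic matrix.
#' @export
build_xi <- function(lh) {
  assert_valid(lh)
  k <- lh$k
  xi <- matrix(0, k, k)
  xi[1, ] <- lh$p
  for (i in 2:k) xi[i, i - 1] <- 1
  dimnames(xi) <- list(seq_len(k), seq_len(k))
  xi
}

# period of the lineage chain: gcd of the cycle lengths through class 1,
# i.e. gcd of the reproductive ages with p_i > 0
lineage_period <- function(p) {
  Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }
    a
  }, which(p > 0))
}

# can every state reach every other (single-lineage chain)?
xi_irreducible <- function(xi) {
  k <- nrow(xi)
  reach <- function(M) {
    R <- diag(k) + M
    for (i in seq_len(k)) R <- R + R %*% M  # k rounds of expansion suffice
    R > 0
  }
  all(reach(xi)) && all(reach(t(xi)))
}

#' Stationary age distribution of a backward lineage
#'
#' Solves \eqn{\pi \xi = \pi} numerically and checks it against the closed
#' form \eqn{\pi_i = (\sum_{j \ge i} p_j) / g}: a lineage sits in class `i`
#' for one year of every parental-age cycle whose length is at least `i`,
#' and cycles have mean length `g`. In particular \eqn{\pi_1 = 1/g}.
#'
#' @param xi Single-lineage matrix from [build_xi()], or a [life_history()].
#' @param tol Agreement required between the numeric solve and the closed
#'   form (when row 1 carries the contribution vector).
#' @return Length-`k` probability vector.
#' @export
stationary_ages <- function(xi, tol = 1e-12) {
  if (inherits(xi, "salmon_lh")) xi <- build_xi(xi)
  k <- nrow(xi)
  if (!xi_irreducible(xi))
    stop("no unique stationary distribution: the lineage chain is reducible")
  # left null space of (xi - I), with the normalisation sum(pi) = 1
  M <- rbind(t(xi) - diag(k), rep(1, k))
  pi_num <- qr.solve(M, c(rep(0, k), 1))
  p <- unname(xi[1, ])
  g <- sum(seq_len(k) * p)
  pi_closed <- rev(cumsum(rev(p))) / g
  if (max(abs(pi_num - pi_closed)) > tol)
    stop(sprintf(
      "closed-form stationary distribution disagrees with numeric solve (%.3g)",
      max(abs(pi_num - pi_closed))))
  pi_closed
}

#' Kronecker product
#'
#' Block tensor product \eqn{(U \otimes V)[(a-1)m + c,\ (b-1)n + d] =
#' U[a,b]\, V[c,d]}. The two-lineage fast dynamics are the Kronecker square
#' of the single-lineage matrix, and the n-step two-lineage matrix is the
#' Kronecker square of the n-step single-lineage matrix (mixed-product
#' property).
#'
#' @param U,V Matrices.
#' @return The Kronecker product matrix.
#' @export
kron_product <- function(U, V) {
  kronecker(U, V)
}

# state bookkeeping for the two-lineage chain: ordered pairs (i, j) in
# lexicographic order, then the absorbing coalesced state "C"
pair_states <- function(k) {
  c(as.vector(t(outer(seq_len(k), seq_len(k),
                      function(i, j) paste0("(", i, ",", j, ")")))), "C")
}

pair_index <- function(i, j, k) (i - 1L) * k + j

#' Two-lineage ancestral chain and its two-time-scale decomposition
#'
#' Builds the exact finite-`N` transition matrix `Pi_N` of two labelled
#' lineages over the \eqn{k^2 + 1} states (ordered age-class pairs plus the
#' absorbing coalesced state `C`), together with the decomposition
#' \eqn{\Pi_N = A + B/N}: `A` is the fast movement process, whose transient
#' block is the Kronecker square \eqn{\xi \otimes \xi}, and `B` carries the
#' slow coalescence, non-zero only in the row for state (1,1) — the only
#' state from which lineages can coalesce, since both must descend from the
#' same year's spawners.
#'
#' From (1,1) each lineage picks a parental class (`m`, `l`) with
#' probability `p[m] p[l]`; if the classes coincide the lineages pick the
#' same parent among the `D_m` spawners with probability `1/D_m`. Hence
#' `Pi_N[(1,1) -> C]` is \eqn{\sum_m p_m^2 / D_m}. Finite-`N` entries use
#' integer death counts `D_m = max(1, round(c_m N))` so `Pi_N` stays a true
#' stochastic matrix at small `N`; `A` and `B` use the exact `c_m`.
#'
#' @param lh A [life_history()].
#' @param N Finite population size for `Pi_N` (defaults to `lh$N`).
#' @return An object of class `salmon_chain` with elements `states`, `Pi_N`,
#'   `A`, `B`, `D`, `lambda` (the one-step coalescence probability from
#'   (1,1)), `N`, and the life history.
#' @export
two_lineage_chain <- function(lh, N = lh$N) {
  assert_valid(lh)
  k <- lh$k
  p <- lh$p
  D <- pmax(1, round(lh$c * N))
  if (any(p > 0 & round(lh$c * N) < 1))
    stop("death count D_m < 1 for a reproductive class at this N")
  ns <- k^2 + 1L
  states <- pair_states(k)
  repro <- which(p > 0)
  lambda <- sum(p[repro]^2 / D[repro])

  Pi <- matrix(0, ns, ns, dimnames = list(states, states))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r <- pair_index(i, j, k)
    if (i >= 2 && j >= 2) {
      Pi[r, pair_index(i - 1L, j - 1L, k)] <- 1
    } else if (i == 1 && j >= 2) {
      for (m in repro) Pi[r, pair_index(m, j - 1L, k)] <- p[m]
    } else if (j == 1 && i >= 2) {
      for (m in repro) Pi[r, pair_index(i - 1L, m, k)] <- p[m]
    } else {
      Pi[r, ns] <- lambda
      for (m in repro) for (l in repro)
        Pi[r, pair_index(m, l, k)] <-
          if (m == l) p[m]^2 * (1 - 1 / D[m]) else p[m] * p[l]
    }
  }
  Pi[ns, ns] <- 1

  A <- matrix(0, ns, ns, dimnames = list(states, states))
  A[seq_len(k^2), seq_len(k^2)] <- kron_product(build_xi(lh), build_xi(lh))
  A[ns, ns] <- 1

  B <- matrix(0, ns, ns, dimnames = list(states, states))
  r11 <- pair_index(1L, 1L, k)
  B[r11, ns] <- sum(p[repro]^2 / lh$c[repro])
  for (m in repro) B[r11, pair_index(m, m, k)] <- -p[m]^2 / lh$c[m]

  structure(list(states = states, Pi_N = Pi, A = A, B = B, D = D,
                 lambda = lambda, N = N, lh = lh),
            class = "salmon_chain")
}

#' @export
print.salmon_chain <- function(x, ...) {
  cat(sprintf("<salmon_chain> %d states, N = %g, P[(1,1) -> C] = %.4g\n",
              length(x$states), x$N, x$lambda))
  invisible(x)
}

#' Two-time-scale limit of the ancestral chain
#'
#' The fast process `A` mixes the lineage pair over age classes on a O(1)
#' timescale while coalescence happens at O(1/N); in the limit the chain
#' converges to a continuous-time process with generator \eqn{G = P B P},
#' where `P` is the long-run projection of the fast process. Every transient
#' row of `P` is the product stationary distribution \eqn{\pi \otimes \pi},
#' so the last column of `G` is constant over transient rows and equals
#' \eqn{\pi_1^2 \sum_m p_m^2 / c_m = (1/g^2) \sum_m p_m^2 / c_m}: the pair
#' coalescence rate per year on the timescale of `N` years. Dividing by a
#' further factor `1/g` to count in generations and inverting gives the
#' coalescent effective size of [ces()].
#'
#' @param chain A [two_lineage_chain()].
#' @return An object of class `salmon_mohle` with `P`, `G`, `pi` (the
#'   single-lineage stationary distribution), `ces_rate`
#'   (\eqn{(1/g^2)\sum p_m^2/c_m}), `g`, and `Ne`.
#' @export
mohle_limit <- function(chain) {
  stopifnot(inherits(chain, "salmon_chain"))
  lh <- chain$lh
  k <- lh$k
  ns <- k^2 + 1L
  pi1 <- stationary_ages(build_xi(lh))
  P <- matrix(0, ns, ns, dimnames = list(chain$states, chain$states))
  pp <- as.vector(t(outer(pi1, pi1)))
  for (r in seq_len(k^2)) P[r, seq_len(k^2)] <- pp
  P[ns, ns] <- 1
  G <- P %*% chain$B %*% P
  g <- generation_length(lh)
  repro <- which(lh$p > 0)
  rate <- sum(lh$p[repro]^2 / lh$c[repro]) / g^2
  structure(list(P = P, G = G, pi = pi1, ces_rate = rate, g = g,
                 Ne = ces(lh), lh = lh),
            class = "salmon_mohle")
}

#' @export
print.salmon_mohle <- function(x, ...) {
  cat(sprintf(
    "<salmon_mohle> pair coalescence rate %.6g per g^2 N-years; Ne = %.6g\n",
    x$ces_rate, x$Ne))
  invisible(x)
}

#' One-row summary of the two-time-scale limit
#'
#' @param x A [mohle_limit()].
#' @param ... Unused.
#' @return A tibble with `g`, `ces_rate`, `Ne` and the invariant-check
#'   residuals `max_row_resid_G` (rows of G should sum to 0) and
#'   `last_col_spread` (the transient last column of G should be constant).
#' @method glance salmon_mohle
#' @export
glance.salmon_mohle <- function(x, ...) {
  k2 <- nrow(x$G) - 1L
  tibble::tibble(
    g = x$g, ces_rate = x$ces_rate, Ne = x$Ne,
    max_row_resid_G = max(abs(rowSums(x$G))),
    last_col_spread = diff(range(x$G[seq_len(k2), k2 + 1L])))
}

#' Numeric long-run projection of the fast process
#'
#' Computes \eqn{A^n} by repeated squaring when the lineage chain is
#' aperiodic, or the Cesaro average \eqn{(1/n)\sum_{m \le n} A^m} when it is
#' periodic (a single reproductive age makes the chain a cycle and the plain
#' power limit does not exist). Note that for a periodic chain the Cesaro
#' average retains the phase structure: each row is uniform over the orbit
#' of its starting state, and only the \eqn{\pi\otimes\pi}-weighted row
#' average recovers the analytic projection used by [mohle_limit()].
#'
#' @param chain A [two_lineage_chain()].
#' @param n Number of steps (power of two recommended for the aperiodic
#'   path).
#' @return A list with the matrix `limit` and the method used (`"power"` or
#'   `"cesaro"`).
#' @export
limit_matrix_numeric <- function(chain, n = 4096) {
  A <- chain$A
  if (lineage_period(chain$lh$p) == 1) {
    M <- A
    steps <- ceiling(log2(n))
    for (s in seq_len(steps)) M <- M %*% M
    list(limit = M, method = "power")
  } else {
    S <- matrix(0, nrow(A), ncol(A))
    M <- diag(nrow(A))
    for (s in seq_len(n)) {
      M <- M %*% A
      S <- S + M
    }
    list(limit = S / n, method = "cesaro")
  }
}

#' Coalescent effective population size
#'
#' Closed form from the two-time-scale limit:
#' \deqn{N_e = \frac{N\, g}{\sum_m p_m^2 / c_m}}
#' with `g` the generation length and the sum over reproductive classes.
#' Equivalently, pairs coalesce at rate \eqn{(1/g^2)\sum_m p_m^2/c_m} per
#' generation when time is counted in units of `N` years, so rescaling by
#' \eqn{N_e} generations recovers the unit-rate pair coalescent.
#'
#' Two special cases anchor the formula: a single reproductive age with
#' equal age classes (`p_k = 1`, `c_k = 1/k`) gives \eqn{N_e = N}, matching
#' the standard Wright-Fisher model; and the conservative weighting
#' \eqn{p_m = m\, c_m} gives \eqn{N_e = N} for any death schedule, the
#' age-structure analogue of conservative migration.
#'
#' @param lh A [life_history()].
#' @return Effective size in individuals (scales linearly in `N`).
#' @export
ces <- function(lh) {
  assert_valid(lh)
  repro <- which(lh$p > 0)
  lh$N * generation_length(lh) / sum(lh$p[repro]^2 / lh$c[repro])
}

#' CES over a grid of late-age parameters
#'
#' Evaluates [ces()] on a grid of the last-class contribution `p5` and death
#' fraction `c5`, holding the third-class parameters and `c4` fixed and
#' taking `p4 = p45 - p5` so the reproductive contributions sum to one.
#' This is the classic exploration surface for a five-class salmon life
#' history: `Ne` increases with the relative abundance of old spawners
#' (`c5`, which lengthens the generation), but is not monotone in `p5`
#' because a dominant last-class contribution concentrates reproductive
#' success in few individuals.
#'
#' Infeasible grid points (negative `p4`, non-positive `c5`) are kept in the
#' output and flagged, never dropped.
#'
#' @param p5,c5 Numeric vectors; the full cross-grid is evaluated.
#' @param N Total population size.
#' @param p3,c3,c4 Fixed parameters.
#' @param p45 Total contribution of classes 4 and 5 (so `p4 = p45 - p5`).
#' @param n_juvenile Number of juvenile classes.
#' @return A tibble of class `salmon_ces_surface` with columns
#'   `p4, p5, c5, Ne, feasible`.
#' @export
ces_surface <- function(p5, c5, N = 1000, p3 = 0.1, c3 = 0.05, c4 = 0.1,
                        p45 = 1 - p3, n_juvenile = 2) {
  grid <- tidyr::expand_grid(p5 = p5, c5 = c5)
  res <- purrr::pmap(grid, function(p5, c5) {
    p4 <- p45 - p5
    ok <- p4 >= 0 && p5 >= 0 && c5 > 0
    Ne <- NA_real_
    if (ok) {
      lh <- life_history(p = c(0, 0, p3, p4, p5), c = c(0, 0, c3, c4, c5),
                         N = N, n_juvenile = n_juvenile)
      ok <- length(validate_life_history(lh)) == 0
      if (ok) Ne <- ces(lh)
    }
    tibble::tibble(p4 = p4, p5 = p5, c5 = c5, Ne = Ne, feasible = ok)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("salmon_ces_surface", class(out))
  attr(out, "fixed") <- list(N = N, p3 = p3, c3 = c3, c4 = c4, p45 = p45)
  out
}

#' Mean absorption time of the exact finite-N chain
#'
#' Independent finite-`N` oracle for the limit theory: solves
#' \eqn{(I - T)\,t = 1} on the transient block `T` of `Pi_N` and averages
#' over the initial distribution. For an aperiodic life history this equals
#' \eqn{N_e\, g} years up to an O(1) entrance transient. The solve is
#' restricted to states reachable from the support of the initial
#' distribution; if any reachable state cannot reach coalescence (periodic
#' life histories put out-of-phase pairs in closed brood lines), the mean is
#' infinite and `Inf` is returned with a warning.
#'
#' @param lh A [life_history()].
#' @param N Population size.
#' @param init `"stationary"` (\eqn{\pi \otimes \pi}), `"uniform-sample"`
#'   (two distinct individuals uniform in the population, weights
#'   \eqn{N_i N_j} off-diagonal and \eqn{N_i(N_i - 1)} on it), or an integer
#'   pair `c(i, j)`.
#' @return Expected years to coalescence.
#' @export
mean_absorption_time <- function(lh, N = lh$N, init = "stationary") {
  chain <- two_lineage_chain(lh, N)
  k <- lh$k
  nt <- k^2
  w <- init_distribution(lh, init)
  Tm <- chain$Pi_N[seq_len(nt), seq_len(nt), drop = FALSE]
  # restrict to states reachable from the support of w
  R <- Tm > 0
  reach <- w > 0
  repeat {
    new <- reach | (as.vector(reach %*% R) > 0)
    if (identical(new, reach)) break
    reach <- new
  }
  idx <- which(reach)
  Tr <- Tm[idx, idx, drop = FALSE]
  # states that can never be absorbed have row sums of exactly 1 forever
  absorb_prob <- 1 - rowSums(Tr)
  if (max(absorb_prob) == 0 ||
      inherits(try(tt <- solve(diag(length(idx)) - Tr, rep(1, length(idx))),
                   silent = TRUE), "try-error")) {
    warning("coalescence unreachable from part of the initial distribution; ",
            "mean absorption time is infinite")
    return(Inf)
  }
  sum(w[idx] * tt) / sum(w[idx])
}

# initial distribution over the k^2 transient pair states
init_distribution <- function(lh, init) {
  k <- lh$k
  if (is.numeric(init) && length(init) == 2) {
    w <- numeric(k^2)
    w[pair_index(init[1], init[2], k)] <- 1
    return(w)
  }
  if (identical(init, "stationary")) {
    pi1 <- stationary_ages(build_xi(lh))
    return(as.vector(t(outer(pi1, pi1))))
  }
  if (identical(init, "uniform-sample")) {
    Ni <- age_classes(lh)
    W <- outer(Ni, Ni)
    diag(W) <- Ni * (Ni - 1)
    W[W < 0] <- 0
    return(as.vector(t(W / sum(W))))
  }
  stop("unknown init: ", deparse(init))
}
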