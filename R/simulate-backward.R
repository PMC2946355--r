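#' Backward-time simulation of a pair of lineages
#'
#' Monte-Carlo engine for the exact finite-`N` two-lineage chain of
#' [two_lineage_chain()]: each replicate walks the chain, year by year, from
#' the initial age-class pair until absorption in the coalesced state, and
#' records the number of years taken. Deterministic stretches (both lineages
#' aging backward) are skipped in blocks, and all replicates advance
#' together through vectorised event steps, so runtime scales with the
#' number of class-1 event years, not with raw years.
#'
#' Coalescence is only reachable when both lineages occupy the first age
#' class in the same year; with a single reproductive age the chain is
#' periodic and out-of-phase pairs sit in closed brood lines that never
#' coalesce, in which case an informative error is raised (choose an
#' in-phase `init` such as `c(1, 1)` to study that case).
#'
#' @param lh A [life_history()].
#' @param N Population size (must allow `D_m >= 1` for reproductive
#'   classes).
#' @param reps Number of replicates.
#' @param seed Integer seed; runs are reproducible and the global RNG state
#'   is left untouched.
#' @param init `"stationary"`, `"uniform-sample"`, or an age-class pair
#'   `c(i, j)`; see [mean_absorption_time()].
#' @param max_years Safety cap per replicate; exceeding it aborts (it should
#'   only trigger on pathological inputs).
#' @return A `coalescence_sample` object; `tidy()` gives per-replicate
#'   times, `glance()` the mean, standard error and the theoretical
#'   \eqn{N_e g} mean.
#' @export
simulate_pair_backward <- function(lh, N = lh$N, reps, seed,
                                   init = "stationary",
                                   max_years = Inf) {
  assert_valid(lh)
  if (N < 2) stop("N must be at least 2 to sample two distinct lineages")
  stopifnot(reps >= 1)
  sp <- size_process(x = 1, q = 1, baseline_N = N)
  times <- walk_pair(lh, sp, reps, seed, init, max_years)
  new_coalescence_sample(times, lh, N, seed, init,
                         theory_years = ces(lh) * generation_length(lh),
                         fluctuating = FALSE)
}

#' Backward-time simulation under fast i.i.d. size fluctuations
#'
#' Same walk as [simulate_pair_backward()], except that in every year where
#' both lineages are in the first age class the coalescence probability uses
#' that year's population size \eqn{N x_t}, with the multiplier drawn i.i.d.
#' from the [size_process()]. Since the yearly sizes are independent and
#' only matter in coalescence-capable years, drawing the multiplier at event
#' years only is equivalent in law to drawing it every year. The mean
#' absorption time follows the harmonic-mean theory of [longterm_ces()].
#'
#' @param lh A [life_history()].
#' @param sp A [size_process()].
#' @param reps,seed,init,max_years As in [simulate_pair_backward()].
#' @return A `coalescence_sample` whose `theory_years` is
#'   `longterm_ces(lh, sp) * generation_length(lh)`.
#' @export
simulate_fluctuating_pair <- function(lh, sp, reps, seed,
                                      init = "stationary",
                                      max_years = Inf) {
  assert_valid(lh)
  stopifnot(inherits(sp, "size_process"), reps >= 1)
  Dmin <- min(sp$x) * sp$baseline_N * lh$c[lh$p > 0]
  if (any(round(Dmin) < 1))
    stop("baseline_N * min(x) leaves a reproductive class with no deaths")
  times <- walk_pair(lh, sp, reps, seed, init, max_years)
  new_coalescence_sample(times, lh, sp$baseline_N, seed, init,
                         theory_years = longterm_ces(lh, sp) *
                           generation_length(lh),
                         fluctuating = TRUE)
}

# vectorised walk of the pair chain; sp degenerate (single atom x = 1)
# reproduces the constant-size chain exactly
walk_pair <- function(lh, sp, reps, seed, init, max_years) {
  k <- lh$k
  p <- lh$p
  natom <- length(sp$x)
  # per-atom 26-outcome distribution from state (1,1):
  # columns 1..k^2 are destination pairs (m,l), column k^2+1 is coalescence
  W <- matrix(0, natom, k^2 + 1L)
  for (a in seq_len(natom)) {
    D <- pmax(1, round(lh$c * sp$baseline_N * sp$x[a]))
    lam <- sum(p[p > 0]^2 / D[p > 0])
    w <- as.vector(t(outer(p, p)))
    for (m in which(p > 0)) w[pair_index(m, m, k)] <- p[m]^2 * (1 - 1 / D[m])
    W[a, ] <- c(w, lam)
  }

  withr::with_seed(seed, {
    w0 <- init_distribution(lh, init)
    # refuse initial states from which coalescence is unreachable
    if (is.infinite(suppressWarnings(
      mean_absorption_time(lh, sp$baseline_N, init))))
      stop("coalescence is unreachable from part of the initial ",
           "distribution (periodic life history out-of-phase states); ",
           "choose an in-phase init such as c(1, 1)")
    st <- sample.int(k^2, reps, TRUE, prob = w0)
    i <- (st - 1L) %/% k + 1L
    j <- (st - 1L) %% k + 1L
    t <- numeric(reps)
    out <- numeric(reps)
    id <- seq_len(reps)

    while (length(id)) {
      d <- pmin(i, j) - 1L
      t <- t + d
      i <- i - d
      j <- j - d
      m11 <- i == 1L & j == 1L
      mi <- i == 1L & !m11
      mj <- j == 1L & !m11
      n11 <- sum(m11)
      if (n11) {
        atom <- if (natom == 1) rep(1L, n11)
                else sample.int(natom, n11, TRUE, prob = sp$q)
        o <- integer(n11)
        for (a in unique(atom)) {
          sel <- atom == a
          o[sel] <- sample.int(k^2 + 1L, sum(sel), TRUE, prob = W[a, ])
        }
        t[m11] <- t[m11] + 1
        ab <- o == k^2 + 1L
        o[ab] <- 1L  # placeholder; rows are removed below
        i[m11] <- (o - 1L) %/% k + 1L
        j[m11] <- (o - 1L) %% k + 1L
        if (any(ab)) {
          done <- which(m11)[ab]
          out[id[done]] <- t[done]
          id <- id[-done]
          i <- i[-done]
          j <- j[-done]
          t <- t[-done]
          if (!length(id)) break
          mi <- mi[-done]
          mj <- mj[-done]
        }
      }
      ni <- sum(mi)
      nj <- sum(mj)
      if (ni) {
        i[mi] <- sample.int(k, ni, TRUE, prob = p)
        j[mi] <- j[mi] - 1L
        t[mi] <- t[mi] + 1
      }
      if (nj) {
        j[mj] <- sample.int(k, nj, TRUE, prob = p)
        i[mj] <- i[mj] - 1L
        t[mj] <- t[mj] + 1
      }
      if (min(t) > max_years)
        stop("max_years exceeded before absorption")
    }
    out
  })
}

#' Backward-time simulation of n lineages
#'
#' Generalises the pair walk to a small sample of `n` lineages: lineages in
#' the first age class in the same year independently choose a parental
#' class (with probabilities `p`) and then a parent uniformly among that
#' year's `D_m` spawners; lineages choosing the same parent merge. Multiple
#' mergers (three or more lineages on one parent, or two simultaneous pair
#' mergers) are possible at finite `N`, are counted, and vanish as `N`
#' grows.
#'
#' The sample size must be small relative to `N`
#' (`n_lineages <= 0.01 * N`), matching the regime in which the limit
#' process is the standard n-coalescent.
#'
#' @param lh A [life_history()].
#' @param N Population size.
#' @param n_lineages Sample size `n`.
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @param init `"stationary"` (each lineage i.i.d. from the lineage
#'   stationary ages) or `"uniform-sample"` (n distinct individuals uniform
#'   in the population).
#' @return A tibble of class `coalescence_sample_n`: one row per merge event
#'   with `replicate`, `time_years`, `group_size` (number of lineages
#'   merging into one parent). The attribute `n_multiple` counts replicates
#'   containing any merger with `group_size > 2` or more than one merger in
#'   a single year.
#' @export
simulate_n_backward <- function(lh, N = lh$N, n_lineages, reps, seed,
                                init = "stationary") {
  assert_valid(lh)
  stopifnot(reps >= 1, n_lineages >= 1)
  if (n_lineages > 0.01 * N)
    stop("n_lineages must be at most 1% of N (small-sample regime)")
  k <- lh$k
  p <- lh$p
  repro <- which(p > 0)
  D <- pmax(1, round(lh$c * N))
  if (any(round(lh$c[repro] * N) < 1))
    stop("death count D_m < 1 for a reproductive class at this N")
  Ni <- age_classes(lh)
  pi1 <- stationary_ages(build_xi(lh))

  cpr <- cumsum(p[repro]) / sum(p[repro])
  withr::with_seed(seed, {
    rep_id <- vector("list", reps)
    mt_all <- vector("list", reps)
    ms_all <- vector("list", reps)
    multi <- logical(reps)
    for (r in seq_len(reps)) {
      ages <- switch(init,
        "stationary" = sample.int(k, n_lineages, TRUE, prob = pi1),
        "uniform-sample" = draw_distinct_classes(Ni, n_lineages),
        stop("unknown init: ", deparse(init)))
      t <- 0
      mt <- numeric(0)
      ms <- integer(0)
      while (length(ages) > 1) {
        d <- min(ages) - 1L
        t <- t + d + 1
        ages <- ages - d
        at1 <- ages == 1L
        n1 <- sum(at1)
        ages <- ages - 1L
        if (n1) {
          cls <- repro[findInterval(stats::runif(n1), cpr) + 1L]
          par <- ceiling(stats::runif(n1) * D[cls])
          key <- cls * (N + 1) + par
          first <- !duplicated(key)
          if (any(!first)) {
            sizes <- tabulate(match(key, unique(key)))
            merged <- sizes[sizes > 1]
            mt <- c(mt, rep(t, length(merged)))
            ms <- c(ms, merged)
            if (any(merged > 2) || length(merged) > 1) multi[r] <- TRUE
          }
          ages[at1] <- cls
          keep <- rep(TRUE, length(ages))
          keep[which(at1)[!first]] <- FALSE
          ages <- ages[keep]
        }
      }
      if (length(mt)) {
        rep_id[[r]] <- rep.int(r, length(mt))
        mt_all[[r]] <- mt
        ms_all[[r]] <- ms
      }
    }
    out <- tibble::tibble(replicate = unlist(rep_id) %||% integer(0),
                          time_years = unlist(mt_all) %||% numeric(0),
                          group_size = as.integer(unlist(ms_all) %||%
                                                    integer(0)))
    out <- dplyr::arrange(out, .data$replicate, .data$time_years)
    class(out) <- c("coalescence_sample_n", class(out))
    attr(out, "n_multiple") <- sum(multi)
    attr(out, "settings") <- list(lh = lh, N = N, n_lineages = n_lineages,
                                  reps = reps, seed = seed, init = init)
    out
  })
}

# draw n distinct individuals uniformly from the population and return
# their age classes (multivariate hypergeometric on rounded class sizes)
draw_distinct_classes <- function(Ni, n) {
  sizes <- round(Ni)
  pool <- rep.int(seq_along(sizes), sizes)
  pool[sample.int(length(pool), n)]
}

new_coalescence_sample <- function(times, lh, N, seed, init, theory_years,
                                   fluctuating) {
  structure(
    list(times_years = times, lh = lh, N = N, seed = seed, init = init,
         theory_years = theory_years, fluctuating = fluctuating),
    class = "coalescence_sample")
}

#' @export
print.coalescence_sample <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<coalescence_sample> %d replicates, N = %g%s\n  mean %.1f years (se %.2f), theory %.1f, z = %.2f\n",
    g$n, x$N, if (x$fluctuating) " (fluctuating size)" else "",
    g$mean_years, g$se_years, g$theory_years, g$z))
  invisible(x)
}

#' Per-replicate coalescence times
#'
#' @param x A `coalescence_sample`.
#' @param ... Unused.
#' @return A tibble with `replicate` and `time_years`.
#' @method tidy coalescence_sample
#' @export
tidy.coalescence_sample <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$times_years),
                 time_years = x$times_years)
}

#' Summary of a coalescence sample against theory
#'
#' @param x A `coalescence_sample`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `mean_years`, `sd_years`, `se_years`,
#'   the theoretical mean `theory_years` (\eqn{N_e g}, or its harmonic-mean
#'   analogue for fluctuating runs) and the z-score of the discrepancy.
#' @method glance coalescence_sample
#' @export
glance.coalescence_sample <- function(x, ...) {
  m <- mean(x$times_years)
  s <- stats::sd(x$times_years)
  se <- s / sqrt(length(x$times_years))
  tibble::tibble(n = length(x$times_years), mean_years = m, sd_years = s,
                 se_years = se, theory_years = x$theory_years,
                 z = (m - x$theory_years) / se)
}
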