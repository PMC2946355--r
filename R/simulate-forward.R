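#' Forward-time Wright-Fisher simulation with pedigree
#'
#' Independent forward-time oracle for the backward theory. Each year, every
#' age class `i` loses its `D_i` dying individuals — chosen uniformly at
#' random within the class; in the reproductive classes the dying
#' individuals are the spawners — and the survivors age by one class. The
#' `N_1` newborns each draw a parental class `m` (multinomially with
#' probabilities `p` by default, or by fixed largest-remainder quotas) and
#' then a parent uniformly among that year's `D_m` spawners, so any one
#' spawner of class `m` is equally likely to parent each of the class-`m`
#' newborns. The full parental pedigree of the first-age-class cohorts is
#' recorded.
#'
#' The life history must be strict (`sum(i * c_i) = 1`) with integer
#' age-class sizes at this `N`, so the bookkeeping `sum(N_i) = N` holds
#' exactly every year; any violation during the run is a hard failure.
#'
#' @param lh A strict [life_history()].
#' @param N Population size; `c * N` and the class sizes must be integers.
#' @param years Number of years to evolve.
#' @param seed Integer seed.
#' @param quota `"multinomial"` (default, Wright-Fisher offspring numbers)
#'   or `"largest-remainder"` (fixed integer class quotas `p_m N_1`).
#' @return An object of class `salmon_pedigree` holding the parent pointer
#'   and birth year of every newborn, per-year per-class offspring totals,
#'   the per-year probability that two random newborns share a parent, and
#'   the final cohort. Use [pedigree_tmrca()] to trace pair coalescence
#'   times and `glance()` for the pair-coalescence summary.
#' @export
simulate_forward <- function(lh, N = lh$N, years, seed,
                             quota = c("multinomial", "largest-remainder")) {
  quota <- match.arg(quota)
  assert_valid(lh, strict = TRUE)
  stopifnot(years >= 1)
  k <- lh$k
  Ni <- age_classes(lh) * N / lh$N
  D <- deaths(lh) * N / lh$N
  if (max(abs(Ni - round(Ni))) > 1e-8 || max(abs(D - round(D))) > 1e-8)
    stop("age-class sizes are not integers at this N; pick N so that c * N ",
         "is integral")
  Ni <- as.integer(round(Ni))
  D <- as.integer(round(D))
  N1 <- Ni[1]
  repro <- which(lh$p > 0)
  p_repro <- lh$p[repro]
  quotas <- if (quota == "largest-remainder")
    largest_remainder(p_repro * N1) else NULL

  n_ids <- sum(Ni) + years * N1
  parent <- integer(n_ids)          # 0 = founder
  birth_year <- integer(n_ids)
  # founders: class i individuals were born i - 1 years ago
  classes <- vector("list", k)
  nxt <- 1L
  for (i in seq_len(k)) {
    ids <- seq.int(nxt, nxt + Ni[i] - 1L)
    classes[[i]] <- ids
    birth_year[ids] <- 1L - i
    nxt <- nxt + Ni[i]
  }

  off_by_class <- matrix(0L, years, k)
  p_share <- numeric(years)

  withr::with_seed(seed, {
    for (yr in seq_len(years)) {
      # choose the dying individuals (spawners, in reproductive classes)
      spawners <- vector("list", k)
      survivors <- vector("list", k)
      for (i in seq_len(k)) {
        if (D[i] == 0L) {
          spawners[[i]] <- integer(0)
          survivors[[i]] <- classes[[i]]
        } else if (D[i] == Ni[i]) {
          spawners[[i]] <- classes[[i]]
          survivors[[i]] <- integer(0)
        } else {
          die <- sample.int(Ni[i], D[i])
          spawners[[i]] <- classes[[i]][die]
          survivors[[i]] <- classes[[i]][-die]
        }
      }
      # newborns: parental class, then parent uniform among its spawners
      cls_draw <- if (is.null(quotas))
        repro[sample.int(length(repro), N1, TRUE, prob = p_repro)]
      else rep.int(repro, quotas)
      ids <- seq.int(nxt, nxt + N1 - 1L)
      nxt <- nxt + N1
      birth_year[ids] <- yr
      counts_sq <- 0
      for (m in repro) {
        sel <- cls_draw == m
        nm <- sum(sel)
        off_by_class[yr, m] <- nm
        if (nm) {
          par_idx <- sample.int(D[m], nm, TRUE)
          parent[ids[sel]] <- spawners[[m]][par_idx]
          cnt <- tabulate(par_idx, nbins = D[m])
          counts_sq <- counts_sq + sum(cnt * (cnt - 1))
        }
      }
      # P(two random newborns share a parent), exact for this year
      p_share[yr] <- counts_sq / (N1 * (N1 - 1))
      # aging
      for (i in k:2) classes[[i]] <- survivors[[i - 1L]]
      classes[[1L]] <- ids
      if (sum(lengths(classes)) != N)
        stop("bookkeeping failure: total size changed at year ", yr)
    }
  })

  structure(
    list(parent = parent, birth_year = birth_year,
         final_cohort = classes[[1L]], off_by_class = off_by_class,
         p_share = p_share, lh = lh, N = N, N1 = N1, D = D,
         years = years, seed = seed, quota = quota),
    class = "salmon_pedigree")
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  need <- round(sum(x)) - sum(fl)
  if (need > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(need)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

#' @export
print.salmon_pedigree <- function(x, ...) {
  cat(sprintf(
    "<salmon_pedigree> N = %d, %d years, %d newborns/year (%s quotas)\n",
    x$N, x$years, x$N1, x$quota))
  cat(sprintf("  mean P(shared parent) = %.4g (theory %.4g)\n",
              mean(x$p_share), pair_coalescence_prob(x$lh, x$N)))
  invisible(x)
}

#' One-step pair coalescence probability
#'
#' The probability that two distinct random newborns of the same year share
#' a parent, \eqn{\sum_m p_m^2 / D_m}: this is also the per-visit
#' coalescence probability of the backward chain from state (1,1).
#'
#' @param lh A [life_history()].
#' @param N Population size.
#' @return A probability.
#' @export
pair_coalescence_prob <- function(lh, N = lh$N) {
  repro <- which(lh$p > 0)
  D <- pmax(1, round(lh$c * N))
  sum(lh$p[repro]^2 / D[repro])
}

#' Per-year pedigree statistics
#'
#' @param x A [simulate_forward()] pedigree.
#' @param ... Unused.
#' @return A tibble with one row per simulated year: newborn counts per
#'   reproductive class and the exact within-year probability that two
#'   random newborns share a parent.
#' @method tidy salmon_pedigree
#' @export
tidy.salmon_pedigree <- function(x, ...) {
  repro <- which(x$lh$p > 0)
  off <- tibble::as_tibble(x$off_by_class[, repro, drop = FALSE],
                           .name_repair = ~ paste0("offspring_age", repro))
  dplyr::bind_cols(tibble::tibble(year = seq_len(x$years)), off,
                   tibble::tibble(p_shared_parent = x$p_share))
}

#' Forward-simulation summary against theory
#'
#' @param x A [simulate_forward()] pedigree.
#' @param ... Unused.
#' @return A one-row tibble: empirical mean and standard error of the
#'   yearly shared-parent probability, its theoretical value
#'   \eqn{\sum p_m^2 / D_m}, and the z-score.
#' @method glance salmon_pedigree
#' @export
glance.salmon_pedigree <- function(x, ...) {
  m <- mean(x$p_share)
  se <- stats::sd(x$p_share) / sqrt(x$years)
  th <- pair_coalescence_prob(x$lh, x$N)
  tibble::tibble(years = x$years, p_share_mean = m, p_share_se = se,
                 p_share_theory = th, z = (m - th) / se)
}

#' Pedigree-based pair TMRCA
#'
#' Samples random distinct pairs from the final newborn cohort of a forward
#' simulation and traces both parental lines back until they first pass
#' through the same ancestor. Because spawning is semelparous, all offspring
#' of any individual are born in the same year, so two lineages can only
#' merge at a shared parent of same-year children; the time to the most
#' recent common ancestor is then `sample_year - child_year + 1` years,
#' which matches the backward chain's absorption clock (siblings have
#' TMRCA 1).
#'
#' @param ped A [simulate_forward()] pedigree.
#' @param n_pairs Number of random pairs to trace.
#' @param seed Integer seed for pair sampling.
#' @return A tibble with `pair`, `tmrca_years` (`NA` when the pair does not
#'   coalesce within the simulated span).
#' @export
pedigree_tmrca <- function(ped, n_pairs, seed) {
  stopifnot(inherits(ped, "salmon_pedigree"), n_pairs >= 1)
  cohort <- ped$final_cohort
  if (length(cohort) < 2) stop("final cohort too small")
  withr::with_seed(seed, {
    res <- numeric(n_pairs)
    for (q in seq_len(n_pairs)) {
      ab <- cohort[sample.int(length(cohort), 2)]
      res[q] <- trace_pair(ped$parent, ped$birth_year, ab[1], ab[2],
                           ped$years)
    }
    tibble::tibble(pair = seq_len(n_pairs), tmrca_years = res)
  })
}

# climb two parent chains until a common individual; NA if a founder is
# reached before the chains meet. Birth years strictly decrease along a
# chain, so stepping the younger side (both on ties) visits the first
# common node. Semelparity puts all children of one spawner in the same
# birth year, so the child years recorded on both sides agree at the merge.
trace_pair <- function(parent, birth_year, a, b, sample_year) {
  ca <- NA_integer_
  while (a != b) {
    ya <- birth_year[a]
    yb <- birth_year[b]
    if (ya >= yb) {
      if (parent[a] == 0L) return(NA_real_)
      ca <- ya
      a <- parent[a]
    }
    if (yb >= ya && a != b) {
      if (parent[b] == 0L) return(NA_real_)
      ca <- yb
      b <- parent[b]
    }
  }
  # the lineages are one individual from the year before their shared
  # children were born: TMRCA matches the backward chain's clock
  sample_year - ca + 1
}
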