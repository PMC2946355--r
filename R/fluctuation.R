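#' Fast i.i.d. population-size process
#'
#' Describes yearly total population sizes \eqn{N x_j}, where the multiplier
#' takes finitely many values `x` with probabilities `q`, independently
#' across years. Fluctuations on this fast timescale leave the age-structure
#' fractions `p` and `c` untouched: every age class grows and shrinks in
#' proportion to the total.
#'
#' @param x Positive size multipliers (finitely many atoms).
#' @param q Atom probabilities, summing to 1.
#' @param baseline_N Reference size so the year-`t` population is
#'   `baseline_N * x[j]`.
#' @return An object of class `size_process`.
#' @export
size_process <- function(x, q, baseline_N) {
  stopifnot(is.numeric(x), is.numeric(q), length(x) == length(q),
            length(x) >= 1, all(x > 0), all(q >= 0), baseline_N > 0)
  if (abs(sum(q) - 1) > 1e-12) stop("atom probabilities must sum to 1")
  structure(list(x = as.numeric(x), q = as.numeric(q),
                 baseline_N = as.numeric(baseline_N)),
            class = "size_process")
}

#' @export
print.size_process <- function(x, ...) {
  cat(sprintf("<size_process> baseline N = %g, %d atoms\n",
              x$baseline_N, length(x$x)))
  print(tibble::tibble(x = x$x, q = x$q))
  invisible(x)
}

#' Harmonic mean of the yearly sizes of a size process
#'
#' \eqn{H = N / \sum_j q_j / x_j}: coalescence probabilities scale as the
#' reciprocal of the yearly size, so the effective long-run size is the
#' harmonic mean.
#'
#' @param sp A [size_process()].
#' @return Harmonic-mean population size.
#' @export
harmonic_size <- function(sp) {
  sp$baseline_N / sum(sp$q / sp$x)
}

#' Long-term CES under fast size fluctuations
#'
#' When the population size fluctuates i.i.d. on the yearly timescale while
#' coalescence happens on the timescale of `N` generations, the per-visit
#' coalescence probability averages over the size distribution and the
#' long-term coalescent effective size becomes
#' \deqn{N_e = \frac{g\, H}{\sum_m p_m^2 / c_m}, \qquad
#'       H = \frac{N}{\sum_j q_j / x_j},}
#' i.e. the constant-size [ces()] evaluated at the harmonic mean of the
#' yearly sizes. A degenerate process (`x = 1`) recovers [ces()] exactly,
#' and by the AM-HM inequality any non-degenerate fluctuation lowers the
#' long-term effective size below the CES at the arithmetic-mean size.
#'
#' @param lh A [life_history()].
#' @param sp A [size_process()].
#' @return Long-term effective size in individuals.
#' @export
longterm_ces <- function(lh, sp) {
  assert_valid(lh)
  stopifnot(inherits(sp, "size_process"))
  repro <- which(lh$p > 0)
  generation_length(lh) * harmonic_size(sp) /
    sum(lh$p[repro]^2 / lh$c[repro])
}

#' Harmonic-mean breeder estimator of effective size
#'
#' Classical multi-year estimator derived under the assumption that each
#' year's spawners contribute equally to the next generation regardless of
#' their abundance: generation length times the harmonic mean of the yearly
#' effective numbers of breeders.
#'
#' @param nb_series Positive vector of yearly breeder counts.
#' @param g Generation length in years.
#' @return Effective-size estimate.
#' @export
waples_harmonic <- function(nb_series, g) {
  if (any(nb_series <= 0)) stop("breeder series must be positive")
  g * length(nb_series) / sum(1 / nb_series)
}

#' Arithmetic-mean breeder estimator of effective size
#'
#' Counterpart of [waples_harmonic()] derived under the assumption that each
#' year's spawners contribute in proportion to their abundance: generation
#' length times the arithmetic mean of the yearly breeder counts. By the
#' AM-HM inequality this never falls below the harmonic estimate.
#'
#' @inheritParams waples_harmonic
#' @return Effective-size estimate.
#' @export
waples_arithmetic <- function(nb_series, g) {
  if (any(nb_series <= 0)) stop("breeder series must be positive")
  g * mean(nb_series)
}

#' Simulate a yearly population-size series
#'
#' Draws i.i.d. uniform integer sizes on `[low, high]` for a span of years —
#' the standard stand-in for strongly fluctuating salmon returns.
#'
#' @param low,high Integer bounds, `0 < low < high`.
#' @param years Series length.
#' @param seed Integer seed.
#' @return A tibble with columns `year` and `N`.
#' @export
simulate_series <- function(low, high, years, seed) {
  stopifnot(low > 0, years >= 1)
  if (low >= high) stop("low must be strictly less than high")
  withr::with_seed(seed, {
    tibble::tibble(year = seq_len(years),
                   N = sample.int(high - low + 1L, years, TRUE) + low - 1L)
  })
}

#' Per-generation-block comparison of effective-size estimates
#'
#' Splits a yearly size series into consecutive blocks of `block_years`
#' years and, per block, computes the yearly breeder counts
#' \eqn{N_b(t) = (\sum_{i > n_j} c_i) N(t)} and three effective-size
#' estimates: the arithmetic (`estimate_A`, [waples_arithmetic()]) and
#' harmonic (`estimate_H`, [waples_harmonic()]) breeder estimators, and the
#' coalescent estimate `estimate_C`, the long-term CES of [longterm_ces()]
#' applied to the block's empirical size distribution. A trailing partial
#' block is dropped and reported via the `dropped_years` attribute.
#'
#' For any non-constant series, `estimate_A > estimate_H` (AM-HM), and for
#' life histories in which per-breeder contribution variance makes the CES
#' fall below the breeder count, `estimate_C` tracks and slightly undercuts
#' `estimate_H` — the coalescent estimate behaves like a harmonic-mean
#' method.
#'
#' @param series A data frame with columns `year` and `N` (as produced by
#'   [simulate_series()]), or a bare numeric vector of yearly sizes.
#' @param lh A [life_history()].
#' @param block_years Years per block; defaults to the rounded generation
#'   length.
#' @param blocks Optional cap on the number of blocks (explicit truncation
#'   of the series, e.g. 12 blocks of a 52-year series uses the first 48
#'   years).
#' @return A tibble of class `salmon_estimates`, one row per block:
#'   `block`, `start_year`, `end_year`, `Nb_arith`, `Nb_harm`,
#'   `estimate_A`, `estimate_H`, `estimate_C`.
#' @export
compare_estimates <- function(series, lh, block_years = NULL, blocks = NULL) {
  assert_valid(lh)
  if (is.data.frame(series)) {
    stopifnot(all(c("year", "N") %in% names(series)))
    Nt <- series$N
  } else {
    Nt <- as.numeric(series)
  }
  if (is.null(block_years)) block_years <- round(generation_length(lh))
  stopifnot(block_years >= 1, length(Nt) >= block_years)
  n_blocks <- length(Nt) %/% block_years
  if (!is.null(blocks)) {
    stopifnot(blocks >= 1)
    if (blocks > n_blocks)
      stop("requested more blocks than the series provides")
    n_blocks <- blocks
  }
  dropped <- length(Nt) - n_blocks * block_years
  g <- generation_length(lh)
  repro <- (lh$n_juvenile + 1):lh$k
  cb <- sum(lh$c[repro])
  sum_p2c <- sum(lh$p[lh$p > 0]^2 / lh$c[lh$p > 0])

  rows <- purrr::map(seq_len(n_blocks), function(b) {
    sel <- ((b - 1) * block_years + 1):(b * block_years)
    Nblock <- Nt[sel]
    nb <- cb * Nblock
    harmN <- length(Nblock) / sum(1 / Nblock)
    tibble::tibble(
      block = b,
      start_year = sel[1], end_year = sel[length(sel)],
      Nb_arith = mean(nb), Nb_harm = length(nb) / sum(1 / nb),
      estimate_A = waples_arithmetic(nb, g),
      estimate_H = waples_harmonic(nb, g),
      estimate_C = g * harmN / sum_p2c)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("salmon_estimates", class(out))
  attr(out, "dropped_years") <- dropped
  attr(out, "settings") <- list(lh = lh, block_years = block_years,
                                contribution_assumption = c(
                                  estimate_A = "yearly contribution proportional to breeder count",
                                  estimate_H = "equal yearly contribution",
                                  estimate_C = "coalescent, harmonic in yearly size"))
  out
}
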