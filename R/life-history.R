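#' Define a semelparous life history
#'
#' A life history bundles the demographic parameters of the constant-size
#' semelparous model: `k` age classes of which the first `n_juvenile` are
#' non-reproducing, the reproductive-contribution fractions `p` (the
#' proportion of each year's newborns parented by each age class), the yearly
#' death fractions `c` (individuals dying in each age class per year, as a
#' fraction of the total size `N`), and the total size `N` itself.
#'
#' Under the constant-structure bookkeeping the derived age-class sizes are
#' \eqn{N_i = N \sum_{j \ge i} c_j} and the yearly death counts are
#' \eqn{D_i = c_i N}. Semelparity means the parents of every newborn are
#' among the dying (spawning) adults of the previous year.
#'
#' Strict validity additionally demands \eqn{\sum_i i\, c_i = 1}, which is
#' equivalent to \eqn{\sum_i N_i = N}. The analytic operations
#' ([ces()], [mohle_limit()], [longterm_ces()]) only need `p`, `c` and `N`,
#' so non-strict mode is the default; the exact finite-population simulators
#' ([simulate_forward()]) need a strict, integer-valued life history.
#'
#' @param p Numeric vector of length `k`: reproductive contribution
#'   fractions, summing to 1, with `p[i] = 0` for juvenile classes.
#' @param c Numeric vector of length `k`: yearly death fractions
#'   \eqn{c_i = D_i / N}.
#' @param N Total population size (all age classes summed).
#' @param n_juvenile Number of initial non-reproducing age classes.
#' @param phi Optional proportion of first-age-class individuals,
#'   \eqn{N_1/N}. In a strict life history this equals `sum(c)` and is
#'   derived; supplying it stores it as metadata only (it enters no formula),
#'   which allows reproducing published parameter sets that quote `phi`
#'   alongside an incomplete death schedule.
#'
#' @return An object of class `salmon_lh`.
#' @seealso [validate_life_history()], [from_survival()],
#'   [generation_length()], [breeders()]
#' @examples
#' lh <- life_history(p = c(0, 0, 0.04, 0.25, 0.71),
#'                    c = c(0.02, 0, 0.01, 0.05, 0.15), N = 1000)
#' generation_length(lh)
#' ces(lh)
#' @export
life_history <- function(p, c, N, n_juvenile = 2, phi = NULL) {
  stopifnot(is.numeric(p), is.numeric(c), length(p) == length(c),
            length(p) >= 2, is.numeric(N), length(N) == 1, N > 0)
  k <- length(p)
  stopifnot(n_juvenile >= 0, n_juvenile < k)
  structure(
    list(k = k, n_juvenile = as.integer(n_juvenile),
         p = as.numeric(p), c = as.numeric(c), N = as.numeric(N),
         phi = if (is.null(phi)) NULL else as.numeric(phi)),
    class = "salmon_lh")
}

#' Validate a life history
#'
#' Checks the structural invariants of a [life_history()] and returns every
#' violation found (an empty character vector means the object is valid).
#' The input is never modified.
#'
#' Non-strict invariants: `p` sums to 1 with non-negative entries and zero
#' juvenile entries; `c` entries are non-negative; every class that parents
#' newborns (`p[i] > 0`) has deaths (`c[i] > 0`), since parents are drawn
#' from the dying spawners; the derived `N_i` are positive. Strict mode
#' additionally requires \eqn{\sum_i i\,c_i = 1} (equivalently
#' \eqn{\sum N_i = N}), the consistency condition under which the yearly
#' inflow of newborns balances the deaths.
#'
#' @param lh A [life_history()].
#' @param strict Also check the \eqn{\sum_i i\,c_i = 1} bookkeeping identity.
#' @param tol Tolerance for the probability-sum check.
#' @param strict_tol Tolerance for the strict bookkeeping identity.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_life_history <- function(lh, strict = FALSE, tol = 1e-12,
                                  strict_tol = 1e-9) {
  stopifnot(inherits(lh, "salmon_lh"))
  v <- character()
  k <- lh$k
  if (any(lh$p < 0)) v <- c(v, "negative reproductive contribution p_i")
  if (abs(sum(lh$p) - 1) > tol)
    v <- c(v, sprintf("sum(p) = %.15g, must equal 1", sum(lh$p)))
  if (lh$n_juvenile > 0 && any(lh$p[seq_len(lh$n_juvenile)] != 0))
    v <- c(v, "juvenile age class with p_i > 0")
  if (any(lh$c < 0)) v <- c(v, "negative death fraction c_i")
  bad <- which(lh$p > 0 & lh$c <= 0)
  if (length(bad))
    v <- c(v, sprintf("reproductive class with zero deaths (age %s)",
                      paste(bad, collapse = ", ")))
  if (sum(lh$c) > 1 + tol)
    v <- c(v, "sum(c) > 1: first age class would exceed the population")
  Ni <- age_classes(lh)
  if (any(Ni <= 0)) v <- c(v, "non-positive derived age-class size N_i")
  if (strict) {
    s <- sum(seq_len(k) * lh$c)
    if (abs(s - 1) > strict_tol)
      v <- c(v, sprintf("sum(i * c_i) = %.9g, must equal 1 in strict mode", s))
  }
  v
}

assert_valid <- function(lh, strict = FALSE) {
  v <- validate_life_history(lh, strict = strict)
  if (length(v))
    stop("invalid life history:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  invisible(lh)
}

#' Build a life history from a fecundity/survival schedule
#'
#' Constructs the age-class sizes from an egg pool and age-specific survival
#' fractions `s(x)`: \eqn{N_1 = E\, s(1)} where `E` is the total egg pool
#' (`n_spawners * eggs_per_spawner`), and \eqn{N_i = N_{i-1} s(i)} for
#' \eqn{i \ge 2}. Deaths follow as \eqn{D_i = N_i - N_{i+1}} (everyone
#' reaching the last class dies there: \eqn{D_k = N_k}), and
#' \eqn{c_i = D_i / N} with \eqn{N = \sum_i N_i}. Eggs that never reach the
#' first age class are not counted in `N`.
#'
#' By default age-class counts are truncated toward zero to integers before
#' summing, matching a worked bookkeeping where the survival products are
#' exact integers; `rounding = "none"` keeps fractional sizes (useful for
#' purely analytic work with non-integer schedules).
#'
#' The reproductive contributions `p` are not determined by a survival
#' schedule. When not supplied they default to the spawner-frequency
#' assumption \eqn{p_i \propto D_i} over the reproductive classes, i.e. the
#' contribution of each age class equals its share of the dying spawners.
#'
#' @param n_spawners Number of spawning females.
#' @param eggs_per_spawner Eggs laid per spawner.
#' @param s Numeric vector of `k` age-specific survival fractions in (0, 1].
#' @param n_juvenile Number of juvenile (non-reproducing) classes.
#' @param p Optional explicit contribution vector overriding the default.
#' @param rounding `"truncate"` (integer counts, default) or `"none"`.
#' @return A [life_history()].
#' @examples
#' # the classic chinook bookkeeping: a 200,000-egg pool
#' lh <- from_survival(500, 400, s = c(0.05, 0.1, 0.8, 0.8, 0.8))
#' lh$N  # 12952
#' @export
from_survival <- function(n_spawners, eggs_per_spawner, s, n_juvenile = 2,
                          p = NULL, rounding = c("truncate", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(n_spawners > 0, eggs_per_spawner > 0,
            all(s > 0), all(s <= 1), length(s) >= 2)
  k <- length(s)
  eggs <- n_spawners * eggs_per_spawner
  Ni <- numeric(k)
  Ni[1] <- eggs * s[1]
  for (i in 2:k) Ni[i] <- Ni[i - 1] * s[i]
  if (rounding == "truncate") Ni <- trunc(Ni)
  if (Ni[1] < 1) stop("empty cohort: no survivors into the first age class")
  N <- sum(Ni)
  D <- c(Ni[-k] - Ni[-1], Ni[k])
  if (is.null(p)) {
    repro <- (n_juvenile + 1):k
    if (sum(D[repro]) <= 0)
      stop("no deaths in reproductive classes; supply p explicitly")
    p <- numeric(k)
    p[repro] <- D[repro] / sum(D[repro])
  }
  life_history(p = p, c = D / N, N = N, n_juvenile = n_juvenile)
}

#' Derived age-class sizes
#'
#' \eqn{N_i = N \sum_{j \ge i} c_j}: everyone now in class `i` will die in
#' some class `j >= i`, so the cumulative upper tail of the death schedule
#' gives the standing size of each class.
#'
#' @param lh A [life_history()].
#' @return Numeric vector of `k` age-class sizes (non-increasing in age).
#' @export
age_classes <- function(lh) {
  lh$N * rev(cumsum(rev(lh$c)))
}

#' Yearly death counts per age class
#'
#' @param lh A [life_history()].
#' @return Numeric vector \eqn{D_i = c_i N}.
#' @export
deaths <- function(lh) lh$c * lh$N

#' Generation length
#'
#' Mean age of the parents of a newborn, \eqn{g = \sum_i i\, p_i} years.
#' This is also the expected return time of a backward lineage to the first
#' age class, so the stationary occupancy of age class one is `1/g`
#' (see [stationary_ages()]).
#'
#' @param lh A [life_history()].
#' @return Years per generation, in `[n_juvenile + 1, k]`.
#' @export
generation_length <- function(lh) {
  sum(seq_len(lh$k) * lh$p)
}

#' Effective number of breeders
#'
#' The number of adults spawning (and dying) in a single year,
#' \eqn{N_b = N \sum_{i > n_j} c_i} where the sum runs over the
#' reproductive classes.
#'
#' @param lh A [life_history()].
#' @return Breeder count, in `(0, N]`.
#' @export
breeders <- function(lh) {
  repro <- (lh$n_juvenile + 1):lh$k
  lh$N * sum(lh$c[repro])
}

#' First-age-class proportion
#'
#' \eqn{\phi = N_1 / N}. For a life history with a complete death schedule
#' this equals `sum(c)` (each year's newborn inflow balances the deaths);
#' when a `phi` value was supplied at construction as metadata it is
#' returned as-is.
#'
#' @param lh A [life_history()].
#' @return A single proportion.
#' @export
phi_first_class <- function(lh) {
  if (!is.null(lh$phi)) lh$phi else sum(lh$c)
}

#' @export
print.salmon_lh <- function(x, ...) {
  cat(sprintf("<salmon_lh> k = %d (%d juvenile), N = %g\n",
              x$k, x$n_juvenile, x$N))
  cat("  p:", paste(signif(x$p, 4), collapse = " "), "\n")
  cat("  c:", paste(signif(x$c, 4), collapse = " "), "\n")
  cat(sprintf("  g = %.4g years, phi = %.4g\n",
              generation_length(x), phi_first_class(x)))
  invisible(x)
}

#' Tidy a life history into a per-age-class table
#'
#' @param x A [life_history()].
#' @param ... Unused.
#' @return A tibble with one row per age class: `age`, `p`, `c`, `N_i`,
#'   `D_i`, `juvenile`.
#' @method tidy salmon_lh
#' @export
tidy.salmon_lh <- function(x, ...) {
  tibble::tibble(
    age = seq_len(x$k),
    p = x$p,
    c = x$c,
    N_i = age_classes(x),
    D_i = deaths(x),
    juvenile = seq_len(x$k) <= x$n_juvenile)
}

#' One-row summary of a life history
#'
#' @param x A [life_history()].
#' @param ... Unused.
#' @return A tibble with `k`, `n_juvenile`, `N`, `g` (generation length),
#'   `phi`, `n_breeders` and the coalescent effective size `Ne`.
#' @method glance salmon_lh
#' @export
glance.salmon_lh <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_juvenile = x$n_juvenile, N = x$N,
    g = generation_length(x), phi = phi_first_class(x),
    n_breeders = breeders(x), Ne = ces(x))
}
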