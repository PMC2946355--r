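#' Write a life history to JSON
#'
#' Serialises the parameter bundle as a flat JSON object
#' `{k, n_juvenile, p, c, N, phi}` (`phi` only when carried as metadata).
#'
#' @param lh A [life_history()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_history <- function(lh, path) {
  stopifnot(inherits(lh, "salmon_lh"))
  obj <- list(k = lh$k, n_juvenile = lh$n_juvenile, p = lh$p, c = lh$c,
              N = lh$N)
  if (!is.null(lh$phi)) obj$phi <- lh$phi
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a life history from JSON
#'
#' Counterpart of [write_life_history()]. Unknown fields are rejected unless
#' `lax = TRUE`, so silent typos in hand-written parameter files
#' (`"n_juveniles"`, say) cannot slip through.
#'
#' @param path JSON file path.
#' @param lax Accept and ignore unknown fields.
#' @return A [life_history()].
#' @export
read_life_history <- function(path, lax = FALSE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("k", "n_juvenile", "p", "c", "N", "phi")
  extra <- setdiff(names(obj), known)
  if (length(extra) && !lax)
    stop("unknown fields in life-history file: ",
         paste(extra, collapse = ", "), " (use lax = TRUE to ignore)")
  miss <- setdiff(c("p", "c", "N"), names(obj))
  if (length(miss))
    stop("missing fields in life-history file: ", paste(miss, collapse = ", "))
  lh <- life_history(p = obj$p, c = obj$c, N = obj$N,
                     n_juvenile = obj$n_juvenile %||% 2,
                     phi = obj$phi)
  if (!is.null(obj$k) && obj$k != lh$k)
    stop("declared k does not match the length of p")
  lh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random valid life history
#'
#' Property-test fixture generator. Contributions `p` are Dirichlet over the
#' reproductive classes. In strict mode the death schedule is drawn so that
#' \eqn{\sum_i i\, c_i = 1} exactly: a positive weight per class, scaled by
#' the age-weighted total. In `balanced` mode the reproductive death
#' fractions are tied to the contributions so the offspring-per-breeder
#' ratios `p_m / c_m` differ by at most a factor ~1.5 across classes —
#' roughly equal reproductive variance per spawner, the regime typical of
#' published salmon parameter sets.
#'
#' @param seed Integer seed.
#' @param k Number of age classes.
#' @param n_juvenile Number of juvenile classes, `0 <= n_juvenile < k`.
#' @param mode `"strict"` (exact bookkeeping) or `"lax"`.
#' @param balanced Tie `c` to `p` as described.
#' @param N Total population size.
#' @return A [life_history()] passing [validate_life_history()] in the
#'   requested mode.
#' @export
generate_fixture <- function(seed, k = 5, n_juvenile = 2,
                             mode = c("strict", "lax"), balanced = FALSE,
                             N = 1e5) {
  mode <- match.arg(mode)
  stopifnot(k > n_juvenile, n_juvenile >= 0)
  withr::with_seed(seed, {
    repro <- (n_juvenile + 1):k
    pr <- stats::rgamma(length(repro), shape = 2)
    pr <- pr / sum(pr)
    p <- numeric(k)
    p[repro] <- pr
    if (balanced) {
      u <- stats::runif(length(repro), 1 / 1.2, 1.2)
      craw <- numeric(k)
      craw[repro] <- pr / u
      w <- stats::runif(1, 0.3, 0.9)  # age-weighted share of deaths in adults
      craw[repro] <- craw[repro] * w / sum(repro * craw[repro])
      if (n_juvenile > 0) {
        jw <- stats::rgamma(n_juvenile, shape = 2)
        craw[seq_len(n_juvenile)] <-
          jw * (1 - w) / sum(seq_len(n_juvenile) * jw)
      } else {
        craw[repro] <- craw[repro] / w
      }
      cc <- craw
    } else {
      craw <- c(stats::runif(n_juvenile, 0, 0.5),
                stats::runif(length(repro), 0.2, 1))
      cc <- craw / sum(seq_len(k) * craw)
    }
    if (mode == "lax") {
      # perturb away from the strict identity but keep feasibility
      cc <- cc * stats::runif(1, 0.5, 0.95)
    }
    life_history(p = p, c = cc, N = N, n_juvenile = n_juvenile)
  })
}

#' Write a CES surface or estimate table to CSV
#'
#' Plain RFC-4180 CSV with a header row; the column layout of
#' [ces_surface()] is `p4,p5,c5,Ne` (plus the feasibility flag) and of
#' [compare_estimates()] the per-block estimate columns.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
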