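# shared fixtures: the worked chinook schedule, the published chinook
# Results parameter set (with and without a strict juvenile completion),
# and a single-reproductive-age (periodic) life history

# survival cascade from a 200,000-egg pool; integer classes
# (10000, 1000, 800, 640, 512), N = 12952
lh_chinook <- function(p = NULL) {
  from_survival(500, 400, s = c(0.05, 0.1, 0.8, 0.8, 0.8), p = p)
}

# published chinook parameters: contributions from spawner frequencies,
# adult death fractions (0.01, 0.05, 0.15); phi = 0.5 carried as metadata
lh_pub <- function(N = 1e5) {
  life_history(p = c(0, 0, 0.04, 0.25, 0.71),
               c = c(0, 0, 0.01, 0.05, 0.15), N = N, phi = 0.5)
}

# same adult schedule completed with juvenile deaths so sum(i * c_i) = 1
# exactly: c_1 = 0.02, c_2 = 0 (integer classes at N multiple of 100)
lh_pub_strict <- function(N = 1e5) {
  life_history(p = c(0, 0, 0.04, 0.25, 0.71),
               c = c(0.02, 0, 0.01, 0.05, 0.15), N = N)
}

# all spawning at age five, equal age classes: periodic lineage chain
lh_single <- function(N = 1000) {
  life_history(p = c(0, 0, 0, 0, 1), c = c(0, 0, 0, 0, 0.2), N = N)
}

sum_p2_over_c <- function(lh) {
  repro <- which(lh$p > 0)
  sum(lh$p[repro]^2 / lh$c[repro])
}

# independent left-eigenvector oracle for the stationary distribution
stationary_eigen <- function(xi) {
  e <- eigen(t(xi))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# a conservative-weights life history: p_m = m * c_m over adults, juvenile
# deaths zero, so the closed form collapses to N_e = N
lh_conservative <- function(seed, k = 5, n_juvenile = 2, N = 1e4) {
  withr::with_seed(seed, {
    repro <- (n_juvenile + 1):k
    craw <- stats::runif(length(repro), 0.2, 1)
    cc <- numeric(k)
    cc[repro] <- craw / sum(repro * craw)
    p <- seq_len(k) * cc
    life_history(p = p, c = cc, N = N, n_juvenile = n_juvenile)
  })
}
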