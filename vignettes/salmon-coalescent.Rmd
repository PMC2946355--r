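---
title: "Coalescent theory for semelparous age-structured populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent theory for semelparous age-structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmoncoal)
```

## The model

We consider a haploid population of constant total size $N$, divided into
$k$ age classes of which the first $n_j$ are juvenile (defaults $k = 5$,
$n_j = 2$, the typical chinook salmon setting). Each year, $D_i = c_i N$
individuals of class $i$ die; in the adult classes the dying individuals
are the spawners, because reproduction is fatal (semelparity). A fraction
$p_i$ of the $N_1$ newborns descend from class-$i$ spawners, each newborn
drawing its parent uniformly among the $D_i$ spawners of its parental
class (Wright–Fisher reproduction within class, multinomial offspring
numbers). Under constant structure the class sizes are
$N_i = N \sum_{j \ge i} c_j$, and consistency of inflow and outflow
requires $\sum_i i\, c_i = 1$ (equivalently $\sum_i N_i = N$). We call a
parameter set *strict* when it satisfies this identity; the analytic
results below need only $p$, $c$ and $N$, so non-strict sets — common in
published parameter tables, which often report adult death fractions only —
are accepted by default, and strict validation is opt-in
(`validate_life_history(lh, strict = TRUE)`).

A note on the parent pool: the expected offspring number of a class-$m$
spawner is $p_m N_1 / D_m$. Some published statements divide by the class
size $N_m$ instead; since only the dying individuals can have spawned, the
package consistently uses $D_m$, and the forward simulator's offspring
check is written against that reading.

## The ancestral chain and its limit

Backward in time a single lineage moves through age classes
deterministically (class $i$ to $i-1$) except in class 1, where it jumps to
its parent's class $m$ with probability $p_m$. The transition matrix $\xi$
has the contribution vector as its first row and shifted unit vectors
below. Its stationary distribution is available in closed form,
$\pi_i = \big(\sum_{j\ge i} p_j\big)/g$ with $g = \sum_i i\,p_i$ the
generation length; the package always cross-checks this form against a
direct linear solve and refuses reducible chains.

For two lineages the state space is the $k^2$ ordered age-class pairs plus
an absorbing coalesced state. Movement factorises as the Kronecker square
$\xi \otimes \xi$ and is $O(1)$ per year; coalescence is possible only from
the pair state $(1,1)$ — both lineages newborn in the same year — and has
probability $\sum_m p_m^2 / D_m = O(1/N)$. Writing the one-step matrix as
$\Pi_N = A + B/N$ and letting $P = \lim_n A^n$, the two-timescale limit has
generator $G = PBP$, whose coalescence rate is
$\pi_1^2 \sum_m p_m^2/c_m = (1/g^2) \sum_m p_m^2/c_m$ per year on the
$N$-year clock. Converting years to generations and inverting gives

$$N_e \;=\; \frac{N\,g}{\sum_m p_m^2 / c_m}.$$

Because the underlying displays in the source literature are not always
printed, the package treats two independent oracles as the authority for
this reconstruction, and both are exercised in the test suite:

* the numeric limit: $P$ built as $\pi\otimes\pi$ agrees with $A^{4096}$
  (or the Cesàro average, below) to $10^{-6}$, and the last column of
  $G = PBP$ is constant at $(1/g^2)\sum p_m^2/c_m$ to $10^{-10}$;
* the exact finite-$N$ chain: the linear-solve mean absorption time equals
  $N_e g$ years up to the $O(1)$ terms discussed below.

Two printed special cases pin the formula: $p_k = 1$ with equal classes
gives $N_e = N$, and the conservative weighting $p_m = m\,c_m$ gives
$N_e = N$ identically (algebraically, $\sum_m (m c_m)^2/c_m =
\sum_m m^2 c_m = g$).

## Numerical and design choices

**Periodic life histories.** With a single reproductive age (say $p_5 = 1$)
the lineage chain is a $5$-cycle: it is irreducible but *periodic*, despite
occasional blanket aperiodicity claims for this model class. Three
consequences are handled explicitly. First, $\lim A^n$ does not exist, so
the numeric validator switches to the Cesàro average
$(1/n)\sum_{m\le n} A^m$; the package detects the period as
$\gcd\{i : p_i > 0\}$. Second, the row-wise Cesàro limit retains phase
structure — each row is uniform over the $5$-state orbit of its start, not
$\pi\otimes\pi$ — and only its $\pi\otimes\pi$-weighted row average
recovers the analytic projection; the tests assert exactly that weighted
statement. Third, and biologically most important, the two-lineage chain
is then *reducible*: pairs sampled out of phase belong to distinct brood
lines and never coalesce, so the mean absorption time from the stationary
product distribution is infinite, and the exact in-phase mean from $(1,1)$
is $1 + g\,(D_k - 1)$ years — of order $N$ years rather than the limit
value $N_e g = N g$ years. The CES formula still returns $N_e = N$: it
describes the phase-averaged limit process, not literal absorption of the
finite periodic chain. The backward simulator refuses initial
distributions from which absorption is unreachable instead of looping
forever.

**Entrance transient and the absorption oracle.** For aperiodic life
histories the exact mean absorption time from any start equals
$N g^2 / \sum_m p_m^2/c_m$ plus an $O(1)$ constant. From the stationary
product start that constant is an entrance transient of a few tens of
years for realistic parameter sets (about $+32$ years for the published
chinook-style schedule, about $+27$ for the survival-cascade example),
giving relative error $\approx 7/N$ to $21/N$; from the coalescence-active
state $(1,1)$, where the slow clock actually runs, the constant nearly
cancels and the relative error is well under $1/N$. The rate check in the
acceptance tests is therefore run from $(1,1)$, and the $O(1/N)$ decay
from stationarity is asserted separately.

**Integer death counts.** The finite-$N$ chain uses
$D_m = \max(1, \mathrm{round}(c_m N))$ so $\Pi_N$ stays a true stochastic
matrix at small $N$; the analytic $A$ and $B$ use exact $c_m$. At sizes
where every $c_m N$ is an integer the decomposition residual
$N(\Pi_N - A) - B$ vanishes exactly; otherwise it is $O(1/N)$ from the
rounding of $1/D_m$.

**Survival-cascade construction.** `from_survival()` builds class sizes by
the cascade $N_1 = E\,s(1)$, $N_i = N_{i-1} s(i)$ from a total egg pool
$E$, truncating to integers by default (the classic worked example — a
200,000-egg pool with $s = (0.05, 0.1, 0.8, 0.8, 0.8)$ — is integral at
every step and satisfies the strict identity exactly); `rounding = "none"`
keeps fractional schedules for analytic work. A survival schedule does not
determine the contributions $p$; the default takes $p_i \propto D_i$ over
adult classes — contributions proportional to spawner frequencies, the
same assumption used in published parameter choices — and an explicit `p`
overrides it.

**The role of $\phi$.** The first-age-class share $\phi = N_1/N$ equals
$\sum_j c_j$ in a strict life history. Published fluctuating-size analyses
quote $\phi = 0.5$ alongside adult-only death schedules for which no
strict juvenile completion exists (with adult fractions
$(0.01, 0.05, 0.15)$ and $\phi = 0.5$, the juvenile completions force
$\sum i\,c_i \ge 1.27$). The constructor therefore accepts $\phi$ as
metadata in non-strict mode; none of the implemented formulas use it — the
derived long-term coalescence rate depends on $p$, $c$ and the size
distribution only.

**Simulators.** The backward pair engine walks the exact finite-$N$ chain
with deterministic aging stretches skipped in blocks and all replicates
advanced together; a single seeded generator drives the whole run
(replicates are interleaved by the vectorised stepping rather than given
per-replicate substreams — with one RNG stream the run is still exactly
reproducible from its seed). Under fast i.i.d. size fluctuations the
yearly multiplier matters only in coalescence-capable years, so drawing it
at event years is equivalent in law and keeps the walk fast. The forward
simulator needs integer class sizes (hence a strict life history) and
enforces $\sum N_i = N$ every year as a hard failure; juvenile deaths are
uniform within class — the exchangeable choice, as the model does not
distinguish juveniles — and newborn class quotas are multinomial by
default, with a largest-remainder fixed-quota mode as an alternative.
Pedigree TMRCA of final-cohort pairs corresponds to the backward chain
started at $(1,1)$, with siblings at TMRCA 1 year; pairs within one
pedigree share deep genealogy, so the forward/backward agreement test
averages over independent runs and uses the between-run standard error
(a fixed 5% band would demand on the order of a hundred runs to be a fair
test, because the population-average TMRCA of a single pedigree has a
coefficient of variation near 50%).

**Fluctuating-size estimators.** The per-generation-block coalescent
estimate applies the long-term harmonic-mean formula to each block's
empirical size distribution; how the published per-block coalescent values
were computed is not stated, so this convention is validated only against
the printed qualitative ordering (coalescent < harmonic < arithmetic in
every block of a varying series), which holds identically for the
published parameter set since
$g/\sum p_m^2/c_m < g \sum_{adult} c_i$ there. Block length defaults to
the rounded generation length; reproducing the published 12-blocks-of-4
split of a 52-year series requires the explicit `blocks = 12` truncation,
which drops the final 4 years and reports it.

## What the generators emulate — and what a green test does not establish

`generate_fixture()` draws structurally valid life histories (exact strict
identity, optional balanced offspring-per-breeder ratios within a factor
1.5) and `simulate_series()` draws i.i.d. uniform yearly sizes between
bounds chosen to match historical chinook return ranges. Real populations
violate both idealisations: age structure drifts, yearly sizes are
autocorrelated, reproductive success is far more variable than multinomial
(raising the prospect of multiple mergers), and the sexes differ. A green
suite establishes that the implementation is faithful to the stated model,
not that the model is faithful to any particular river.

## Known limitations

* Sample sizes $n > 2$ are covered by simulation only
  (`simulate_n_backward()`, which also counts finite-$N$ multiple
  mergers); the $k^n$-state analytic chain is not built.
* Diploidy, two sexes, spatial subdivision, selection and mutation are out
  of scope; size fluctuations on the coalescent timescale (rather than
  fast i.i.d.) are not modelled.
* The matrix exponential of $G$ is never formed; all uses go through the
  rate, the generator's structure, or simulation.
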