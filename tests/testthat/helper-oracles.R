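# Independent oracles used by the unit and acceptance tests. These are
# deliberately written as literal, brute-force restatements of the model
# rules, sharing no code with the implementation they check.

# Walks every index pair and applies the verbal placement rules for the
# scenario's correlated mutational effects. Block order (queen survival,
# queen fecundity, worker survival, worker fecundity) is the package-wide
# layout constant.
oracle_scenario_matrix <- function(scenario, k, rho, delay) {
  n <- 4L * k
  block_of <- function(i) (i - 1L) %/% k + 1L # 1=Qs, 2=Qf, 3=Ws, 4=Wf
  age_of <- function(i) (i - 1L) %% k + 1L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        M[i, j] <- 1
        next
      }
      bi <- block_of(i); bj <- block_of(j)
      ai <- age_of(i); aj <- age_of(j)
      hit <- switch(scenario,
        baseline = FALSE,
        # same trait, same caste, ages delay apart, never worker fecundity
        WCWT = bi == bj && bi %in% c(1L, 2L, 3L) && abs(ai - aj) == delay,
        # queen fecundity at a with queen survival at a + delay
        WCBT = (bi == 2L && bj == 1L && aj - ai == delay) ||
               (bi == 1L && bj == 2L && ai - aj == delay),
        # queen survival with worker survival, same age
        BCWT = ((bi == 1L && bj == 3L) || (bi == 3L && bj == 1L)) && ai == aj,
        # queen fecundity with worker survival, same age
        BCBT = ((bi == 2L && bj == 3L) || (bi == 3L && bj == 2L)) && ai == aj
      )
      if (hit) M[i, j] <- rho
    }
  }
  M
}

# Monte-Carlo life expectancy: push `n` independent individuals through the
# age-specific survival gauntlet and average the number of completed age
# classes.
oracle_life_expectancy_mc <- function(survival, n = 2e5) {
  k <- length(survival)
  u <- matrix(runif(n * k), n, k)
  alive <- t(apply(u < rep(survival, each = n), 1, cumprod))
  counts <- rowSums(alive)
  list(mean = mean(counts), se = stats::sd(counts) / sqrt(n))
}

# Grid-search maximiser of the limiting offspring function min(E, R) over
# the queen's foraging fraction. The closed-form allocation rule is the
# egg-resource balance point E = R (with a clamp at z = 0), which is the
# argmax of min(E, R); it is NOT the argmax of the smooth offspring function
# E*R/(E+R), whose maximiser lies at smaller z whenever f_a > 1.
oracle_best_z <- function(f_a, w, step = 1e-4) {
  z <- seq(0, 1, by = step)
  E <- f_a * (1 - z)
  R <- z + w
  z[which.max(pmin(E, R))]
}

# Strip dimnames and ad-hoc attributes so matrices compare on values alone.
bare <- function(M) array(as.numeric(M), dim(M))
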