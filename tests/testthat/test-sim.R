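test_that("without mutation every genetic value stays at the founder value", {
  # a mutation-free population is perfectly synchronised: every queen dies of
  # max age at multiples of k, so measure mid-cycle when workers exist
  p <- sim_params(N = 50, T = 210, mu = 0, init_value = 5,
                  check_invariants = TRUE, checkpoint_every = 70)
  sim <- run_replicate(p, seed = 4)
  expect_equal(sim$status, "completed")
  g <- sim$genomes
  expect_true(all(g$queen_a == 5) && all(g$queen_b == 5))
  expect_true(all(g$queen_sperm == 5))
  expect_true(nrow(g$worker_a) > 0)
  expect_true(all(g$worker_a == 5) && all(g$worker_b == 5))
  # queen and worker summaries coincide exactly
  s <- sim$summary
  expect_equal(s$life_expectancy[1], s$life_expectancy[2])
  expect_equal(s$lifetime_fecundity[1], s$lifetime_fecundity[2])
})

test_that("a replicate is a deterministic function of its seed", {
  p <- sim_params(N = 30, T = 400, checkpoint_every = 100)
  a <- run_replicate(p, seed = 123)
  b <- run_replicate(p, seed = 123)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(tidy(a), tidy(b))
  c <- run_replicate(p, seed = 124)
  expect_false(identical(a$genomes, c$genomes))
})

test_that("structural invariants hold throughout a mutating run", {
  p <- sim_params(N = 30, T = 1500, check_invariants = TRUE,
                  checkpoint_every = 250)
  sim <- run_replicate(p, seed = 9) # the core stops on any violation
  expect_equal(sim$status, "completed")
  g <- sim$genomes
  expect_lte(length(g$queen_age), p$N) # at most one queen per slot
  expect_true(all(g$queen_age >= 1 & g$queen_age <= p$k))
  expect_true(all(g$worker_age >= 1 & g$worker_age <= p$k))
  expect_true(all(g$worker_colony %in% g$queen_colony)) # workers live in queened slots
  ts <- dplyr::distinct(sim$timeseries, step, n_queens)
  expect_true(all(ts$n_queens <= p$N))
})

test_that("an inviable founder population goes extinct with the step recorded", {
  p <- sim_params(N = 20, T = 100, init_value = -5) # survival ~ 0 everywhere
  sim <- run_replicate(p, seed = 1)
  expect_equal(sim$status, "extinct")
  expect_lt(sim$steps_run, 10)
  expect_equal(length(sim$genomes$queen_age), 0L)
  expect_true(all(is.na(sim$summary$life_expectancy)))
})

test_that("full extrinsic mortality forces an annual life cycle: every queen is a first-year founder", {
  # h_ext = 1 kills every forager; lone founding queens always forage, so
  # each generation survives only through eggs withdrawn at requeening
  p <- sim_params(N = 40, T = 50, h_ext = 1, mu = 0)
  sim <- run_replicate(p, seed = 6)
  g <- sim$genomes
  if (sim$status == "completed") {
    expect_true(all(g$queen_age == 1))
    expect_equal(length(g$worker_age), 0L)
    expect_gt(sim$requeen_fallback, 0)
  } else {
    expect_equal(sim$status, "extinct")
  }
})

test_that("requeening picks source colonies proportionally to their egg counts", {
  set.seed(17)
  weights <- c(3, 1)
  n <- 1e4
  picks <- replicate(n, sample_weighted_index(weights))
  p_hat <- mean(picks == 1)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  weights <- c(0, 5, 0, 2, 3)
  picks <- replicate(n, sample_weighted_index(weights))
  expect_false(any(picks %in% c(1, 3))) # zero-egg colonies are never chosen
  for (i in c(2, 4, 5)) {
    pr <- weights[i] / sum(weights)
    expect_lt(abs(mean(picks == i) - pr), 3 * sqrt(pr * (1 - pr) / n))
  }
  expect_error(sample_weighted_index(c(0, 0)), "positive total")
  expect_error(sample_weighted_index(c(-1, 2)), "non-negative")
})

test_that("worker fecundity, being unexpressed, decays under biased mutation while selected traits hold up", {
  p <- sim_params(N = 60, T = 30000, checkpoint_every = 10000)
  sim <- run_replicate(p, seed = 21)
  expect_equal(sim$status, "completed")
  g <- sim$genomes
  sums <- colMeans(g$queen_a + g$queen_b)
  lay <- trait_layout(p$k)
  wf <- mean(sums[trait_index(lay, "worker", "fecundity", 1:p$k)])
  qf_young <- mean(sums[trait_index(lay, "queen", "fecundity", 1:10)])
  init_sum <- 2 * p$init_value
  expect_lt(wf, init_sum - 0.5) # neutral block has slid from the founder value
  expect_gt(qf_young, wf) # selection holds queen fecundity higher
})

test_that("replicate outputs expose tidy, glance and plots", {
  p <- sim_params(N = 30, T = 1000, checkpoint_every = 250)
  sim <- run_replicate(p, seed = 3)
  td <- tidy(sim)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$caste, c("queen", "worker"))
  expect_true(all(td$lifespan_proportion >= 0 & td$lifespan_proportion <= 1))
  gl <- glance(sim)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$scenario, "baseline")
  pl <- ggplot2::autoplot(sim, trait = "both")
  expect_s3_class(pl, "ggplot")
  out <- write_replicate(sim, tempfile("rep"))
  expect_true(all(file.exists(out)))
})
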