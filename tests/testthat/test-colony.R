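test_that("queen time allocation follows the closed form and its clamps", {
  expect_equal(foraging_time(5, 2), 0.5)
  expect_equal(foraging_time(0, 0), 0)
  expect_equal(foraging_time(0, 7), 0)
  expect_equal(foraging_time(3, 10), 0) # enough workers: queen stays in nest
  expect_error(foraging_time(-1, 2), "non-negative")
  # lone founding queen with any positive fecundity must forage
  expect_gt(foraging_time(0.1, 0), 0)
})

test_that("the closed-form z balances eggs against resources and maximises the limiting offspring function", {
  set.seed(5)
  w <- sample(0:50, 1000, replace = TRUE)
  f <- runif(1000, 0, 5)
  z_closed <- foraging_time(f, w)
  # at an unclamped optimum the egg number equals the resource total exactly
  interior <- z_closed > 0
  E <- eggs_laid(f, z_closed)
  R <- resources(z_closed, w)
  expect_equal(E[interior], R[interior], tolerance = 1e-12)
  # and the rule (including its clamped z = 0 branch) matches a grid-search
  # maximisation of min(E, R)
  z_grid <- mapply(oracle_best_z, f, w)
  expect_lt(max(abs(z_closed - z_grid)), 1e-4 + 1e-9)
  M_closed <- pmin(E, R)
  M_grid <- pmin(eggs_laid(f, z_grid), resources(z_grid, w))
  expect_true(all(M_closed + 1e-9 >= M_grid))
})

test_that("resources, eggs and expected offspring follow the colony economics", {
  expect_equal(resources(0, 0), 0)
  expect_equal(resources(0.5, 2), 2.5)
  expect_equal(resources(1, 10), 11)
  expect_equal(eggs_laid(5, 1), 0)
  expect_equal(eggs_laid(5, 0.5), 2.5)
  expect_equal(eggs_laid(0, 0), 0)
  expect_equal(expected_offspring(0, 5), 0)
  expect_equal(expected_offspring(4, 4), 2)
  # consistency of F = E * R / (E + R) with F = E * g(R/E), g(x) = x/(1+x)
  expect_equal(expected_offspring(2.5, 2.5), 1.25)
  expect_equal(expected_offspring(2.5, 2.5), 2.5 * (1 / (1 + 1)))
})

test_that("expected offspring is monotone and bounded by eggs and resources", {
  E <- seq(0.1, 6, length.out = 25)
  R <- seq(0.1, 6, length.out = 25)
  for (r in R) {
    F_along_E <- expected_offspring(E, r)
    expect_true(all(diff(F_along_E) >= 0))
    expect_true(all(F_along_E < pmin(E, r)))
  }
  for (e in E) {
    expect_true(all(diff(expected_offspring(e, R)) >= 0))
  }
})

test_that("realized offspring are Poisson with the expected mean", {
  expect_identical(realize_offspring(0), 0L)
  set.seed(31)
  x <- realize_offspring(rep(2, 1e5))
  expect_lt(abs(mean(x) - 2), 3 * sqrt(2 / 1e5))
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("foraging mortality interpolates between shielded queens and exposed workers", {
  h <- c(0, 0.05, 0.2, 0.5, 0.9)
  expect_equal(foraging_death_prob(h, 1), h) # workers forage full time
  expect_equal(foraging_death_prob(h, 0), rep(0, 5)) # nest-bound queen
  expect_equal(foraging_death_prob(0.2, 0.5), 1 - 0.8^0.5)
  expect_equal(foraging_death_prob(0.2, 0.5), 0.10557, tolerance = 1e-4)
  # monotone in both arguments
  z <- seq(0, 1, by = 0.1)
  expect_true(all(diff(foraging_death_prob(0.3, z)) > 0))
  expect_true(all(diff(foraging_death_prob(h, 0.7)) > 0))
  expect_error(foraging_death_prob(1, 0.5), "\\[0, 1\\)")
})

test_that("survival couples intrinsic and extrinsic chances multiplicatively", {
  expect_true(all(survive_step(rep(1, 50), rep(0, 50))))
  expect_false(any(survive_step(rep(0, 50), runif(50))))
  set.seed(13)
  alive <- survive_step(rep(0.9, 1e5), rep(0.2, 1e5))
  p <- 0.9 * 0.8
  expect_lt(abs(mean(alive) - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("the per-step colony outcome ties the pieces together", {
  set.seed(2)
  out <- colony_step_outcome(f_a = 5, w = 2, h_ext = 0.2)
  expect_equal(out$z, 0.5)
  expect_equal(out$R, 2.5)
  expect_equal(out$E, 2.5)
  expect_equal(out$F_mean, 1.25)
  expect_equal(out$n_males, out$n_offspring)
  expect_equal(out$d_ext_queen, 1 - 0.8^0.5)
  expect_lte(out$F_mean, min(out$E, out$R))
})
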