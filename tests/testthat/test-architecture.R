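test_that("scenario matrices match the rule-enumerating oracle entry by entry", {
  for (scenario in scenario_names()) {
    for (k in c(8L, 20L)) {
      P <- build_partial_correlation(scenario, k = k, rho = -0.8, delay = 5)
      O <- oracle_scenario_matrix(scenario, k = k, rho = -0.8, delay = 5)
      expect_identical(unname(P), O,
                       label = sprintf("%s k=%d vs oracle", scenario, k))
    }
  }
})

test_that("delayed effects occupy exactly k - delay positions per affected block", {
  P <- build_partial_correlation("WCWT", k = 20, rho = -0.8, delay = 5)
  up <- P[upper.tri(P)]
  # queen survival, queen fecundity and worker survival blocks; never worker
  # fecundity
  expect_equal(sum(up == -0.8), 3L * 15L)
  wf <- 61:80
  offdiag <- P[wf, ]
  diag(offdiag[, wf]) <- 0
  expect_true(all(offdiag == 0))

  # delayed pairs sit at (a, a + 5) only while a + 5 <= k
  qs <- P[1:20, 1:20]
  expect_equal(unname(which(qs[15, ] == -0.8)), c(10L, 20L)) # ages 10 and 20
  expect_true(all(qs[16:20, 16:20][upper.tri(diag(5))] == 0))
})

test_that("zero correlation collapses every scenario to the baseline matrix", {
  base <- build_partial_correlation("baseline", k = 12)
  for (scenario in setdiff(scenario_names(), "baseline")) {
    expect_identical(build_partial_correlation(scenario, k = 12, rho = 0), base)
    arch <- mutation_architecture(scenario, k = 12, rho = 0)
    expect_equal(bare(arch$Sigma), diag(0.4^2, 48), tolerance = 1e-12)
  }
})

test_that("baseline covariance is exactly sigma^2 times the identity", {
  P <- build_partial_correlation("baseline", k = 20)
  Sigma <- partial_to_covariance(P, 0.4)
  expect_identical(bare(Sigma), diag(0.4^2, 80))
  expect_false(attr(Sigma, "repair")$fired)
})

test_that("pairwise-disjoint scenarios keep rho exactly; all covariances are PSD", {
  for (scenario in c("WCBT", "BCWT", "BCBT")) {
    arch <- mutation_architecture(scenario, k = 20)
    expect_false(arch$repair$fired)
    C <- stats::cov2cor(arch$Sigma)
    pos <- which(arch$P == -0.8)
    expect_equal(C[pos], rep(-0.8, length(pos)), tolerance = 1e-12)
  }
  # analytic 2x2 check: queen survival age a with worker survival age a
  arch <- mutation_architecture("BCWT", k = 8)
  sub <- arch$Sigma[c(1, 17), c(1, 17)]
  expect_equal(sub, matrix(0.16 * c(1, -0.8, -0.8, 1), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  for (scenario in scenario_names()) {
    arch <- mutation_architecture(scenario, k = 20)
    ev <- eigen(arch$Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(bare(arch$Sigma), bare(t(arch$Sigma)))
    expect_equal(unname(diag(arch$Sigma)), rep(0.16, 80), tolerance = 1e-10)
  }
})

test_that("the nearest-correlation repair fires only when needed and preserves signs", {
  arch <- mutation_architecture("WCWT", k = 20)
  expect_true(arch$repair$fired)
  expect_gt(arch$repair$frobenius, 0)
  # sign contract: wherever the requested correlation is non-negligible the
  # repaired covariance keeps its sign
  strong <- which(abs(arch$P) >= 0.1 & upper.tri(arch$P))
  expect_true(all(sign(arch$Sigma[strong]) == sign(arch$P[strong])))
  # repair is idempotent: re-projecting the repaired correlation changes nothing
  C <- stats::cov2cor(arch$Sigma)
  Sigma2 <- partial_to_covariance(C, 0.4)
  expect_false(attr(Sigma2, "repair")$fired)
  expect_equal(bare(Sigma2), bare(0.4^2 * C), tolerance = 1e-12)
})

test_that("matrix construction rejects invalid configurations", {
  expect_error(build_partial_correlation("WTWC", k = 20), "unknown scenario")
  expect_error(build_partial_correlation("WCWT", k = 5, delay = 5), "exceed")
  expect_error(build_partial_correlation("WCWT", k = 20, rho = -1.2), "\\[-1, 1\\]")
  P <- build_partial_correlation("BCWT", k = 8)
  P[1, 2] <- 0.5 # break symmetry
  expect_error(partial_to_covariance(P, 0.4), "symmetric")
  P <- build_partial_correlation("BCWT", k = 8)
  diag(P)[3] <- 0.9
  expect_error(partial_to_covariance(P, 0.4), "unit diagonal")
  expect_error(partial_to_covariance(build_partial_correlation("baseline", 8), -1),
               "positive")
})

test_that("architecture matrices export as labelled CSV", {
  arch <- mutation_architecture("BCWT", k = 8)
  paths <- export_architecture(arch, tempfile("arch"))
  expect_true(all(file.exists(paths)))
  P <- utils::read.csv(paths[["P"]])
  expect_equal(dim(P), c(32L, 32L))
  expect_equal(names(P)[1], "Q_surv_a1")
  expect_equal(P[1, 17], -0.8)
})

test_that("mutation draws have the biased mean, the requested spread, and collapse as sigma -> 0", {
  arch <- mutation_architecture("baseline", k = 20)
  set.seed(11)
  draws <- sample_mutation(arch, n = 10000)
  expect_equal(dim(draws), c(10000L, 80L))
  # pooled over coordinates (all have identical, independent marginals)
  expect_lt(abs(mean(draws) + 0.2), 4 * 0.4 / sqrt(length(draws)))
  expect_lt(abs(mean(apply(draws, 2, stats::var)) - 0.16), 0.003)

  tiny <- mutation_architecture("baseline", k = 8, sigma = 1e-12)
  expect_equal(sample_mutation(tiny), rep(-0.2, 32), tolerance = 1e-9)
})
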