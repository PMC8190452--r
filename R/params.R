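#' Simulation parameter set
#'
#' Collects and validates every model parameter. Defaults are the study
#' conditions of the full-scale experiment: 1000 colonies, 10^6 time steps,
#' 20 age classes, mutation rate 0.005 with mean effect -0.2 and sd 0.4,
#' partial correlations of -0.8 with a 5-age-class effect delay, maximum
#' fecundity 5 per age class, and extrinsic hazard 0 or 0.2.
#'
#' @param N Number of colony slots (`>= 2`).
#' @param T Number of discrete time steps.
#' @param k Number of age classes (maximum lifespan; must exceed `delay`).
#' @param h_ext Extrinsic hazard probability in `[0, 1]`, applied only while
#'   foraging.
#' @param mu Mutation probability per transmitted network.
#' @param b Mean mutational effect size (negative = deleterious bias).
#' @param sigma Standard deviation of mutational effect sizes.
#' @param rho Partial correlation of the scenario's antagonistic effects.
#' @param delay Age-class offset of delayed antagonistic effects.
#' @param m Maximum fecundity per age class.
#' @param scenario Mutational-architecture scenario, one of
#'   [scenario_names()].
#' @param init_value Founder genetic value at every position. The default 5
#'   (allelic sum 10) starts founders senescence-free near the trait optimum:
#'   intrinsic survival ~ 0.99995 and fecundity ~ `m` at every age, so any
#'   age-specific decline that appears is evolved, not seeded. Values at or
#'   below ~1 put founder survival so low that lone founding queens cannot
#'   replace themselves and the population crashes within a few steps.
#' @param recombine Per-position free recombination in gametes instead of
#'   whole-network transmission.
#' @param checkpoint_every Steps between time-series checkpoints (default:
#'   `T / 100`, at least 1).
#' @param check_invariants Run per-step structural checks (slot count,
#'   monogyny, age bounds) inside the simulator; for testing, slows the run.
#' @return A validated list of class `sim_params`.
#' @examples
#' p <- sim_params(N = 100, T = 1000, h_ext = 0.2, scenario = "BCWT")
#' @export
sim_params <- function(N = 1000, T = 1e6, k = 20, h_ext = 0, mu = 0.005,
                       b = -0.2, sigma = 0.4, rho = -0.8, delay = 5, m = 5,
                       scenario = "baseline", init_value = 5,
                       recombine = FALSE, checkpoint_every = NULL,
                       check_invariants = FALSE) {
  scenario <- match_scenario(scenario)
  chk_num <- function(x, name, lo = -Inf, hi = Inf, int = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi ||
        (int && x != round(x))) {
      stop(sprintf("`%s` must be a single %s in [%s, %s]", name,
                   if (int) "integer" else "number", format(lo), format(hi)),
           call. = FALSE)
    }
    if (int) as.integer(x) else x
  }
  N <- chk_num(N, "N", 2, Inf, int = TRUE)
  T <- chk_num(T, "T", 1, Inf, int = TRUE)
  k <- chk_num(k, "k", 2, Inf, int = TRUE)
  delay <- chk_num(delay, "delay", 1, Inf, int = TRUE)
  if (k <= delay) stop("`k` must exceed `delay`", call. = FALSE)
  h_ext <- chk_num(h_ext, "h_ext", 0, 1)
  mu <- chk_num(mu, "mu", 0, 1)
  sigma <- chk_num(sigma, "sigma", 1e-300, Inf)
  rho <- chk_num(rho, "rho", -1, 1)
  m <- chk_num(m, "m", 1e-12, Inf)
  b <- chk_num(b, "b")
  init_value <- chk_num(init_value, "init_value")
  if (is.null(checkpoint_every)) checkpoint_every <- max(1L, T %/% 100L)
  checkpoint_every <- chk_num(checkpoint_every, "checkpoint_every", 1, Inf, int = TRUE)
  structure(
    list(N = N, T = T, k = k, h_ext = h_ext, mu = mu, b = b, sigma = sigma,
         rho = rho, delay = delay, m = m, scenario = scenario,
         init_value = init_value, recombine = isTRUE(recombine),
         checkpoint_every = checkpoint_every,
         check_invariants = isTRUE(check_invariants)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", x$scenario,
      sprintf("N = %d, T = %g, k = %d, h_ext = %g, mu = %g, b = %g, sigma = %g, rho = %g, delay = %d, m = %g\n",
              x$N, as.double(x$T), x$k, x$h_ext, x$mu, x$b, x$sigma, x$rho,
              x$delay, x$m))
  invisible(x)
}

#' Scale presets for the experiment grid
#'
#' `"full"` is the headline configuration (1000 colonies, 10^6 steps, 20
#' replicates per cell), sized for cluster hardware. `"desk"` (120 colonies,
#' 1.5 x 10^5 steps, 5 replicates) is the smallest configuration inside the
#' quasi-stationary regime: population-mean life-expectancy trajectories
#' plateau from roughly 1.5 x 10^5 steps, and with many fewer colonies the
#' evolved worker lifespan is dominated by drift between replicates. A desk
#' replicate takes roughly half a minute on one CPU.
#'
#' @param preset `"desk"` or `"full"`.
#' @return List with `N`, `T` and `replicates`.
#' @export
sim_preset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  switch(preset,
    desk = list(N = 120L, T = 150000L, replicates = 5L),
    full = list(N = 1000L, T = 1000000L, replicates = 20L)
  )
}
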