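#' Optimal queen foraging time
#'
#' Fraction of a time step the queen spends foraging,
#' `z = max(0, 1 - (1 + w) / (1 + f_a))`: the allocation that maximises the
#' colony's expected offspring given her age-specific fecundity `f_a` and the
#' current worker count `w`. With enough workers the queen stays in the nest
#' (`z = 0`); a lone founding queen must forage (semiclaustral founding) and
#' is thereby exposed to extrinsic mortality.
#'
#' @param f_a Queen fecundity at her current age class (`>= 0`); vectorised.
#' @param w Worker count (non-negative integer); vectorised.
#' @return Foraging fraction in `[0, 1)`.
#' @examples
#' foraging_time(5, 2)   # 0.5
#' foraging_time(3, 10)  # 0: queen stays in nest
#' @export
foraging_time <- function(f_a, w) {
  if (any(f_a < 0) || any(w < 0)) stop("`f_a` and `w` must be non-negative", call. = FALSE)
  pmax(0, 1 - (1 + w) / (1 + f_a))
}

#' Colony resources foraged in one time step
#'
#' Queens and workers are equally successful foragers, so resources equal
#' the queen's foraging fraction plus the number of (always-foraging)
#' workers: `R = z + w`.
#'
#' @param z Queen foraging fraction in `[0, 1]`.
#' @param w Worker count.
#' @return Resources in worker-equivalents.
#' @export
resources <- function(z, w) z + w

#' Eggs laid by the queen in one time step
#'
#' During the non-foraging fraction of her time the queen lays eggs at her
#' age-specific rate: `E = f_a * (1 - z)`. Eggs are a (possibly non-integer)
#' intensity; the realised offspring count is Poisson-distributed downstream.
#'
#' @param f_a Queen fecundity at her current age class.
#' @param z Queen foraging fraction in `[0, 1]`.
#' @return Expected egg number `>= 0`.
#' @export
eggs_laid <- function(f_a, z) f_a * (1 - z)

#' Expected offspring from eggs and resources
#'
#' Per-egg survival rises with resources per egg as `g(x) = x / (1 + x)`,
#' `x = R / E`, giving expected offspring `F = E * R / (E + R)` (0 when both
#' are 0). `F` is bounded by `min(E, R)` and increases in each argument.
#'
#' @param E Eggs laid (`>= 0`); vectorised.
#' @param R Resources foraged (`>= 0`); vectorised.
#' @return Expected offspring number.
#' @examples
#' expected_offspring(4, 4)  # 2
#' @export
expected_offspring <- function(E, R) {
  if (any(E < 0) || any(R < 0)) stop("`E` and `R` must be non-negative", call. = FALSE)
  tot <- E + R
  ifelse(tot > 0, E * R / tot, 0)
}

#' Realise an offspring count
#'
#' Samples the number of diploid offspring actually produced this step from
#' a Poisson distribution with the expected-offspring mean.
#'
#' @param F_mean Expected offspring (`>= 0`).
#' @return Non-negative integer count.
#' @export
realize_offspring <- function(F_mean) {
  stopifnot(F_mean >= 0)
  stats::rpois(length(F_mean), F_mean)
}

#' Extrinsic death probability while foraging
#'
#' An age-independent extrinsic hazard `h_ext` applies only during foraging:
#' `d_ext = 1 - (1 - h_ext)^z`. Workers always forage (`z = 1`), so their
#' extrinsic death probability is `h_ext`; a queen inside the nest (`z = 0`)
#' is fully shielded.
#'
#' @param h_ext Extrinsic hazard probability in `[0, 1)`; vectorised.
#' @param z Foraging fraction in `[0, 1]`; vectorised.
#' @return Death probability in `[0, h_ext]`.
#' @examples
#' foraging_death_prob(0.2, 1)    # 0.2 (worker)
#' foraging_death_prob(0.2, 0)    # 0 (nest-bound queen)
#' @export
foraging_death_prob <- function(h_ext, z) {
  if (any(h_ext < 0) || any(h_ext >= 1)) stop("`h_ext` must be in [0, 1)", call. = FALSE)
  if (any(z < 0) || any(z > 1)) stop("`z` must be in [0, 1]", call. = FALSE)
  1 - (1 - h_ext)^z
}

#' Bernoulli survival of one individual over one time step
#'
#' Survival combines the genetically determined intrinsic age-specific
#' survival probability with extrinsic foraging survival: the individual
#' survives with probability `intrinsic_s * (1 - d_ext)`.
#'
#' @param intrinsic_s Intrinsic survival probability in `[0, 1]`; vectorised.
#' @param d_ext Extrinsic death probability in `[0, 1]`; vectorised.
#' @return Logical: alive after this step?
#' @export
survive_step <- function(intrinsic_s, d_ext) {
  stopifnot(all(intrinsic_s >= 0 & intrinsic_s <= 1), all(d_ext >= 0 & d_ext <= 1))
  n <- max(length(intrinsic_s), length(d_ext))
  stats::runif(n) < intrinsic_s * (1 - d_ext)
}

#' One colony's per-step economics, deterministically and stochastically
#'
#' Convenience wrapper chaining the per-step colony operations for a queen of
#' fecundity `f_a` with `w` workers: time allocation, resources, eggs,
#' expected offspring, realised diploid offspring (Poisson), matched haploid
#' male eggs, and the queen's extrinsic death probability for the step.
#'
#' @param f_a Queen fecundity at her current age class.
#' @param w Worker count.
#' @param h_ext Extrinsic hazard probability.
#' @return A tibble with one row: `z`, `R`, `E`, `F_mean`, `n_offspring`,
#'   `n_males`, `d_ext_queen`.
#' @examples
#' set.seed(1)
#' colony_step_outcome(f_a = 5, w = 2, h_ext = 0.2)
#' @export
colony_step_outcome <- function(f_a, w, h_ext = 0) {
  z <- foraging_time(f_a, w)
  R <- resources(z, w)
  E <- eggs_laid(f_a, z)
  F_mean <- expected_offspring(E, R)
  n_off <- realize_offspring(F_mean)
  tibble::tibble(
    z = z, R = R, E = E, F_mean = F_mean,
    n_offspring = n_off, n_males = n_off,
    d_ext_queen = foraging_death_prob(h_ext, z)
  )
}
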