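#' Population-mean expressed trait curves for one caste
#'
#' Averages the expressed (not realised) age-specific intrinsic survival
#' probabilities and fecundities over the genomes of all living members of
#' the caste: queen-caste means over living queens, worker-caste means over
#' living workers.
#'
#' @param population A `caste_sim` result (or any list with the `genomes`
#'   element that [run_replicate()] produces) plus `params`.
#' @param caste `"queen"` or `"worker"`.
#' @return List with `survival` and `fecundity`, numeric vectors of length
#'   `k`.
#' @export
population_mean_traits <- function(population, caste) {
  caste <- match.arg(caste, c("queen", "worker"))
  stopifnot(!is.null(population$genomes), !is.null(population$params))
  g <- population$genomes
  if (caste == "queen") {
    A <- g$queen_a; B <- g$queen_b
  } else {
    A <- g$worker_a; B <- g$worker_b
  }
  if (is.null(A) || nrow(A) == 0) {
    stop("no living ", caste, "s to average over", call. = FALSE)
  }
  k <- population$params$k
  m <- population$params$m
  lay <- trait_layout(k)
  sums <- A + B
  idx_s <- trait_index(lay, caste, "survival", seq_len(k))
  idx_f <- trait_index(lay, caste, "fecundity", seq_len(k))
  list(
    survival = colMeans(logistic(sums[, idx_s, drop = FALSE])),
    fecundity = m * colMeans(logistic(sums[, idx_f, drop = FALSE]))
  )
}

#' Life expectancy: area under the discrete survivorship curve
#'
#' From age-specific intrinsic survival probabilities `s_1..s_k`, the
#' survivorship to age `a` is `l_a = prod(s_1..s_a)` and life expectancy is
#' `sum(l_a)` over `a = 1..k` — the number of age classes an individual is
#' expected to complete, with maximum `k` when all survival probabilities
#' are 1. Extrinsic mortality is not included: this is the evolved,
#' intrinsic lifespan.
#'
#' @param mean_survival Numeric vector of `k` probabilities in `[0, 1]`.
#' @return A single number in `[0, k]`.
#' @examples
#' life_expectancy(rep(1, 20))    # 20
#' life_expectancy(rep(0.5, 20))  # ~1
#' @export
life_expectancy <- function(mean_survival) {
  stopifnot(is.numeric(mean_survival), all(is.finite(mean_survival)),
            all(mean_survival >= 0), all(mean_survival <= 1))
  sum(cumprod(mean_survival))
}

#' Lifetime fecundity: sum of age-specific fecundities
#'
#' A pure fecundity measure, unweighted by survivorship: the sum of the
#' population-mean age-specific fecundity values, with maximum `k * m`.
#'
#' @param mean_fecundity Numeric vector of `k` non-negative values.
#' @return A single number in `[0, k * m]`.
#' @export
lifetime_fecundity <- function(mean_fecundity) {
  stopifnot(is.numeric(mean_fecundity), all(is.finite(mean_fecundity)),
            all(mean_fecundity >= 0))
  sum(mean_fecundity)
}

#' Proportion transform of evolved lifespans and fecundities
#'
#' Divides evolved life expectancies by the maximum achievable lifespan `k`
#' and lifetime fecundities by the maximum achievable lifetime fecundity
#' `k * m`, yielding proportions in `[0, 1]` ready for proportion-scale
#' statistics (e.g. beta regression).
#'
#' @param summary A data frame with columns `life_expectancy` and
#'   `lifetime_fecundity` (e.g. from [summarize_replicate()]).
#' @param k Number of age classes.
#' @param m Maximum fecundity per age class.
#' @return The input tibble with `lifespan_proportion` and
#'   `fecundity_proportion` columns added (replaced if present).
#' @export
proportion_transform <- function(summary, k, m) {
  stopifnot(is.data.frame(summary), k > 0, m > 0,
            all(c("life_expectancy", "lifetime_fecundity") %in% names(summary)))
  dplyr::mutate(
    tibble::as_tibble(summary),
    lifespan_proportion = .data$life_expectancy / k,
    fecundity_proportion = .data$lifetime_fecundity / (k * m)
  )
}

#' Per-caste summary table of one replicate
#'
#' One row per caste with the evolved population-mean outcome measures:
#' life expectancy (area under the intrinsic survivorship curve), lifetime
#' fecundity (sum of age-specific fecundities), and their proportion
#' transforms.
#'
#' @param sim A `caste_sim`.
#' @return A tibble with columns `scenario`, `h_ext`, `seed`, `status`,
#'   `caste`, `life_expectancy`, `lifetime_fecundity`,
#'   `lifespan_proportion`, `fecundity_proportion`.
#' @export
summarize_replicate <- function(sim) {
  stopifnot(inherits(sim, "caste_sim"))
  p <- sim$params
  rows <- purrr::map(c("queen", "worker"), function(caste) {
    mt <- try(population_mean_traits(sim, caste), silent = TRUE)
    if (inherits(mt, "try-error")) {
      return(tibble::tibble(caste = caste, life_expectancy = NA_real_,
                            lifetime_fecundity = NA_real_))
    }
    tibble::tibble(
      caste = caste,
      life_expectancy = life_expectancy(mt$survival),
      lifetime_fecundity = lifetime_fecundity(mt$fecundity)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out,
    scenario = p$scenario, h_ext = p$h_ext, seed = sim$seed,
    status = sim$status, .before = 1
  )
  proportion_transform(out, p$k, p$m)
}

#' Write a replicate's outputs to plain-text files
#'
#' Writes `summary.csv` (per-caste outcome measures), `curves.csv`
#' (long-format mean trait curves), `timeseries.csv` (checkpointed curves),
#' `final_genomes.csv` (per-individual allele values, flat-index header) and
#' `params.json`-style `params.yaml` (resolved configuration) to `dir`.
#'
#' @param sim A `caste_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_replicate <- function(sim, dir) {
  stopifnot(inherits(sim, "caste_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("summary.csv", "curves.csv", "timeseries.csv",
                            "final_genomes.csv", "params.yaml"))
  utils::write.csv(sim$summary, paths[1], row.names = FALSE)
  utils::write.csv(trait_curves(sim), paths[2], row.names = FALSE)
  utils::write.csv(sim$timeseries, paths[3], row.names = FALSE)
  g <- sim$genomes
  dump <- rbind(
    genome_dump_rows(g$queen_a, g$queen_b, g$queen_age, g$queen_colony, "queen"),
    genome_dump_rows(g$worker_a, g$worker_b, g$worker_age, g$worker_colony, "worker")
  )
  utils::write.csv(dump, paths[4], row.names = FALSE)
  meta <- sim$params
  class(meta) <- NULL
  meta$seed <- sim$seed
  meta$status <- sim$status
  yaml::write_yaml(meta, paths[5])
  invisible(paths)
}

genome_dump_rows <- function(A, B, age, colony, caste) {
  if (is.null(A) || nrow(A) == 0) return(NULL)
  data.frame(caste = caste, colony = colony, age = age,
             copy = rep(c("a", "b"), each = nrow(A)),
             rbind(as.data.frame(A), as.data.frame(B)),
             check.names = FALSE)
}
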