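#' Deterministic replicate seed for a grid cell
#'
#' Derives the seed of replicate `replicate` in cell
#' `(scenario, h_ext, rho, delay)` from the master seed by a fixed integer
#' hash. Seeds are cell-addressed, never order-addressed, so permuting the
#' execution order of grid cells cannot change any result.
#'
#' @param master_seed Integer master seed.
#' @param scenario Scenario name.
#' @param h_ext Extrinsic hazard of the cell.
#' @param replicate Replicate number within the cell.
#' @param rho,delay Remaining cell coordinates.
#' @return A positive integer seed below 2^31.
#' @export
cell_seed <- function(master_seed, scenario, h_ext, replicate,
                      rho = -0.8, delay = 5) {
  key <- paste(scenario, format(h_ext, digits = 10), format(rho, digits = 10),
               delay, replicate, sep = "|")
  p <- 2147480009 # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% p
  as.integer((h + (as.double(master_seed) %% p) * 7919) %% p) + 1L
}

#' Run a replicated scenario x extrinsic-mortality experiment grid
#'
#' Runs `replicates` independent simulations for every combination of
#' `scenarios` and `h_ext` values (optionally crossed with `rho` and `delay`
#' sweeps) and aggregates the evolved outcome measures. Aggregates are order
#' statistics (median, min, max) over replicate values and are recomputable
#' from the returned per-replicate table.
#'
#' @param scenarios Character vector, subset of [scenario_names()].
#' @param h_ext Numeric vector of extrinsic hazard probabilities.
#' @param replicates Replicates per cell; defaults to the preset's value.
#' @param preset `"desk"` (100 colonies, 5e4 steps, 5 replicates) or
#'   `"full"` (1000 colonies, 1e6 steps, 20 replicates); see [sim_preset()].
#' @param master_seed Integer master seed; replicate seeds come from
#'   [cell_seed()].
#' @param rho,delay Vectors swept as additional grid dimensions.
#' @param ... Further arguments passed to [sim_params()] (e.g. `mu`, `b`,
#'   `N`, `T` to override the preset).
#' @return An object of class `caste_grid`: list with `replicates` (tibble,
#'   one row per replicate x caste), `aggregate` (per-cell x caste medians
#'   and ranges), `runs` (the `caste_sim` objects, named by cell and
#'   replicate), `master_seed` and the resolved base parameters.
#' @examples
#' \donttest{
#' g <- run_grid(c("baseline", "BCWT"), h_ext = 0, replicates = 2,
#'               N = 30, T = 2000, master_seed = 1)
#' g$aggregate
#' }
#' @export
run_grid <- function(scenarios = scenario_names(), h_ext = c(0, 0.2),
                     replicates = NULL, preset = "desk", master_seed = 1,
                     rho = -0.8, delay = 5, ...) {
  scenarios <- vapply(scenarios, match_scenario, character(1))
  pre <- sim_preset(preset)
  if (is.null(replicates)) replicates <- pre$replicates
  dots <- list(...)
  base <- list(N = pre$N, T = pre$T)
  base[names(dots)] <- dots

  cells <- tidyr::expand_grid(scenario = scenarios, h_ext = h_ext,
                              rho = rho, delay = delay,
                              replicate = seq_len(replicates))
  runs <- purrr::pmap(cells, function(scenario, h_ext, rho, delay, replicate) {
    args <- c(list(scenario = scenario, h_ext = h_ext, rho = rho,
                   delay = delay), base)
    params <- do.call(sim_params, args)
    run_replicate(params,
                  seed = cell_seed(master_seed, scenario, h_ext, replicate,
                                   rho = rho, delay = delay))
  })
  names(runs) <- sprintf("%s_h%s_rho%s_d%s_r%d", cells$scenario,
                         cells$h_ext, cells$rho, cells$delay, cells$replicate)

  rep_tbl <- purrr::map2(runs, cells$replicate, function(sim, r) {
    dplyr::mutate(sim$summary, replicate = r, rho = sim$params$rho,
                  delay = sim$params$delay, .after = "h_ext")
  }) |> dplyr::bind_rows()

  agg <- rep_tbl |>
    dplyr::filter(.data$status == "completed") |>
    dplyr::group_by(.data$scenario, .data$h_ext, .data$rho, .data$delay,
                    .data$caste) |>
    dplyr::summarise(
      dplyr::across(
        c("life_expectancy", "lifetime_fecundity",
          "lifespan_proportion", "fecundity_proportion"),
        list(median = ~ median(.x, na.rm = TRUE),
             min = ~ min(.x, na.rm = TRUE),
             max = ~ max(.x, na.rm = TRUE))
      ),
      n_replicates = dplyr::n(), .groups = "drop"
    )

  structure(
    list(replicates = rep_tbl, aggregate = agg, runs = runs,
         master_seed = master_seed, base = base,
         extinctions = sum(rep_tbl$status != "completed") / 2),
    class = "caste_grid"
  )
}

#' @export
print.caste_grid <- function(x, ...) {
  cells <- dplyr::distinct(x$replicates, .data$scenario, .data$h_ext,
                           .data$rho, .data$delay)
  cat("<caste_grid>", nrow(cells), "cell(s),",
      length(x$runs), "replicate run(s), master seed", x$master_seed, "\n")
  if (x$extinctions > 0) cat("  ", x$extinctions, "replicate(s) ended early\n")
  print(x$aggregate, n = 20)
  invisible(x)
}

#' @export
tidy.caste_grid <- function(x, ...) x$replicates

#' @export
glance.caste_grid <- function(x, ...) {
  tibble::tibble(
    cells = nrow(dplyr::distinct(x$replicates, .data$scenario, .data$h_ext,
                                 .data$rho, .data$delay)),
    runs = length(x$runs),
    extinctions = x$extinctions,
    master_seed = x$master_seed
  )
}

#' Queen-worker divergence table of an aggregated grid
#'
#' Per grid cell: the difference and ratio of median queen and worker life
#' expectancies, and the number of replicates in which the queen outlived
#' the worker caste.
#'
#' @param grid A `caste_grid` (or its per-replicate tibble).
#' @return Tibble with one row per cell: `queen_minus_worker`,
#'   `queen_worker_ratio`, `n_queen_longer`, `n_replicates`.
#' @export
compare_castes <- function(grid) {
  rep_tbl <- if (inherits(grid, "caste_grid")) grid$replicates else grid
  stopifnot(is.data.frame(rep_tbl),
            all(c("caste", "life_expectancy") %in% names(rep_tbl)))
  wide <- rep_tbl |>
    dplyr::select(dplyr::any_of(c("scenario", "h_ext", "rho", "delay",
                                  "replicate")),
                  "caste", "life_expectancy") |>
    tidyr::pivot_wider(names_from = "caste", values_from = "life_expectancy")
  if (!all(c("queen", "worker") %in% names(wide))) {
    stop("both castes must be present in the summary table", call. = FALSE)
  }
  wide |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("scenario", "h_ext",
                                                  "rho", "delay")))) |>
    dplyr::summarise(
      queen_minus_worker = median(.data$queen - .data$worker),
      queen_worker_ratio = median(.data$queen / .data$worker),
      n_queen_longer = sum(.data$queen > .data$worker),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Plot an aggregated grid as dot-range panels
#'
#' Median evolved life expectancy (or fecundity) per scenario and caste,
#' with error bars spanning the replicate range.
#'
#' @param object A `caste_grid`.
#' @param measure `"life_expectancy"` or `"lifetime_fecundity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.caste_grid <- function(object, measure = c("life_expectancy",
                                                    "lifetime_fecundity"),
                                ...) {
  measure <- match.arg(measure)
  agg <- object$aggregate
  ggplot2::ggplot(agg, ggplot2::aes(.data$scenario,
                                    .data[[paste0(measure, "_median")]],
                                    colour = .data$caste)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data[[paste0(measure, "_min")]],
                   ymax = .data[[paste0(measure, "_max")]]),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(~h_ext, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "scenario", y = gsub("_", " ", measure))
}
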