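#' Run one replicate of the colony-population simulation
#'
#' Advances a fixed-size population of `N` monogynous colonies through `T`
#' discrete time steps. Each step executes, in order: per-colony
#' reproduction (queen time allocation, Poisson offspring, mutated gamete
#' transmission, one haploid male egg per diploid egg), Bernoulli survival
#' and ageing with maximum-age death, collapse of queenless colonies,
#' requeening of vacant slots from hatching eggs sampled proportionally to
#' per-colony egg counts (the new queen mates with a uniformly random male
#' from this step's male pool), and hatching of the remaining eggs into
#' age-1 workers. Eggs develop for one time step before hatching; males
#' mature and die within their production step.
#'
#' A run halts early, with the step recorded, if the population goes extinct
#' or a new queen finds no male to mate with.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; one seeded RNG stream drives the whole
#'   replicate.
#' @return An object of class `caste_sim`: a list with `params`, `seed`,
#'   `status` (`"completed"`, `"extinct"` or `"no_males"`), `steps_run`,
#'   `architecture` (with any positive-definiteness repair recorded),
#'   checkpointed `timeseries` (tibble), final `genomes` (queen and worker
#'   allele matrices with ages and colony ids), requeening counters, the
#'   per-caste `summary` tibble and a quasi-equilibrium flag.
#' @examples
#' p <- sim_params(N = 20, T = 200, checkpoint_every = 50)
#' sim <- run_replicate(p, seed = 1)
#' tidy(sim)
#' @export
run_replicate <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  seed <- as.integer(seed)
  arch <- mutation_architecture(params$scenario, k = params$k, rho = params$rho,
                                delay = params$delay, b = params$b,
                                sigma = params$sigma)
  set.seed(seed)
  raw <- run_sim_cpp(
    N = params$N, T = params$T, k = params$k, h_ext = params$h_ext,
    mu = params$mu, m = params$m, init_value = params$init_value,
    b = params$b, root = arch$root, recombine = params$recombine,
    checkpoint_every = params$checkpoint_every,
    check_invariants = params$check_invariants
  )
  status <- c("completed", "extinct", "no_males")[raw$status + 1L]
  lab <- trait_labels(arch$layout)
  colnames(raw$queen_a) <- colnames(raw$queen_b) <- lab
  colnames(raw$queen_sperm) <- lab
  if (nrow(raw$worker_a) > 0) colnames(raw$worker_a) <- colnames(raw$worker_b) <- lab

  sim <- structure(
    list(
      params = params, seed = seed, status = status,
      steps_run = raw$steps_run,
      architecture = arch,
      timeseries = timeseries_tibble(raw$timeseries, arch$layout, params$m),
      genomes = list(
        queen_a = raw$queen_a, queen_b = raw$queen_b,
        queen_sperm = raw$queen_sperm,
        queen_age = raw$queen_age, queen_colony = raw$queen_colony,
        queen_workers = raw$queen_workers,
        worker_a = raw$worker_a, worker_b = raw$worker_b,
        worker_age = raw$worker_age, worker_colony = raw$worker_colony
      ),
      requeen_events = raw$requeen_events,
      requeen_fallback = raw$requeen_fallback
    ),
    class = "caste_sim"
  )
  sim$summary <- summarize_replicate(sim)
  sim$quasi_equilibrium <- quasi_equilibrium(sim)
  sim
}

# wide checkpoint matrix from the core -> long tibble
timeseries_tibble <- function(ts, layout, m) {
  k <- layout$k
  base <- tibble::tibble(step = ts[, 1], n_queens = ts[, 2], n_workers = ts[, 3])
  vals <- ts[, -(1:3), drop = FALSE]
  colnames(vals) <- paste(
    rep(c("queen", "queen", "worker", "worker"), each = k),
    rep(c("survival", "fecundity", "survival", "fecundity"), each = k),
    rep(seq_len(k), times = 4), sep = "."
  )
  dplyr::bind_cols(base, tibble::as_tibble(vals)) |>
    tidyr::pivot_longer(-c("step", "n_queens", "n_workers"),
                        names_to = c("caste", "trait", "age"), names_sep = "\\.",
                        values_to = "value") |>
    dplyr::mutate(age = as.integer(.data$age))
}

#' @export
print.caste_sim <- function(x, ...) {
  cat("<caste_sim>", x$params$scenario,
      sprintf("h_ext = %g, N = %d, T = %g, seed = %d\n",
              x$params$h_ext, x$params$N, as.double(x$params$T), x$seed))
  cat("  status:", x$status, "after", x$steps_run, "steps;",
      length(x$genomes$queen_age), "queens,",
      length(x$genomes$worker_age), "workers alive\n")
  le <- x$summary
  cat(sprintf("  life expectancy: queen %.2f, worker %.2f (max %d)\n",
              le$life_expectancy[le$caste == "queen"],
              le$life_expectancy[le$caste == "worker"], x$params$k))
  invisible(x)
}

# Checkpointed life expectancies change < 2% over the final 10% of steps?
quasi_equilibrium <- function(sim, window = 0.1, tol = 0.02) {
  ts <- sim$timeseries
  le <- ts |>
    dplyr::filter(.data$trait == "survival", !is.na(.data$value)) |>
    dplyr::group_by(.data$step, .data$caste) |>
    dplyr::summarise(le = sum(cumprod(.data$value[order(.data$age)])),
                     .groups = "drop")
  cut <- (1 - window) * sim$steps_run
  tail <- dplyr::filter(le, .data$step >= cut)
  if (length(unique(tail$step)) < 2) return(NA)
  chg <- tail |>
    dplyr::group_by(.data$caste) |>
    dplyr::summarise(rel = diff(range(.data$le)) / max(.data$le, 1e-12),
                     .groups = "drop")
  all(chg$rel < tol)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @rdname run_replicate
#' @param x A `caste_sim` object.
#' @param ... Unused.
tidy.caste_sim <- function(x, ...) x$summary

#' @export
#' @rdname run_replicate
glance.caste_sim <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    scenario = x$params$scenario, h_ext = x$params$h_ext,
    N = x$params$N, T = as.double(x$params$T), k = x$params$k,
    seed = x$seed, status = x$status, steps_run = x$steps_run,
    n_queens = length(x$genomes$queen_age),
    n_workers = length(x$genomes$worker_age),
    requeen_events = x$requeen_events,
    requeen_fallback = x$requeen_fallback,
    repair_fired = x$architecture$repair$fired,
    quasi_equilibrium = x$quasi_equilibrium,
    queen_life_expectancy = s$life_expectancy[s$caste == "queen"],
    worker_life_expectancy = s$life_expectancy[s$caste == "worker"],
    queen_lifetime_fecundity = s$lifetime_fecundity[s$caste == "queen"]
  )
}

#' Plot a replicate's evolved mean trait curves
#'
#' Final population-mean intrinsic survival (and optionally fecundity)
#' curves by caste.
#'
#' @param object A `caste_sim`.
#' @param trait `"survival"`, `"fecundity"` or `"both"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.caste_sim <- function(object, trait = c("survival", "fecundity", "both"),
                               ...) {
  trait <- match.arg(trait)
  cur <- trait_curves(object)
  if (trait != "both") cur <- dplyr::filter(cur, .data$trait == !!trait)
  p <- ggplot2::ggplot(cur, ggplot2::aes(.data$age, .data$value,
                                         colour = .data$caste)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "age class", y = "population mean trait value",
      title = sprintf("%s, h_ext = %g (after %g steps)",
                      object$params$scenario, object$params$h_ext,
                      as.double(object$steps_run))
    )
  if (trait == "both") p <- p + ggplot2::facet_wrap(~trait, scales = "free_y")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Final population-mean trait curves of a replicate
#'
#' @param sim A `caste_sim`.
#' @return Long tibble: `caste`, `trait`, `age`, `value`.
#' @export
trait_curves <- function(sim) {
  stopifnot(inherits(sim, "caste_sim"))
  k <- sim$params$k
  rows <- list()
  for (caste in c("queen", "worker")) {
    mt <- try(population_mean_traits(sim, caste), silent = TRUE)
    if (inherits(mt, "try-error")) next
    rows[[caste]] <- tibble::tibble(
      caste = caste,
      trait = rep(c("survival", "fecundity"), each = k),
      age = rep(seq_len(k), 2),
      value = c(mt$survival, mt$fecundity)
    )
  }
  dplyr::bind_rows(rows)
}
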