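#' Found a diploid genome with uniform genetic values
#'
#' Populations are initialised with individuals that all carry the same
#' genetic value at every caste x trait x age position on both copies of the
#' gene-regulatory network, so queens and workers start with identical
#' age-specific survival and fecundity curves.
#'
#' @param k Number of age classes.
#' @param init_value Genetic value placed at every position of both copies
#'   (default 0, giving survival 0.5 and fecundity `m/2` everywhere).
#' @return An object of class `diploid_genome`: list with haploid vectors
#'   `a` and `b` (length `4k`) and the shared [trait_layout()].
#' @examples
#' g <- founder_genome(k = 20)
#' express(g, "queen")$survival[1]  # 0.5
#' @export
founder_genome <- function(k, init_value = 0) {
  stopifnot(is.numeric(init_value), length(init_value) == 1L, is.finite(init_value))
  lay <- trait_layout(k)
  diploid_genome(rep(init_value, lay$n), rep(init_value, lay$n), lay)
}

#' Construct a diploid genome from two haploid networks
#'
#' @param a,b Numeric vectors of length `4k`: the two haploid
#'   gene-regulatory-network copies, in [trait_layout()] order.
#' @param layout The shared [trait_layout()]; inferred from `length(a)` when
#'   missing.
#' @return An object of class `diploid_genome`.
#' @export
diploid_genome <- function(a, b, layout = NULL) {
  if (is.null(layout)) {
    if (length(a) %% 4L != 0L) stop("haploid length must be a multiple of 4", call. = FALSE)
    layout <- trait_layout(length(a) %/% 4L)
  }
  stopifnot(inherits(layout, "trait_layout"))
  if (length(a) != layout$n || length(b) != layout$n) {
    stop("both genome copies must have length 4k for a shared layout", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("genetic values must be finite", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), layout = layout),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("<diploid_genome> k =", x$layout$k, "age classes;",
      "allelic sums in [", sprintf("%.3g", min(x$a + x$b)), ",",
      sprintf("%.3g", max(x$a + x$b)), "]\n")
  invisible(x)
}

#' Express a diploid genome into caste-specific traits
#'
#' The two allelic values at each position interact additively; the allelic
#' sum `x` is mapped through a logistic function to the trait scale:
#' survival probability `1 / (1 + exp(-x))` and fecundity
#' `m / (1 + exp(-x))`. Expression is caste-specific: a queen reads only the
#' queen blocks of the network, a worker only the worker blocks (worker
#' fecundity is expressed for completeness but unused by colony dynamics,
#' since workers are sterile).
#'
#' @param genome A [diploid_genome()].
#' @param caste `"queen"` or `"worker"`.
#' @param m Maximum fecundity per age class (default 5).
#' @return List with numeric vectors `survival` (in `[0, 1]`) and
#'   `fecundity` (in `[0, m]`), each of length `k`.
#' @examples
#' g <- founder_genome(20, init_value = 0)
#' express(g, "worker", m = 5)$fecundity[1]  # 2.5
#' @export
express <- function(genome, caste, m = 5) {
  stopifnot(inherits(genome, "diploid_genome"))
  caste <- match.arg(caste, c("queen", "worker"))
  stopifnot(is.numeric(m), length(m) == 1L, m > 0)
  lay <- genome$layout
  x <- genome$a + genome$b
  idx_s <- trait_index(lay, caste, "survival", seq_len(lay$k))
  idx_f <- trait_index(lay, caste, "fecundity", seq_len(lay$k))
  list(survival = logistic(x[idx_s]), fecundity = m * logistic(x[idx_f]))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Form a gamete from a diploid genome
#'
#' By default one of the two whole network copies is transmitted, chosen
#' uniformly at random (networks are inherited as units). With
#' `recombine = TRUE` each position independently takes the value of either
#' copy with probability 1/2 (free recombination), for sensitivity checks.
#'
#' @param genome A [diploid_genome()].
#' @param recombine Logical; per-position free recombination instead of
#'   whole-network transmission.
#' @return Numeric haploid vector of length `4k`.
#' @export
make_gamete <- function(genome, recombine = FALSE) {
  stopifnot(inherits(genome, "diploid_genome"))
  if (!recombine) {
    if (stats::runif(1) < 0.5) genome$a else genome$b
  } else {
    pick_a <- stats::runif(genome$layout$n) < 0.5
    ifelse(pick_a, genome$a, genome$b)
  }
}

#' Mutate a transmitted haploid network
#'
#' After transmission a network mutates with probability `mu`; a mutation is
#' a single draw of correlated, biased effects from the architecture's
#' multivariate normal, added to all `4k` positions at once. At most one
#' mutation event occurs per transmission.
#'
#' @param gamete Numeric haploid vector of length `4k`.
#' @param mu Mutation probability per transmission, in `[0, 1]`.
#' @param architecture A [mutation_architecture()] with matching `k`.
#' @return The (possibly mutated) haploid vector.
#' @export
mutate_gamete <- function(gamete, mu, architecture) {
  stopifnot(inherits(architecture, "mutation_architecture"),
            is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1,
            length(gamete) == architecture$layout$n)
  if (mu > 0 && stats::runif(1) < mu) {
    gamete + sample_mutation(architecture)
  } else {
    gamete
  }
}
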