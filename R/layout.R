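#' Caste x trait x age index layout of a gene-regulatory network
#'
#' A haploid gene-regulatory network holds `4 * k` real-valued regulatory
#' values: one per combination of caste (queen, worker), trait (survival,
#' fecundity) and age class `1..k`. The flat layout is fixed as four
#' consecutive blocks of length `k`:
#' queen survival, queen fecundity, worker survival, worker fecundity.
#' All matrices (partial correlations, mutational covariances) and all genome
#' vectors in the package use this order.
#'
#' @param k Number of age classes (positive integer).
#' @return An object of class `trait_layout`: a list with `k`, `n` (`= 4k`),
#'   the block order, and per-position `caste`, `trait` and `age` vectors.
#' @examples
#' lay <- trait_layout(20)
#' trait_index(lay, "worker", "survival", 3)
#' @export
trait_layout <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("`k` must be a single positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  blocks <- c("queen_survival", "queen_fecundity", "worker_survival", "worker_fecundity")
  structure(
    list(
      k = k,
      n = 4L * k,
      blocks = blocks,
      caste = rep(c("queen", "queen", "worker", "worker"), each = k),
      trait = rep(c("survival", "fecundity", "survival", "fecundity"), each = k),
      age = rep(seq_len(k), times = 4L)
    ),
    class = "trait_layout"
  )
}

#' @export
print.trait_layout <- function(x, ...) {
  cat("<trait_layout> k =", x$k, "age classes,", x$n, "positions\n")
  cat("block order:", paste(x$blocks, collapse = ", "), "\n")
  invisible(x)
}

#' Flat index of a (caste, trait, age) position
#'
#' @param layout A [trait_layout()].
#' @param caste `"queen"` or `"worker"` (vectorised).
#' @param trait `"survival"` or `"fecundity"` (vectorised).
#' @param age Age class in `1..k` (vectorised).
#' @return Integer flat indices in `1..4k`.
#' @export
trait_index <- function(layout, caste, trait, age) {
  stopifnot(inherits(layout, "trait_layout"))
  caste <- match.arg(caste, c("queen", "worker"), several.ok = TRUE)
  trait <- match.arg(trait, c("survival", "fecundity"), several.ok = TRUE)
  if (any(age < 1 | age > layout$k | age != round(age))) {
    stop("`age` must be in 1..k", call. = FALSE)
  }
  block <- 2L * (caste == "worker") + (trait == "fecundity")
  as.integer(block * layout$k + age)
}

#' Recover (caste, trait, age) from a flat index
#'
#' @param layout A [trait_layout()].
#' @param index Flat indices in `1..4k`.
#' @return A tibble with columns `index`, `caste`, `trait`, `age`.
#' @export
trait_position <- function(layout, index) {
  stopifnot(inherits(layout, "trait_layout"))
  index <- as.integer(index)
  if (any(index < 1L | index > layout$n)) stop("`index` out of range", call. = FALSE)
  tibble::tibble(
    index = index,
    caste = layout$caste[index],
    trait = layout$trait[index],
    age = layout$age[index]
  )
}

#' Position labels ("Q_surv_a1", ...) for matrix headers and genome dumps
#'
#' @param layout A [trait_layout()].
#' @return Character vector of length `4k`.
#' @export
trait_labels <- function(layout) {
  stopifnot(inherits(layout, "trait_layout"))
  code <- c(queen = "Q", worker = "W")[layout$caste]
  tr <- c(survival = "surv", fecundity = "fec")[layout$trait]
  paste0(code, "_", tr, "_a", layout$age)
}
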