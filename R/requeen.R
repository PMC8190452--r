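#' Egg-weighted colony sampling (requeening kernel)
#'
#' Samples one index with probability proportional to the given
#' non-negative weights. This is the exact routine the simulator uses to
#' pick the source colony of a new queen, with weights equal to per-colony
#' hatching-egg counts; it is exported so the weighting can be audited
#' directly. Uses R's global random number stream.
#'
#' @param weights Non-negative, finite numeric weights with a positive sum.
#' @return A single integer index in `1..length(weights)`.
#' @examples
#' set.seed(1)
#' table(replicate(1000, sample_weighted_index(c(3, 1))))
#' @export
sample_weighted_index <- function(weights) {
  sample_weighted_index_cpp(as.numeric(weights))
}
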