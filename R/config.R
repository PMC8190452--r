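#' Read a simulation configuration from a YAML file
#'
#' The file may contain any [sim_params()] argument plus, optionally,
#' `replicates` and `master_seed` (used by the command-line batch runner).
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with `params` (a validated [sim_params()] object),
#'   `replicates` and `master_seed`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file must contain a YAML mapping", call. = FALSE)
  extra <- c("replicates", "master_seed")
  allowed <- c(names(formals(sim_params)), extra)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(
    params = do.call(sim_params, cfg[setdiff(names(cfg), extra)]),
    replicates = if (!is.null(cfg$replicates)) as.integer(cfg$replicates) else 1L,
    master_seed = if (!is.null(cfg$master_seed)) as.integer(cfg$master_seed) else 1L
  )
}
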