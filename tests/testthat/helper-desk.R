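# Desk-scale replicate runs are shared between the acceptance tests that
# need them (several contrasts are measured against the same baseline
# cells). Computed lazily, once per test session.
.desk_cache <- new.env(parent = emptyenv())

desk_cell <- function(scenario, h_ext, master_seed = 1) {
  key <- sprintf("%s|%g|%d", scenario, h_ext, master_seed)
  if (is.null(.desk_cache[[key]])) {
    pre <- sim_preset("desk")
    reps <- lapply(seq_len(pre$replicates), function(r) {
      params <- sim_params(N = pre$N, T = pre$T, scenario = scenario,
                           h_ext = h_ext)
      tidy(run_replicate(params, seed = cell_seed(master_seed, scenario,
                                                  h_ext, r)))
    })
    .desk_cache[[key]] <- dplyr::bind_rows(reps, .id = "replicate")
  }
  .desk_cache[[key]]
}

desk_measure <- function(tbl, caste, col) {
  tbl[[col]][tbl$caste == caste]
}
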