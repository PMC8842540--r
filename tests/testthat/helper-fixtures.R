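# Shared, lazily cached toy fixtures (building the toy reference repeatedly
# would dominate test runtime).
.fx <- new.env(parent = emptyenv())

fx_reference <- function() {
  if (is.null(.fx$ref)) .fx$ref <- toy_rdna_reference()
  .fx$ref
}

fx_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- toy_snv_panel(fx_reference())
  .fx$panel
}

fx_truth <- function(seed = 42L) {
  key <- paste0("truth_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_ground_truth(
      simulation_config(seed = as.integer(seed)), fx_reference())
  .fx[[key]]
}

fx_bs <- function(seed = 42L, depth = 60) {
  key <- paste0("bs_", seed, "_", depth)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- simulate_bisulfite_reads(fx_truth(seed), fx_panel(),
                                           depth = depth)
  .fx[[key]]
}

# Minimal hand-built bs_obs for unit-scale blink tests.
make_bs <- function(reads, snv_calls, cpg_calls, panel = fx_panel(),
                    reference = fx_reference()) {
  structure(list(reads = reads, snv_calls = snv_calls, cpg_calls = cpg_calls,
                 panel = panel, reference = reference), class = "bs_obs")
}
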