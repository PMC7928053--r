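# Shared fixtures, built once per test run (generation is deterministic).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

fixture_model <- function() memo("planar", planar_arm_model)

fixture_cc_muscles <- function() c("ELFLX", "ELEXT", "BIFLX", "BIEXT")

# 4 s / 200 node (50 Hz) planar reference without co-contraction
fixture_ref <- function() memo("planar_ref", function() {
  generate_reference(fixture_model(), duration = 4, n_nodes = 200,
                     cocontraction = "none",
                     cocontraction_muscles = character())
})

fixture_ref_cc <- function(level) memo(paste0("planar_ref_", level), function() {
  generate_reference(fixture_model(), duration = 4, n_nodes = 200,
                     cocontraction = level,
                     cocontraction_muscles = fixture_cc_muscles())
})

arm_fixture <- function() memo("arm", arm_model)

# desk-scale 2 s / 200 node (100 Hz) arm references
arm_ref <- function(level = "mid") memo(paste0("arm_ref_", level), function() {
  generate_reference(arm_fixture(), duration = 2, n_nodes = 200,
                     cocontraction = level)
})

random_q <- function(model, n = 1) {
  cmod <- compile_model(model)
  span <- cmod$qmax - cmod$qmin
  t(vapply(seq_len(n), function(i)
    cmod$qmin + 0.1 * span + 0.8 * span * runif(cmod$nq),
    numeric(cmod$nq)))
}
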