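# shared fixtures; built once per test run
kv_test_env <- new.env(parent = emptyenv())

test_spectrum <- function() {
  if (is.null(kv_test_env$spectrum)) kv_test_env$spectrum <- tube_spectrum(80)
  kv_test_env$spectrum
}

# minimal hand-built transport-result stand-in for the pure accessor tests
fake_slab_result <- function(cell_dose, materials = NULL, segments = NULL,
                             energy_hist = NULL, hist_materials = "water") {
  n <- length(cell_dose)
  if (is.null(materials)) materials <- rep("water", n)
  ph <- slab_phantom(materials, segments = segments)
  eh <- energy_hist
  if (is.null(eh)) {
    eh <- matrix(0, nrow = 2000, ncol = length(hist_materials),
                 dimnames = list(NULL, hist_materials))
  }
  structure(list(
    is_slab = TRUE, phantom = ph,
    cell_dose = cell_dose, cell_dose_stderr = rep(0, n),
    depth_mm = (seq_len(n) - 0.5) * 0.1,
    electron_energy_keV = (seq_len(nrow(eh)) - 0.5) * 0.05,
    electron_energy_hist = eh), class = "kv_transport_result")
}
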