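# tiny configurations shared across tests; built in code, never stored

tiny_config <- function(n = 5, C = 1, seed = 1, ...) {
  network_config(nE = n, nI = 0, C = C, n_engrams = 0, engram_size = 1,
                 seed = seed, ...)
}

# small E-I network used for simulator-level tests (fast: ~120 neurons)
small_ei_config <- function(C = 0.25, n_engrams = 0, seed = 1, ...) {
  network_config(nE = 100, nI = 20, C = C, n_engrams = n_engrams,
                 engram_size = 20, g_EE = 0.02, g_IE = 0.41, g_EI = 0.56,
                 g_II = 0.14, g_M_EE = 0.68, g_O_E = 0.082, g_O_I = 0.172,
                 seed = seed, ...)
}
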