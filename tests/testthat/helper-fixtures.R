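# Shared fixtures: exact Michaelis-Menten panels and standard truths.

`%||%` <- function(a, b) if (is.null(a)) b else a

S_GRID <- c(80, 125, 200, 330, 500)
I_GRID <- c(0, 2.5, 5, 10)

# Exact (noiseless) single-concentration MM panel.
exact_panel <- function(Km = 100, Vmax = 10, S = S_GRID, I = 0) {
  data.frame(S_uM = S, I_uM = I, v0 = Vmax * S / (Km + S), replicate = 1L)
}

make_truth <- function(mechanism, Ki_c = NULL, Ki_u = NULL, noise_cv = 0,
                       seed = 1L, Km = 100, Vmax = 10) {
  inhibition_truth(mechanism, Km = Km, Vmax = Vmax, Ki_c = Ki_c,
                   Ki_u = Ki_u, noise_cv = noise_cv, seed = seed)
}

# mm_fit stub for rule-lookup tests (exact parameters, negligible SEs).
mm_stub <- function(Km, Vmax, se = 1e-9, method = "nonlinear", I = 0) {
  structure(list(Km = Km, Vmax = Vmax, se_Km = se * Km, se_Vmax = se * Vmax,
                 r2_or_gof = 1, method = method, n_points = 15L, I_uM = I),
            class = "mm_fit")
}
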