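# Shared fixtures built in code.

flat_spectrum <- function(level = 1, wl = 310:320, ex = 295) {
  emission_spectrum(wl, rep(level, length(wl)), excitation_nm = ex)
}

gaussian_spectrum <- function(center = 328, sd = 25, amp = 1000,
                              wl = seq(310, 500, by = 1), ex = 295) {
  emission_spectrum(wl, amp * exp(-((wl - center)^2) / (2 * sd^2)),
                    excitation_nm = ex)
}

# Noiseless titration intensities from the accessible-fraction model.
forward_F <- function(Q_M, F0, f_a, K_SV) {
  F0 * ((1 - f_a) + f_a / (1 + K_SV * Q_M))
}

make_titration <- function(f_a = 1, K_SV = 2.5e4, F0 = 1000,
                           Q_uM = seq(0, 50, 5), tau0_ns = 2.5) {
  titration_series(Q_uM, forward_F(Q_uM * 1e-6, F0, f_a, K_SV),
                   tau0_ns = tau0_ns)
}

# Replicated probe readings for a two-group design.
probe_df <- function(values_by_group, control = "control") {
  do.call(rbind, lapply(names(values_by_group), function(g)
    data.frame(treatment = g,
               concentration_uM = if (g == control) 0 else 25,
               replicate = seq_along(values_by_group[[g]]),
               value = values_by_group[[g]])))
}
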