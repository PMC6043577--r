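# shared fixture builders (all synthetic, generated at test time)

# small noiseless two-state system and its dispersion dataset
small_noiseless_dataset <- function(n_residues = 5, seed = 3) {
  truth <- generate_two_state_system(n_residues = n_residues,
                                     noise_fraction = 0, seed = seed)
  tab <- generate_dispersion_intensities(truth, seed = seed)
  list(truth = truth, dataset = r2eff_from_intensities(tab))
}

# close-packed solid atom cluster (no cavity)
solid_cluster <- function(half_width = 4, spacing = 1.2) {
  g <- expand.grid(x = seq(-half_width, half_width, spacing),
                   y = seq(-half_width, half_width, spacing),
                   z = seq(-half_width, half_width, spacing))
  structure_coords(data.frame(element = "C", g, radius = 1.7))
}

# isotropic-rotor relaxation records for tau_c inversion tests
rotor_records <- function(tau_c, field_mhz, n = 10, noe_override = NULL) {
  r <- iso_rotor_rates(tau_c, field_mhz)
  data.frame(residue_id = sprintf("R%02d", seq_len(n)),
             r1 = rep(r$r1, n), r2 = rep(r$r2, n),
             het_noe = rep(if (is.null(noe_override)) r$noe else
               noe_override, n))
}
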