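# shared fixtures built in code

default_design <- incubation_design()

# a tiny noiseless transect + records, reused across files
noiseless_case <- function(n_sites = 3, seed = 101) {
  tr <- generate_transect(n_sites, seed = seed)
  rec <- simulate_incubation(tr, default_design,
                             noise_flux_rel = 0, noise_atom_abs = 0,
                             seed = seed)
  list(transect = tr, records = rec)
}

# write a small well-formed incubation CSV and return its path
write_incubation_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste("site_id", "bottle_id", "treatment", "replicate", "day",
                  "co2_conc_mmol_mol", "flux_ugC_g_d", "atom_pc",
                  "delta13c_permil", sep = ",")
  writeLines(c(header, rows), path)
  path
}
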