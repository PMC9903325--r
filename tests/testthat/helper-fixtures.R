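# Shared small fixtures, built in code at test time.

toy_spectrum <- function(mz, intensity, id = "toy", pmz = 500.25, z = 2L) {
  spectrum(id, pmz, z, peak_table(mz, intensity))
}

# noise-free annotated library entry for a peptide
clean_entry <- function(sequence = "PEPTIDESK", charge = 2L, mods = NULL,
                        tol_ppm = 20) {
  p <- peptide(sequence, charge, mods)
  frags <- theoretical_fragments(p, c("b", "y"), max_charge = min(2L, charge))
  sp <- spectrum(paste0("clean_", sequence), precursor_mz(p), charge,
                 peak_table(frags$mz, seq(1000, 100, length.out = nrow(frags))))
  annotate_spectrum(library_entry(p, sp, origin = "fixture"), tol_ppm)
}

small_fixture <- function(n = 30L, seed = 42L, ...) {
  cfg <- sim_config(n_peptides = n, seed = seed, ...)
  peps <- generate_peptides(cfg)
  lib <- build_fixture_library(peps, cfg)
  list(cfg = cfg, peptides = peps, library = lib)
}
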