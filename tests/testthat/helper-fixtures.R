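# Small fixtures built in code.

# The miR-2137 worked example: printed sequence and the two motif consensus
# strings it carries.
MIR2137_SEQ <- "GCCGGCGGGAGCCCCAGGGAG"

fixture_dir <- function() {
  system.file("extdata", "cisbp_synthetic", package = "mirsort")
}

fixture_motifs <- function() {
  read_cisbp_motifs(fixture_dir(), file.path(fixture_dir(), "rbp_info.tsv"))
}

# A tiny two-compartment profile pair with hand-set signals.
toy_profiles <- function(signals_cell, signals_sev,
                         p_cell = NULL, p_sev = NULL) {
  ids <- rownames(signals_cell)
  if (is.null(p_cell)) p_cell <- matrix(0.01, nrow(signals_cell),
                                        ncol(signals_cell))
  if (is.null(p_sev)) p_sev <- matrix(0.01, nrow(signals_sev),
                                      ncol(signals_sev))
  list(cell = abundance_profile("CELL", ids, signals_cell, p_cell),
       sev = abundance_profile("SEV", ids, signals_sev, p_sev))
}
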