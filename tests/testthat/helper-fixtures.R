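# minimal frontier-only record: one occupied + one virtual orbital
frontier_record <- function(label, homo, lumo, dipole = NULL) {
  qc_record(label, c(homo, lumo), c(TRUE, FALSE), dipole = dipole)
}

# record set carrying the nine reference structures' frontier energies and
# printed dipole magnitudes
reference_record_set <- function() {
  fo <- ref_frontier_orbitals()
  td <- ref_gap_tdm()
  record_set(lapply(seq_len(nrow(fo)), function(i) {
    frontier_record(fo$label[i], fo$homo[i], fo$lumo[i],
                    dipole = td$tdm[match(fo$label[i], td$label)])
  }))
}
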