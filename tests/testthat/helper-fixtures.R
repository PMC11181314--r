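# In-code fixtures shared across test files.

# Minimal well-level feature table: one plate, control values per feature
# given as a list of numeric vectors, plus one test well per compound.
make_wells <- function(controls, tests, dmso_percent = 0.1, plate = "P1") {
  feats <- names(controls)
  n_ctrl <- length(controls[[1]])
  ctrl_rows <- tibble::tibble(
    plate_id = plate,
    well = sprintf("A%02d", seq_len(n_ctrl)),
    compound_id = "DMSO",
    concentration_um = 0,
    role = "control",
    dmso_percent = dmso_percent
  )
  for (f in feats) ctrl_rows[[f]] <- controls[[f]]
  test_rows <- tibble::tibble(
    plate_id = plate,
    well = sprintf("B%02d", seq_len(nrow(tests))),
    compound_id = tests$compound_id,
    concentration_um = 10,
    role = "test",
    dmso_percent = dmso_percent
  )
  for (f in feats) test_rows[[f]] <- tests[[f]]
  dplyr::bind_rows(ctrl_rows, test_rows)
}

# Profile tibble straight from a Z matrix (rows = compounds).
make_profiles <- function(z, compound_ids = sprintf("C%03d", seq_len(nrow(z))),
                          cutoff = 3) {
  feats <- sprintf("f%03d", seq_len(ncol(z)))
  colnames(z) <- feats
  out <- dplyr::bind_cols(
    tibble::tibble(compound_id = compound_ids),
    tibble::as_tibble(z)
  )
  out$induction <- apply(z, 1, induction, cutoff = cutoff)
  attr(out, "features") <- feats
  out
}

# Independent Pearson-based oracle for biosimilarity.
oracle_biosim <- function(x, y) max(0, stats::cor(x, y)) * 100
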