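# Small in-code fixtures shared across test files.

make_decay_series <- function(residue = 1, i0 = 10, rate = 2,
                              delays = nmrdyn:::R1_DELAYS_S,
                              noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- i0 * exp(-rate * delays)
  if (noise > 0) y <- y * (1 + rnorm(length(delays), 0, noise))
  intensity_series(residue, "ALA", delays, y,
                   error = if (noise > 0) noise * i0 * exp(-rate * delays),
                   x_kind = "relaxation_delay")
}

write_tmp_intensity_table <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_shift_table <- function(residues = 1:3,
                            h = c(8.1, 8.5, 7.9), n = c(118.2, 121.0, 125.5)) {
  data.frame(residue = residues,
             residue_name = c("ALA", "GLY", "LEU")[seq_along(residues)],
             H_ppm = h[seq_along(residues)], N_ppm = n[seq_along(residues)])
}

# A tiny multi-model PDB with per-model coordinates supplied explicitly.
write_toy_pdb <- function(path, models) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- models[[m]]
    for (i in seq_len(nrow(at))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, sprintf(" %-3s", at$name[i]), at$resn[i], at$res[i],
        at$x[i], at$y[i], at$z[i], substr(at$name[i], 1, 1)), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

toy_atom_frame <- function(xyz, name = "CA", resn = "ALA") {
  data.frame(res = seq_len(nrow(xyz)), name = name, resn = resn,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
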