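AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Analysis configuration: spectrometer, physical constants, seeds
#'
#' Central configuration object shared by all fitting stages. Temperatures are
#' Kelvin internally (degrees Celsius only at file boundaries) and energies are
#' kcal/mol throughout.
#'
#' @param field_mhz Spectrometer 1H Larmor frequency in MHz.
#' @param r_nh N-H bond length in Angstrom used for the dipolar constant.
#' @param csa 15N chemical-shift anisotropy (Delta-sigma) in ppm; negative by
#'   convention for the backbone amide nitrogen.
#' @param temperature_k Sample temperature in Kelvin.
#' @param seed Integer seed recorded in every report and used for all
#'   Monte-Carlo uncertainty estimation.
#' @param mc_replicates Number of Monte-Carlo replicates for uncertainty
#'   estimation.
#' @param sw_h,sw_n Spectral widths (Hz) of the 1H and 15N dimensions, used to
#'   weight 15N shifts in chemical-shift displacement mapping.
#'
#' @return A list of class `nmr_config` with the above fields plus the gas
#'   constant `R_kcal` (kcal mol^-1 K^-1) and gyromagnetic ratios `gamma_h`,
#'   `gamma_n` (rad s^-1 T^-1).
#' @export
#' @examples
#' cfg <- nmr_config()
#' cfg$field_mhz
nmr_config <- function(field_mhz = 600.0, r_nh = 1.02, csa = -160,
                       temperature_k = 298.15, seed = 1L,
                       mc_replicates = 200L,
                       sw_h = 8000, sw_n = 2000) {
  stopifnot(field_mhz > 0, r_nh > 0, temperature_k > 0,
            sw_h > 0, sw_n > 0, mc_replicates >= 1)
  structure(list(
    field_mhz = field_mhz,
    r_nh = r_nh,
    csa = csa,
    temperature_k = temperature_k,
    seed = as.integer(seed),
    mc_replicates = as.integer(mc_replicates),
    sw_h = sw_h,
    sw_n = sw_n,
    R_kcal = 1.9872e-3,
    gamma_h = 2.6752218744e8,
    gamma_n = -2.71261804e7,
    # ratio of 15N to 1H Larmor frequencies, for ppm <-> rad/s conversion
    freq_ratio_n = 0.101329118
  ), class = "nmr_config")
}

#' @export
print.nmr_config <- function(x, ...) {
  cat("NMR analysis configuration\n")
  cat(sprintf("  field:       %.1f MHz (15N %.2f MHz)\n",
              x$field_mhz, x$field_mhz * x$freq_ratio_n))
  cat(sprintf("  r_NH:        %.3f A   CSA: %.0f ppm\n", x$r_nh, x$csa))
  cat(sprintf("  temperature: %.2f K\n", x$temperature_k))
  cat(sprintf("  seed: %d   MC replicates: %d\n", x$seed, x$mc_replicates))
  invisible(x)
}

validate_residue_keys <- function(residue, residue_name, where = "table") {
  if (any(residue < 1)) {
    stop("residue numbers must be >= 1 in ", where, call. = FALSE)
  }
  bad <- !(toupper(residue_name) %in% AA3)
  if (any(bad)) {
    stop("unknown residue name(s) in ", where, ": ",
         paste(unique(residue_name[bad]), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(residue)
  if (any(dup)) {
    stop("duplicate residue row(s) in ", where, ": ",
         paste(unique(residue[dup]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

X_KINDS <- c("relaxation_delay", "cpmg_field", "mixing_time", "exchange_time")

#' Read a per-residue intensity table
#'
#' Reads a delimited text table (tab- or comma-separated, auto-detected from
#' the header) with columns `residue`, `residue_name`, then one numeric-named
#' column per value of the independent variable (e.g. relaxation delay in
#' seconds or CPMG field in Hz). A repeated x column is kept as a replicate
#' pair and used downstream for error estimation. Optional error columns are
#' named `err_<x>`.
#'
#' @param path Path to the delimited file.
#' @param x_kind One of `"relaxation_delay"`, `"cpmg_field"`, `"mixing_time"`,
#'   `"exchange_time"`; declares the unit convention of the x columns
#'   (seconds for times, Hz for CPMG fields).
#' @return A list of `intensity_series` objects, one per residue, each with
#'   fields `residue`, `residue_name`, `x`, `intensity`, `error` (or `NULL`),
#'   `x_kind`.
#' @export
read_intensity_table <- function(path, x_kind) {
  x_kind <- match.arg(x_kind, X_KINDS)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cn <- names(df)
  if (!identical(cn[1:2], c("residue", "residue_name"))) {
    stop("intensity table must start with columns 'residue', 'residue_name'; got: ",
         paste(cn[1:2], collapse = ", "), call. = FALSE)
  }
  rest <- cn[-(1:2)]
  err_cols <- grepl("^err_", rest)
  x_raw <- rest[!err_cols]
  x_num <- suppressWarnings(as.numeric(x_raw))
  if (anyNA(x_num)) {
    stop("unparsable x column header(s): ",
         paste(x_raw[is.na(x_num)], collapse = ", "), call. = FALSE)
  }
  if (any(x_num < 0)) stop("x values must be non-negative", call. = FALSE)
  validate_residue_keys(df$residue, df$residue_name, where = basename(path))
  has_err <- any(err_cols)
  err_x <- if (has_err) as.numeric(sub("^err_", "", rest[err_cols])) else NULL

  lapply(seq_len(nrow(df)), function(i) {
    ints <- as.numeric(df[i, x_raw, drop = TRUE])
    if (any(ints < 0)) {
      warning("negative intensity for residue ", df$residue[i],
              "; value kept", call. = FALSE)
    }
    errs <- NULL
    if (has_err) {
      errs <- as.numeric(df[i, rest[err_cols], drop = TRUE])[match(x_num, err_x)]
    }
    intensity_series(residue = df$residue[i],
                     residue_name = toupper(df$residue_name[i]),
                     x = x_num, intensity = ints, error = errs,
                     x_kind = x_kind)
  })
}

#' Construct an intensity series for one residue
#'
#' @param residue Residue number (1-based, matching the structure numbering).
#' @param residue_name Three-letter residue code.
#' @param x Independent-variable values (seconds or Hz per `x_kind`).
#' @param intensity Peak intensities (arbitrary units).
#' @param error Optional per-point intensity uncertainties.
#' @param x_kind Kind of independent variable; see [read_intensity_table()].
#' @return An object of class `intensity_series`.
#' @export
intensity_series <- function(residue, residue_name, x, intensity,
                             error = NULL, x_kind = "relaxation_delay") {
  x_kind <- match.arg(x_kind, X_KINDS)
  stopifnot(length(x) == length(intensity), all(x >= 0))
  if (!is.null(error)) {
    stopifnot(length(error) == length(intensity))
    if (any(!is.na(error) & error <= 0)) stop("intensity errors must be positive")
  }
  structure(list(residue = as.integer(residue),
                 residue_name = toupper(residue_name),
                 x = as.numeric(x),
                 intensity = as.numeric(intensity),
                 error = if (is.null(error)) NULL else as.numeric(error),
                 x_kind = x_kind),
            class = "intensity_series")
}

#' Write intensity series back to a delimited table
#'
#' @param series List of `intensity_series` with identical x grids.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, the path.
#' @export
write_intensity_table <- function(series, path, sep = "\t") {
  x <- series[[1]]$x
  has_err <- !is.null(series[[1]]$error)
  mat <- t(vapply(series, function(s) s$intensity, numeric(length(x))))
  df <- data.frame(residue = vapply(series, `[[`, integer(1), "residue"),
                   residue_name = vapply(series, `[[`, character(1), "residue_name"))
  idf <- as.data.frame(mat)
  names(idf) <- as.character(x)
  df <- cbind(df, idf)
  if (has_err) {
    emat <- t(vapply(series, function(s) s$error, numeric(length(x))))
    edf <- as.data.frame(emat)
    names(edf) <- paste0("err_", x)
    df <- cbind(df, edf)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-residue chemical shift table
#'
#' Expects columns `residue`, `residue_name`, `H_ppm`, `N_ppm` in a tab- or
#' comma-separated file with dot-decimal numbers.
#'
#' @param path Path to the delimited file.
#' @return A data frame with columns `residue`, `residue_name`, `H_ppm`,
#'   `N_ppm`.
#' @export
read_shift_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("residue", "residue_name", "H_ppm", "N_ppm")
  if (!all(need %in% names(df))) {
    stop("shift table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("residue", "H_ppm", "N_ppm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' in column %s, row %d (dot decimal required)",
                   df[[col]][bad], col, bad), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$residue <- as.integer(df$residue)
  df$residue_name <- toupper(df$residue_name)
  validate_residue_keys(df$residue, df$residue_name, where = basename(path))
  out_of_range <- df$H_ppm < 5 | df$H_ppm > 12 | df$N_ppm < 100 | df$N_ppm > 135
  if (any(out_of_range)) {
    warning("shift(s) outside typical amide ranges for residue(s): ",
            paste(df$residue[out_of_range], collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Write a chemical shift table
#' @param shifts Data frame as returned by [read_shift_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return Invisibly, the path.
#' @export
write_shift_table <- function(shifts, path, sep = "\t") {
  utils::write.table(shifts, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a (possibly multi-model) PDB file as a structure ensemble
#'
#' Parses a standard PDB file through bio3d. Single-model files yield a
#' one-model ensemble. All models must share atom count and ordering;
#' insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @return An object of class `structure_ensemble`: list with `atoms` (data
#'   frame: residue, residue_name, atom, elety per atom), `xyz` (matrix,
#'   one row per model, 3*natom columns), `n_models`, `sequence` (three-letter
#'   codes by residue).
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (any(nzchar(trimws(pdb$atom$insert)) & !is.na(pdb$atom$insert))) {
    stop("insertion codes are not supported", call. = FALSE)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atoms <- data.frame(residue = pdb$atom$resno,
                      residue_name = pdb$atom$resid,
                      atom = pdb$atom$elety,
                      stringsAsFactors = FALSE)
  if (ncol(xyz) != 3 * nrow(atoms)) {
    stop("inconsistent atom sets across models: first model has ",
         ncol(xyz) / 3, " coordinates but atom table lists ", nrow(atoms),
         call. = FALSE)
  }
  res_idx <- !duplicated(atoms$residue)
  structure(list(atoms = atoms,
                 xyz = xyz,
                 n_models = nrow(xyz),
                 sequence = atoms$residue_name[res_idx],
                 residues = atoms$residue[res_idx]),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d model(s), %d atoms, %d residues\n",
              x$n_models, nrow(x$atoms), length(x$residues)))
  invisible(x)
}

#' Serialize a stage result to a self-describing JSON report
#'
#' Every report embeds the configuration block (including the random seed) and
#' the package version, so results are reproducible from the report alone.
#' Numbers are written at full precision; [load_results()] restores them to
#' better than 1e-10 relative.
#'
#' @param result Any stage result (named list / data frame tree).
#' @param path Output path for the JSON report.
#' @param config An `nmr_config` (recorded in the report).
#' @return Invisibly, the path.
#' @export
serialize_results <- function(result, path, config = nmr_config()) {
  payload <- list(
    software = list(package = "nmrdyn",
                    version = as.character(utils::packageVersion("nmrdyn"))),
    config = unclass(config),
    result = result
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load a serialized stage report
#' @param path Path written by [serialize_results()].
#' @return The full report list (`software`, `config`, `result`).
#' @export
load_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
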