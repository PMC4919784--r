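#' Weighted chemical-shift displacement between apo and bound states
#'
#' CSD = sqrt(ddH^2 + (w ddN)^2) per residue, with the 15N weight
#' w = SW_1H(ppm) / SW_15N(ppm) by default (ratio of the spectral widths of
#' the two dimensions expressed in ppm), or a fixed user-supplied weight.
#' Residues present in only one table are reported, not fatal.
#'
#' @param apo,holo Shift tables ([read_shift_table()] format).
#' @param config An [nmr_config()] providing SW_1H, SW_15N (Hz) and the
#'   spectrometer frequency for the ppm conversion.
#' @param weight Optional fixed 15N weight overriding the SW ratio
#'   (common fixed choices are 0.10-0.20).
#' @return List of class `csd_result`: `table` (residue, d_h, d_n, csd),
#'   `weight`, `unmatched` (residues missing from one table).
#' @export
compute_csd <- function(apo, holo, config = nmr_config(), weight = NULL) {
  m <- merge(apo, holo, by = "residue", suffixes = c("_apo", "_holo"))
  if (nrow(m) == 0) stop("no residues in common between tables", call. = FALSE)
  unmatched <- c(setdiff(apo$residue, holo$residue),
                 setdiff(holo$residue, apo$residue))
  if (is.null(weight)) {
    sw_h_ppm <- config$sw_h / config$field_mhz
    sw_n_ppm <- config$sw_n / (config$field_mhz * config$freq_ratio_n)
    weight <- sw_h_ppm / sw_n_ppm
  }
  d_h <- m$H_ppm_holo - m$H_ppm_apo
  d_n <- m$N_ppm_holo - m$N_ppm_apo
  csd <- sqrt(d_h^2 + (weight * d_n)^2)
  structure(list(table = data.frame(residue = m$residue,
                                    residue_name = m$residue_name_apo,
                                    d_h = d_h, d_n = d_n, csd = csd),
                 weight = weight, unmatched = unmatched),
            class = "csd_result")
}

#' Flag significant chemical-shift displacements
#'
#' The significance threshold is mean(CSD) + n_sd * SD(CSD) over all computed
#' residues (default one SD above the mean). A robust variant uses
#' median + n_sd * MAD instead.
#'
#' @param csd A `csd_result` from [compute_csd()] (>= 5 residues).
#' @param n_sd Threshold multiplier.
#' @param robust Use median + MAD instead of mean + SD.
#' @return The `csd_result` with `threshold`, `stat` (mean/sd or
#'   median/mad used) added and a logical `significant` column in `table`.
#' @export
significant_csd <- function(csd, n_sd = 1, robust = FALSE) {
  v <- csd$table$csd
  if (length(v) < 5) stop("need >= 5 residues for a threshold", call. = FALSE)
  if (robust) {
    ctr <- stats::median(v); spr <- stats::mad(v)
  } else {
    ctr <- mean(v); spr <- stats::sd(v)
  }
  threshold <- ctr + n_sd * spr
  csd$table$significant <- csd$table$csd >= threshold
  csd$threshold <- threshold
  csd$stat <- c(center = ctr, spread = spr, n_sd = n_sd)
  csd$robust <- robust
  csd
}
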