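# Standard atomic masses for the elements found in protein heavy atoms + H.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

atom_masses <- function(atom_names, scheme = c("standard", "unit")) {
  scheme <- match.arg(scheme)
  if (scheme == "unit") return(rep(1, length(atom_names)))
  el <- substr(gsub("^[0-9]", "", trimws(atom_names)), 1, 1)
  m <- ATOMIC_MASS[el]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Center of mass and inertia frame of a model
#'
#' Computes the mass-weighted center of mass and the principal axes of the
#' inertia tensor for one model of an ensemble. Axes are orthonormal and
#' ordered by ascending principal moment; the smallest-moment axis is the long
#' axis of the molecule and is the conventional unique-axis candidate for an
#' axially symmetric diffusion tensor.
#'
#' @param ensemble A `structure_ensemble` from [read_pdb_ensemble()].
#' @param model Model index (default 1).
#' @param mass_scheme `"standard"` atomic masses or `"unit"` (geometry only).
#' @return List of class `inertia_frame`: `center` (3-vector, Angstrom),
#'   `axes` (3x3, columns = principal axes, ascending moment), `moments`,
#'   `degenerate` (logical: near-equal moments).
#' @export
center_and_inertia <- function(ensemble, model = 1,
                               mass_scheme = c("standard", "unit")) {
  mass_scheme <- match.arg(mass_scheme)
  xyz <- matrix(ensemble$xyz[model, ], ncol = 3, byrow = TRUE)
  if (nrow(xyz) < 3) stop("need at least 3 atoms", call. = FALSE)
  m <- atom_masses(ensemble$atoms$atom, mass_scheme)
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  # degenerate geometry check: rank of centred coordinates
  if (qr(r)$rank < 2) stop("degenerate (collinear) coordinates", call. = FALSE)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  I <- matrix(c(
    sum(m * (y^2 + z^2)), -sum(m * x * y),       -sum(m * x * z),
    -sum(m * x * y),       sum(m * (x^2 + z^2)), -sum(m * y * z),
    -sum(m * x * z),      -sum(m * y * z),        sum(m * (x^2 + y^2))
  ), 3, 3)
  e <- eigen(I, symmetric = TRUE)
  ord <- order(e$values)
  axes <- e$vectors[, ord, drop = FALSE]
  moments <- e$values[ord]
  # right-handed frame
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  degenerate <- diff(range(moments)) < 1e-8 * max(abs(moments), 1)
  structure(list(center = com, axes = axes, moments = moments,
                 degenerate = degenerate),
            class = "inertia_frame")
}

#' Per-residue NH bond vectors and alpha angles to a unique axis
#'
#' Extracts backbone N and amide H atoms for every usable residue (prolines
#' and the N-terminal residue have no amide proton and are skipped) and
#' computes the angle alpha between the unit NH vector and the supplied
#' unique axis. Because all diffusion-tensor spectral-density coefficients
#' depend on cos^2(alpha), alpha is folded to [0, 90] degrees; the fold loses
#' no information for the dynamics model.
#'
#' @param ensemble A `structure_ensemble`.
#' @param unique_axis Numeric 3-vector (need not be normalized).
#' @param model Model index.
#' @return Data frame with columns `residue`, `residue_name`, `alpha_deg`,
#'   unit vector components `ux`, `uy`, `uz`; attribute `skipped` records
#'   residues without a usable amide and the reason.
#' @export
nh_alpha_angles <- function(ensemble, unique_axis, model = 1) {
  axis <- unique_axis / sqrt(sum(unique_axis^2))
  xyz <- matrix(ensemble$xyz[model, ], ncol = 3, byrow = TRUE)
  at <- ensemble$atoms
  res <- unique(at$residue)
  first_res <- min(res)
  rows <- list(); skipped <- list()
  for (rn in res) {
    sel <- at$residue == rn
    rname <- at$residue_name[sel][1]
    if (rname == "PRO") { skipped[[length(skipped) + 1]] <-
      data.frame(residue = rn, reason = "proline"); next }
    if (rn == first_res) { skipped[[length(skipped) + 1]] <-
      data.frame(residue = rn, reason = "N-terminal"); next }
    iN <- which(sel & at$atom == "N")
    iH <- which(sel & at$atom %in% c("H", "HN"))
    if (length(iN) != 1 || length(iH) < 1) {
      skipped[[length(skipped) + 1]] <-
        data.frame(residue = rn, reason = "missing N or H atom")
      next
    }
    v <- xyz[iH[1], ] - xyz[iN, ]
    u <- v / sqrt(sum(v^2))
    alpha <- acos(min(1, abs(sum(u * axis)))) * 180 / pi
    rows[[length(rows) + 1]] <- data.frame(
      residue = rn, residue_name = rname, alpha_deg = alpha,
      ux = u[1], uy = u[2], uz = u[3], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue = integer(), residue_name = character(),
               alpha_deg = numeric(), ux = numeric(), uy = numeric(),
               uz = numeric())
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

select_atoms <- function(ensemble, selection = c("backbone", "heavy"),
                         range = NULL) {
  selection <- match.arg(selection)
  at <- ensemble$atoms
  keep <- if (selection == "backbone") {
    at$atom %in% c("N", "CA", "C", "O")
  } else {
    !grepl("^[0-9]*H", at$atom)
  }
  if (!is.null(range)) keep <- keep & at$residue >= range[1] & at$residue <= range[2]
  which(keep)
}

# Kabsch least-squares rotation aligning mobile onto fixed (both centred).
kabsch_rotation <- function(mobile, fixed) {
  s <- svd(t(mobile) %*% fixed)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

superpose_onto <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  R <- kabsch_rotation(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cf, `+`)
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

ensemble_coords <- function(ensemble, idx) {
  lapply(seq_len(ensemble$n_models), function(m) {
    matrix(ensemble$xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
  })
}

#' Ensemble RMSD to the mean structure (and pairwise variant)
#'
#' Each model is least-squares superposed (Kabsch) onto the unweighted mean
#' structure, where the mean itself is refined by iterative superposition
#' (models superposed, mean recomputed) until the mean moves by less than
#' `tol` Angstrom or `max_iter` rounds. With `pairwise = TRUE` the average
#' pairwise RMSD over all model pairs is returned instead.
#'
#' @param ensemble A `structure_ensemble` with at least 2 models.
#' @param selection `"backbone"` (N, CA, C, O) or `"heavy"` atoms.
#' @param range Optional residue range `c(first, last)`.
#' @param pairwise If `TRUE`, report the averaged pairwise RMSD.
#' @param max_iter,tol Iterative mean-structure refinement controls.
#' @return List: `per_model` RMSD values (or pairwise matrix), `mean`, `sd`.
#' @export
ensemble_rmsd_to_mean <- function(ensemble, selection = "backbone",
                                  range = NULL, pairwise = FALSE,
                                  max_iter = 10, tol = 1e-6) {
  if (ensemble$n_models < 2) stop("need >= 2 models", call. = FALSE)
  idx <- select_atoms(ensemble, selection, range)
  if (length(idx) == 0) stop("empty atom selection", call. = FALSE)
  coords <- ensemble_coords(ensemble, idx)
  if (pairwise) {
    n <- length(coords)
    vals <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      vals <- c(vals, rmsd_of(superpose_onto(coords[[j]], coords[[i]]),
                              coords[[i]]))
    }
    return(list(per_pair = vals, mean = mean(vals), sd = stats::sd(vals)))
  }
  ref <- coords[[1]]
  aligned <- lapply(coords, superpose_onto, fixed = ref)
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(coords, superpose_onto, fixed = mean_str)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    shift <- sqrt(max(rowSums((new_mean - mean_str)^2)))
    mean_str <- new_mean
    if (shift < tol) break
  }
  per_model <- vapply(aligned, rmsd_of, numeric(1), b = mean_str)
  list(per_model = per_model, mean = mean(per_model),
       sd = stats::sd(per_model), mean_structure = mean_str)
}

#' Per-residue root-mean-square fluctuation over frames
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2), averaged over the selected
#' backbone atoms of each residue. Frames are used as supplied unless
#' `superpose = TRUE`, in which case they are first superposed onto their
#' iteratively refined mean.
#'
#' @param ensemble A `structure_ensemble` whose models are frames.
#' @param selection Atom selection (see [ensemble_rmsd_to_mean()]).
#' @param superpose Superpose frames before computing fluctuations.
#' @return Data frame `residue`, `rmsf` (Angstrom).
#' @export
ensemble_rmsf <- function(ensemble, selection = "backbone",
                          superpose = FALSE) {
  if (ensemble$n_models < 2) stop("need >= 2 frames", call. = FALSE)
  idx <- select_atoms(ensemble, selection)
  coords <- ensemble_coords(ensemble, idx)
  if (superpose) {
    ref <- coords[[1]]
    aligned <- lapply(coords, superpose_onto, fixed = ref)
    mean_str <- Reduce(`+`, aligned) / length(aligned)
    for (it in 1:2) {
      aligned <- lapply(coords, superpose_onto, fixed = mean_str)
      mean_str <- Reduce(`+`, aligned) / length(aligned)
    }
    coords <- aligned
  }
  arr <- simplify2array(coords)              # natom x 3 x nframe
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply(arr, 3, function(f) rowSums((f - mean_pos)^2))
  atom_rmsf <- sqrt(rowMeans(dev2))
  res <- ensemble$atoms$residue[idx]
  agg <- tapply(atom_rmsf, res, mean)
  data.frame(residue = as.integer(names(agg)), rmsf = as.numeric(agg))
}
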