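#' Fit a two-parameter single-exponential intensity decay
#'
#' Fits I(t) = I0 * exp(-R t) to a peak-height decay by nonlinear least
#' squares (Levenberg-Marquardt), with the initial guess taken from a
#' log-linear regression on the positive intensities. This is the classical
#' model for 15N R1/R2 peak-height decays; no offset term is used by default.
#'
#' Per-point uncertainties are taken from the series when present; otherwise
#' a global fractional error is estimated from a replicate x point (duplicate
#' delay) when one exists, else from the RMS fit residual. Rate and amplitude
#' uncertainties come from the covariance matrix, or from seeded Monte-Carlo
#' resampling of the noise when `method = "monte_carlo"`.
#'
#' @param series An `intensity_series` with x in seconds (>= 3 distinct x).
#' @param config An [nmr_config()] (seed, Monte-Carlo replicate count).
#' @param method Uncertainty method: `"covariance"` or `"monte_carlo"`.
#' @param offset If `TRUE`, fit I(t) = I0 exp(-R t) + C (off by default).
#' @return List of class `rate_estimate`: `residue`, `rate` (s^-1), `i0`,
#'   `rate_sd`, `i0_sd`, `chisq_red`, `method`, `flag` (`"ok"` or
#'   `"nonpositive_rate"`), `sigma` (per-point error used).
#' @export
fit_exponential_decay <- function(series, config = nmr_config(),
                                  method = c("covariance", "monte_carlo"),
                                  offset = FALSE) {
  method <- match.arg(method)
  x <- series$x; y <- series$intensity
  if (length(unique(x)) < 3) {
    stop("need >= 3 distinct x values to fit a decay", call. = FALSE)
  }
  start <- loglin_start(x, y)
  fit <- exp_fit_once(x, y, start, offset = offset)
  sigma <- point_errors(series, fit$resid)
  # refit weighted if we have per-point errors
  weighted <- !is.null(series$error)
  if (weighted) {
    fit <- exp_fit_once(x, y, c(fit$par["i0"], fit$par["rate"]),
                        offset = offset, w = 1 / sigma^2)
  }
  rate <- unname(fit$par["rate"]); i0 <- unname(fit$par["i0"])
  npar <- if (offset) 3L else 2L
  dof <- max(1L, length(x) - npar)
  chisq_red <- sum((fit$resid / sigma)^2) / dof
  if (method == "covariance") {
    sds <- fit_sds(fit, known_errors = weighted)
  } else {
    sds <- mc_exp_sds(x, y, sigma, c(i0 = i0, rate = rate), offset, config)
  }
  structure(list(residue = series$residue,
                 residue_name = series$residue_name,
                 rate = rate, i0 = i0,
                 rate_sd = sds["rate"], i0_sd = sds["i0"],
                 chisq_red = chisq_red, method = method,
                 flag = if (rate <= 0 || rate * max(x) < 1e-6)
                   "nonpositive_rate" else "ok",
                 sigma = sigma),
            class = "rate_estimate")
}

loglin_start <- function(x, y) {
  pos <- y > 0
  if (sum(pos) >= 2) {
    co <- stats::coef(stats::lm(log(y[pos]) ~ x[pos]))
    c(i0 = exp(unname(co[1])), rate = -unname(co[2]))
  } else {
    c(i0 = max(y), rate = 1 / max(x[x > 0], 1))
  }
}

exp_fit_once <- function(x, y, start, offset = FALSE, w = NULL) {
  df <- data.frame(x = x, y = y)
  st <- list(i0 = unname(start[1]), rate = unname(start[2]))
  if (offset) st$C <- 0
  form <- if (offset) y ~ i0 * exp(-rate * x) + C else y ~ i0 * exp(-rate * x)
  do_fit <- function(st) minpack.lm::nlsLM(
    form, data = df, start = st,
    weights = if (is.null(w)) rep(1, length(y)) else w,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fit <- try(do_fit(st), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate starts (e.g. exactly flat data): nudge the rate
    st$rate <- max(abs(st$rate), 1e-3 / max(x[x > 0], 1))
    fit <- do_fit(st)
  }
  par <- stats::coef(fit)
  list(par = par, resid = y - stats::predict(fit), nls = fit)
}

point_errors <- function(series, resid) {
  n <- length(series$x)
  if (!is.null(series$error)) return(series$error)
  dup <- series$x[duplicated(series$x)]
  if (length(dup) >= 1) {
    xd <- dup[1]
    pair <- series$intensity[series$x == xd]
    frac <- abs(diff(pair[1:2])) / sqrt(2) / mean(pair[1:2])
    sig <- pmax(frac * abs(series$intensity), 1e-12)
    return(sig)
  }
  rep(max(sqrt(mean(resid^2)), 1e-12), n)
}

fit_sds <- function(fit, known_errors = FALSE) {
  sm <- try(summary(fit$nls), silent = TRUE)
  if (inherits(sm, "try-error")) return(c(i0 = NA_real_, rate = NA_real_))
  se <- sm$coefficients[, "Std. Error"]
  # with known per-point errors (weights 1/sigma_i^2) the parameter
  # covariance is (J' W J)^-1: undo nls's residual-variance rescaling
  if (known_errors && is.finite(sm$sigma) && sm$sigma > 0) se <- se / sm$sigma
  out <- se[c("i0", "rate")]
  names(out) <- c("i0", "rate")
  out
}

mc_exp_sds <- function(x, y, sigma, par, offset, config) {
  set.seed(config$seed)
  yhat <- par["i0"] * exp(-par["rate"] * x)
  reps <- replicate(config$mc_replicates, {
    ysim <- yhat + stats::rnorm(length(x), 0, sigma)
    f <- try(exp_fit_once(x, ysim, par, offset = offset, w = 1 / sigma^2),
             silent = TRUE)
    if (inherits(f, "try-error")) c(NA, NA) else f$par[c("i0", "rate")]
  })
  c(i0 = stats::sd(reps[1, ], na.rm = TRUE),
    rate = stats::sd(reps[2, ], na.rm = TRUE))
}

#' Heteronuclear NOE from saturated/reference intensity pairs
#'
#' NOE = I_sat / I_ref, with the uncertainty propagated as
#' sigma = |NOE| sqrt((s_sat/I_sat)^2 + (s_ref/I_ref)^2). Negative NOEs are
#' physical (flexible termini) and returned as-is.
#'
#' @param i_sat,i_ref Saturated and reference intensities.
#' @param sd_sat,sd_ref Their uncertainties.
#' @param residue,residue_name Residue key.
#' @param noise_floor Reference intensities at or below this level yield an
#'   error (undefined NOE).
#' @return List of class `noe_estimate`: `residue`, `noe`, `noe_sd`.
#' @export
compute_hetnoe <- function(i_sat, i_ref, sd_sat, sd_ref,
                           residue = NA_integer_, residue_name = NA_character_,
                           noise_floor = 0) {
  if (i_ref <= noise_floor) {
    stop("reference intensity at/below noise floor: NOE undefined for residue ",
         residue, call. = FALSE)
  }
  noe <- i_sat / i_ref
  sdv <- abs(noe) * sqrt((sd_sat / i_sat)^2 + (sd_ref / i_ref)^2)
  structure(list(residue = as.integer(residue), residue_name = residue_name,
                 noe = noe, noe_sd = sdv),
            class = "noe_estimate")
}

#' Merge per-residue relaxation results and summarize
#'
#' Outer-joins R1, R2 and NOE tables on residue number and reports the mean
#' and SD of each quantity over residues whose fits are not flagged. Flagged
#' or missing residues are excluded from the ensemble statistics but kept in
#' the merged table.
#'
#' @param r1,r2 Lists of `rate_estimate` (or data frames with `residue`,
#'   `rate`, `rate_sd`, `flag`).
#' @param noe List of `noe_estimate` (or data frame `residue`, `noe`,
#'   `noe_sd`), optional.
#' @return List: `table` (merged per-residue data frame), `summary`
#'   (mean/sd/n per quantity).
#' @export
summarize_relaxation <- function(r1, r2, noe = NULL) {
  as_rate_df <- function(lst, prefix) {
    if (is.data.frame(lst)) {
      df <- lst
    } else {
      df <- do.call(rbind, lapply(lst, function(e) data.frame(
        residue = e$residue, rate = e$rate, rate_sd = e$rate_sd,
        flag = e$flag, stringsAsFactors = FALSE)))
    }
    names(df)[names(df) == "rate"] <- prefix
    names(df)[names(df) == "rate_sd"] <- paste0(prefix, "_sd")
    names(df)[names(df) == "flag"] <- paste0(prefix, "_flag")
    df
  }
  t1 <- as_rate_df(r1, "R1"); t2 <- as_rate_df(r2, "R2")
  tab <- merge(t1, t2, by = "residue", all = TRUE)
  if (!is.null(noe)) {
    tn <- if (is.data.frame(noe)) noe else do.call(rbind, lapply(noe, function(e)
      data.frame(residue = e$residue, noe = e$noe, noe_sd = e$noe_sd)))
    tab <- merge(tab, tn, by = "residue", all = TRUE)
  }
  ok1 <- is.na(tab$R1_flag) | tab$R1_flag == "ok"
  ok2 <- is.na(tab$R2_flag) | tab$R2_flag == "ok"
  usable <- (!is.na(tab$R1) & ok1) | (!is.na(tab$R2) & ok2)
  if (!any(usable)) stop("no usable residues to summarize", call. = FALSE)
  smr <- function(v, keep) {
    v <- v[keep & !is.na(v)]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  summary <- list(R1 = smr(tab$R1, ok1), R2 = smr(tab$R2, ok2))
  if (!is.null(noe)) summary$NOE <- smr(tab$noe, rep(TRUE, nrow(tab)))
  list(table = tab, summary = summary)
}

#' Average two rate tables residue-by-residue
#'
#' Supports plain averaging (default) or inverse-variance weighting of two
#' independent measurements of the same rates.
#'
#' @param a,b Data frames with `residue`, `rate`, `rate_sd`.
#' @param weighted Inverse-variance weighting if `TRUE`.
#' @return Data frame `residue`, `rate`, `rate_sd`.
#' @export
average_rate_tables <- function(a, b, weighted = FALSE) {
  m <- merge(a, b, by = "residue", suffixes = c("_a", "_b"))
  if (weighted) {
    wa <- 1 / m$rate_sd_a^2; wb <- 1 / m$rate_sd_b^2
    rate <- (wa * m$rate_a + wb * m$rate_b) / (wa + wb)
    sdv <- sqrt(1 / (wa + wb))
  } else {
    rate <- (m$rate_a + m$rate_b) / 2
    sdv <- sqrt(m$rate_sd_a^2 + m$rate_sd_b^2) / 2
  }
  data.frame(residue = m$residue, rate = rate, rate_sd = sdv)
}
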