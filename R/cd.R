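# Circular-dichroism analysis: mean residue ellipticity, two-state folded
# fraction, pH-transition fitting, isodichroic-point location.

#' Mean residue ellipticity from raw ellipticity
#'
#' Default (`mode = "standard"`) uses the path-length form
#' `MRE = theta_mdeg / (10 * l_cm * C_molar * n_residues)`
#' in deg cm^2 dmol^-1. `mode = "as-printed"` evaluates the formula
#' `M0 * theta_deg / (100 * C * lambda)` literally for audit against sources
#' that divide by the wavelength; it is not recommended for analysis.
#'
#' @param theta_mdeg Measured ellipticity, millidegrees.
#' @param conc_M Protein concentration, molar.
#' @param path_cm Cuvette path length, cm.
#' @param n_residues Number of amino acid residues.
#' @param M0 Mean residue molar mass, g/mol (used by `"as-printed"` only).
#' @param wavelength_nm Wavelength, nm (used by `"as-printed"` only).
#' @param mode `"standard"` or `"as-printed"`.
#' @return MRE, deg cm^2 dmol^-1; linear in `theta_mdeg`.
#' @export
compute_mre <- function(theta_mdeg, conc_M, path_cm, n_residues = NULL,
                        M0 = NULL, wavelength_nm = NULL,
                        mode = c("standard", "as-printed")) {
  mode <- match.arg(mode)
  if (any(conc_M <= 0)) abort("protein concentration must be positive")
  if (mode == "standard") {
    if (path_cm <= 0) abort("path length must be positive")
    if (is.null(n_residues)) abort("n_residues is required for the standard form")
    return(theta_mdeg / (10 * path_cm * conc_M * n_residues))
  }
  if (is.null(M0) || is.null(wavelength_nm)) {
    abort("M0 and wavelength_nm are required for the as-printed form")
  }
  M0 * (theta_mdeg / 1000) / (100 * conc_M * wavelength_nm)
}

#' Two-state folded fraction from MRE at 222 nm
#'
#' Linear interpolation between reference MRE values of the fully unfolded
#' and fully folded states. Values are reported as-is (may fall slightly
#' outside `[0, 1]` under noise); set `clip = TRUE` to truncate, in which
#' case a message reports how many values were clipped.
#'
#' @param mre222 MRE values at 222 nm.
#' @param folded_ref,unfolded_ref Reference MRE of the folded and unfolded
#'   states (must differ).
#' @param clip Truncate to `[0, 1]`?
#' @return Folded fractions.
#' @export
fraction_helix <- function(mre222, folded_ref, unfolded_ref, clip = FALSE) {
  if (folded_ref == unfolded_ref) abort("reference MRE values must differ")
  fh <- (mre222 - unfolded_ref) / (folded_ref - unfolded_ref)
  if (clip) {
    n_out <- sum(fh < 0 | fh > 1)
    if (n_out > 0) inform(sprintf("%d value(s) clipped to [0, 1]", n_out))
    fh <- pmin(pmax(fh, 0), 1)
  }
  fh
}

#' Fit a two-state pH transition
#'
#' Nonlinear least squares of the modified Henderson-Hasselbalch sigmoid
#' `f(pH) = (f_base + f_acid * 10^(n(pKa - pH))) / (1 + 10^(n(pKa - pH)))`
#' with plateaus, pKa and the Hill coefficient all free, multistarted over a
#' pKa grid from 4 to 9. The parameterization is canonicalized to `n > 0`
#' with `f_acid` the low-pH plateau (the `(f_acid <-> f_base, n -> -n)`
#' reflection gives an identical curve).
#'
#' @param series A `ph_series` or data frame with columns `ph`, `fh` and
#'   optionally `err`.
#' @return A `ph_fit` object with elements `pKa`, `n`, `f_acid`, `f_base`,
#'   standard errors, `rss` and `fitted_fn`.
#' @export
fit_ph_transition <- function(series) {
  assert_cols(series, c("ph", "fh"), "pH series")
  if (nrow(series) < 6) abort("at least 6 pH points are required")
  ph <- series$ph
  fh <- series$fh
  if (is.unsorted(ph, strictly = TRUE)) abort("pH values must be strictly increasing")
  wts <- if ("err" %in% names(series) && any(series$err > 0)) {
    fit_weights(series$err)
  } else rep(1, length(ph))

  resid_fn <- function(par) {
    sqrt(wts) * (fh - ph_two_state(ph, par[1], par[2], par[3], par[4]))
  }
  # crude plateau guesses from the curve ends
  k <- max(2, floor(length(ph) / 4))
  fa0 <- mean(fh[seq_len(k)])
  fb0 <- mean(fh[seq(length(fh) - k + 1, length(fh))])
  best <- NULL
  for (pka0 in seq(4, 9, by = 0.5)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(c(fa0, fb0, pka0, 1),
                         lower = c(-Inf, -Inf, 2, -20),
                         upper = c(Inf, Inf, 12, 20),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) {
      best <- fit; best_rss <- rss
    }
  }
  if (is.null(best)) abort("pH-transition fit failed: no inflection found in range")
  par <- best$par
  if (par[4] < 0) {   # canonicalize the reflected solution
    par <- c(par[2], par[1], par[3], -par[4])
  }
  span <- abs(par[1] - par[2])
  if (span < 1e-12 || par[3] < min(ph) - 1 || par[3] > max(ph) + 1) {
    abort("pH-transition fit failed: no resolvable transition in the sampled range")
  }
  jac <- num_jacobian(function(p) sqrt(wts) * (fh - ph_two_state(ph, p[1], p[2], p[3], p[4])), par)
  se <- se_from_jacobian(jac, best$fvec)
  structure(list(
    f_acid = par[1], f_base = par[2], pKa = par[3], n = par[4],
    se = setNames(se, c("f_acid", "f_base", "pKa", "n")),
    rss = best_rss, n_obs = length(ph), series = as_tibble(series),
    fitted_fn = function(p) ph_two_state(p, par[1], par[2], par[3], par[4])
  ), class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("<ph_fit> pKa = %.3f +/- %.3f, n = %.3g, plateaus %.3g -> %.3g\n",
              x$pKa, x$se[["pKa"]], x$n, x$f_acid, x$f_base))
  invisible(x)
}

#' Locate the isodichroic point of a spectral series
#'
#' Given MRE spectra collected across a titration (e.g. pH), finds the
#' wavelength at which the across-spectra variance of MRE is minimal. A true
#' two-state transition has a crossing point where that variance vanishes;
#' a large residual variance flags a non-two-state (or non-crossing) series.
#'
#' @param spectra A data frame with columns `wavelength_nm`, `mre` and a
#'   spectrum identifier column `id` (one value per spectrum); all spectra
#'   must share the wavelength grid.
#' @param degenerate_tol Relative variance below which the whole series is
#'   flagged degenerate (identical spectra).
#' @return A list with `wavelength_nm`, `residual_variance`, `flag`
#'   (`"ok"`, `"degenerate"` or `"no-crossing"`) and the per-wavelength
#'   variance profile.
#' @export
find_isodichroic <- function(spectra, degenerate_tol = 1e-12) {
  assert_cols(spectra, c("wavelength_nm", "mre", "id"), "spectral series")
  ids <- unique(spectra$id)
  if (length(ids) < 3) abort("at least 3 spectra are required")
  grids <- split(spectra$wavelength_nm, spectra$id)
  ref <- sort(grids[[1]])
  same <- all(vapply(grids, function(g) identical(sort(g), ref), logical(1)))
  if (!same) abort("spectra are not on a common wavelength grid")
  prof <- spectra |>
    group_by(.data$wavelength_nm) |>
    summarise(variance = var(.data$mre), .groups = "drop")
  total <- mean(prof$variance)
  i_min <- which.min(prof$variance)
  flag <- "ok"
  if (total < degenerate_tol * max(1, mean(spectra$mre^2))) {
    flag <- "degenerate"
  } else if (prof$variance[i_min] > 0.05 * max(prof$variance)) {
    flag <- "no-crossing"
  }
  list(wavelength_nm = prof$wavelength_nm[i_min],
       residual_variance = prof$variance[i_min],
       flag = flag, profile = prof)
}
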