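# NMR titration analysis: weighted chemical-shift perturbations, docking
# active-residue selection, and pulsed-field-gradient diffusion fitting with
# oligomeric-state calling.

#' Weighted chemical-shift perturbation profile
#'
#' Per-residue combined amide shift change between free and ligand-bound
#' peak lists, `sqrt(dH^2 + 0.15 dN^2)` in ppm. Residues missing from either
#' list (unassigned or broadened beyond detection) are reported as missing
#' values and excluded from the profile mean/SD, never treated as zero.
#'
#' @param free,bound Peak-list data frames with columns `residue`, `dH_ppm`,
#'   `dN_ppm` and optionally `present` (logical) and `aa`.
#' @param n_weight Weight on the 15N term; 0.15 by convention.
#' @return A `csp_profile` tibble (`residue`, `csp`, `missing`) with the
#'   profile `mean`, `sd` and `n_weight` as attributes.
#' @export
#' @examples
#' free <- data.frame(residue = 1:2, dH_ppm = c(8, 8), dN_ppm = c(120, 120))
#' bound <- data.frame(residue = 1:2, dH_ppm = c(8.1, 8), dN_ppm = c(120.5, 121))
#' weighted_csp(free, bound)
weighted_csp <- function(free, bound, n_weight = 0.15) {
  for (pl in list(free, bound)) {
    assert_cols(pl, c("residue", "dH_ppm", "dN_ppm"), "peak list")
    if (anyDuplicated(pl$residue)) abort("duplicate residue numbers in a peak list")
  }
  present_or_true <- function(pl) if ("present" %in% names(pl)) pl$present else TRUE
  free <- mutate(as_tibble(free), .present = present_or_true(free) & is.finite(.data$dH_ppm))
  bound <- mutate(as_tibble(bound), .present = present_or_true(bound) & is.finite(.data$dH_ppm))
  common <- intersect(free$residue, bound$residue)
  if (!length(common)) abort("no residues in common between the two peak lists")
  f <- free[match(common, free$residue), ]
  b <- bound[match(common, bound$residue), ]
  ok <- f$.present & b$.present
  csp <- ifelse(ok,
                sqrt((b$dH_ppm - f$dH_ppm)^2 + n_weight * (b$dN_ppm - f$dN_ppm)^2),
                NA_real_)
  out <- tibble(residue = common, csp = csp, missing = !ok)
  if ("aa" %in% names(f)) out$aa <- f$aa
  attr(out, "mean") <- mean(csp, na.rm = TRUE)
  attr(out, "sd") <- sd(csp, na.rm = TRUE)
  attr(out, "n_weight") <- n_weight
  class(out) <- c("csp_profile", class(out))
  out
}

#' Select active residues for docking restraints
#'
#' Residues whose perturbation exceeds the profile mean by `sd_cutoff`
#' standard deviations AND whose relative solvent accessibility exceeds
#' `acc_cutoff` are selected as active (directly interface-forming) residues.
#' Residues whose bound-state peak vanished are returned separately as
#' `broadened`: their perturbation is unquantifiable, not zero.
#'
#' @param profile A `csp_profile` from [weighted_csp()].
#' @param accessibility Data frame with columns `residue` and `rel_sasa`
#'   (fractional, 0-1), covering the profiled residues.
#' @param sd_cutoff SD multiple above the profile mean (default 2).
#' @param acc_cutoff Relative-accessibility threshold (default 0.5).
#' @return A list with integer vectors `active` and `broadened` and the
#'   per-residue decision table `detail`.
#' @export
select_active_residues <- function(profile, accessibility, sd_cutoff = 2,
                                   acc_cutoff = 0.5) {
  assert_cols(accessibility, c("residue", "rel_sasa"), "accessibility table")
  need <- profile$residue[!profile$missing]
  if (!all(need %in% accessibility$residue)) {
    abort("accessibility table does not cover all profiled residues")
  }
  thr <- attr(profile, "mean") + sd_cutoff * attr(profile, "sd")
  detail <- left_join(as_tibble(profile),
                      as_tibble(accessibility)[c("residue", "rel_sasa")],
                      by = "residue") |>
    mutate(high_csp = !.data$missing & .data$csp > thr,
           exposed = .data$rel_sasa > acc_cutoff,
           active = .data$high_csp & .data$exposed)
  active <- detail$residue[which(detail$active)]
  if (!length(active)) warn("no residues pass both thresholds")
  list(active = active,
       broadened = detail$residue[detail$missing],
       detail = detail, threshold = thr)
}

#' Fit Stejskal-Tanner diffusion attenuation
#'
#' Nonlinear least squares of `I(g) = I0 exp(-D (gamma g delta)^2 (Delta -
#' delta/3))`, with a linearized `ln I` versus `g^2` regression available as
#' a cross-check (`method = "linear"`). Acquisition constants are taken from
#' the table's attributes when present (as written by
#' [sim_gradient_series()]) or passed explicitly.
#'
#' @param att A `gradient_attenuation` tibble (`g`, `intensity`).
#' @param Delta,delta,gamma Acquisition constants (s, s, rad s^-1 T^-1);
#'   defaults come from `attr(att, "acquisition")`.
#' @param method `"nls"` (default) or `"linear"`.
#' @return A `diffusion_fit` with `D`, `se_D`, `I0` and the fitted curve.
#' @export
fit_diffusion <- function(att, Delta = NULL, delta = NULL, gamma = NULL,
                          method = c("nls", "linear")) {
  method <- match.arg(method)
  assert_cols(att, c("g", "intensity"), "attenuation table")
  if (nrow(att) < 8) abort("at least 8 gradient points are required")
  if (is.unsorted(att$g, strictly = TRUE)) abort("gradient amplitudes must be strictly increasing")
  acq <- attr(att, "acquisition") %||% list()
  Delta <- Delta %||% acq$Delta
  delta <- delta %||% acq$delta
  gamma <- gamma %||% acq$gamma %||% 2.6752218744e8
  if (is.null(Delta) || is.null(delta)) {
    abort("Delta and delta must be supplied (or present as attributes)")
  }
  b <- (gamma * att$g * delta)^2 * (Delta - delta / 3)
  y <- att$intensity
  # attenuation should fall monotonically in g beyond noise
  sm <- stats::runmed(y, k = min(5, 2 * floor((nrow(att) - 1) / 2) + 1))
  if (any(diff(sm) > 0.05 * max(y))) warn("attenuation is non-monotone beyond noise level")

  lin <- lm(log(pmax(y, .Machine$double.eps)) ~ b)
  D_lin <- -unname(coef(lin)[2])
  I0_lin <- exp(unname(coef(lin)[1]))
  if (method == "linear") {
    se <- summary(lin)$coefficients[2, 2]
    return(new_diffusion_fit(D_lin, se, I0_lin, att, b, method))
  }
  # fit k = D * max(b) (order-one scale) so derivatives are well conditioned
  b_max <- max(b)
  x <- b / b_max
  resid_fn <- function(par) y - par[2] * exp(-par[1] * x)
  fit <- minpack.lm::nls.lm(c(max(D_lin * b_max, 1e-3), max(I0_lin, max(y))),
                            lower = c(0, 0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  jac <- num_jacobian(resid_fn, fit$par)
  se <- se_from_jacobian(jac, fit$fvec)
  new_diffusion_fit(fit$par[1] / b_max, se[1] / b_max, fit$par[2], att, b,
                    method)
}

new_diffusion_fit <- function(D, se_D, I0, att, b, method) {
  structure(list(D = D, se_D = se_D, I0 = I0, method = method,
                 data = as_tibble(att), b = b,
                 fitted = I0 * exp(-D * b)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g m^2/s (I0 = %.4g, %s fit)\n",
              x$D, x$se_D, x$I0, x$method))
  invisible(x)
}

#' Call the oligomeric state from a diffusion coefficient
#'
#' Compares a fitted diffusion coefficient against externally predicted
#' monomer and dimer values (e.g. from hydrodynamic modelling) and calls the
#' nearer one in relative terms. When the measurement is more than
#' `n_se` standard errors away from even the nearer reference, the call is
#' `"ambiguous"`.
#'
#' @param fit A `diffusion_fit` (or a list with `D` and `se_D`).
#' @param D_monomer,D_dimer Reference predictions, m^2/s (must differ).
#' @param n_se Distance threshold in SE units (default 3).
#' @return A list with `call` (`"monomer"`, `"dimer"` or `"ambiguous"`) and
#'   the relative deviations from each reference.
#' @export
classify_oligomer <- function(fit, D_monomer, D_dimer, n_se = 3) {
  if (D_monomer == D_dimer) abort("reference predictions must differ")
  D <- fit$D
  se <- fit$se_D %||% 0
  dev <- c(monomer = abs(D - D_monomer) / D_monomer,
           dimer = abs(D - D_dimer) / D_dimer)
  nearer <- names(dev)[which.min(dev)]
  abs_near <- min(abs(D - D_monomer), abs(D - D_dimer))
  call <- nearer
  if (is.finite(se) && se > 0 && abs_near > n_se * se) call <- "ambiguous"
  # exact midpoint: no preference regardless of SE
  if (abs(abs(D - D_monomer) - abs(D - D_dimer)) < 1e-12 * abs(D_monomer - D_dimer)) {
    call <- "ambiguous"
  }
  list(call = call, deviation = dev, D = D, se_D = se,
       references = c(monomer = D_monomer, dimer = D_dimer))
}
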