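# Dose-response (MST) binding analysis: baseline normalization, mono- and
# biphasic Hill fits with SEM weighting and multistart, AICc model selection.

#' Coerce a data frame to a titration series
#'
#' @param data Data frame with columns `conc_nM`, `fnorm` and optionally
#'   `sem`; concentrations must be positive (zero allowed as a baseline
#'   anchor) and there must be at least 6 points.
#' @param labels Optional named list of labels (protein, DNA sequence, pH).
#' @return A `titration_series` tibble.
#' @export
as_titration_series <- function(data, labels = NULL) {
  assert_cols(data, c("conc_nM", "fnorm"), "titration data")
  if (!"sem" %in% names(data)) data$sem <- 0
  if (nrow(data) < 6) abort("a titration series needs at least 6 points")
  if (any(data$conc_nM < 0)) abort("concentrations must be non-negative")
  if (any(data$sem < 0)) abort("SEM must be non-negative")
  data <- arrange(as_tibble(data), .data$conc_nM)
  new_titration_series(data, truth = attr(data, "truth"), labels = labels)
}

#' Subtract the curve minimum from a titration
#'
#' MST curves from different DNA sequences are put on a common scale by
#' subtracting each curve's minimum observable value; concentrations and
#' errors are untouched, and the fitted KD is invariant to the shift.
#'
#' @param series A `titration_series` (or data frame with `conc_nM`, `fnorm`).
#' @return The series with `min(fnorm) == 0`.
#' @export
normalize_baseline <- function(series) {
  series <- as_titration_series(series)
  series$fnorm <- series$fnorm - min(series$fnorm)
  series
}

#' Fit a Hill (or biphasic Hill) binding model
#'
#' Weighted nonlinear least squares of
#' `fnorm(c) = baseline + sum_m dF_m * c^n_m / (KD_m^n_m + c^n_m)`
#' with one or two binding modes. Weights are `1/SEM^2` when SEMs are
#' available (floored at 20% of the median positive SEM so single lucky
#' points cannot dominate); fits are multistarted over log-spaced KD
#' initial values and the best weighted-RSS solution is kept.
#'
#' @param series A `titration_series` or data frame (`conc_nM`, `fnorm`,
#'   optional `sem`).
#' @param modes 1 (single Hill term) or 2 (additive biphasic model; needs
#'   >= 10 points).
#' @param fix_n Fix all Hill coefficients to 1 instead of fitting them
#'   within `[0.5, 4]`.
#' @param n_starts Number of multistart KD initial values per mode.
#' @return A `binding_fit` object; see [tidy.binding_fit()] and
#'   [glance.binding_fit()]. Fields include per-mode `kd`, `hill_n`,
#'   `amplitude`, their standard errors, `baseline`, `rss`, `aicc`, and
#'   `flags` (notably `"unbounded"` when a KD lands outside the sampled
#'   concentration range).
#' @export
fit_binding <- function(series, modes = 1, fix_n = FALSE, n_starts = 5) {
  series <- as_titration_series(series)
  modes <- as.integer(modes)
  stopifnot(modes %in% c(1L, 2L))
  if (modes == 2L && nrow(series) < 10) {
    abort("the biphasic model needs at least 10 points")
  }
  conc <- series$conc_nM
  obs <- series$fnorm
  wts <- fit_weights(series$sem)
  cpos <- conc[conc > 0]
  lo_k <- log(min(cpos) / 100)
  hi_k <- log(max(cpos) * 100)

  model_fn <- function(par) {
    # par: baseline, then per mode (dF, logK, n)
    y <- par[1]
    for (m in seq_len(modes)) {
      i <- 1 + (m - 1) * 3
      y <- y + par[i + 1] * hill_saturation(conc, exp(par[i + 2]), par[i + 3])
    }
    y
  }
  resid_fn <- function(par) sqrt(wts) * (obs - model_fn(par))

  amp0 <- diff(range(obs))
  if (amp0 == 0) amp0 <- 1
  starts <- kd_starts(cpos, modes, n_starts)
  lower <- c(-Inf, rep(c(-Inf, lo_k, if (fix_n) 1 else 0.5), modes))
  upper <- c(Inf, rep(c(Inf, hi_k, if (fix_n) 1 else 4), modes))

  best <- NULL
  for (s in starts) {
    par0 <- c(min(obs), unlist(lapply(seq_len(modes), function(m) {
      c(amp0 / modes, s[m], 1)
    })))
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) abort("binding fit failed to converge from every start")

  par <- best$par
  n_par <- length(par) - if (fix_n) modes else 0
  jac <- num_jacobian(resid_fn, par)
  se <- se_from_jacobian(jac, best$fvec, n_par)

  kd <- exp(par[1 + 3 * (seq_len(modes) - 1) + 2])
  ord <- order(kd)
  idx <- function(field) 1 + 3 * (ord - 1) + field
  kd <- kd[ord]
  amplitude <- par[idx(1)]
  hill_n <- par[idx(3)]
  se_kd <- kd * se[idx(2)]       # delta method from log-KD
  se_amp <- se[idx(1)]
  se_n <- se[idx(3)]

  flags <- character()
  if (any(kd < min(cpos) | kd > max(cpos))) flags <- c(flags, "unbounded")
  # amplitude indistinguishable from zero: within 2 SE of it, buried in the
  # residual noise, or negligible against the observable's own scale
  resid_sd <- sd(obs - model_fn(par))
  if (any(abs(amplitude) < 2 * se_amp, na.rm = TRUE) ||
      any(abs(amplitude) <= 3 * resid_sd) ||
      any(abs(amplitude) <= 1e-6 * max(abs(obs)))) {
    flags <- c(flags, "weak-amplitude")
  }

  structure(list(
    modes = modes,
    kd = kd, se_kd = se_kd,
    hill_n = hill_n, se_n = if (fix_n) rep(0, modes) else se_n,
    amplitude = amplitude, se_amplitude = se_amp,
    baseline = par[1], se_baseline = se[1],
    fix_n = fix_n,
    rss = best_rss,
    aicc = aicc_ls(best_rss, length(obs), n_par),
    n_obs = length(obs),
    flags = flags,
    series = series,
    fitted_fn = function(c_new) {
      y <- par[1]
      for (m in seq_len(modes)) {
        i <- 1 + (m - 1) * 3
        y <- y + par[i + 1] * hill_saturation(c_new, exp(par[i + 2]), par[i + 3])
      }
      y
    }
  ), class = "binding_fit")
}

fit_weights <- function(sem) {
  if (all(sem <= 0)) return(rep(1, length(sem)))
  floor_ <- 0.2 * median(sem[sem > 0])
  1 / pmax(sem, floor_)^2
}

kd_starts <- function(cpos, modes, n_starts) {
  grid <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = n_starts))
  if (modes == 1) return(lapply(log(grid), function(x) x))
  pairs <- list()
  for (i in seq_len(n_starts - 1)) {
    for (j in seq((i + 1), n_starts)) {
      pairs[[length(pairs) + 1]] <- log(c(grid[i], grid[j]))
    }
  }
  pairs
}

#' Choose between mono- and biphasic binding
#'
#' Fits both the 1- and 2-mode Hill models and keeps the mode count with the
#' lower small-sample-corrected AIC; differences below 2 are treated as ties
#' and resolved in favour of the single-mode model.
#'
#' @inheritParams fit_binding
#' @return A list with `modes` (the selected count), `fit` (the selected
#'   `binding_fit`), `fits` (both fits) and `delta_aicc`.
#' @export
select_binding_model <- function(series, fix_n = FALSE) {
  series <- as_titration_series(series)
  f1 <- fit_binding(series, modes = 1, fix_n = fix_n)
  f2 <- tryCatch(fit_binding(series, modes = 2, fix_n = fix_n),
                 error = function(e) NULL)
  if (is.null(f2)) {
    return(list(modes = 1L, fit = f1, fits = list(f1), delta_aicc = NA_real_))
  }
  delta <- f1$aicc - f2$aicc
  modes <- if (is.finite(delta) && delta > 2) 2L else 1L
  list(modes = modes, fit = if (modes == 2) f2 else f1,
       fits = list(f1, f2), delta_aicc = delta)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %d mode(s), %d points\n", x$modes, x$n_obs))
  for (m in seq_len(x$modes)) {
    cat(sprintf("  mode %d: KD = %.4g +/- %.2g nM, n = %.3g, dF = %.3g\n",
                m, x$kd[m], x$se_kd[m], x$hill_n[m], x$amplitude[m]))
  }
  cat(sprintf("  baseline = %.4g, RSS = %.4g, AICc = %.4g\n",
              x$baseline, x$rss, x$aicc))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
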