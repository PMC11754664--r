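# broom-style tidiers for the fitted-object classes.

#' Tidy a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `mode`, `estimate`, `std.error`.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  per_mode <- bind_rows(lapply(seq_len(x$modes), function(m) {
    tibble(term = c("kd_nM", "hill_n", "amplitude"), mode = m,
           estimate = c(x$kd[m], x$hill_n[m], x$amplitude[m]),
           std.error = c(x$se_kd[m], x$se_n[m], x$se_amplitude[m]))
  }))
  bind_rows(per_mode,
            tibble(term = "baseline", mode = NA_integer_,
                   estimate = x$baseline, std.error = x$se_baseline))
}

#' @rdname tidy.binding_fit
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(modes = x$modes, rss = x$rss, aicc = x$aicc, n_obs = x$n_obs,
         flags = paste(x$flags, collapse = ";"))
}

#' @method augment binding_fit
#' @export
augment.binding_fit <- function(x, ...) {
  mutate(as_tibble(x$series), .fitted = x$fitted_fn(.data$conc_nM),
         .resid = .data$fnorm - .data$.fitted)
}

#' Tidy a pH-transition fit
#'
#' @param x A `ph_fit`.
#' @param ... Unused.
#' @return One row per parameter with estimate and standard error.
#' @method tidy ph_fit
#' @export
tidy.ph_fit <- function(x, ...) {
  tibble(term = c("f_acid", "f_base", "pKa", "n"),
         estimate = c(x$f_acid, x$f_base, x$pKa, x$n),
         std.error = unname(x$se))
}

#' @rdname tidy.ph_fit
#' @method glance ph_fit
#' @export
glance.ph_fit <- function(x, ...) {
  tibble(rss = x$rss, n_obs = x$n_obs)
}

#' Tidy a biexponential decay fit
#'
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return One row per parameter with estimate and standard error.
#' @method tidy biexp_fit
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(term = c("A1", "A2", "tau1_ns", "tau2_ns", "baseline", "shift_ns"),
         estimate = c(x$A1, x$A2, x$tau1, x$tau2, x$baseline, x$shift_ns),
         std.error = c(x$se[["A1"]], x$se[["A2"]], x$se[["tau1"]],
                       x$se[["tau2"]], x$se[["baseline"]], NA))
}

#' @rdname tidy.biexp_fit
#' @method glance biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(tau_intensity_ns = x$tau_intensity, integral = x$integral,
         chisq_reduced = x$chisq_reduced)
}

#' Tidy a diffusion fit
#'
#' @param x A `diffusion_fit`.
#' @param ... Unused.
#' @return Parameter estimates (`D_m2s`, `I0`) with standard errors.
#' @method tidy diffusion_fit
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = c("D_m2s", "I0"), estimate = c(x$D, x$I0),
         std.error = c(x$se_D, NA))
}

#' @rdname tidy.diffusion_fit
#' @method glance diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D_m2s = x$D, se_D = x$se_D, method = x$method,
         n_obs = nrow(x$data))
}
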