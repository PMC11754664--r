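# ggplot2 autoplot methods for the main result types.

#' Plot a binding fit
#'
#' Data with SEM error bars on a log concentration axis, overlaid with the
#' fitted mono- or biphasic Hill curve.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  s <- object$series
  cpos <- s$conc_nM[s$conc_nM > 0]
  grid <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = 200))
  curve <- tibble(conc_nM = grid, fnorm = object$fitted_fn(grid))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$conc_nM, y = .data$fnorm)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fnorm - .data$sem,
                                        ymax = .data$fnorm + .data$sem),
                           width = 0.05, linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "titrant (nM)", y = "observable",
                  subtitle = sprintf("KD = %s nM",
                                     paste(signif(object$kd, 3), collapse = ", ")))
}

#' Plot a pH-transition fit
#'
#' @param object A `ph_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ph_fit
#' @export
autoplot.ph_fit <- function(object, ...) {
  s <- object$series
  grid <- seq(min(s$ph), max(s$ph), length.out = 200)
  curve <- tibble(ph = grid, fh = object$fitted_fn(grid))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$ph, y = .data$fh)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$pKa, linetype = "dashed") +
    ggplot2::labs(x = "pH", y = "folded fraction",
                  subtitle = sprintf("pKa = %.2f, n = %.2f", object$pKa, object$n))
}

#' Plot a chemical-shift-perturbation profile
#'
#' Per-residue weighted shift changes with 1- and 2-SD threshold lines;
#' residues whose bound-state peak vanished are marked at the axis.
#'
#' @param object A `csp_profile`.
#' @param sd_lines SD multiples to draw (default 1 and 2).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot csp_profile
#' @export
autoplot.csp_profile <- function(object, sd_lines = c(1, 2), ...) {
  mu <- attr(object, "mean"); sdev <- attr(object, "sd")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$csp)) +
    ggplot2::geom_col(width = 0.8, fill = "grey35") +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)"))
  for (k in sd_lines) {
    p <- p + ggplot2::geom_hline(yintercept = mu + k * sdev,
                                 colour = if (k >= 2) "red" else "orange",
                                 linetype = "dashed")
  }
  miss <- object[object$missing, ]
  if (nrow(miss)) {
    p <- p + ggplot2::geom_point(data = mutate(miss, csp = 0), shape = 4)
  }
  p
}

#' Plot a decay fit
#'
#' Counts and fitted reconvolution on a log scale.
#'
#' @param object A `biexp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot biexp_fit
#' @export
autoplot.biexp_fit <- function(object, ...) {
  df <- tibble(t_ns = object$t_ns, counts = object$counts,
               fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ns)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts",
                  subtitle = sprintf("tau = %.3g / %.3g ns", object$tau1, object$tau2))
}

#' Plot a diffusion fit
#'
#' Log intensity against the Stejskal-Tanner b-factor; a single diffusing
#' species gives a straight line.
#'
#' @param object A `diffusion_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diffusion_fit
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  df <- mutate(object$data, b = object$b, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b)) +
    ggplot2::geom_point(ggplot2::aes(y = log(.data$intensity))) +
    ggplot2::geom_line(ggplot2::aes(y = log(.data$fitted)), colour = "steelblue") +
    ggplot2::labs(x = expression(b ~ (s / m^2)), y = "ln I",
                  subtitle = sprintf("D = %.3g m^2/s", object$D))
}
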