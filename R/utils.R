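# Shared numerical helpers.

#' Hill saturation function
#'
#' Fractional saturation `c^n / (kd^n + c^n)`, evaluated stably on the log
#' scale. `c = 0` returns exactly 0 so that ligand-free baseline points can be
#' kept in a titration.
#'
#' @param conc Titrant concentrations (same units as `kd`), non-negative.
#' @param kd Half-saturation constant (> 0).
#' @param n Hill coefficient (> 0).
#' @return Numeric vector of saturations in `[0, 1]`.
#' @export
#' @examples
#' hill_saturation(10, kd = 10, n = 1)  # 0.5 at c = KD for any n
hill_saturation <- function(conc, kd, n = 1) {
  stopifnot(kd > 0, n > 0, all(conc >= 0))
  out <- numeric(length(conc))
  pos <- conc > 0
  # c^n/(kd^n + c^n) = 1/(1 + exp(n*(log kd - log c)))
  out[pos] <- 1 / (1 + exp(n * (log(kd) - log(conc[pos]))))
  out
}

# Small-sample-corrected Akaike criterion for least-squares fits.
# k counts the fitted mean parameters; the error variance adds one.
aicc_ls <- function(rss, n_obs, k) {
  k <- k + 1
  aic <- n_obs * log(rss / n_obs) + 2 * k
  if (n_obs - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n_obs - k - 1)
}

# Standard errors from a residual-function fit: cov = s^2 (J'J)^-1 with
# residuals already weighted. Returns NA where the curvature is singular.
se_from_jacobian <- function(jac, resid, n_par = ncol(jac)) {
  dof <- length(resid) - n_par
  if (dof <= 0) return(rep(NA_real_, n_par))
  s2 <- sum(resid^2) / dof
  jtj <- crossprod(jac)
  cov <- tryCatch(solve(jtj) * s2, error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, n_par))
  sqrt(pmax(diag(cov), 0))
}

# Forward-difference Jacobian of a vector-valued function.
num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  jac <- matrix(0, length(f0), length(par))
  for (i in seq_along(par)) {
    h <- eps * max(1, abs(par[i]))
    p <- par
    p[i] <- p[i] + h
    jac[, i] <- (fn(p) - f0) / h
  }
  jac
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  quat_to_mat(q)
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rotation about a random axis by a Normal(0, sd_deg) angle.
small_rotation <- function(sd_deg) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- rnorm(1, 0, sd_deg) * pi / 180
  axis_angle_mat(ax, ang)
}

axis_angle_mat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); t_ <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(
    t_ * x * x + c_,     t_ * x * y - s_ * z, t_ * x * z + s_ * y,
    t_ * x * y + s_ * z, t_ * y * y + c_,     t_ * y * z - s_ * x,
    t_ * x * z - s_ * y, t_ * y * z + s_ * x, t_ * z * z + c_
  ), 3, 3, byrow = TRUE)
}

assert_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
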