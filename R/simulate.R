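# Synthetic-data generators. Every generator is a pure function of its
# parameters and `seed`: the global RNG state is saved and restored, and a
# fixed seed reproduces the output byte for byte.

#' Simulate an MST dose-response titration
#'
#' Generates a normalized-fluorescence (F_norm) titration of a labelled DNA
#' with increasing protein concentration. The response is a sum of one or two
#' Hill terms (specific and nonspecific binding modes) on a constant baseline,
#' with additive Gaussian replicate noise. The reported observable is the
#' replicate mean and the per-point error its standard error, mirroring how
#' MST experiments with n >= 3 repeats are summarised.
#'
#' @param kd_nM Ground-truth dissociation constant(s), nM; length 1 or 2.
#'   With two modes the first entry is the high-affinity (specific) mode.
#' @param hill_n Hill coefficient(s), recycled to `length(kd_nM)`.
#' @param amplitude Response amplitude(s) per mode (F_norm units).
#' @param baseline Baseline F_norm value.
#' @param conc_range Titrant range, nM; points are log-spaced across it.
#' @param n_points Number of titration points.
#' @param replicates Technical replicates per point (>= 1); defaults to 3.
#' @param sigma Gaussian noise SD per replicate, in F_norm units.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `titration_series` tibble with columns `conc_nM`, `fnorm`, `sem`
#'   and the ground truth stored in `attr(, "truth")`.
#' @export
#' @examples
#' sim_titration(kd_nM = 25.3, sigma = 0, seed = 1)
sim_titration <- function(kd_nM, hill_n = 1, amplitude = 1, baseline = 0,
                          conc_range = c(1, 500), n_points = 16,
                          replicates = 3, sigma = 0.02, seed = 1) {
  n_modes <- length(kd_nM)
  stopifnot(n_modes %in% c(1L, 2L), all(kd_nM > 0), replicates >= 1,
            n_points >= 2, all(conc_range > 0))
  hill_n <- rep_len(hill_n, n_modes)
  amplitude <- rep_len(amplitude, n_modes)
  if (n_modes == 2) {
    ratio <- max(kd_nM) / min(kd_nM)
    if (ratio < 5) {
      warn(sprintf("KD separation %.2g-fold < 5: the two binding modes may not be resolvable", ratio))
    }
  }
  conc <- exp(seq(log(conc_range[1]), log(conc_range[2]), length.out = n_points))
  model <- baseline
  for (m in seq_len(n_modes)) {
    model <- model + amplitude[m] * hill_saturation(conc, kd_nM[m], hill_n[m])
  }
  withr::with_seed(seed, {
    reps <- matrix(rnorm(n_points * replicates, mean = model, sd = sigma),
                   nrow = n_points)
  })
  fnorm <- rowMeans(reps)
  sem <- if (replicates > 1) apply(reps, 1, sd) / sqrt(replicates) else rep(0, n_points)
  out <- tibble(conc_nM = conc, fnorm = fnorm, sem = sem)
  new_titration_series(out,
    truth = list(kd_nM = kd_nM, hill_n = hill_n, amplitude = amplitude,
                 baseline = baseline, sigma = sigma, replicates = replicates))
}

new_titration_series <- function(data, truth = NULL, labels = NULL) {
  attr(data, "truth") <- truth
  attr(data, "labels") <- labels
  class(data) <- c("titration_series", class(data))
  data
}

#' Simulate a pH-folding series
#'
#' Folded (helical) fraction versus pH for a two-state transition controlled
#' by a single protonation equilibrium: a sigmoid with inflection `pKa` and
#' Hill slope `n`, running from the acidic plateau `f_acid` to the basic
#' plateau `f_base`, plus Gaussian noise.
#'
#' @param pKa Transition midpoint.
#' @param n Hill coefficient (number of protons involved); must be nonzero.
#' @param f_acid,f_base Plateau folded fractions below and above the
#'   transition.
#' @param ph pH grid; defaults to 4.5-8.5 in 0.5 steps.
#' @param sigma Gaussian noise SD on the folded fraction.
#' @param seed Integer seed.
#' @return A `ph_series` tibble with columns `ph`, `fh`, `err`.
#' @export
sim_ph_series <- function(pKa = 5.98, n = 1, f_acid = 0.10, f_base = 0.35,
                          ph = seq(4.5, 8.5, by = 0.5), sigma = 0.02,
                          seed = 1) {
  if (n == 0) abort("Hill coefficient n = 0 gives no transition")
  if (pKa < min(ph) || pKa > max(ph)) {
    warn("pKa lies outside the sampled pH range; the transition is not covered")
  }
  model <- ph_two_state(ph, f_acid, f_base, pKa, n)
  withr::with_seed(seed, fh <- rnorm(length(ph), model, sigma))
  out <- tibble(ph = ph, fh = fh, err = rep(sigma, length(ph)))
  attr(out, "truth") <- list(pKa = pKa, n = n, f_acid = f_acid, f_base = f_base,
                             sigma = sigma)
  class(out) <- c("ph_series", class(out))
  out
}

# Two-state sigmoid parameterized by plateau role: at pH << pKa the
# 10^(n(pKa-pH)) term dominates and f -> f_acid; at pH >> pKa, f -> f_base.
ph_two_state <- function(ph, f_acid, f_base, pKa, n) {
  q <- 10^(n * (pKa - ph))
  (f_base + f_acid * q) / (1 + q)
}

#' Simulate a set of time-resolved fluorescence decays
#'
#' Each waveform is a biexponential decay `A1 exp(-t/tau1) + A2 exp(-t/tau2)`
#' convolved with the instrument response function, scaled so the model
#' maximum equals `peak_counts`, with optional Poisson photon noise.
#'
#' @param amplitudes Numeric vector of length 2, or a list of such vectors
#'   (one per waveform); relative amplitudes of the two components.
#' @param tau_ns Lifetimes, ns (length 2, shared across the set).
#' @param t_max,dt Time window and sampling step, ns.
#' @param irf Either `c(center, sigma)` of a Gaussian IRF (ns), a full
#'   waveform on the grid, or `"delta"` for an ideal instrument.
#' @param peak_counts Counts at the model maximum.
#' @param baseline Constant background counts per bin.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed.
#' @return A list of `decay_waveform` tibbles (`t_ns`, `counts`, `irf`), with
#'   ground truth attached to each.
#' @export
sim_decay_set <- function(amplitudes = c(1, 1), tau_ns = c(1, 4),
                          t_max = 50, dt = 0.1, irf = c(2, 0.15),
                          peak_counts = 1e4, baseline = 0,
                          noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  stopifnot(length(tau_ns) == 2, all(tau_ns > 0), dt > 0)
  if (dt > min(tau_ns) / 5) {
    warn(sprintf("grid spacing %.3g ns undersamples the fastest lifetime %.3g ns", dt, min(tau_ns)))
  }
  if (!is.list(amplitudes)) amplitudes <- list(amplitudes)
  t_grid <- seq(0, t_max, by = dt)
  irf_counts <- make_irf(irf, t_grid)
  tau <- sort(tau_ns)
  waves <- withr::with_seed(seed, {
    lapply(amplitudes, function(a) {
      stopifnot(length(a) == 2, all(a >= 0))
      decay <- a[1] * exp(-t_grid / tau[1]) + a[2] * exp(-t_grid / tau[2])
      model <- pmax(conv_causal(decay, irf_counts), 0)
      scale <- peak_counts / max(model)
      lambda <- model * scale + baseline
      counts <- if (noise == "poisson") rpois(length(lambda), lambda) else lambda
      w <- tibble(t_ns = t_grid, counts = counts, irf = irf_counts)
      attr(w, "truth") <- list(amplitudes = a * scale, tau_ns = tau,
                               baseline = baseline, scale = scale)
      class(w) <- c("decay_waveform", class(w))
      w
    })
  })
  waves
}

make_irf <- function(irf, t_grid) {
  if (identical(irf, "delta")) {
    out <- numeric(length(t_grid))
    out[1] <- 1
    return(out)
  }
  if (length(irf) == 2 && is.numeric(irf)) {
    out <- exp(-0.5 * ((t_grid - irf[1]) / irf[2])^2)
    return(out / sum(out))
  }
  if (length(irf) == length(t_grid)) {
    if (all(irf == 0)) abort("IRF is identically zero")
    return(irf / sum(irf))
  }
  abort("irf must be 'delta', c(center, sigma), or a waveform on the grid")
}

#' Simulate a fluorescence-lifetime titration
#'
#' For each titrant concentration, generates a decay from a mixture of a free
#' species (lifetime `tau_free`) and a bound species (`tau_bound`) whose bound
#' fraction follows a Hill curve. Amplitudes are scaled so each species'
#' time-integrated emission is proportional to its population (equal molecular
#' brightness), making the intensity-weighted lifetime linear in the bound
#' fraction.
#'
#' @param conc_nM Titrant concentrations, nM.
#' @param kd_nM Ground-truth dissociation constant, nM.
#' @param hill_n Hill coefficient of the binding curve.
#' @param tau_free,tau_bound Lifetimes of the free and bound species, ns.
#' @inheritParams sim_decay_set
#' @return A list with `waveforms` (list of `decay_waveform`) and `conc_nM`.
#' @export
sim_flt_titration <- function(conc_nM, kd_nM = 29.4, hill_n = 1,
                              tau_free = 1, tau_bound = 2,
                              t_max = 50, dt = 0.1, irf = c(2, 0.15),
                              peak_counts = 1e4, noise = "poisson", seed = 1) {
  theta <- hill_saturation(conc_nM, kd_nM, hill_n)
  # amplitude ~ population / tau so integrated intensity A*tau ~ population
  amps <- lapply(theta, function(th) c((1 - th) / tau_free, th / tau_bound))
  waves <- sim_decay_set(amplitudes = amps, tau_ns = c(tau_free, tau_bound),
                         t_max = t_max, dt = dt, irf = irf,
                         peak_counts = peak_counts, noise = noise, seed = seed)
  list(waveforms = waves, conc_nM = conc_nM,
       truth = list(kd_nM = kd_nM, hill_n = hill_n,
                    tau_free = tau_free, tau_bound = tau_bound))
}

#' Simulate a pulsed-field-gradient attenuation series
#'
#' Stejskal-Tanner attenuation `I(g) = I0 exp(-D (gamma g delta)^2 (Delta -
#' delta/3))` over a gradient ramp, with Gaussian noise. All acquisition
#' constants are recorded in the output so fits never assume them.
#'
#' @param D Ground-truth diffusion coefficient, m^2/s.
#' @param I0 Signal at zero gradient.
#' @param g_max Maximum gradient, T/m.
#' @param g_frac Gradient amplitudes as fractions of `g_max`.
#' @param Delta Diffusion time, s.
#' @param delta Gradient pulse width, s.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1 (1H default).
#' @param sigma Gaussian noise SD in units of `I0`.
#' @param seed Integer seed.
#' @return A `gradient_attenuation` tibble with columns `g`, `intensity` and
#'   acquisition constants as attributes.
#' @export
sim_gradient_series <- function(D = 1.86e-10, I0 = 1, g_max = 0.53,
                                g_frac = seq(0.02, 0.98, length.out = 32),
                                Delta = 0.060, delta = 0.004,
                                gamma = 2.6752218744e8, sigma = 0.01,
                                seed = 1) {
  stopifnot(D > 0, I0 > 0, length(g_frac) >= 2)
  g <- g_max * g_frac
  b <- (gamma * g * delta)^2 * (Delta - delta / 3)
  model <- I0 * exp(-D * b)
  if (model[length(model)] / I0 > 0.9) {
    warn("signal attenuates < 10% at the maximum gradient: D is not measurable")
  }
  withr::with_seed(seed, intensity <- rnorm(length(g), model, sigma * I0))
  out <- tibble(g = g, intensity = intensity)
  attr(out, "acquisition") <- list(Delta = Delta, delta = delta, gamma = gamma)
  attr(out, "truth") <- list(D = D, I0 = I0, sigma = sigma)
  class(out) <- c("gradient_attenuation", class(out))
  out
}

#' Simulate free/bound NMR peak lists
#'
#' Builds a free-state amide peak list and a bound-state copy in which a
#' stated set of interface residues is shifted by given 1H/15N amounts, all
#' other residues receive small Gaussian jitter, and an optional random subset
#' of bound peaks is dropped to emulate exchange broadening.
#'
#' @param residues Integer residue numbers (unique).
#' @param interface Residue numbers to perturb.
#' @param d_h,d_n Interface shift changes, ppm (recycled over `interface`).
#' @param jitter SD of the incidental 1H jitter, ppm; the 15N jitter is
#'   5x larger, matching the relative shift dispersions.
#' @param drop_prob Probability that a bound-state peak is missing.
#' @param seed Integer seed.
#' @return A list with `free` and `bound` peak-list tibbles
#'   (`residue`, `aa`, `dH_ppm`, `dN_ppm`, `present`).
#' @export
sim_peaklists <- function(residues = 1:60, interface = c(36, 37, 40, 44, 45),
                          d_h = 0.08, d_n = 0.5, jitter = 0.002,
                          drop_prob = 0, seed = 1) {
  if (anyDuplicated(residues)) abort("duplicate residue numbers")
  stopifnot(all(interface %in% residues))
  n_res <- length(residues)
  d_h <- rep_len(d_h, length(interface))
  d_n <- rep_len(d_n, length(interface))
  withr::with_seed(seed, {
    free <- tibble(
      residue = residues,
      aa = sample(names(AA3), n_res, replace = TRUE),
      dH_ppm = rnorm(n_res, 8.2, 0.45),
      dN_ppm = rnorm(n_res, 119, 4.5),
      present = TRUE
    )
    bound <- free
    idx <- match(interface, residues)
    sgn_h <- sample(c(-1, 1), length(idx), replace = TRUE)
    sgn_n <- sample(c(-1, 1), length(idx), replace = TRUE)
    bound$dH_ppm <- bound$dH_ppm + rnorm(n_res, 0, jitter)
    bound$dN_ppm <- bound$dN_ppm + rnorm(n_res, 0, 5 * jitter)
    bound$dH_ppm[idx] <- free$dH_ppm[idx] + sgn_h * d_h
    bound$dN_ppm[idx] <- free$dN_ppm[idx] + sgn_n * d_n
    if (drop_prob > 0) {
      dropped <- runif(n_res) < drop_prob
      bound$present[dropped] <- FALSE
      bound$dH_ppm[dropped] <- NA_real_
      bound$dN_ppm[dropped] <- NA_real_
    }
  })
  list(free = free, bound = bound,
       truth = list(interface = interface, d_h = d_h, d_n = d_n,
                    jitter = jitter, drop_prob = drop_prob))
}

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
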