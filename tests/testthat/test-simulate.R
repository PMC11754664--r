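# The synthetic-data generators: determinism, exact noise-free values, and
# agreement of replicate means with the underlying model.

test_that("every generator is a pure, seed-deterministic function", {
  expect_identical(sim_titration(kd_nM = 25.3, seed = 1),
                   sim_titration(kd_nM = 25.3, seed = 1))
  expect_identical(sim_ph_series(seed = 4), sim_ph_series(seed = 4))
  expect_identical(sim_decay_set(seed = 9), sim_decay_set(seed = 9))
  expect_identical(sim_gradient_series(seed = 2), sim_gradient_series(seed = 2))
  expect_identical(sim_peaklists(seed = 3), sim_peaklists(seed = 3))
  # and a different seed changes the noise
  expect_false(identical(sim_titration(kd_nM = 25.3, seed = 1)$fnorm,
                         sim_titration(kd_nM = 25.3, seed = 2)$fnorm))
  # generators do not disturb the global RNG stream
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(sim_titration(kd_nM = 10, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free titration passes through half-saturation at KD", {
  s <- sim_titration(kd_nM = 10, baseline = 0.2, amplitude = 0.6,
                     conc_range = c(10 / 81, 10 * 81), n_points = 9,
                     sigma = 0, seed = 1)
  # log-spaced 9 points over kd/81..81kd puts the middle point exactly at KD
  expect_equal(s$fnorm[5], 0.2 + 0.6 / 2, tolerance = 1e-12)
})

test_that("replicate means converge to the biphasic model curve", {
  kd <- c(20, 2000)
  s <- sim_titration(kd_nM = kd, amplitude = c(0.5, 0.5),
                     conc_range = c(1, 2e4), replicates = 2000,
                     sigma = 0.05, seed = 11)
  model <- 0.5 * hill_saturation(s$conc_nM, kd[1]) +
    0.5 * hill_saturation(s$conc_nM, kd[2])
  expect_true(all(abs(s$fnorm - model) < 3 * s$sem))
  # 1/sqrt(n) scaling of the SEM
  s10 <- sim_titration(kd_nM = kd, amplitude = c(0.5, 0.5),
                       conc_range = c(1, 2e4), replicates = 10,
                       sigma = 0.05, seed = 11)
  expect_rel_equal(median(s$sem) / median(s10$sem), sqrt(10 / 2000), 0.3)
})

test_that("unresolvably close binding modes trigger a warning", {
  expect_warning(sim_titration(kd_nM = c(10, 30), seed = 1), "not be resolvable")
  expect_silent(sim_titration(kd_nM = c(10, 100), conc_range = c(0.1, 1e4),
                              sigma = 0, seed = 1))
})

test_that("pH series matches the two-state sigmoid limits", {
  s <- sim_ph_series(pKa = 6, n = 1.5, f_acid = 0.1, f_base = 0.4,
                     ph = seq(4, 8, 0.25), sigma = 0, seed = 1)
  expect_equal(s$fh[s$ph == 6], (0.1 + 0.4) / 2, tolerance = 1e-12)
  far <- sim_ph_series(pKa = 6, n = 2, f_acid = 0.1, f_base = 0.4,
                       ph = seq(5, 12, 0.5), sigma = 0, seed = 1)
  expect_equal(far$fh[far$ph == 12], 0.4, tolerance = 1e-6)
  expect_error(sim_ph_series(n = 0), "transition")
})

test_that("decay generator reduces to pure biexponential under a delta IRF", {
  w <- sim_decay_set(amplitudes = c(3, 1), tau_ns = c(1, 4), irf = "delta",
                     noise = "none", seed = 1)[[1]]
  tr <- attr(w, "truth")
  expect_equal(w$counts,
               tr$amplitudes[1] * exp(-w$t_ns / 1) + tr$amplitudes[2] * exp(-w$t_ns / 4),
               tolerance = 1e-9)
  # log counts linear in t once a single component dominates
  expect_warning(sim_decay_set(tau_ns = c(0.2, 4), dt = 0.1, seed = 1),
                 "undersamples")
})

test_that("total decay counts match the A1*tau1 + A2*tau2 integral", {
  w <- sim_decay_set(amplitudes = c(2, 1), tau_ns = c(1, 4), irf = "delta",
                     dt = 0.01, peak_counts = 2e4, seed = 5)[[1]]
  tr <- attr(w, "truth")
  expected <- sum(tr$amplitudes * tr$tau_ns) / 0.01
  # trapezoid vs sum edge correction: half the peak bin
  expected <- expected - tr$amplitudes %*% c(1, 1) / 2
  expect_rel_equal(sum(w$counts), as.numeric(expected), 0.01)
})

test_that("gradient attenuation hits I0 at zero gradient and scales with D", {
  g <- sim_gradient_series(D = 2e-10, I0 = 3, g_frac = c(1e-9, seq(0.02, 0.98, length.out = 31)),
                           sigma = 0, seed = 1)
  expect_equal(g$intensity[1], 3, tolerance = 1e-6)
  g1 <- sim_gradient_series(D = 2e-10, sigma = 0, seed = 1)
  g2 <- sim_gradient_series(D = 1e-10, sigma = 0, seed = 1)
  slope <- function(x) coef(lm(log(x$intensity) ~ I(x$g^2)))[2]
  expect_rel_equal(slope(g1) / slope(g2), 2, 1e-9)
  expect_warning(sim_gradient_series(D = 1e-13, sigma = 0, seed = 1),
                 "not measurable")
})

test_that("peak lists perturb exactly the stated interface residues", {
  pl <- sim_peaklists(residues = 1:40, interface = c(5, 9), d_h = 0.1,
                      d_n = 0.6, jitter = 0, seed = 2)
  prof <- weighted_csp(pl$free, pl$bound)
  expect_equal(sort(prof$residue[prof$csp > 1e-9]), c(5, 9))
  none <- sim_peaklists(residues = 1:40, interface = integer(0), d_h = numeric(0),
                        d_n = numeric(0), jitter = 0, seed = 2)
  expect_true(all(weighted_csp(none$free, none$bound)$csp == 0))
  expect_error(sim_peaklists(residues = c(1, 1, 2)), "duplicate")
})

test_that("dropped bound peaks are reported missing, never as zero shift", {
  pl <- sim_peaklists(residues = 1:50, drop_prob = 0.3, seed = 8)
  expect_true(any(!pl$bound$present))
  expect_true(all(is.na(pl$bound$dH_ppm[!pl$bound$present])))
  prof <- weighted_csp(pl$free, pl$bound)
  expect_true(all(is.na(prof$csp[prof$missing])))
})

test_that("toy duplex has fiber-model geometry and complementary strands", {
  m <- sim_toy_complex("ACGTACGTAC", protein_len = 10)
  at <- m$atoms
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  bp_center <- function(i) {
    a <- colMeans(as.matrix(at[at$chain == "A" & at$res_id == i &
                                 at$name %in% ring, c("x", "y", "z")]))
    b <- colMeans(as.matrix(at[at$chain == "B" & at$res_id == 11 - i &
                                 at$name %in% ring, c("x", "y", "z")]))
    (a + b) / 2
  }
  expect_equal(sqrt(sum((bp_center(1) - bp_center(10))^2)), 9 * 3.38,
               tolerance = 1e-6)
  # strand B (read 5'->3' along its own numbering) reverse-complements strand A
  seq_of <- function(chain) {
    b <- unique(at[at$chain == chain, c("res_id", "res_name")])
    sub("^D", "", b$res_name[order(b$res_id)])
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  expect_identical(seq_of("B"), unname(rev(comp[seq_of("A")])))
  expect_error(sim_toy_complex("ACGX"), "ACGT")
})

test_that("PDB write/read round-trip preserves coordinates to 0.001 A", {
  m <- sim_toy_complex("ACGT", protein_len = 5)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, tmp)
  m2 <- read_structure(tmp)
  expect_identical(m2$roles, m$roles)
  expect_lt(max(abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                    as.matrix(m2$atoms[, c("x", "y", "z")]))), 0.001)
})
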