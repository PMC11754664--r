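# Rigid-body docking engine: geometry descriptors, potential derivation,
# Monte Carlo search vs a brute-force oracle, clustering, superposition,
# interfaces and SASA.

test_that("residue-base geometry matches hand trigonometry", {
  # sidechain vector in the base plane
  g0 <- residue_base_geometry(toy_pair_model(r = 5.5, phi_deg = 0))
  expect_equal(nrow(g0), 1L)
  expect_equal(g0$r, 5.5, tolerance = 1e-9)
  expect_equal(g0$phi_deg, 0, tolerance = 1e-9)
  # sidechain vector along the plane normal
  g90 <- residue_base_geometry(toy_pair_model(r = 5.5, phi_deg = 90))
  expect_equal(g90$phi_deg, 90, tolerance = 1e-9)
  # oblique case: phi is exactly the chosen elevation angle
  for (ang in c(12.5, 37, 61)) {
    g <- residue_base_geometry(toy_pair_model(r = 7.2, phi_deg = ang))
    expect_equal(g$r, 7.2, tolerance = 1e-9)
    expect_equal(g$phi_deg, ang, tolerance = 1e-9)
  }
  # beyond the cutoff the pair is omitted
  expect_equal(nrow(residue_base_geometry(toy_pair_model(r = 20), cutoff = 15)), 0L)
})

test_that("interaction energy sums table values over in-range pairs", {
  m <- toy_pair_model(r = 5.5, phi_deg = 20, aa = "ALA", base = "A")
  expect_equal(interaction_energy(m, potential = orientation_potential(0)), 0)
  # single in-range pair reads its own bin
  pot <- orientation_potential(0)
  pot$energy["ALA", "A", 6, 2] <- -1.2   # r in [5,6), phi in [15,30)
  expect_equal(interaction_energy(m, potential = pot), -1.2)
  # additivity over residues: CB at r = 5.5 each, phi = 20 and 0 degrees
  v20 <- c(cos(20 * pi / 180), 0, sin(20 * pi / 180))
  m2 <- as_molecular_model(dplyr::bind_rows(
    base_atoms(base = "A"),
    residue_atoms(c(5.5, 0, 0) - v20, c(5.5, 0, 0), res_id = 1),
    residue_atoms(c(-6.5, 0, 0), c(-5.5, 0, 0), res_id = 2, serial0 = 200)
  ))
  pot$energy["ALA", "A", 6, 1] <- -0.7
  e_both <- interaction_energy(m2, potential = pot)
  expect_equal(e_both, -1.2 + -0.7, tolerance = 1e-12)
})

test_that("energy is invariant under a joint rigid transform", {
  m <- sim_toy_complex("ACGT", protein_len = 6, protein_offset = c(12, 0, 5))
  pot <- potential_from_function(function(r, phi, aa, base) -exp(-(r - 6)^2 / 8))
  e0 <- interaction_energy(m, potential = pot)
  R <- paibind:::random_rotation()
  shift <- c(3, -7, 11)
  m2 <- m
  xyz <- as.matrix(m2$atoms[, c("x", "y", "z")])
  m2$atoms[, c("x", "y", "z")] <- as.data.frame(sweep(xyz %*% t(R), 2, shift, "+"))
  expect_equal(interaction_energy(m2, potential = pot), e0, tolerance = 1e-9)
})

test_that("inverse-Boltzmann derivation matches hand-computed ratios", {
  # 24 single-contact complexes in one (aa, base, r) stratum: 8 in the first
  # angle bin, 4 in each of the other four populated bins
  angles <- c(rep(7, 8), rep(22, 4), rep(40, 4), rep(55, 4), rep(70, 4))
  models <- lapply(angles, function(a) toy_pair_model(r = 5.5, phi_deg = a))
  pot <- derive_potential(models, pseudocount = 0)
  # marginal 24 over 6 bins -> N_ref = 4; first bin N_obs = 8 -> -ln 2
  expect_equal(pot$energy["ALA", "A", 6, 1], -log(2), tolerance = 1e-12)
  expect_equal(pot$energy["ALA", "A", 6, 2], 0, tolerance = 1e-12)   # 4/4
  expect_equal(pot$energy["ALA", "A", 6, 6], 0)                      # 0/4 -> empty obs
  # doubling the training set leaves energies unchanged
  pot2 <- derive_potential(c(models, models), pseudocount = 0)
  expect_equal(pot2$energy, pot$energy, tolerance = 1e-12)
  expect_error(derive_potential(list(toy_pair_model(r = 40)), pseudocount = 0),
               "no in-range")
})

test_that("Kabsch superposition recovers synthetic rotations", {
  pts <- withr::with_seed(3, matrix(rnorm(36), 12, 3))
  sp0 <- superpose(pts, pts)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-12)
  R <- withr::with_seed(4, paibind:::random_rotation())
  mob <- sweep(pts %*% t(R), 2, c(5, -2, 9), "+")
  sp <- superpose(pts, mob)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(sp$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # mirror images: a proper rotation is chosen and RMSD stays positive
  mirror <- pts %*% diag(c(-1, 1, 1))
  spm <- superpose(pts, mirror)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-9)
  expect_gt(spm$rmsd, 0.1)
  expect_error(superpose(pts[1:2, ], mob[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition agrees with the bio3d reference implementation", {
  pts <- withr::with_seed(9, matrix(rnorm(30), 10, 3))
  R <- withr::with_seed(10, paibind:::random_rotation())
  mob <- sweep(pts %*% t(R), 2, c(1, 2, 3), "+") +
    withr::with_seed(11, matrix(rnorm(30, 0, 0.3), 10, 3))
  sp <- superpose(pts, mob)
  xyz_fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(pts)),
                                             mobile = as.numeric(t(mob))))
  rmsd_bio3d <- sqrt(mean((xyz_fit - as.numeric(t(pts)))^2) * 3)
  expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("Monte Carlo docking is deterministic and elitist", {
  m <- sim_toy_complex("ACGTAC", protein_len = 8, protein_offset = c(14, 0, 8.45))
  pot <- potential_from_function(function(r, phi, aa, base) -exp(-(r - 6)^2 / 8))
  p1 <- mc_dock(m, pot, runs = 3, steps = 300, seed = 7)
  p2 <- mc_dock(m, pot, runs = 3, steps = 300, seed = 7)
  expect_identical(p1$total, p2$total)
  expect_identical(p1$rotation, p2$rotation)
  expect_s3_class(p1, "dock_poses")
  # elitism: returned pose is never worse than the initial pose of its run
  inits <- vapply(seq_len(3), function(k) {
    withr::with_seed(7 + k - 1, {
      prep <- paibind:::dock_prep(m)
      dna_ctr <- colMeans(prep$dna_heavy)
      sphere_r <- max(sqrt(rowSums(sweep(prep$dna_heavy, 2, dna_ctr)^2))) +
        max(sqrt(rowSums(sweep(prep$prot_heavy, 2, prep$prot_centroid)^2))) + 4
      R <- paibind:::random_rotation()
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      tv <- (dna_ctr + sphere_r * u) - prep$prot_centroid
      e <- paibind:::energy_of_pose(prep, pot, R, tv, 2.5, 1)
      e$table + e$steric
    })
  }, numeric(1))
  expect_true(all(p1$total <= inits + 1e-9))
})

test_that("translation-only MC matches the exhaustive 0.5 A grid oracle", {
  m <- sim_toy_complex("ACGT", protein_len = 6, protein_offset = c(13, 0, 5.07))
  pot <- potential_from_function(function(r, phi, aa, base) -exp(-(r - 6)^2 / 8))
  prep <- paibind:::dock_prep(m)
  # independent oracle: enumerate all translations on a 0.5 A grid
  grid <- as.matrix(expand.grid(x = seq(-18, 0, 0.5), y = seq(-6, 6, 0.5),
                                z = seq(-6, 6, 0.5)))
  grid_vals <- apply(grid, 1, function(tv) {
    e <- paibind:::energy_of_pose(prep, pot, diag(3), tv,
                                  steric_cutoff = 2.5, steric_k = 1)
    e$table + e$steric
  })
  e_grid <- min(grid_vals)
  poses <- mc_dock(m, pot, runs = 5, steps = 1500, seed = 2, rotate = FALSE,
                   trans_step = 0.8)
  e_mc <- min(poses$total)
  expect_lt(e_mc, 0)
  expect_lt((e_mc - e_grid) / abs(e_grid), 0.01)
})

test_that("complete-linkage clustering bounds diameters and ranks by energy", {
  m <- sim_toy_complex("ACGT", protein_len = 6)
  # two tight pose groups far apart, plus energies making group 2 the best
  mk <- function(tv, e) tibble::tibble(run = 1L, seed = 1L, energy = e,
                                       steric = 0, total = e,
                                       rotation = list(diag(3)),
                                       translation = list(tv))
  poses <- dplyr::bind_rows(
    mk(c(0, 0, 0), -1), mk(c(0.5, 0, 0), -2), mk(c(0, 0.5, 0), -1.5),
    mk(c(20, 0, 0), -5), mk(c(20.4, 0, 0), -3)
  )
  class(poses) <- c("dock_poses", class(poses))
  cl <- cluster_poses(poses, m, cutoff = 3)
  expect_identical(length(unique(cl$labels)), 2L)
  # max intra-cluster pairwise RMSD <= cutoff (here: pure translations)
  for (g in unique(cl$labels)) {
    tvs <- do.call(rbind, poses$translation[cl$labels == g])
    dmax <- max(dist(tvs))
    expect_lte(dmax, 3)
  }
  # the cluster holding the global minimum pose ranks first
  top <- cl$ranking$cluster[cl$ranking$rank == 1]
  expect_identical(unname(cl$labels[which.min(poses$total)]), top)
  expect_equal(cl$ranking$rep_energy[cl$ranking$rank == 1], -5)
  # all poses identical -> one cluster
  one <- dplyr::bind_rows(mk(c(0, 0, 0), -1), mk(c(0, 0, 0), -1))
  class(one) <- c("dock_poses", class(one))
  expect_identical(length(unique(cluster_poses(one, m, cutoff = 3)$labels)), 1L)
  # cluster count is monotone non-increasing in the cutoff
  counts <- vapply(c(0.1, 0.6, 3, 25), function(h) {
    length(unique(cluster_poses(poses, m, cutoff = h)$labels))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # top-k ranking variant runs and covers every pose exactly once
  cl10 <- cluster_poses(poses, m, cutoff = 3, rank = "topk", k = 2)
  expect_identical(sort(unique(cl10$labels)), 1:2)
  expect_length(cl10$labels, nrow(poses))
})

test_that("interface atoms and hydrogen bonds obey the distance rules", {
  # one lysine-like donor at hydrogen-bond range above a base oxygen
  xo <- 1.4 * cos(pi / 3); yo <- 1.4 * sin(pi / 3)   # above ring position 2
  prot <- tibble::tibble(
    serial = 101:103, name = c("CA", "CD", "NZ"), res_name = "LYS",
    chain = "P", res_id = 1,
    x = rep(xo, 3), y = rep(yo, 3), z = c(5.8, 4.3, 2.9))
  base <- base_atoms(centroid = c(0, 0, 0), base = "C")
  base$name[2] <- "O2"   # ring position (0.7, 1.21, 0) becomes an oxygen
  m <- as_molecular_model(dplyr::bind_rows(base, prot))
  ic <- interface_contacts(m, cutoff = 5)
  expect_true("NZ" %in% ic$protein_atoms$name)
  expect_true(nrow(ic$dna_atoms) > 0)
  # N-O at 2.9 A with a 180 deg donor angle is a hydrogen bond
  hb <- ic$hbonds
  expect_true(any(hb$donor_atom == "NZ" & hb$acceptor_atom == "O2" &
                    abs(hb$dist - 2.9) < 1e-6 & hb$angle_deg > 160))
  # beyond 5 A: no interface at all
  far <- prot
  far[, c("x", "y", "z")] <- far[, c("x", "y", "z")] + 100
  ic_far <- interface_contacts(as_molecular_model(dplyr::bind_rows(base, far)),
                               cutoff = 5)
  expect_identical(nrow(ic_far$protein_atoms), 0L)
  expect_identical(nrow(ic_far$hbonds), 0L)
  # 4.9 A pair is interface, 5.1 A is not (probe sits above one ring atom)
  near <- function(dz) {
    p <- tibble::tibble(serial = 1, name = "CB", res_name = "ALA", chain = "P",
                        res_id = 1, x = 1.4, y = 0, z = dz)
    mm <- as_molecular_model(dplyr::bind_rows(
      base_atoms(centroid = c(0, 0, 0), base = "A"), p))
    nrow(interface_contacts(mm, cutoff = 5)$protein_atoms)
  }
  expect_identical(near(4.9), 1L)
  expect_identical(near(5.1), 0L)
})

test_that("Shrake-Rupley SASA matches analytic spheres", {
  one <- as_molecular_model(tibble::tibble(
    serial = 1, name = "CA", res_name = "GLY", chain = "P", res_id = 1,
    x = 0, y = 0, z = 0, element = "C"))
  s1 <- sasa(one)
  expect_rel_equal(s1$sasa, 4 * pi * (1.70 + 1.4)^2, 0.01)
  # two identical atoms far apart: each keeps the isolated-atom area
  two <- as_molecular_model(tibble::tibble(
    serial = 1:2, name = "CA", res_name = "GLY", chain = "P", res_id = 1:2,
    x = c(0, 50), y = 0, z = 0, element = "C"))
  s2 <- sasa(two)
  expect_equal(s2$sasa, rep(s1$sasa, 2), tolerance = 1e-9)
  # an atom enclosed in a tight shell is buried
  shell_pts <- paibind:::fibonacci_sphere(40) * 2.4
  shell <- tibble::tibble(
    serial = 2:41, name = "C", res_name = "GLY", chain = "P", res_id = 2,
    x = shell_pts[, 1], y = shell_pts[, 2], z = shell_pts[, 3], element = "C")
  buried <- as_molecular_model(dplyr::bind_rows(
    tibble::tibble(serial = 1, name = "CA", res_name = "GLY", chain = "P",
                   res_id = 1, x = 0, y = 0, z = 0, element = "C"), shell))
  sb <- sasa(buried)
  expect_lt(sb$sasa[sb$residue == 1], 1)
  # unknown element falls back with a warning
  odd <- as_molecular_model(tibble::tibble(
    serial = 1, name = "XX", res_name = "GLY", chain = "P", res_id = 1,
    x = 0, y = 0, z = 0, element = "Q"))
  expect_warning(sasa(odd), "unknown element")
})

test_that("structure reader flags malformed and non-standard input", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("garbage that is not a pdb", tmp)
  expect_error(read_structure(tmp))
  # unknown residue names are flagged and excluded from scoring roles
  mixed <- tibble::tibble(
    serial = 1:2, name = c("CA", "C1"), res_name = c("ALA", "XYZ"),
    chain = c("P", "Z"), res_id = 1,
    x = 0, y = 0, z = 0, element = "C")
  expect_warning(mm <- as_molecular_model(mixed), "non-standard")
  expect_identical(unname(mm$roles["Z"]), "other")
})
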