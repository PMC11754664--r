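# Rigid-body protein-DNA docking: residue/base geometry descriptors, the
# binned distance/orientation knowledge-based potential, Metropolis Monte
# Carlo search, and complete-linkage pose clustering.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
RING_ATOMS <- list(
  purine = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6")
)

base_type <- function(res_name) sub("^D", "", res_name)

# Precompute everything pose-independent: per-residue reference points in the
# protein frame, per-base ring centroids/normals, heavy-atom coordinates.
dock_prep <- function(model) {
  atoms <- model$atoms
  prot_chains <- names(model$roles)[model$roles == "protein"]
  dna_chains <- names(model$roles)[model$roles == "dna"]
  if (!length(prot_chains) || !length(dna_chains)) {
    abort("model must contain both a protein and a DNA chain")
  }
  pa <- atoms[atoms$chain %in% prot_chains, ]
  da <- atoms[atoms$chain %in% dna_chains, ]

  res_keys <- unique(pa[, c("chain", "res_id", "res_name")])
  ca_list <- list(); sc_list <- list(); keep <- logical(nrow(res_keys))
  for (i in seq_len(nrow(res_keys))) {
    sel <- pa$chain == res_keys$chain[i] & pa$res_id == res_keys$res_id[i]
    ra <- pa[sel, ]
    ca <- ra[ra$name == "CA", c("x", "y", "z")]
    if (nrow(ca) != 1) {
      warn(sprintf("residue %s%d has no CA; skipped", res_keys$chain[i], res_keys$res_id[i]))
      next
    }
    side <- ra[!ra$name %in% BACKBONE_ATOMS & ra$element != "H", c("x", "y", "z")]
    sc <- if (nrow(side)) colMeans(as.matrix(side)) else as.numeric(ca)
    ca_list[[i]] <- as.numeric(ca)
    sc_list[[i]] <- sc
    keep[i] <- TRUE
  }
  res_keys <- res_keys[keep, ]
  ca_mat <- do.call(rbind, ca_list[keep])
  sc_mat <- do.call(rbind, sc_list[keep])

  base_keys <- unique(da[, c("chain", "res_id", "res_name")])
  cent_list <- list(); norm_list <- list(); bkeep <- logical(nrow(base_keys))
  for (i in seq_len(nrow(base_keys))) {
    bt <- base_type(base_keys$res_name[i])
    ring <- RING_ATOMS[[if (bt %in% c("A", "G")) "purine" else "pyrimidine"]]
    sel <- da$chain == base_keys$chain[i] & da$res_id == base_keys$res_id[i] &
      da$name %in% ring
    pts <- as.matrix(da[sel, c("x", "y", "z")])
    if (nrow(pts) < 3) {
      warn(sprintf("base %s%d has too few ring atoms; skipped",
                   base_keys$chain[i], base_keys$res_id[i]))
      next
    }
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    cent_list[[i]] <- ctr
    norm_list[[i]] <- sv$v[, 3]   # least-squares plane normal
    bkeep[i] <- TRUE
  }
  base_keys <- base_keys[bkeep, ]

  list(
    res = res_keys, ca = ca_mat, sc = sc_mat,
    aa_idx = match(res_keys$res_name, PROTEIN_RES),
    prot_heavy = as.matrix(pa[pa$element != "H", c("x", "y", "z")]),
    prot_centroid = colMeans(as.matrix(pa[, c("x", "y", "z")])),
    base = base_keys,
    base_idx = match(base_type(base_keys$res_name), c("A", "C", "G", "T")),
    base_centroid = do.call(rbind, cent_list[bkeep]),
    base_normal = do.call(rbind, norm_list[bkeep]),
    dna_heavy = as.matrix(da[da$element != "H", c("x", "y", "z")])
  )
}

transform_points <- function(pts, R, tvec, ctr) {
  sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr + tvec, "+")
}

identity_pose <- function() list(rotation = diag(3), translation = c(0, 0, 0))

#' Residue-base geometry descriptors
#'
#' For every protein-residue / DNA-base pair within `cutoff`, the distance
#' `r` between the residue sidechain centroid (Calpha for glycine) and the
#' base ring centroid, and the angle `phi` in `[0, 90]` degrees between the
#' sidechain direction (Calpha to sidechain centroid) and the base plane,
#' fitted by least squares to the ring atoms. Residues whose sidechain
#' coincides with Calpha get `phi = 0` by convention.
#'
#' @param model A `molecular_model` with protein and DNA chains.
#' @param pose Optional rigid pose applied to the protein.
#' @param cutoff Maximum `r` reported, Angstrom.
#' @return A tibble with one row per in-range pair: residue/base identities,
#'   `r` and `phi_deg`.
#' @export
residue_base_geometry <- function(model, pose = NULL, cutoff = 15) {
  prep <- dock_prep(model)
  pose <- pose %||% identity_pose()
  geom <- pair_geometry(prep, pose$rotation, pose$translation, cutoff)
  geom
}

# Fast pose-dependent geometry: index vectors, no tibble allocation (the MC
# inner loop calls this thousands of times).
pair_geometry_core <- function(prep, R, tvec, cutoff) {
  sc <- transform_points(prep$sc, R, tvec, prep$prot_centroid)
  ca <- transform_points(prep$ca, R, tvec, prep$prot_centroid)
  v <- sc - ca
  vlen <- sqrt(rowSums(v^2))
  d2 <- outer(rowSums(sc^2), rowSums(prep$base_centroid^2), "+") -
    2 * sc %*% t(prep$base_centroid)
  r <- sqrt(pmax(d2, 0))
  dots <- abs((v / pmax(vlen, 1e-12)) %*% t(prep$base_normal))
  phi <- asin(pmin(dots, 1)) * 180 / pi
  phi[vlen < 1e-9, ] <- 0
  idx <- which(r <= cutoff, arr.ind = TRUE)
  list(res = idx[, 1], base = idx[, 2], r = r[idx], phi = phi[idx])
}

pair_geometry <- function(prep, R, tvec, cutoff) {
  g <- pair_geometry_core(prep, R, tvec, cutoff)
  tibble(
    res_chain = prep$res$chain[g$res],
    residue = prep$res$res_id[g$res],
    res_name = prep$res$res_name[g$res],
    base_chain = prep$base$chain[g$base],
    base_id = prep$base$res_id[g$base],
    base = base_type(prep$base$res_name[g$base]),
    r = g$r,
    phi_deg = g$phi
  )
}

#' Construct an orientation potential
#'
#' Bins are explicit configuration: contiguous distance-bin edges ending at
#' the interaction cutoff and angle-bin edges covering 0-90 degrees. The
#' energy table is indexed by amino-acid type, base type, distance bin and
#' angle bin; contributions beyond the last distance edge are exactly zero.
#'
#' @param energy 4-d array `[20 aa, 4 bases, n_r, n_phi]` with dimnames, or
#'   a single number recycled (handy for tests).
#' @param r_edges Distance bin edges, Angstrom (default 0-15 in 1 A steps).
#' @param phi_edges Angle bin edges, degrees (default 0-90 in 15 deg steps).
#' @return An `orientation_potential`.
#' @export
orientation_potential <- function(energy = 0, r_edges = 0:15,
                                  phi_edges = seq(0, 90, by = 15)) {
  stopifnot(!is.unsorted(r_edges, strictly = TRUE),
            !is.unsorted(phi_edges, strictly = TRUE),
            phi_edges[1] == 0, phi_edges[length(phi_edges)] == 90)
  dims <- c(length(PROTEIN_RES), 4, length(r_edges) - 1, length(phi_edges) - 1)
  dn <- list(PROTEIN_RES, c("A", "C", "G", "T"), NULL, NULL)
  if (length(energy) == 1) energy <- array(energy, dims, dn)
  stopifnot(all(dim(energy) == dims), all(is.finite(energy)))
  dimnames(energy) <- dn
  structure(list(energy = energy, r_edges = r_edges, phi_edges = phi_edges,
                 cutoff = r_edges[length(r_edges)]),
            class = "orientation_potential")
}

#' Build a potential from a function of the bin centers
#'
#' @param f Function `(r_mid, phi_mid, aa, base) -> energy`, vectorized over
#'   nothing (called per bin); useful for engineering smooth test wells.
#' @inheritParams orientation_potential
#' @return An `orientation_potential`.
#' @export
potential_from_function <- function(f, r_edges = 0:15,
                                    phi_edges = seq(0, 90, by = 15)) {
  pot <- orientation_potential(0, r_edges, phi_edges)
  r_mid <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  p_mid <- (phi_edges[-1] + phi_edges[-length(phi_edges)]) / 2
  for (i in seq_along(PROTEIN_RES)) for (j in 1:4) {
    for (k in seq_along(r_mid)) for (l in seq_along(p_mid)) {
      pot$energy[i, j, k, l] <- f(r_mid[k], p_mid[l], PROTEIN_RES[i],
                                  c("A", "C", "G", "T")[j])
    }
  }
  pot
}

lookup_energy <- function(pot, res_name, base, r, phi) {
  kr <- findInterval(r, pot$r_edges, rightmost.closed = TRUE)
  kp <- findInterval(phi, pot$phi_edges, rightmost.closed = TRUE)
  ok <- kr >= 1 & kr <= length(pot$r_edges) - 1 & res_name %in% PROTEIN_RES
  i <- match(res_name, PROTEIN_RES)
  j <- match(base, c("A", "C", "G", "T"))
  e <- numeric(length(r))
  w <- which(ok)
  if (length(w)) {
    e[w] <- pot$energy[cbind(i[w], j[w], kr[w], pmin(kp[w], dim(pot$energy)[4]))]
  }
  e
}

#' Knowledge-based interaction energy of a pose
#'
#' Sum over all residue-base pairs within the potential's distance cutoff of
#' the tabulated energy at their (distance, plane angle) bin (arbitrary
#' units). Invariant under any global rigid transform applied jointly to
#' protein and DNA. Optionally adds the soft-core steric penalty used during
#' Monte Carlo search (reported separately by [mc_dock()]).
#'
#' @param model A `molecular_model`.
#' @param pose Rigid pose for the protein (`NULL` = as-is).
#' @param potential An `orientation_potential`.
#' @param steric Include the quadratic clash penalty?
#' @param steric_cutoff,steric_k Clash onset distance (A) and stiffness.
#' @return Energy (one number), with attribute `"steric"` when requested.
#' @export
interaction_energy <- function(model, pose = NULL, potential,
                               steric = FALSE, steric_cutoff = 2.5,
                               steric_k = 1) {
  prep <- dock_prep(model)
  pose <- pose %||% identity_pose()
  e <- energy_of_pose(prep, potential, pose$rotation, pose$translation,
                      steric_cutoff = if (steric) steric_cutoff else NULL,
                      steric_k = steric_k)
  out <- e$table
  if (steric) attr(out, "steric") <- e$steric
  out
}

energy_of_pose <- function(prep, pot, R, tvec, steric_cutoff = NULL,
                           steric_k = 1) {
  g <- pair_geometry_core(prep, R, tvec, pot$cutoff)
  e_tab <- 0
  if (length(g$r)) {
    kr <- findInterval(g$r, pot$r_edges, rightmost.closed = TRUE)
    kp <- pmin(findInterval(g$phi, pot$phi_edges, rightmost.closed = TRUE),
               dim(pot$energy)[4])
    i <- prep$aa_idx[g$res]
    j <- prep$base_idx[g$base]
    ok <- !is.na(i) & !is.na(j) & kr >= 1 & kr <= length(pot$r_edges) - 1
    if (any(ok)) {
      e_tab <- sum(pot$energy[cbind(i[ok], j[ok], kr[ok], kp[ok])])
    }
  }
  e_st <- 0
  if (!is.null(steric_cutoff)) {
    ph <- transform_points(prep$prot_heavy, R, tvec, prep$prot_centroid)
    d2 <- outer(rowSums(ph^2), rowSums(prep$dna_heavy^2), "+") -
      2 * ph %*% t(prep$dna_heavy)
    d <- sqrt(pmax(d2, 0))
    ov <- pmax(steric_cutoff - d, 0)
    e_st <- steric_k * sum(ov^2)
  }
  list(table = e_tab, steric = e_st)
}

#' Monte Carlo rigid-body docking
#'
#' Independent Metropolis runs over 6-DOF rigid poses of the protein around
#' the DNA. Each run starts from a random orientation on a sphere around the
#' DNA (re-initialized, with a log entry, if sterically irresolvable), takes
#' random rotation + translation moves under a geometric cooling schedule,
#' and returns its best-seen pose (elitism). The search energy is the
#' knowledge-based table energy plus a soft-core quadratic clash penalty
#' (pure table energy has no excluded volume and rigid docking collapses
#' without one); both parts are reported separately.
#'
#' @param model A `molecular_model` with protein and DNA.
#' @param potential An `orientation_potential`.
#' @param runs Number of independent runs (the reference workflow uses 200).
#' @param steps Metropolis steps per run.
#' @param seed Base seed; run `k` uses `seed + k - 1`.
#' @param trans_step,rot_step_deg Move sizes (A, degrees). `rot_step_deg = 0`
#'   with `rotate = FALSE` restricts the search to translations.
#' @param temp Start and end temperatures of the geometric schedule
#'   (arbitrary-unit energies).
#' @param rotate Sample orientations? `FALSE` freezes the initial (or given)
#'   orientation for reduced-dimensionality searches.
#' @param init_translation,init_rotation Optional fixed starting pose.
#' @param steric_cutoff,steric_k Clash penalty parameters.
#' @return A `dock_poses` tibble: `run`, `seed`, `energy` (table part),
#'   `steric`, `total`, and list-columns `rotation`, `translation`.
#' @export
mc_dock <- function(model, potential, runs = 200, steps = 2500, seed = 1,
                    trans_step = 1.0, rot_step_deg = 5, temp = c(5, 0.1),
                    rotate = TRUE, init_translation = NULL,
                    init_rotation = NULL, steric_cutoff = 2.5, steric_k = 1) {
  stopifnot(runs >= 1, steps >= 1)
  prep <- dock_prep(model)
  cool <- exp(seq(log(temp[1]), log(temp[2]), length.out = steps))
  dna_ctr <- colMeans(prep$dna_heavy)
  sphere_r <- max(sqrt(rowSums(sweep(prep$dna_heavy, 2, dna_ctr)^2))) +
    max(sqrt(rowSums(sweep(prep$prot_heavy, 2, prep$prot_centroid)^2))) + 4

  run_one <- function(run_seed, run_id) {
    withr::with_seed(run_seed, {
      for (attempt in 1:20) {
        R <- if (!is.null(init_rotation)) init_rotation
             else if (rotate) random_rotation() else diag(3)
        tv <- if (!is.null(init_translation)) init_translation else {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          (dna_ctr + sphere_r * u) - prep$prot_centroid
        }
        e <- energy_of_pose(prep, potential, R, tv, steric_cutoff, steric_k)
        if (e$steric < 100) break
        if (attempt == 20) inform(sprintf("run %d: steric overlap unresolved after 20 re-initializations", run_id))
      }
      cur <- e; cur_R <- R; cur_t <- tv
      best <- cur; best_R <- R; best_t <- tv
      for (s in seq_len(steps)) {
        prop_R <- if (rotate && rot_step_deg > 0) small_rotation(rot_step_deg) %*% cur_R else cur_R
        prop_t <- cur_t + rnorm(3, 0, trans_step)
        prop <- energy_of_pose(prep, potential, prop_R, prop_t,
                               steric_cutoff, steric_k)
        dE <- (prop$table + prop$steric) - (cur$table + cur$steric)
        if (dE <= 0 || runif(1) < exp(-dE / cool[s])) {
          cur <- prop; cur_R <- prop_R; cur_t <- prop_t
          if (cur$table + cur$steric < best$table + best$steric) {
            best <- cur; best_R <- cur_R; best_t <- cur_t
          }
        }
      }
      tibble(run = run_id, seed = run_seed,
             energy = best$table, steric = best$steric,
             total = best$table + best$steric,
             rotation = list(best_R), translation = list(best_t))
    })
  }

  out <- bind_rows(lapply(seq_len(runs), function(k) run_one(seed + k - 1, k)))
  attr(out, "protein_centroid") <- prep$prot_centroid
  class(out) <- c("dock_poses", class(out))
  out
}

#' Cluster docking poses by Calpha RMSD
#'
#' Pairwise distance between two poses is the RMSD of protein Calpha atoms
#' after the DNA frames are superposed (poses from [mc_dock()] share the DNA
#' frame, so their Calpha coordinates are compared directly). Complete-
#' linkage hierarchical clustering is cut at `cutoff`, which bounds every
#' cluster's diameter by the cutoff. Clusters are ranked by the energy of
#' their representative (lowest-energy member); `rank = "topk"` ranks by the
#' mean energy of each cluster's `k` best members instead.
#'
#' @param poses A `dock_poses` tibble.
#' @param model The `molecular_model` the poses refer to.
#' @param cutoff RMSD cut height, Angstrom (default 3).
#' @param rank `"representative"` or `"topk"`.
#' @param k Members averaged under `"topk"`.
#' @return A `cluster_solution`: `labels` (per pose), `ranking` tibble
#'   (cluster, size, representative pose index, energy, rank), and the
#'   `hclust` tree.
#' @export
cluster_poses <- function(poses, model, cutoff = 3,
                          rank = c("representative", "topk"), k = 10) {
  rank <- match.arg(rank)
  if (nrow(poses) < 2) abort("at least 2 poses are required")
  prep <- dock_prep(model)
  flat <- t(vapply(seq_len(nrow(poses)), function(i) {
    as.numeric(transform_points(prep$ca, poses$rotation[[i]],
                                poses$translation[[i]], prep$prot_centroid))
  }, numeric(3 * nrow(prep$ca))))
  d <- dist(flat) / sqrt(nrow(prep$ca))   # ||vec diff|| / sqrt(n) = Calpha RMSD
  hc <- hclust(d, method = "complete")
  labels <- cutree(hc, h = cutoff)
  energy <- poses$total
  ranking <- tibble(cluster = sort(unique(labels))) |>
    mutate(
      size = vapply(.data$cluster, function(cl) sum(labels == cl), integer(1)),
      representative = vapply(.data$cluster, function(cl) {
        members <- which(labels == cl)
        members[which.min(energy[members])]
      }, integer(1)),
      rep_energy = energy[.data$representative],
      score = if (rank == "representative") .data$rep_energy else
        vapply(.data$cluster, function(cl) {
          e <- sort(energy[labels == cl])
          mean(e[seq_len(min(k, length(e)))])
        }, numeric(1))
    ) |>
    arrange(.data$score) |>
    mutate(rank = row_number())
  structure(list(labels = labels, ranking = ranking, hclust = hc,
                 cutoff = cutoff, rank_method = rank),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d poses in %d cluster(s) at %.1f A (%s ranking)\n",
              length(x$labels), nrow(x$ranking), x$cutoff, x$rank_method))
  print(x$ranking, n = 5)
  invisible(x)
}

#' Inverse-Boltzmann orientation potential from training complexes
#'
#' Counts residue-base contacts of the training complexes in the
#' (aa, base, distance, angle) bins and converts them to energies
#' `E = -ln[(N_obs + p) / (N_ref + p)]` with pseudo-count `p`. The reference
#' state is distance-marginal: the observed counts of each
#' (aa, base, distance) stratum spread uniformly across the angle bins, so
#' the potential measures orientational preference at each distance.
#'
#' @param models List of `molecular_model` training complexes.
#' @param r_edges,phi_edges Bin edges (see [orientation_potential()]).
#' @param pseudocount Additive regularizer `p`.
#' @return An `orientation_potential`.
#' @export
derive_potential <- function(models, r_edges = 0:15,
                             phi_edges = seq(0, 90, by = 15),
                             pseudocount = 1) {
  if (inherits(models, "molecular_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  pot <- orientation_potential(0, r_edges, phi_edges)
  n_obs <- pot$energy    # zero array with the right shape
  for (m in models) {
    geom <- residue_base_geometry(m, cutoff = pot$cutoff)
    if (!nrow(geom)) next
    kr <- findInterval(geom$r, r_edges, rightmost.closed = TRUE)
    kp <- findInterval(geom$phi_deg, phi_edges, rightmost.closed = TRUE)
    kp <- pmin(kp, length(phi_edges) - 1)
    i <- match(geom$res_name, PROTEIN_RES)
    j <- match(geom$base, c("A", "C", "G", "T"))
    ok <- !is.na(i) & kr >= 1 & kr <= length(r_edges) - 1
    for (w in which(ok)) {
      n_obs[i[w], j[w], kr[w], kp[w]] <- n_obs[i[w], j[w], kr[w], kp[w]] + 1
    }
  }
  if (sum(n_obs) == 0) abort("no in-range contacts in the training set")
  n_phi <- length(phi_edges) - 1
  marg <- apply(n_obs, c(1, 2, 3), sum)
  n_ref <- aperm(array(rep(marg / n_phi, n_phi),
                       c(dim(marg), n_phi)), c(1, 2, 3, 4))
  e <- -log((n_obs + pseudocount) / (n_ref + pseudocount))
  # bins with no observations carry no statistics: neutral, not repulsive
  if (pseudocount == 0) e[n_obs == 0] <- 0
  e[!is.finite(e)] <- 0
  pot$energy <- e
  pot
}
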