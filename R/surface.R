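# Molecular surfaces and interfaces: Shrake-Rupley solvent-accessible
# surface area, relative accessibility against Gly-X-Gly references, 5 A
# interface annotation and heavy-atom hydrogen-bond listing.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# Theoretical maximum accessible areas of residue X in an extended
# Gly-X-Gly tripeptide (A^2), used to normalize per-residue SASA.
GXG_REFERENCE <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA with `n_points` quadrature points per atom (>= 960 for ~1%
#' accuracy on an isolated sphere). Per-residue areas are normalized by
#' extended Gly-X-Gly reference areas to give relative accessibility for
#' protein residues; unknown residue types get `NA` relative values.
#'
#' @param model A `molecular_model` (or an atom tibble).
#' @param probe Probe radius, Angstrom (water, 1.4).
#' @param n_points Sphere points per atom.
#' @return A tibble per residue: `chain`, `residue`, `res_name`, `sasa`
#'   (A^2), `rel_sasa`. Atom-level areas are attached as `attr(, "atoms")`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960) {
  atoms <- if (inherits(model, "molecular_model")) model$atoms else as_tibble(model)
  el <- atoms$element
  unknown <- !el %in% names(VDW_RADII)
  if (any(unknown)) {
    warn(sprintf("unknown element(s) %s: default 1.7 A radius used",
                 paste(unique(el[unknown]), collapse = ", ")))
  }
  radii <- unname(VDW_RADII[el])
  radii[is.na(radii)] <- 1.70
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(n_points)
  rr <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * rr[i], 2, xyz[i, ], "+")
    d_nb <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(d_nb < rr[i] + rr & seq_len(n) != i)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 > rr[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * rr[i]^2
  }
  out <- atoms |>
    mutate(.area = areas) |>
    group_by(.data$chain, .data$res_id, .data$res_name) |>
    summarise(sasa = sum(.data$.area), .groups = "drop") |>
    mutate(rel_sasa = .data$sasa / unname(GXG_REFERENCE[.data$res_name])) |>
    dplyr::rename(residue = "res_id")
  attr(out, "atoms") <- mutate(atoms, sasa = areas)
  out
}

#' Protein-DNA interface atoms and hydrogen bonds
#'
#' Interface atoms are those with any partner atom within `cutoff`
#' (default 5 A). Hydrogen bonds are donor-acceptor heavy-atom pairs within
#' `hbond_dist` whose angle at the donor (bonded-neighbor - donor - acceptor)
#' is at least `hbond_angle` degrees. Donor/acceptor assignment uses a
#' bundled heavy-atom chemistry heuristic: nitrogens with a bonded heavy
#' neighbor donate; oxygens and ring nitrogens accept.
#'
#' @param model A `molecular_model` with protein and DNA chains.
#' @param pose Optional rigid pose applied to the protein.
#' @param cutoff Interface distance cutoff, Angstrom.
#' @param hbond_dist,hbond_angle Hydrogen-bond criteria (A, degrees).
#' @return A list with `protein_atoms` and `dna_atoms` (interface atom
#'   tibbles) and `hbonds` (one row per donor-acceptor pair, either
#'   direction).
#' @export
interface_contacts <- function(model, pose = NULL, cutoff = 5,
                               hbond_dist = 3.5, hbond_angle = 120) {
  if (!is.null(pose)) model <- apply_pose(model, pose)
  atoms <- model$atoms
  prot <- atoms[atoms$chain %in% names(model$roles)[model$roles == "protein"], ]
  dna <- atoms[atoms$chain %in% names(model$roles)[model$roles == "dna"], ]
  if (!nrow(prot) || !nrow(dna)) abort("model must contain protein and DNA chains")
  P <- as.matrix(prot[, c("x", "y", "z")])
  D <- as.matrix(dna[, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(D^2), "+") - 2 * P %*% t(D)
  d <- sqrt(pmax(d2, 0))
  in_p <- apply(d <= cutoff, 1, any)
  in_d <- apply(d <= cutoff, 2, any)

  hb <- hbond_pairs(prot, dna, d, hbond_dist, hbond_angle)
  list(protein_atoms = prot[in_p, ], dna_atoms = dna[in_d, ], hbonds = hb)
}

# acceptors: O anywhere; ring N (N1/N3/N7) on bases. donors: N with a bonded
# heavy neighbor in the same residue (proxy for carrying a proton).
hbond_pairs <- function(prot, dna, d, hbond_dist, hbond_angle) {
  role_of <- function(a) {
    donor <- a$element == "N"
    acceptor <- a$element == "O" |
      (a$element == "N" & a$name %in% c("N1", "N3", "N7"))
    list(donor = donor, acceptor = acceptor)
  }
  rp <- role_of(prot)
  rd <- role_of(dna)
  cand <- which(d <= hbond_dist, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(tibble(donor_chain = character(), donor_residue = integer(),
                  donor_atom = character(), acceptor_chain = character(),
                  acceptor_residue = integer(), acceptor_atom = character(),
                  dist = numeric(), angle_deg = numeric()))
  }
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    for (dir in c("p2d", "d2p")) {
      if (dir == "p2d" && !(rp$donor[i] && rd$acceptor[j])) next
      if (dir == "d2p" && !(rd$donor[j] && rp$acceptor[i])) next
      don <- if (dir == "p2d") prot[i, ] else dna[j, ]
      acc <- if (dir == "p2d") dna[j, ] else prot[i, ]
      don_set <- if (dir == "p2d") prot else dna
      ante <- donor_antecedent(don, don_set)
      if (is.null(ante)) next
      ang <- vec_angle(as.numeric(ante - don[, c("x", "y", "z")]),
                       as.numeric(acc[, c("x", "y", "z")] - don[, c("x", "y", "z")]))
      if (ang < hbond_angle) next
      rows[[length(rows) + 1]] <- tibble(
        donor_chain = don$chain, donor_residue = don$res_id,
        donor_atom = don$name, acceptor_chain = acc$chain,
        acceptor_residue = acc$res_id, acceptor_atom = acc$name,
        dist = d[i, j], angle_deg = ang)
    }
  }
  if (!length(rows)) return(hbond_pairs(prot[0, ], dna[0, ], d[0, 0, drop = FALSE],
                                        hbond_dist, hbond_angle))
  bind_rows(rows)
}

donor_antecedent <- function(donor, same_mol, bond_max = 1.8) {
  sel <- same_mol$res_id == donor$res_id & same_mol$chain == donor$chain &
    same_mol$name != donor$name & same_mol$element != "H"
  nb <- same_mol[sel, ]
  if (!nrow(nb)) return(NULL)
  dd <- sqrt((nb$x - donor$x)^2 + (nb$y - donor$y)^2 + (nb$z - donor$z)^2)
  if (min(dd) > bond_max) {
    # toy structures may have sparse residues: fall back to nearest heavy atom
    if (min(dd) > 3.0) return(NULL)
  }
  as.numeric(nb[which.min(dd), c("x", "y", "z")])
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}
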