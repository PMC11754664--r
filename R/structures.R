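# Molecular models: atom-table container, PDB I/O (via bio3d), an idealized
# B-DNA/poly-alanine toy-complex builder, rigid transforms and Kabsch
# superposition.

DNA_RES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T")
PROTEIN_RES <- names(AA3)

#' Build a molecular model from an atom table
#'
#' @param atoms Data frame with columns `serial`, `name`, `res_name`,
#'   `chain`, `res_id`, `x`, `y`, `z` (and optionally `element`, inferred
#'   from the atom name otherwise).
#' @return A `molecular_model`: the atom tibble plus per-chain roles
#'   (`protein`, `dna` or `other`). Chains containing residues that are
#'   neither standard amino acids nor A/C/G/T deoxynucleotides are flagged
#'   `other` and excluded from scoring.
#' @export
as_molecular_model <- function(atoms) {
  assert_cols(atoms, c("serial", "name", "res_name", "chain", "res_id",
                       "x", "y", "z"), "atom table")
  atoms <- as_tibble(atoms)
  if (!"element" %in% names(atoms)) {
    atoms$element <- infer_element(atoms$name)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates")
  }
  roles <- vapply(split(atoms$res_name, atoms$chain), function(rn) {
    rn <- unique(rn)
    if (all(rn %in% DNA_RES)) "dna"
    else if (all(rn %in% PROTEIN_RES)) "protein"
    else "other"
  }, character(1))
  if (any(roles == "other")) {
    warn(sprintf("chain(s) %s contain non-standard residues and are excluded from scoring",
                 paste(names(roles)[roles == "other"], collapse = ", ")))
  }
  structure(list(atoms = atoms, roles = roles), class = "molecular_model")
}

infer_element <- function(name) {
  el <- sub("^[0-9']*", "", name)
  substr(el, 1, 1)
}

#' @export
print.molecular_model <- function(x, ...) {
  cat(sprintf("<molecular_model> %d atoms; chains: %s\n", nrow(x$atoms),
              paste(sprintf("%s (%s)", names(x$roles), x$roles), collapse = ", ")))
  invisible(x)
}

model_coords <- function(model, role = NULL, chain = NULL) {
  a <- model$atoms
  if (!is.null(role)) a <- a[a$chain %in% names(model$roles)[model$roles == role], ]
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Read a PDB file into a molecular model
#'
#' Thin wrapper over [bio3d::read.pdb()] keeping ATOM/HETATM records and
#' assigning per-chain protein/DNA roles.
#'
#' @param path Path to a PDB file.
#' @return A `molecular_model`.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) abort(sprintf("cannot parse PDB: %s", conditionMessage(e))))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) abort("no ATOM/HETATM records found")
  as_molecular_model(tibble(
    serial = a$eleno, name = a$elety, res_name = a$resid,
    chain = a$chain, res_id = a$resno,
    x = a$x, y = a$y, z = a$z,
    element = ifelse(is.na(a$elesy) | a$elesy == "", infer_element(a$elety), a$elesy)
  ))
}

#' Write a molecular model to a PDB file
#'
#' Coordinates are written at PDB precision (0.001 A). If a pose is given it
#' is baked into the protein coordinates first. A list of poses writes one
#' MODEL record per pose.
#'
#' @param model A `molecular_model`.
#' @param path Output file.
#' @param pose Optional `(rotation, translation)` pose (see [mc_dock()]) or
#'   list of poses.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, pose = NULL) {
  poses <- if (is.null(pose)) list(NULL)
           else if (!is.null(pose$rotation)) list(pose)
           else pose
  multi <- length(poses) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    m <- if (is.null(poses[[i]])) model else apply_pose(model, poses[[i]])
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    a <- m$atoms
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, formatC(substr(a$name, 1, 4), width = 4),
      substr(a$res_name, 1, 3), substr(a$chain, 1, 1), a$res_id,
      a$x, a$y, a$z, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Apply a rigid pose to the protein chains of a model
#'
#' A pose rotates the protein about its own centroid and then translates it:
#' `x' = R (x - c) + c + t` with `c` the protein centroid.
#'
#' @param model A `molecular_model`.
#' @param pose List with `rotation` (3x3 proper rotation) and `translation`
#'   (length-3, Angstrom).
#' @return The model with transformed protein coordinates.
#' @export
apply_pose <- function(model, pose) {
  R <- pose$rotation
  stopifnot(all(dim(R) == c(3, 3)))
  if (abs(det(R) - 1) > 1e-6) abort("pose rotation must be proper (det = +1)")
  prot <- model$atoms$chain %in% names(model$roles)[model$roles == "protein"]
  xyz <- as.matrix(model$atoms[prot, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  new_xyz <- sweep(xyz, 2, ctr) %*% t(R)
  new_xyz <- sweep(new_xyz, 2, ctr + pose$translation, "+")
  model$atoms[prot, c("x", "y", "z")] <- as.data.frame(new_xyz)
  model
}

#' Build an idealized toy protein-DNA complex
#'
#' A fiber-model B-form duplex (3.38 A rise, 36 deg twist per base pair,
#' planar idealized base rings perpendicular to the helix axis) paired with a
#' reverse-complementary second strand, plus a poly-alanine alpha-helix
#' placed at a stated offset from the helix axis. Intended as a fully
#' synthetic, analytically tractable system for exercising the docking
#' engine; it does not model sequence-dependent DNA geometry.
#'
#' @param dna_seq Forward-strand sequence (ACGT only).
#' @param protein_len Number of alanine residues (>= 2).
#' @param protein_offset Translation applied to the protein after centering,
#'   Angstrom; default parks it 16 A off the DNA axis at mid-height.
#' @return A `molecular_model` with chains A/B (DNA) and P (protein).
#' @export
sim_toy_complex <- function(dna_seq = "ACGTACGTAC", protein_len = 12,
                            protein_offset = NULL) {
  bases <- strsplit(toupper(dna_seq), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) abort("DNA sequence must contain only ACGT")
  n_bp <- length(bases)
  stopifnot(n_bp >= 2, protein_len >= 2)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  rise <- 3.38
  twist <- 36 * pi / 180

  rot2 <- function(theta, v) {
    cbind(cos(theta) * v[, 1] - sin(theta) * v[, 2],
          sin(theta) * v[, 1] + cos(theta) * v[, 2])
  }
  base_atoms_local <- function(base) {
    ang <- seq(0, 300, by = 60) * pi / 180
    ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang))
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    if (base %in% c("A", "G")) {
      ring <- rbind(ring, cbind(c(-2.1, -2.8, -2.1), c(-1.2, 0, 1.2)))
      nm <- c(nm, "N7", "C8", "N9")
    }
    # center so the ring centroid sits exactly at the nominal base position
    ring <- sweep(ring, 2, colMeans(ring))
    list(xy = ring, names = nm)
  }

  rows <- list()
  serial <- 0
  add_atom <- function(name, res_name, chain, res_id, xyz) {
    serial <<- serial + 1
    rows[[length(rows) + 1]] <<- tibble(
      serial = serial, name = name, res_name = res_name, chain = chain,
      res_id = res_id, x = xyz[1], y = xyz[2], z = xyz[3])
  }

  for (i in seq_len(n_bp)) {
    theta <- twist * (i - 1)
    z <- rise * (i - 1)
    for (strand in c("A", "B")) {
      b <- if (strand == "A") bases[i] else comp[[bases[i]]]
      res_id <- if (strand == "A") i else n_bp + 1 - i
      sgn <- if (strand == "A") 1 else -1
      centroid <- c(2.75 * sgn, 0)
      ba <- base_atoms_local(b)
      xy <- sweep(sgn * ba$xy, 2, centroid, "+")
      xy <- rot2(theta, xy)
      for (k in seq_len(nrow(xy))) {
        add_atom(ba$names[k], paste0("D", b), strand, res_id, c(xy[k, ], z))
      }
      bb_ang <- theta + sgn * 70 * pi / 180 + if (strand == "B") pi else 0
      add_atom("C1'", paste0("D", b), strand, res_id,
               c(5.9 * cos(bb_ang), 5.9 * sin(bb_ang), z))
      add_atom("P", paste0("D", b), strand, res_id,
               c(8.9 * cos(bb_ang + 0.3 * sgn), 8.9 * sin(bb_ang + 0.3 * sgn), z))
    }
  }

  # poly-alanine alpha helix: 100 deg / 1.5 A per residue, Calpha radius 2.3 A
  ca <- t(vapply(seq_len(protein_len), function(i) {
    th <- 100 * pi / 180 * (i - 1)
    c(2.3 * cos(th), 2.3 * sin(th), 1.5 * (i - 1))
  }, numeric(3)))
  ca <- sweep(ca, 2, colMeans(ca))
  offset <- protein_offset %||% c(16, 0, rise * (n_bp - 1) / 2)
  ca <- sweep(ca, 2, offset, "+")
  axis_xy <- c(offset[1], offset[2])
  for (i in seq_len(protein_len)) {
    radial <- c(ca[i, 1] - axis_xy[1], ca[i, 2] - axis_xy[2], 0)
    radial <- radial / sqrt(sum(radial^2))
    up <- c(0, 0, 1)
    add_atom("N", "ALA", "P", i, ca[i, ] - 0.8 * up - 0.9 * radial)
    add_atom("CA", "ALA", "P", i, ca[i, ])
    add_atom("C", "ALA", "P", i, ca[i, ] + 0.8 * up - 0.9 * radial)
    add_atom("O", "ALA", "P", i, ca[i, ] + 1.0 * up - 1.9 * radial)
    add_atom("CB", "ALA", "P", i, ca[i, ] + 1.53 * radial)
  }
  as_molecular_model(bind_rows(rows))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R x_mobile + t` onto the reference points. Reflections are excluded by
#' the determinant correction, so mirror-related sets superpose with a
#' nonzero RMSD.
#'
#' @param reference,mobile Matrices (n x 3) of paired coordinates, `n >= 3`,
#'   not collinear.
#' @return A list with `rotation`, `translation` and `rmsd`.
#' @export
superpose <- function(reference, mobile) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile)) abort("point counts differ")
  if (nrow(reference) < 3) abort("at least 3 points are required")
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) abort("degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}
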