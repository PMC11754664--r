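# Hand-built miniature structures used across the geometry and docking tests.

# A single base with its ring in the z = 0 plane, centered at `centroid`.
base_atoms <- function(centroid = c(0, 0, 0), base = "A", chain = "A",
                       res_id = 1, serial0 = 0) {
  ring <- if (base %in% c("A", "G")) {
    c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  } else c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- seq(0, length.out = length(ring), by = 2 * pi / length(ring))
  tibble::tibble(
    serial = serial0 + seq_along(ring), name = ring,
    res_name = paste0("D", base), chain = chain, res_id = res_id,
    x = centroid[1] + 1.4 * cos(ang), y = centroid[2] + 1.4 * sin(ang),
    z = centroid[3]
  )
}

# One amino-acid residue reduced to CA + CB, with the sidechain vector
# CA -> CB chosen directly. Sidechain centroid is CB.
residue_atoms <- function(ca, cb, aa = "ALA", chain = "P", res_id = 1,
                          serial0 = 100) {
  tibble::tibble(
    serial = serial0 + 1:2, name = c("CA", "CB"), res_name = aa,
    chain = chain, res_id = res_id,
    x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3])
  )
}

# Minimal protein-DNA complex: one residue, one base, with the sidechain
# vector at `phi_deg` to the base plane and CB at distance `r` from the ring
# centroid. The base plane is z = 0, so phi is set by the z-component.
toy_pair_model <- function(r = 5.5, phi_deg = 0, aa = "ALA", base = "A") {
  phi <- phi_deg * pi / 180
  v <- c(cos(phi), 0, sin(phi))          # unit sidechain direction
  cb <- c(r, 0, 0)                       # distance r from base centroid
  ca <- cb - v
  as_molecular_model(dplyr::bind_rows(
    base_atoms(base = base),
    residue_atoms(ca, cb, aa = aa)
  ))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
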