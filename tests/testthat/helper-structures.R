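# small structure fixtures built in code

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, " ", resname, chain, resno, x, y, z, occ, b, element)
}

# handcrafted 3-residue PDB text (N, CA, C, O per residue)
toy_pdb_lines <- function() {
  c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.000, 0.000, 0.000, b = 1.5),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000, b = 1.5),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.009, 1.420, 0.000, b = 1.5),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 1.251, 2.390, 0.000, b = 1.5),
    pdb_atom_line(5, "N",  "GLY", "A", 2, 3.332, 1.536, 0.000, b = 2.0),
    pdb_atom_line(6, "CA", "GLY", "A", 2, 4.042, 2.791, 0.132, b = 2.0),
    pdb_atom_line(7, "C",  "GLY", "A", 2, 5.502, 2.598, 0.510, b = 2.0),
    pdb_atom_line(8, "O",  "GLY", "A", 2, 6.012, 1.480, 0.560, b = 2.0),
    pdb_atom_line(9, "N",  "SER", "A", 3, 6.188, 3.702, 0.780, b = 2.5),
    pdb_atom_line(10, "CA", "SER", "A", 3, 7.610, 3.680, 1.140, b = 2.5),
    pdb_atom_line(11, "C",  "SER", "A", 3, 8.460, 3.100, 0.020, b = 2.5),
    pdb_atom_line(12, "O",  "SER", "A", 3, 8.000, 2.980, -1.120, b = 2.5),
    "TER",
    "END"
  )
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_lines(), path)
  path
}

# apply an arbitrary rigid transform (rotation about an axis + translation)
rigid_transform <- function(s, angle = 0.8, axis = c(1, 2, 3),
                            shift = c(5, -3, 7)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  a <- s$atoms
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  structure_model(a, model_id = s$model_id, chain_id = s$chain_id)
}

# displace the CA (or all atoms) of chosen residues by a vector
displace_residues <- function(s, resnos, delta, atoms = NULL) {
  a <- s$atoms
  sel <- a$resno %in% resnos
  if (!is.null(atoms)) sel <- sel & a$atom %in% atoms
  a$x[sel] <- a$x[sel] + delta[1]
  a$y[sel] <- a$y[sel] + delta[2]
  a$z[sel] <- a$z[sel] + delta[3]
  structure_model(a, model_id = s$model_id, chain_id = s$chain_id)
}

fixture_target_table <- function() {
  read_target_table(system.file("extdata", "casp13_refinement_targets.tsv",
                                package = "refinemetrics"))
}
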