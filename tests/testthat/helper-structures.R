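# In-code fixtures shared across test files.

# a small protein-like structure: n residues of 3 atoms each on chain A
toy_chain <- function(n_res = 10, seed = 42) {
  set.seed(seed)
  at <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(name = c("N", "CA", "C"), resn = "ALA", chain = "A",
               resi = i, x = rnorm(3, i * 2), y = rnorm(3), z = rnorm(3),
               element = c("N", "C", "C"), stringsAsFactors = FALSE)
  }))
  tomo_structure(at, id = "toy_chain")
}

random_structure <- function(n = 25, seed = 7) {
  set.seed(seed)
  tomo_structure(data.frame(
    name = paste0("C", seq_len(n)), resn = "UNK", chain = "A",
    resi = seq_len(n), x = rnorm(n, sd = 4), y = rnorm(n, sd = 3),
    z = rnorm(n, sd = 5), element = "C", stringsAsFactors = FALSE),
    id = "cloud")
}

random_rigid_transform <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  rigid_transform(diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K,
                  runif(3, -10, 10))
}

# text of a minimal PDB file (two protein atoms + one water)
MINI_PDB <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
  "END")

# PDBQT dialect: charge in columns 67-76, AutoDock type in 78-79
MINI_PDBQT <- c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00    -0.347 N ",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00     0.177 C ",
  "ATOM      3  CB  ALA A   1      12.000   7.000  -4.000  1.00  0.00     0.042 A ",
  "END")

write_lines_tmp <- function(lines, ext = ".pdb") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force pairwise score: the independent oracle for toy_score
brute_score <- function(rec_xyz, rec_lab, lig_xyz, lig_lab, cutoff = 8,
                        A = 1, C = 10, rmin = 2.5, d0 = 3, w = 1) {
  match1 <- function(a, b) {
    (a == "donor" && b == "acceptor") || (a == "acceptor" && b == "donor") ||
      (a == "aromatic" && b == "aromatic") || (a == "apolar" && b == "apolar")
  }
  s <- 0
  for (i in seq_len(nrow(rec_xyz))) for (j in seq_len(nrow(lig_xyz))) {
    d <- sqrt(sum((rec_xyz[i, ] - lig_xyz[j, ])^2))
    if (d <= cutoff) {
      s <- s + C * max(0, rmin - d)^2
      if (match1(rec_lab[i], lig_lab[j])) s <- s - A * exp(-(d - d0)^2 / w)
    }
  }
  s
}

# structure with explicit pharmacophore labels from a coordinate matrix
labelled_structure <- function(xyz, labels, elements = NULL, id = "lab",
                               names = NULL) {
  n <- nrow(xyz)
  if (is.null(elements))
    elements <- c(donor = "N", acceptor = "O", aromatic = "C",
                  apolar = "C", inert = "C")[labels]
  if (is.null(names)) names <- paste0("X", seq_len(n))
  tomo_structure(data.frame(
    name = names, resn = "UNK", chain = "A", resi = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], element = unname(elements),
    label = labels, stringsAsFactors = FALSE), id = id)
}
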