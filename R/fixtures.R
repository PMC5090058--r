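# Synthetic fixtures: a toy tubular pocket with planted ground truth (an
# engagement niche, a constriction filter, a base binding site) and two toy
# ligands -- one that can descend to the base and one that cannot -- so the
# whole pipeline is testable with no external structures or binaries.
#
# Geometry (internal frame; the emitted receptor is rigidly moved by a
# seeded rotation+translation so frame alignment is actually exercised):
#   z axis = pocket depth, mouth ring at z = 0, base plane at z = depth.
#   Wall: rings of `wall_atoms` inert (purely steric) carbons, radius
#     `radius`; structural atoms carry no attraction so the only attractive
#     sites are the planted niche and base acceptors.
#   Niche: a vertical pair of acceptor oxygens on the back wall near the
#     mouth; their vertical spacing matches the ligands' donor-pair spacing,
#     so full engagement forces the tail (and hence the ring plane) vertical.
#   Filter: two rings of donor nitrogens at reduced radius `aperture`,
#     placed in the depth band the ligand ring sweeps through during the
#     descent to the base.
#   Base: two vertical acceptor pairs flanking the axis; a ligand standing
#     on the axis contacts all four at the optimum distance, making the
#     base site strictly deeper (more negative) than the niche.
#   Floor: an apolar disk below the base plane; the blocked ligand's longer
#     tail cannot contact the base acceptors without driving its terminal
#     atoms into the floor or its ring into the constriction.

#' Specification of the toy pocket
#'
#' @param depth base-plane depth, angstrom (mouth ring is at depth 0).
#' @param radius wall tube radius, angstrom.
#' @param aperture constriction (filter ring) radius, angstrom.
#' @param filter_depths depths of the two filter rings, angstrom.
#' @param wall_atoms atoms per wall ring.
#' @param seed seed for the rigid motion applied to the emitted receptor.
#' @export
toy_pocket_spec <- function(depth = 13, radius = 5.5, aperture = 4.0,
                            filter_depths = c(7.4, 8.2), wall_atoms = 10,
                            seed = 1) {
  stopifnot(depth > 8, radius > aperture, aperture > 2.5,
            all(filter_depths > 0 & filter_depths < depth),
            wall_atoms >= 6)
  structure(list(depth = depth, radius = radius, aperture = aperture,
                 filter_depths = sort(filter_depths),
                 wall_atoms = as.integer(wall_atoms),
                 seed = as.integer(seed)),
            class = "toy_pocket_spec")
}

ring_xyz <- function(radius, z, n, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(radius * cos(th), radius * sin(th), z)
}

toy_atoms <- function(xyz, name_stem, resn, resi, element, label,
                      serial0 = 0L) {
  n <- nrow(xyz)
  data.frame(serial = serial0 + seq_len(n),
             name = paste0(name_stem, seq_len(n)),
             resn = resn, chain = "A", resi = resi,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = element, label = label, stringsAsFactors = FALSE)
}

#' Generate the toy pocket receptor with planted ground truth
#'
#' Deterministic given `spec$seed`. The returned receptor is rigidly
#' rotated and translated (seeded), so [scan_axis()] and [align_to_axis()]
#' do real work downstream.
#'
#' @param spec a [toy_pocket_spec()].
#' @return list with `receptor` (`tomo_structure`), `pocket`
#'   ([pocket_definition()]), `niche` ([niche_definition()]), and `truth`:
#'   the planted ground-truth manifest (filter residues, niche residues,
#'   base depth threshold, expected pocket depth, ligand ring atom names).
#' @export
make_toy_pocket <- function(spec = toy_pocket_spec()) {
  D <- spec$depth; R <- spec$radius; nw <- spec$wall_atoms
  fz <- spec$filter_depths
  if (any(abs(fz[1] - fz[2]) > 3))
    stop("filter rings must be within 3 A of each other")
  blocks <- list()
  resi <- 0L
  add <- function(xyz, stem, resn, element, label, split2 = FALSE) {
    if (split2) {
      # split a ring into 2-atom residues so wall bookkeeping stays below
      # any candidate threshold and inclusion tables stay legible
      for (i in seq(1L, nrow(xyz), by = 2L)) {
        resi <<- resi + 1L
        idx <- i:min(i + 1L, nrow(xyz))
        blocks[[length(blocks) + 1L]] <<-
          toy_atoms(xyz[idx, , drop = FALSE], stem, resn, resi, element, label)
      }
    } else {
      resi <<- resi + 1L
      blocks[[length(blocks) + 1L]] <<-
        toy_atoms(xyz, stem, resn, resi, element, label)
    }
    resi
  }
  # mouth ring: one whole residue, the mouth reference
  mouth_resi <- add(ring_xyz(R, 0, nw), "C", "MTH", "C", "inert")
  # upper wall rings
  for (z in c(-1.5, 1.5, 3.0, 4.5))
    add(ring_xyz(R, z, nw, phase = z), "C", "WAL", "C", "inert",
        split2 = TRUE)
  # engagement niche: a vertical slot formed by an acceptor pair on the +x
  # wall and a partner pair across the tail line; a donor pair standing in
  # the slot contacts all four acceptors at the optimum distance
  niche_resi <- c(
    add(rbind(c(R - 0.9, 0, 1.2), c(R - 0.9, 0, 3.5)),
        "O", "NCH", "O", "acceptor"),
    add(rbind(c(R - 6.9, 0, 1.2), c(R - 6.9, 0, 3.5)),
        "O", "NCH", "O", "acceptor"))
  # inert blocker pair under the niche: engaging the niche with the ring
  # pointing down the pocket clashes here, so engagement is only possible
  # with the ring above the tail (toward the mouth)
  add(rbind(c(2.2, 1.2, 6.2), c(2.2, -1.2, 6.2)), "C", "BLK", "C", "inert")
  # corridor columns flanking the niche approach: only a donor pair held in
  # the vertical plane through the acceptors can engage both of them, which
  # forces the tail (and the ring plane) perpendicular to the pocket base
  for (zc in c(0.8, 2.3, 3.8))
    add(rbind(c(3.1, 2.4, zc), c(3.1, -2.4, zc)), "C", "NCL", "C", "inert")
  # azimuth pincers in the chamber: pin the ring plane of descending poses
  # to one vertical plane, so score-degenerate spins about the pocket axis
  # do not masquerade as pose changes
  add(rbind(c(0, 2.2, fz[2] - 0.3), c(0, -2.2, fz[2] - 0.3)), "C", "PIN",
      "C", "inert")
  # constriction filter: two 6-atom nitrogen rings at reduced radius
  filter_resi <- c(
    add(ring_xyz(spec$aperture, fz[1], 6), "N", "FLT", "N", "donor"),
    add(ring_xyz(spec$aperture, fz[2], 6, phase = pi / 6), "N", "FLT", "N",
        "donor"))
  # chamber wall rings below the filter
  for (z in unique(pmin(c(fz[2] + 2.1, fz[2] + 3.6, D - 0.2), D - 0.2)))
    add(ring_xyz(R, z, nw, phase = z), "C", "WAL", "C", "inert",
        split2 = TRUE)
  # base site: two 3-fold acceptor rings flanking the axis at the donor-pair
  # spacing; a ligand standing on the axis contacts all six at the optimum
  # distance. The bottom reference residue.
  base_z <- c(D - 0.2, D - 2.5)
  base_resi <- add(rbind(ring_xyz(3, base_z[1], 3),
                         ring_xyz(3, base_z[2], 3)),
                   "O", "BAS", "O", "acceptor")
  # floor: inert disk below the base acceptor plane -- purely steric, it
  # attracts nothing but repels anything driven into it
  floor_z <- base_z[1] + 2.6
  floor_xyz <- rbind(c(0, 0, floor_z),
                     ring_xyz(1.75, floor_z, 6),
                     ring_xyz(3.5, floor_z, 12))
  floor_resi <- add(floor_xyz, "C", "FLR", "C", "inert")

  at <- do.call(rbind, blocks)
  at$serial <- seq_len(nrow(at))
  receptor <- tomo_structure(at, id = sprintf("toy_pocket_seed%d", spec$seed))

  # seeded rigid motion so the emitted receptor is not pre-aligned
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  Rm <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  tv <- stats::runif(3, -15, 15)
  receptor <- apply_transform(receptor, rigid_transform(Rm, tv))

  pocket <- pocket_definition(
    lining = list(residue_range("A", 1L, floor_resi)),
    mouth_ref = residue_ref("A", mouth_resi, "MTH"),
    bottom_ref = residue_ref("A", base_resi, "BAS"))
  niche <- niche_definition(lapply(niche_resi, function(i)
    residue_ref("A", i, "NCH")), cutoff = 4)
  truth <- list(
    depth = D,
    pocket_depth = mean(base_z),   # mouth centroid to BAS centroid
    base_depth = fz[2],   # "past the deepest filter ring"
    filter_residues = filter_resi,
    niche_residues = niche_resi,
    mouth_residue = mouth_resi,
    bottom_residue = base_resi,
    floor_residue = floor_resi,
    ring_atoms = paste0("C", 1:6),
    donor_spacing = 2.3,
    base_contact_z = base_z,
    seed = spec$seed)
  list(receptor = receptor, pocket = pocket, niche = niche, truth = truth)
}

#' Generate the toy ligand pair
#'
#' Both ligands share a planar aromatic six-ring and a polar tail bearing
#' two donor nitrogens whose spacing matches the pocket's niche and base
#' acceptor pairs. The passing ligand ends at the tip donor: standing on
#' the pocket axis it contacts all four base acceptors with every atom
#' clear of the constriction and the floor. The blocked ligand carries two
#' extra apolar tail atoms beyond the tip; any pose that engages the base
#' acceptors drives those atoms into the floor disk (or, tilted, its ring
#' into the constriction), so under the built-in potential it cannot reach
#' the pocket base.
#'
#' @param spec a [toy_pocket_spec()] (spacings are derived from it).
#' @return list with `passing` and `blocked` (`tomo_structure`s, ring atoms
#'   named C1..C6) and `ring_atoms`.
#' @export
make_toy_ligands <- function(spec = toy_pocket_spec()) {
  ring <- ring_xyz(1.3, 0, 6)        # ring in the x-y plane of the template
  # template: ring centered at origin in the x-z plane, tail along +z
  ring <- cbind(ring[, 1], 0, ring[, 2])
  tail <- rbind(c(0, 0, 2.0),        # apolar linker
                c(0, 0, 2.6),        # donor 1
                c(0, 0, 4.9))        # donor 2 (tip)
  mk <- function(extra, id) {
    xyz <- rbind(ring, tail, extra)
    at <- data.frame(
      serial = seq_len(nrow(xyz)),
      name = c(paste0("C", 1:6), "CT", "N1", "N2",
               if (nrow(extra)) paste0("CX", seq_len(nrow(extra)))),
      resn = "LIG", chain = "L", resi = 1L,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = c(rep("C", 6), "C", "N", "N",
                  rep("C", nrow(extra))),
      label = c(rep("aromatic", 6), "apolar", "donor", "donor",
                rep("apolar", nrow(extra))),
      stringsAsFactors = FALSE)
    tomo_structure(at, id = id)
  }
  list(passing = mk(matrix(numeric(0), 0, 3), "toy_ligand_passing"),
       blocked = mk(rbind(c(0, 0, 6.3), c(0, 0, 7.7), c(0, 0, 9.1)),
                    "toy_ligand_blocked"),
       ring_atoms = paste0("C", 1:6))
}

#' Write the toy system to disk
#'
#' Emits receptor and ligand PDB files, a pocket YAML, a niche YAML, and
#' the ground-truth manifest JSON.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [toy_pocket_spec()].
#' @return `out_dir`, invisibly.
#' @export
write_toy_system <- function(out_dir, spec = toy_pocket_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_pocket(spec)
  lig <- make_toy_ligands(spec)
  write_structure(toy$receptor, file.path(out_dir, "receptor.pdb"))
  write_structure(lig$passing, file.path(out_dir, "ligand_passing.pdb"))
  write_structure(lig$blocked, file.path(out_dir, "ligand_blocked.pdb"))
  p <- toy$pocket
  yaml::write_yaml(list(
    chain = "A",
    ranges = lapply(p$lining, function(r) c(r$start, r$end)),
    mouth_ref = list(resi = p$mouth_ref$resi, resn = p$mouth_ref$resn),
    bottom_ref = list(resi = p$bottom_ref$resi, resn = p$bottom_ref$resn)),
    file.path(out_dir, "pocket.yaml"))
  yaml::write_yaml(list(
    cutoff = toy$niche$cutoff,
    residues = lapply(toy$niche$residues, function(r)
      list(chain = r$chain, resi = r$resi, resn = r$resn))),
    file.path(out_dir, "niche.yaml"))
  jsonlite::write_json(toy$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
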