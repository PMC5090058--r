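# hand-built trajectories: a pose is just coords + score here
make_traj <- function(coord_list, scores = NULL) {
  n <- length(coord_list)
  if (is.null(scores)) scores <- rep(-1, n)
  structure(list(
    summary = data.frame(step = seq_len(n), score = scores,
                         repetition = rep(1, n)),
    poses = lapply(seq_len(n), function(k)
      list(coords = coord_list[[k]], score = scores[k])),
    plan = NULL), class = "tomo_trajectory")
}

# a 9-atom ligand: hexagonal ring (C1..C6) + 3-atom tail, ring initially in
# the x-y plane centered at the origin
ring_ligand <- function() {
  th <- 2 * pi * (0:5) / 6
  xyz <- rbind(cbind(1.3 * cos(th), 1.3 * sin(th), 0),
               c(0, 0, 1.4), c(0, 0, 2.8), c(0, 0, 4.2))
  labelled_structure(xyz, c(rep("aromatic", 6), "apolar", "donor", "donor"),
                     id = "ring_lig",
                     names = c(paste0("C", 1:6), "CT", "N1", "N2"))
}

ring_receptor <- function() {
  labelled_structure(rbind(c(0, 0, 8), c(3, 0, 0)),
                     c("acceptor", "inert"), id = "niche_rec")
}

test_that("orientation angles follow the ring-plane convention", {
  lig <- ring_ligand()
  rec <- ring_receptor()
  niche <- niche_definition(list(residue_ref("A", 1)), cutoff = 4)
  flat <- coords(lig)                         # ring in the x-y plane: 0 deg
  Rx <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3)
  upright <- flat %*% t(Rx)                   # ring contains z: 90 deg
  traj <- make_traj(list(flat, upright))
  m <- step_metrics(traj, rec, lig, paste0("C", 1:6), niche)
  expect_equal(m$orientation_angle, c(0, 90), tolerance = 1e-9)
  expect_equal(m$depth, c(mean(flat[, 3]), mean(upright[, 3])))
  # tail atom within 4 A of the niche residue only in the first pose
  expect_true(m$tail_in_niche[1])   # tail tip at (0,0,4.2), niche at (0,0,8)
  expect_false(m$tail_in_niche[2])

  expect_error(step_metrics(traj, rec, lig, c("C1", "C2"), niche),
               "at least 3")
  expect_error(step_metrics(traj, rec, lig, c("C1", "C2", "NOPE"), niche),
               "not found")
})

test_that("plane fitting matches a brute-force eigendecomposition", {
  lig <- ring_ligand()
  rec <- ring_receptor()
  set.seed(15)
  for (i in 1:25) {
    tr <- random_rigid_transform(i * 3 + 1)
    pose <- apply_transform(coords(lig), tr)
    traj <- make_traj(list(pose, pose))
    m <- step_metrics(traj, rec, lig, paste0("C", 1:6))
    ring <- pose[1:6, ]
    ev <- eigen(crossprod(sweep(ring, 2, colMeans(ring))), symmetric = TRUE)
    normal <- ev$vectors[, 3]
    want <- acos(min(1, abs(normal[3]))) * 180 / pi
    expect_equal(m$orientation_angle[1], want, tolerance = 1e-6)
  }
  collinear <- labelled_structure(cbind(1:4, 0, 0), rep("aromatic", 4))
  traj <- make_traj(list(coords(collinear), coords(collinear)))
  expect_error(step_metrics(traj, rec, collinear, paste0("X", 1:4)),
               "collinear")
})

test_that("change flags fire on depth, orientation, or displacement", {
  lig <- ring_ligand()
  rec <- ring_receptor()
  base <- coords(lig)
  shifted <- sweep(base, 2, c(0, 0, 2), "+")
  traj <- make_traj(list(base, base, shifted))
  m <- step_metrics(traj, rec, lig, paste0("C", 1:6))
  f <- flag_changes(m, traj, depth_tol = 0.5, rmsd_tol = 1.0, angle_tol = 20)
  expect_true(f$significant[1])        # entry step always flagged
  expect_false(f$significant[2])       # identical consecutive poses
  expect_true(f$significant[3])        # 2 A translation: depth and rmsd
  expect_true(f$depth_changed[3])
  expect_true(f$rmsd_changed[3])
  expect_false(f$orientation_changed[3])
})

test_that("a single planted jump is flagged exactly once in the interior", {
  lig <- ring_ligand()
  rec <- ring_receptor()
  base <- coords(lig)
  set.seed(44)
  for (jump_at in c(3, 5, 8)) {
    coordsk <- lapply(1:9, function(k)
      if (k < jump_at) base else sweep(base, 2, c(0, 1.5, 3), "+"))
    traj <- make_traj(coordsk)
    m <- step_metrics(traj, rec, lig, paste0("C", 1:6))
    f <- flag_changes(m, traj)
    # brute-force pairwise comparison
    brute <- vapply(2:9, function(k)
      !isTRUE(all.equal(coordsk[[k]], coordsk[[k - 1]])), logical(1))
    expect_equal(f$significant[-1], brute)
    expect_equal(sum(f$significant[-1]), 1L)
    expect_equal(which(f$significant[-1]) + 1L, jump_at)
  }
})

test_that("plateaus merge unflagged runs with their preceding flagged step", {
  fake_flags <- function(flagged, n) {
    data.frame(step = seq_len(n), significant = seq_len(n) %in% flagged)
  }
  g <- plateaus(fake_flags(c(1, 3, 8, 10), 15))
  expect_equal(g, list(1:2, 3:7, 8:9, 10:15))
  # no interior flags: one group covering everything
  expect_equal(plateaus(fake_flags(1, 6)), list(1:6))
  # round-trip: group starts reconstruct the flag set exactly
  set.seed(10)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    flagged <- sort(unique(c(1L, sample(2:n, sample(0:(n - 1), 1)))))
    g <- plateaus(fake_flags(flagged, n))
    expect_equal(vapply(g, min, integer(1)), flagged)
    expect_identical(sort(unlist(g)), seq_len(n))   # partition
    expect_true(all(vapply(g, function(x) all(diff(x) == 1), logical(1))))
  }
})

test_that("filter identification follows the flagged-step atom-count rule", {
  atoms <- data.frame(
    chain = "A",
    resi = c(rep(5L, 4), rep(6L, 4), rep(7L, 2), rep(8L, 3)),
    resn = c(rep("FLT", 4), rep("SER", 4), rep("WAL", 2), rep("NCH", 3)),
    name = "X", element = c(rep("N", 8), "C", "C", rep("O", 3)),
    first_step = c(4L, 4L, 4L, 4L,   6L, 6L, 6L, 6L,   4L, 4L,   3L, 4L, 4L),
    stringsAsFactors = FALSE)
  res <- aggregate(rep(1L, nrow(atoms)),
                   by = list(step = atoms$first_step, chain = atoms$chain,
                             resi = atoms$resi, resn = atoms$resn), FUN = sum)
  names(res)[5] <- "n_new"
  incl <- structure(list(atoms = atoms, residues = res, n_steps = 8L),
                    class = "inclusion_table")
  flags <- data.frame(step = 1:8,
                      significant = c(TRUE, FALSE, FALSE, TRUE, FALSE,
                                      FALSE, FALSE, FALSE))
  niche <- niche_definition(list(residue_ref("A", 8)), cutoff = 4)
  out <- identify_filter(incl, flags, niche, min_new_atoms = 3, window = 1)
  # residue 5 (4 new atoms at flagged step 4) is the only candidate:
  # residue 6 arrives on the plateau, 7 is below threshold, 8 is niche
  expect_equal(out$resi, 5L)
  expect_equal(out$polarity, "polar")
  expect_match(out$rationale, "flagged step")
  nr <- attr(out, "niche_report")
  expect_equal(nr$resi, 8L)

  # no interior flagged steps: no candidates, not an error
  quiet <- data.frame(step = 1:8, significant = c(TRUE, rep(FALSE, 7)))
  expect_equal(nrow(identify_filter(incl, quiet, niche)), 0L)

  # raising the threshold never adds candidates
  for (m in 1:6) {
    lo <- identify_filter(incl, flags, niche, min_new_atoms = m)
    hi <- identify_filter(incl, flags, niche, min_new_atoms = m + 1)
    expect_true(all(hi$resi %in% lo$resi))
  }
})

test_that("ligand classification needs engagement and base depth together", {
  m <- data.frame(step = 1:6, score = -1,
                  depth = c(0, 0, 0, 0, 8, 8),
                  orientation_angle = c(85, 85, 85, 85, 40, 40),
                  tail_in_niche = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  f <- data.frame(step = 1:6,
                  significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  good <- classify_ligand(m, f, base_depth = 6)
  expect_equal(good$classification, "binder-like")
  expect_true(good$niche_engagement)
  expect_true(good$reaches_base)

  # same trajectory but the pocket base is never reached
  m2 <- m; m2$depth <- c(0, 0, 0, 0, 2, 2)
  shallow <- classify_ligand(m2, f, base_depth = 6)
  expect_equal(shallow$classification, "non-binder-like")
  expect_false(shallow$reaches_base)

  # niche contact absent throughout: criterion (a) fails
  m3 <- m; m3$tail_in_niche <- FALSE
  no_niche <- classify_ligand(m3, f, base_depth = 6)
  expect_equal(no_niche$classification, "non-binder-like")
  expect_false(no_niche$niche_engagement)

  # engagement plateau with a tilted ring also fails criterion (a)
  m4 <- m; m4$orientation_angle[1:4] <- 40
  tilted <- classify_ligand(m4, f, base_depth = 6)
  expect_false(tilted$niche_engagement)
})
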