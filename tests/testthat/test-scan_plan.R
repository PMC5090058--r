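# aligned-frame fixture: mouth marker residue at z = 0, bottom marker at
# z = depth, filler atoms along the tube so the structure is well-formed
plan_fixture <- function(depth = 10, mouth_z = 0) {
  filler_z <- seq(-1, depth, by = 1)
  at <- data.frame(
    name = "C",
    resn = c("MTH", "BOT", rep("FIL", length(filler_z))),
    chain = "A",
    resi = c(1L, 2L, seq_along(filler_z) + 10L),
    x = c(0, 0, rep(2, length(filler_z))),
    y = 0,
    z = c(mouth_z, depth, filler_z),
    element = "C", stringsAsFactors = FALSE)
  s <- tomo_structure(at, id = "plan_fixture")
  pd <- pocket_definition(list(residue_range("A", 11, 11 + length(filler_z))),
                          residue_ref("A", 1), residue_ref("A", 2))
  list(s = s, pocket = pd)
}

test_that("scan config validates ranges and warns below the engine cutoff", {
  cfg <- scan_config()
  expect_equal(cfg$edge, 18)
  expect_equal(cfg$step, 1)
  expect_equal(cfg$repetitions, 100L)
  expect_equal(cfg$exhaustiveness, 16L)
  expect_warning(scan_config(edge = 6), "cutoff")
  expect_error(scan_config(step = 0))
  expect_error(scan_config(repetitions = 0))
})

test_that("box membership uses a closed boundary and matches the predicate oracle", {
  box <- search_box(c(0, 0, 0), 10)
  on_face <- matrix(c(5, 0, 0), 1)
  expect_equal(atoms_in_box(on_face, box), 1L)
  outside <- matrix(c(5.001, 0, 0), 1)
  expect_length(atoms_in_box(outside, box), 0L)

  set.seed(21)
  pts <- matrix(runif(300, -8, 8), ncol = 3)
  got <- atoms_in_box(pts, box)
  want <- which(apply(pts, 1, function(p) all(abs(p) <= 5)))
  expect_identical(got, want)

  # hydrogens drop out under heavy_only
  s <- labelled_structure(rbind(c(0, 0, 0), c(1, 0, 0)),
                          labels = c("apolar", "apolar"),
                          elements = c("C", "H"))
  expect_equal(atoms_in_box(s, box, heavy_only = TRUE), 1L)
  expect_equal(atoms_in_box(s, box, heavy_only = FALSE), c(1L, 2L))
})

test_that("scan boxes advance by exactly one step along +z from the mouth face", {
  fx <- plan_fixture(depth = 10)
  cfg <- scan_config(edge = 18, step = 1, repetitions = 1, seed = 1)
  plan <- build_scan(fx$s, fx$pocket, cfg)
  centers <- t(vapply(plan$boxes, function(b) b$center, numeric(3)))
  # lateral center constant on the mouth centroid, z advancing by step
  expect_true(all(abs(centers[, 1]) < 1e-12))
  expect_true(all(abs(centers[, 2]) < 1e-12))
  expect_equal(diff(centers[, 3]), rep(cfg$step, plan$n_steps - 1))
  d <- sqrt(rowSums((centers[-1, , drop = FALSE] -
                     centers[-plan$n_steps, , drop = FALSE])^2))
  expect_equal(d, rep(cfg$step, plan$n_steps - 1))
  # leading face of box 1 tangent to the deepest mouth atom
  expect_equal(plan$boxes[[1]]$center[3] + cfg$edge / 2, 0)
  # last box is the first containing the bottom reference
  bot <- which(fx$s$resn == "BOT")
  in_last <- atoms_in_box(coords(fx$s)[bot, , drop = FALSE],
                          plan$boxes[[plan$n_steps]], heavy_only = FALSE)
  expect_length(in_last, length(bot))
  in_prev <- atoms_in_box(coords(fx$s)[bot, , drop = FALSE],
                          plan$boxes[[plan$n_steps - 1]], heavy_only = FALSE)
  expect_lt(length(in_prev), length(bot))
})

test_that("n_steps equals the brute-force smallest covering step", {
  for (depth in c(3.2, 7.9, 12.4)) {
    fx <- plan_fixture(depth = depth)
    cfg <- scan_config(edge = 18, step = 1, repetitions = 1)
    plan <- build_scan(fx$s, fx$pocket, cfg)
    bot_xyz <- coords(fx$s)[fx$s$resn == "BOT", , drop = FALSE]
    brute <- NA_integer_
    for (k in 1:200) {
      box <- search_box(c(0, 0, -9 + (k - 1)), 18, k)
      if (length(atoms_in_box(bot_xyz, box, heavy_only = FALSE)) ==
          nrow(bot_xyz)) { brute <- k; break }
    }
    expect_equal(plan$n_steps, max(2L, brute))
  }
})

test_that("a bottom reference inside box 1 still yields a two-step scan", {
  # the mouth marker sits deeper than the bottom marker, so box 1 already
  # contains the bottom reference and the scan degenerates to two steps
  fx <- plan_fixture(depth = 2, mouth_z = 3)
  plan <- build_scan(fx$s, fx$pocket, scan_config(repetitions = 1))
  expect_equal(plan$n_steps, 2L)
})

test_that("an unreachable bottom reference is reported as a misoriented axis", {
  fx <- plan_fixture(depth = 10)
  df <- as.data.frame(fx$s)
  df$x[df$resn == "BOT"] <- 500   # laterally out of every box
  s_bad <- tomo_structure(df)
  expect_error(build_scan(s_bad, fx$pocket, scan_config(repetitions = 1)),
               "misoriented")
})

test_that("inclusion steps are conveyor-belt monotone in depth and cover refs", {
  fx <- plan_fixture(depth = 12)
  plan <- build_scan(fx$s, fx$pocket, scan_config(repetitions = 1))
  incl <- inclusion_table(fx$s, plan)
  z <- coords(fx$s)[, 3]
  inc <- incl$atoms$first_step
  expect_true(all(inc > 0L))   # everything inside the lateral cross-section
  ord <- order(z)
  expect_true(all(diff(inc[ord]) >= 0))
  # union over steps covers mouth and bottom reference atoms
  expect_true(all(inc[fx$s$resn %in% c("MTH", "BOT")] > 0L))
})

test_that("inclusion tables report first steps, residue counts, and sentinels", {
  at <- data.frame(
    name = paste0("C", 1:6),
    resn = c(rep("AAA", 3), rep("BBB", 2), "FAR"),
    chain = "A", resi = c(1, 1, 1, 2, 2, 3),
    x = c(0, 1, -1, 0, 1, 300), y = 0,
    z = c(-1, -2, -3, 6, 7, 0),
    element = "C", stringsAsFactors = FALSE)
  s <- tomo_structure(at)
  pd <- pocket_definition(list(residue_range("A", 1, 3)),
                          residue_ref("A", 1), residue_ref("A", 2))
  plan <- build_scan(s, pd, scan_config(edge = 10, step = 1, repetitions = 1))
  incl <- inclusion_table(s, plan, pd)
  a <- incl$atoms
  # residue 1 sits above the first leading face: all in at step 1, never again
  expect_equal(unique(a$first_step[a$resi == 1]), 1L)
  r <- incl$residues
  expect_equal(r$n_new[r$resi == 1], 3L)
  expect_equal(r$step[r$resi == 1], 1L)
  # the far-away atom is never included: sentinel step 0
  expect_equal(a$first_step[a$resn == "FAR"], 0L)
  expect_false(3 %in% r$resi)
  # per-residue counts sum to each residue's in-box atom total
  for (ri in unique(r$resi))
    expect_equal(sum(r$n_new[r$resi == ri]),
                 sum(a$first_step > 0 & a$resi == ri))
  # TSV export writes "none" for the sentinel
  tsv <- tempfile(fileext = ".tsv")
  write_inclusion_table(incl, atoms_path = tsv)
  tab <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(tab$first_inclusion[tab$resn == "FAR"], "none")
})

test_that("the static baseline box is centered on the lining centroid", {
  fx <- plan_fixture(depth = 8)
  box <- static_box(fx$s, fx$pocket, edge = 18)
  lining <- select_residues(fx$s, fx$pocket$lining)
  expect_equal(box$center, colMeans(coords(lining)))
  expect_length(atoms_in_box(lining, box, heavy_only = FALSE), nrow(lining))
  expect_warning(static_box(fx$s, fx$pocket, edge = 2), "does not contain")
})
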