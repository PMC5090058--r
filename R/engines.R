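# Docking engines. The package's contribution is engine-agnostic
# orchestration, so the engine is a pluggable contract: dock(receptor,
# ligand, box, params) -> list of poses sorted by ascending score. Two
# implementations ship: a deterministic built-in rigid-body engine ("mock")
# for desk-scale work and tests, and an adapter driving an external AutoDock
# Vina binary ("vina") for production runs.

# Built-in scoring constants. These are fixture conventions for a smooth,
# additive surrogate potential -- not physical claims.
TOY_A <- 1       # attraction well depth per matched pair
TOY_C <- 10      # soft-sphere clash stiffness
TOY_RMIN <- 2.5  # clash onset distance, A
TOY_D0 <- 3.0    # attraction optimum distance, A
TOY_W <- 1.0     # attraction Gaussian width, A^2

#' Engine parameters
#' @param exhaustiveness sampling effort (the built-in engine draws a number
#'   of starting placements proportional to it).
#' @param n_poses number of poses to return.
#' @param seed random seed for this invocation.
#' @export
engine_params <- function(exhaustiveness = 16, n_poses = 9, seed = 1) {
  stopifnot(exhaustiveness >= 1, n_poses >= 1)
  structure(list(exhaustiveness = as.integer(exhaustiveness),
                 n_poses = as.integer(n_poses), seed = as.integer(seed)),
            class = "engine_params")
}

# Pharmacophore label fallback from element.
default_labels <- function(s) {
  lab <- s$label
  el <- s$element
  fallback <- ifelse(el == "N", "donor",
              ifelse(el %in% c("O", "S"), "acceptor", "apolar"))
  ifelse(is.na(lab) | !nzchar(lab), fallback, lab)
}

# Attraction applies between label-matched pairs: donor-acceptor (either
# way), aromatic-aromatic, apolar-apolar.
labels_match <- function(a, b) {
  (a == "donor" & b == "acceptor") | (a == "acceptor" & b == "donor") |
    (a == "aromatic" & b == "aromatic") | (a == "apolar" & b == "apolar")
}

#' Built-in pairwise surrogate score
#'
#' Sum over receptor-ligand atom pairs within `cutoff` of a soft-sphere
#' clash penalty `C * max(0, r_min - d)^2` plus, for label-matched pairs, a
#' Gaussian attraction `-A * exp(-(d - d0)^2 / w)`. Lower is better; the
#' score is exactly additive over pairs and continuous in the coordinates.
#' Atom pharmacophore labels come from the structures' `label` column, with
#' an element fallback (N = donor, O/S = acceptor, else apolar).
#'
#' @param receptor receptor `tomo_structure`.
#' @param ligand_coords n x 3 matrix of ligand atom coordinates.
#' @param ligand_labels character vector of ligand pharmacophore labels
#'   (length n).
#' @param cutoff interaction cutoff, angstrom (default 8, matching the
#'   external engine's interaction cutoff).
#' @return scalar score.
#' @export
toy_score <- function(receptor, ligand_coords, ligand_labels, cutoff = 8) {
  stopifnot(cutoff > 0)
  rc <- coords(receptor)
  rl <- default_labels(receptor)
  toy_score_mat(rc, rl, ligand_coords, ligand_labels, cutoff)
}

# matrix-level core so the search loop avoids repeated data.frame access
toy_score_mat <- function(rec_xyz, rec_lab, lig_xyz, lig_lab, cutoff = 8) {
  toy_score_ctx(score_context(rec_xyz, rec_lab, lig_lab, cutoff), lig_xyz)
}

# everything about the receptor and the ligand labels is pose-independent;
# precompute it once per search
score_context <- function(rec_xyz, rec_lab, lig_lab, cutoff = 8) {
  n <- nrow(rec_xyz); m <- length(lig_lab)
  list(rec = rec_xyz, n = n, m = m,
       rs = rowSums(rec_xyz^2),
       match = as.numeric(outer(rec_lab, lig_lab, labels_match)),
       cut2 = cutoff^2)
}

toy_score_ctx <- function(ctx, lig_xyz) {
  if (ctx$n == 0L) return(0)
  d2 <- -2 * tcrossprod(ctx$rec, lig_xyz) + ctx$rs
  d2 <- d2 + rep(rowSums(lig_xyz^2), each = ctx$n)
  idx <- which(d2 <= ctx$cut2)
  if (!length(idx)) return(0)
  d <- sqrt(pmax(d2[idx], 0))
  over <- TOY_RMIN - d
  pen <- TOY_C * sum(over[over > 0]^2)
  mi <- ctx$match[idx]
  hit <- mi > 0
  att <- if (any(hit)) TOY_A * sum(exp(-(d[hit] - TOY_D0)^2 / TOY_W)) else 0
  pen - att
}

# uniform random rotation matrix (Shoemake quaternion method), uses the
# current RNG stream
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_mat(q)
}

quat_to_mat <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
           2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
           2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# enumerate (receptor atom pair, ligand atom pair) combinations with
# mutually compatible labels and separations within 1 A of each other;
# capped for cost
match_pair_duos <- function(rec_xyz, rec_lab, lig0, lig_lab,
                            max_duos = 64L) {
  li <- which(lig_lab %in% c("donor", "acceptor", "aromatic", "apolar"))
  if (length(li) < 2L || nrow(rec_xyz) < 2L) return(list())
  lp <- utils::combn(li, 2L)
  duos <- list()
  for (j in seq_len(ncol(lp))) {
    a <- lp[1L, j]; b <- lp[2L, j]
    dl <- sqrt(sum((lig0[a, ] - lig0[b, ])^2))
    if (dl < 1) next
    ra <- which(labels_match(rec_lab, lig_lab[a]))
    rb <- which(labels_match(rec_lab, lig_lab[b]))
    if (!length(ra) || !length(rb)) next
    for (p in ra) for (q in rb) {
      if (p == q) next
      dr <- sqrt(sum((rec_xyz[p, ] - rec_xyz[q, ])^2))
      if (abs(dr - dl) <= 1) {
        duos[[length(duos) + 1L]] <- list(lig = c(a, b), rec = c(p, q))
        if (length(duos) >= max_duos) return(duos)
      }
    }
  }
  duos
}

# start pose aligning a ligand atom pair to a receptor atom pair: pair axes
# parallel, ligand atoms offset by d0 perpendicular to the pair axis in
# direction angle `w_phi`, spun about the axis by `phi`
duo_start <- function(rec_xyz, lig0, duo, phi, w_phi) {
  pa <- lig0[duo$lig[1L], ]; pb <- lig0[duo$lig[2L], ]
  qa <- rec_xyz[duo$rec[1L], ]; qb <- rec_xyz[duo$rec[2L], ]
  u <- qb - qa; u <- u / sqrt(sum(u^2))
  R0 <- rotation_between((pb - pa) / sqrt(sum((pb - pa)^2)), u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  Rspin <- diag(3) + sin(phi) * K + (1 - cos(phi)) * K %*% K
  R <- Rspin %*% R0
  v1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- v1 - sum(v1 * u) * u; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  w <- cos(w_phi) * v1 + sin(w_phi) * v2
  mid_r <- (qa + qb) / 2 + TOY_D0 * w
  tr <- mid_r - drop(R %*% ((pa + pb) / 2))
  list(R = R, t = tr)
}

# deterministic pharmacophore grid: every matched duo crossed with a grid
# of spins about the pair axis and offset directions perpendicular to it;
# each start carries its duo id so per-duo bests can be refined
duo_grid_starts <- function(rec_xyz, lig0, duos, n_spin = 12L, n_off = 6L,
                            max_starts = 960L) {
  out <- list()
  for (d in seq_along(duos)) {
    for (phi in 2 * pi * (seq_len(n_spin) - 1L) / n_spin)
      for (w_phi in 2 * pi * (seq_len(n_off) - 1L) / n_off) {
        st <- duo_start(rec_xyz, lig0, duos[[d]], phi, w_phi)
        st$group <- d
        out[[length(out) + 1L]] <- st
        if (length(out) >= max_starts) return(out)
      }
  }
  out
}

axis_rotation <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Built-in rigid-body docking search
#'
#' Seeded random restarts (uniform translations of the ligand centroid
#' within the box crossed with uniform rotations), each scored with
#' [toy_score()]; the best starts are refined by rigid-body coordinate
#' descent over translations and small rotations with a shrinking step
#' schedule. The number of restarts is proportional to
#' `params$exhaustiveness`. Identical inputs and seed give bit-identical
#' results.
#'
#' @param receptor receptor `tomo_structure`.
#' @param ligand ligand `tomo_structure` (treated as rigid).
#' @param box a [search_box()]; pose centroids are constrained inside it.
#' @param params an [engine_params()].
#' @param cutoff interaction cutoff, angstrom.
#' @return list of poses (`coords`, `score`, `engine = "mock"`), sorted by
#'   ascending score.
#' @export
toy_search <- function(receptor, ligand, box, params = engine_params(),
                       cutoff = 8) {
  lig_xyz <- coords(ligand)
  lig_lab <- default_labels(ligand)
  rad <- sqrt(max(rowSums(sweep(lig_xyz, 2, colMeans(lig_xyz))^2)))
  if (2 * rad > box$edge)
    stop("ligand bounding sphere (", round(2 * rad, 1),
         " A) exceeds the box edge (", box$edge, " A)")
  # prune receptor to atoms that can interact with any in-box pose
  rc_all <- coords(receptor)
  reach <- box$edge / 2 + rad + cutoff
  near <- abs(rc_all[, 1] - box$center[1]) <= reach &
          abs(rc_all[, 2] - box$center[2]) <= reach &
          abs(rc_all[, 3] - box$center[3]) <= reach
  rec_xyz <- rc_all[near, , drop = FALSE]
  rec_lab <- default_labels(receptor)[near]
  ctx <- score_context(rec_xyz, rec_lab, lig_lab, cutoff)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)

  lig0 <- sweep(lig_xyz, 2, colMeans(lig_xyz))  # centered template
  half <- box$edge / 2
  # matched receptor/ligand atom pairs for attraction-guided restarts
  # (anchor a random matched pair at the optimum distance, then refine)
  pair_ok <- which(outer(rec_lab, lig_lab, labels_match), arr.ind = TRUE)
  # matched pair-of-pairs for pharmacophore-pair restarts: a ligand atom
  # pair is aligned to a receptor atom pair of compatible labels and
  # similar separation, offset by d0 perpendicular to the pair axis
  duos <- match_pair_duos(rec_xyz, rec_lab, lig0, lig_lab)
  starts <- duo_grid_starts(rec_xyz, lig0, duos)
  # clamp grid starts so pose centroids obey the box
  for (i in seq_along(starts))
    starts[[i]]$t <- pmin(pmax(starts[[i]]$t, box$center - half),
                          box$center + half)
  n_rand <- 12L * params$exhaustiveness
  for (i in seq_len(n_rand)) {
    if (i %% 2L == 0L && nrow(pair_ok)) {
      # single anchor: place a random matched ligand atom at distance d0
      # from its receptor partner, in a random direction
      R <- random_rotation()
      pr <- pair_ok[sample.int(nrow(pair_ok), 1L), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      tr <- rec_xyz[pr[1L], ] + TOY_D0 * dir - drop(R %*% lig0[pr[2L], ])
      tr <- pmin(pmax(tr, box$center - half), box$center + half)
    } else {
      R <- random_rotation()
      tr <- box$center + stats::runif(3, -half, half)
    }
    starts[[length(starts) + 1L]] <- list(R = R, t = tr)
  }
  scores <- vapply(starts, function(st)
    toy_score_ctx(ctx, sweep(lig0 %*% t(st$R), 2, st$t, "+")), numeric(1))
  n_start <- length(starts)
  n_refine <- min(n_start, max(params$n_poses, 2L + params$exhaustiveness %/% 4L))
  # refinement candidates: the best start of every pharmacophore duo (so
  # no attraction site is starved by a stronger one; capped at 12 duos by
  # their best start scores), plus a greedy diversity fill over all starts
  # (3 A minimum centroid separation) up to n_refine more
  ord0 <- order(scores)
  groups <- vapply(starts, function(s) s$group %||% 0L, integer(1))
  gset <- setdiff(unique(groups), 0L)
  gbest <- vapply(gset, function(g) {
    gi <- which(groups == g); gi[which.min(scores[gi])]
  }, integer(1))
  if (length(gbest) > 12L)
    gbest <- gbest[order(scores[gbest])][1:12]
  top <- gbest[order(scores[gbest])]
  n_more <- n_refine
  for (i in ord0) {
    if (n_more <= 0L) break
    if (i %in% top) next
    ti <- starts[[i]]$t
    if (all(vapply(top, function(j)
      sum((starts[[j]]$t - ti)^2) >= 9, logical(1)))) {
      top <- c(top, i)
      n_more <- n_more - 1L
    }
  }
  if (n_more > 0L) {
    fill <- setdiff(ord0, top)
    top <- c(top, fill[seq_len(min(n_more, length(fill)))])
  }
  refined <- lapply(top, function(i)
    refine_pose(ctx, lig0, starts[[i]], box))
  sc <- vapply(refined, `[[`, numeric(1), "score")
  ord <- order(sc)
  keep <- ord[seq_len(min(params$n_poses, length(ord)))]
  lapply(keep, function(i)
    list(coords = refined[[i]]$coords, score = refined[[i]]$score,
         engine = "mock"))
}

# Rigid-body coordinate descent: sweep +-delta translations along x/y/z and
# +-theta rotations about x/y/z through the ligand centroid, halving the
# step schedule; centroid stays inside the box.
refine_pose <- function(ctx, lig0, start, box) {
  half <- box$edge / 2
  R <- start$R; tr <- start$t
  score_of <- function(R, tr) {
    toy_score_ctx(ctx, sweep(lig0 %*% t(R), 2, tr, "+"))
  }
  best <- score_of(R, tr)
  deltas <- c(1.2, 0.5, 0.2, 0.08)
  thetas <- c(0.5, 0.22, 0.1, 0.04)
  for (lev in seq_along(deltas)) {
    improved <- TRUE
    iter <- 0L
    while (improved && iter < 10L) {
      improved <- FALSE
      iter <- iter + 1L
      for (ax in 1:3) for (sgn in c(-1, 1)) {
        t2 <- tr; t2[ax] <- t2[ax] + sgn * deltas[lev]
        if (any(abs(t2 - box$center) > half)) next
        s2 <- score_of(R, t2)
        if (s2 < best - 1e-12) { best <- s2; tr <- t2; improved <- TRUE }
      }
      for (ax in c("x", "y", "z")) for (sgn in c(-1, 1)) {
        R2 <- axis_rotation(ax, sgn * thetas[lev]) %*% R
        s2 <- score_of(R2, tr)
        if (s2 < best - 1e-12) { best <- s2; R <- R2; improved <- TRUE }
      }
    }
  }
  list(coords = sweep(lig0 %*% t(R), 2, tr, "+"), score = best)
}

#' Dock a ligand in a search box
#'
#' The engine contract: returns at least one pose, sorted by ascending
#' score, with every pose centroid inside the box.
#'
#' @inheritParams toy_search
#' @param engine `"mock"` for the built-in engine. (Production runs against
#'   an external binary go through [vina_adapter()], which works on PDBQT
#'   files rather than in-memory structures.)
#' @export
dock <- function(receptor, ligand, box, params = engine_params(),
                 engine = "mock") {
  if (engine != "mock")
    stop("dock() runs the built-in engine; use vina_adapter() for ",
         "external engines")
  toy_search(receptor, ligand, box, params)
}

# ---- AutoDock Vina adapter --------------------------------------------------

#' Write a Vina-style configuration file
#' @param box a [search_box()].
#' @param params an [engine_params()].
#' @param receptor,ligand PDBQT paths recorded in the config.
#' @param out output pose path recorded in the config.
#' @param path config file destination.
#' @export
write_vina_config <- function(box, params, receptor, ligand, out, path) {
  writeLines(c(
    sprintf("receptor = %s", receptor),
    sprintf("ligand = %s", ligand),
    sprintf("out = %s", out),
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %g", box$edge),
    sprintf("size_y = %g", box$edge),
    sprintf("size_z = %g", box$edge),
    sprintf("exhaustiveness = %d", params$exhaustiveness),
    sprintf("num_modes = %d", params$n_poses),
    sprintf("seed = %d", params$seed)), path)
  invisible(path)
}

#' Parse poses from a Vina output PDBQT file
#'
#' Reads MODEL blocks and their `REMARK VINA RESULT` score lines.
#'
#' @param path Vina output PDBQT.
#' @return list of poses (`coords`, `score`, `engine = "vina"`), in file
#'   order (Vina writes them best-first).
#' @export
parse_vina_poses <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts))
    stop("no MODEL records in Vina output: ", path)
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records in Vina output: ", path)
  lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    res <- grep("^REMARK VINA RESULT:", blk, value = TRUE)
    if (!length(res))
      stop("MODEL ", i, " lacks a REMARK VINA RESULT line in ", path)
    score <- as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "",
                                            res[1])), "\\s+")[[1]][1])
    at <- blk[substr(blk, 1, 6) %in% c("ATOM  ", "HETATM")]
    m <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
    list(coords = m, score = score, engine = "vina")
  })
}

#' Run an external AutoDock Vina binary on one box
#'
#' Writes a config file (cube center/size, exhaustiveness, seed, num_modes),
#' invokes the binary, and parses the output PDBQT into poses.
#'
#' @param receptor_pdbqt,ligand_pdbqt prepared PDBQT input paths.
#' @param box a [search_box()].
#' @param params an [engine_params()].
#' @param vina_bin binary name or path (default `"vina"`).
#' @param work_dir scratch directory for config/output files.
#' @return list of poses as in [parse_vina_poses()].
#' @export
vina_adapter <- function(receptor_pdbqt, ligand_pdbqt, box,
                         params = engine_params(), vina_bin = "vina",
                         work_dir = tempfile("vina_")) {
  if (Sys.which(vina_bin) == "" && !file.exists(vina_bin))
    stop("AutoDock Vina binary not found (looked for '", vina_bin,
         "'); install it or pass vina_bin")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- file.path(work_dir, "conf.txt")
  out <- file.path(work_dir, "out.pdbqt")
  write_vina_config(box, params, receptor_pdbqt, ligand_pdbqt, out, cfg)
  log <- suppressWarnings(
    system2(vina_bin, c("--config", cfg), stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status")
  if ((!is.null(status) && status != 0) || !file.exists(out))
    stop("Vina run failed (exit ", status %||% "?", "):\n",
         paste(utils::tail(log, 20), collapse = "\n"))
  parse_vina_poses(out)
}
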