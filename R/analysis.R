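# Trajectory analysis: per-step depth/orientation metrics, significant
# pose-change flags, plateau grouping, selectivity-filter residue
# identification and binder/non-binder classification.

#' Engagement-niche definition
#' @param residues list of [residue_ref()] objects forming the niche.
#' @param cutoff engagement distance cutoff, angstrom (default 4, a typical
#'   polar-contact distance).
#' @export
niche_definition <- function(residues, cutoff = 4) {
  if (inherits(residues, "residue_ref")) residues <- list(residues)
  stopifnot(length(residues) >= 1L, cutoff > 0)
  structure(list(residues = residues, cutoff = cutoff),
            class = "niche_definition")
}

# least-squares plane normal through >= 3 points: the smallest-variance
# eigenvector of the centered covariance
plane_normal <- function(pts) {
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2L, ctr)
  e <- eigen(crossprod(cen), symmetric = TRUE)
  if (e$values[2] < 1e-9 * max(e$values[1], 1))
    stop("ring atoms are collinear; cannot fit a plane")
  e$vectors[, 3L]
}

#' Per-step depth, orientation and niche-engagement metrics
#'
#' For each step's best pose: depth is the ligand centroid z in the aligned
#' frame (the mouth origin is z = 0, increasing toward the pocket bottom);
#' the orientation angle is `arccos |n . z|` in degrees, where `n` is the
#' unit normal of the least-squares plane through the named ring atoms --
#' 0 means the ring lies parallel to the pocket base, 90 means perpendicular
#' (the engagement orientation); `tail_in_niche` is true when any non-ring
#' ligand atom lies within the niche cutoff of any niche-residue atom.
#'
#' @param traj a [best_pose_per_step()] trajectory.
#' @param receptor_aligned the aligned receptor (frame of the poses).
#' @param ligand the ligand structure (atom names index the poses).
#' @param ring_atoms character vector of ligand atom names forming the ring
#'   system (at least 3, non-collinear).
#' @param niche a [niche_definition()] (optional; without it
#'   `tail_in_niche` is `NA`).
#' @return data.frame of class `step_metrics`: step, score, depth,
#'   orientation_angle, tail_in_niche.
#' @export
step_metrics <- function(traj, receptor_aligned, ligand, ring_atoms,
                         niche = NULL) {
  ring_idx <- match(ring_atoms, ligand$name)
  if (anyNA(ring_idx))
    stop("ring atoms not found in ligand: ",
         paste(ring_atoms[is.na(ring_idx)], collapse = ", "))
  if (length(ring_idx) < 3L) stop("need at least 3 ring atoms")
  tail_idx <- setdiff(seq_len(nrow(ligand)), ring_idx)
  niche_xyz <- if (!is.null(niche)) {
    idx <- unlist(lapply(niche$residues, function(r)
      resolve_ref(receptor_aligned, r)))
    coords(receptor_aligned)[idx, , drop = FALSE]
  }
  n <- nrow(traj$summary)
  out <- data.frame(step = seq_len(n), score = traj$summary$score,
                    depth = NA_real_, orientation_angle = NA_real_,
                    tail_in_niche = NA)
  for (k in seq_len(n)) {
    xyz <- traj$poses[[k]]$coords
    out$depth[k] <- mean(xyz[, 3])
    nrm <- plane_normal(xyz[ring_idx, , drop = FALSE])
    out$orientation_angle[k] <- acos(min(1, abs(nrm[3]))) * 180 / pi
    if (!is.null(niche_xyz) && length(tail_idx)) {
      tl <- xyz[tail_idx, , drop = FALSE]
      d2 <- outer(rowSums(tl^2), rowSums(niche_xyz^2), "+") -
        2 * tcrossprod(tl, niche_xyz)
      out$tail_in_niche[k] <- any(d2 <= niche$cutoff^2 + 1e-12)
    }
  }
  class(out) <- c("step_metrics", "data.frame")
  out
}

#' Flag steps with a significant pose change
#'
#' Step 1 is always flagged (pocket entry). A later step is flagged when,
#' relative to the previous step's best pose, the depth changes by more
#' than `depth_tol`, the in-frame RMSD (no superposition) exceeds
#' `rmsd_tol`, or the ring orientation angle changes by more than
#' `angle_tol`.
#'
#' @param metrics a [step_metrics()] result.
#' @param traj the matching trajectory (for pose RMSD).
#' @param depth_tol,rmsd_tol,angle_tol change thresholds (angstrom,
#'   angstrom, degrees).
#' @return data.frame of class `change_flags`: step, depth_changed,
#'   orientation_changed, rmsd_changed, significant.
#' @export
flag_changes <- function(metrics, traj, depth_tol = 0.5, rmsd_tol = 1.0,
                         angle_tol = 20) {
  n <- nrow(metrics)
  if (n < 2L) stop("need at least 2 steps to flag changes")
  out <- data.frame(step = seq_len(n), depth_changed = FALSE,
                    orientation_changed = FALSE, rmsd_changed = FALSE,
                    significant = FALSE)
  out$significant[1L] <- TRUE   # entry step
  for (k in 2:n) {
    dd <- abs(metrics$depth[k] - metrics$depth[k - 1L])
    da <- abs(metrics$orientation_angle[k] - metrics$orientation_angle[k - 1L])
    rmsd <- sqrt(mean(rowSums(
      (traj$poses[[k]]$coords - traj$poses[[k - 1L]]$coords)^2)))
    out$depth_changed[k] <- dd > depth_tol
    out$orientation_changed[k] <- da > angle_tol
    out$rmsd_changed[k] <- rmsd > rmsd_tol
    out$significant[k] <- out$depth_changed[k] || out$orientation_changed[k] ||
      out$rmsd_changed[k]
  }
  attr(out, "tolerances") <- c(depth = depth_tol, rmsd = rmsd_tol,
                               angle = angle_tol)
  class(out) <- c("change_flags", "data.frame")
  out
}

#' Group scan steps into pose plateaus
#'
#' Maximal runs of consecutive unflagged steps are merged with their
#' preceding flagged step, yielding an ordered partition of all steps. A
#' plateau is thus a run of steps over which the best pose does not change
#' significantly.
#'
#' @param flags a [flag_changes()] result.
#' @return list of integer step vectors, disjoint, ordered, covering
#'   1..n_steps.
#' @export
plateaus <- function(flags) {
  grp <- cumsum(flags$significant)
  grp[grp == 0L] <- 1L   # defensive: steps before any flag join group 1
  unname(split(flags$step, grp))
}

#' Identify selectivity-filter residue candidates
#'
#' A residue is a filter candidate when it contributes at least
#' `min_new_atoms` newly included heavy atoms at a step where the docked
#' pose actually changed (a flagged step after the first), or within
#' `window` steps before such a step. Residues whose new atoms arrive only
#' at plateau (unflagged) steps are excluded: by then the pose has already
#' assumed a position that does not change, so those atoms cannot have
#' driven a transition. Step 1 never triggers candidates -- its inclusions
#' reflect the initial box contents, not scan progression. Niche residues
#' are reported separately, not as filter members. Candidates are ranked by
#' the number of triggering flagged steps, then by total new-atom count.
#'
#' @param incl an [inclusion_table()].
#' @param flags a [flag_changes()] result.
#' @param niche a [niche_definition()] (or `NULL`).
#' @param min_new_atoms minimum newly included atoms at a triggering step.
#' @param window how many steps before a flagged step still count toward
#'   it.
#' @return data.frame of class `filter_candidates`: chain, resi, resn,
#'   steps, new_atoms, polarity, n_triggers, rationale; niche residues that
#'   met the rule are in `attr(, "niche_report")`.
#' @export
identify_filter <- function(incl, flags, niche = NULL, min_new_atoms = 3,
                            window = 1) {
  trig <- flags$step[flags$significant & flags$step > 1L]
  res <- incl$residues
  empty <- data.frame(chain = character(), resi = integer(),
                      resn = character(), steps = character(),
                      new_atoms = integer(), polarity = character(),
                      n_triggers = integer(), rationale = character(),
                      stringsAsFactors = FALSE)
  if (!length(trig) || !nrow(res)) {
    class(empty) <- c("filter_candidates", "data.frame")
    attr(empty, "niche_report") <- empty
    return(empty)
  }
  niche_key <- if (!is.null(niche))
    vapply(niche$residues, function(r) paste(r$chain, r$resi), character(1))
  else character()
  rows <- list()
  for (key in unique(paste(res$chain, res$resi))) {
    sub <- res[paste(res$chain, res$resi) == key, , drop = FALSE]
    hit_steps <- integer(); hit_atoms <- integer()
    for (t in trig) {
      win <- max(2L, t - window):t   # step 1 never counts
      n_new <- sum(sub$n_new[sub$step %in% win])
      if (n_new >= min_new_atoms) {
        hit_steps <- c(hit_steps, t)
        hit_atoms <- c(hit_atoms, n_new)
      }
    }
    if (!length(hit_steps)) next
    atoms <- incl$atoms[paste(incl$atoms$chain, incl$atoms$resi) == key &
                          incl$atoms$first_step > 0L, , drop = FALSE]
    polar_frac <- mean(atoms$element %in% c("N", "O", "S", "P"))
    polarity <- if (polar_frac >= 0.99) "polar"
    else if (polar_frac <= 0.01) "apolar" else "mixed"
    rows[[key]] <- data.frame(
      chain = sub$chain[1L], resi = sub$resi[1L], resn = sub$resn[1L],
      steps = paste(hit_steps, collapse = ","),
      new_atoms = max(hit_atoms), polarity = polarity,
      n_triggers = length(hit_steps),
      rationale = sprintf(
        "%s %s-%d contributes %d new %s atom(s) at flagged step(s) %s, where the docked pose changes",
        sub$resn[1L], sub$chain[1L], sub$resi[1L], max(hit_atoms), polarity,
        paste(hit_steps, collapse = ", ")),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    class(empty) <- c("filter_candidates", "data.frame")
    attr(empty, "niche_report") <- empty
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  is_niche <- paste(out$chain, out$resi) %in% niche_key
  niche_report <- out[is_niche, , drop = FALSE]
  out <- out[!is_niche, , drop = FALSE]
  out <- out[order(-out$n_triggers, -out$new_atoms, out$resi), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("filter_candidates", "data.frame")
  attr(out, "niche_report") <- niche_report
  out
}

#' @export
print.filter_candidates <- function(x, ...) {
  cat("Filter residue candidates:\n")
  if (nrow(x)) print.data.frame(x[, setdiff(names(x), "rationale")],
                                row.names = FALSE)
  else cat("  (none)\n")
  nr <- attr(x, "niche_report")
  if (!is.null(nr) && nrow(nr)) {
    cat("Niche residues meeting the rule (reported separately):\n")
    print.data.frame(nr[, setdiff(names(nr), "rationale")], row.names = FALSE)
  }
  invisible(x)
}

#' Classify a ligand as binder-like or non-binder-like
#'
#' Binder-like requires (a) some plateau of at least two steps whose poses
#' show the tail engaged in the niche with the ring within `angle_tol`
#' degrees of perpendicular to the pocket base, and (b) a final-plateau
#' depth of at least `base_depth`. Both criteria are reported individually.
#' This is a heuristic pose-series label, not a binding-affinity
#' prediction.
#'
#' @param metrics a [step_metrics()] result.
#' @param flags a [flag_changes()] result.
#' @param base_depth depth (angstrom, aligned frame) the final plateau must
#'   reach to count as bound at the pocket base.
#' @param angle_tol tolerance from perpendicular, degrees.
#' @return list of class `ligand_classification`: `classification`,
#'   `niche_engagement` (criterion a), `reaches_base` (criterion b).
#' @export
classify_ligand <- function(metrics, flags, base_depth, angle_tol = 20) {
  groups <- plateaus(flags)
  engaged <- vapply(groups, function(g) {
    length(g) >= 2L &&
      any(metrics$tail_in_niche[g] &
            metrics$orientation_angle[g] >= 90 - angle_tol, na.rm = TRUE)
  }, logical(1))
  final <- groups[[length(groups)]]
  reaches <- mean(metrics$depth[final]) >= base_depth
  structure(list(
    classification = if (any(engaged) && reaches) "binder-like"
                     else "non-binder-like",
    niche_engagement = any(engaged), reaches_base = reaches,
    final_depth = mean(metrics$depth[final])),
    class = "ligand_classification")
}

#' @export
print.ligand_classification <- function(x, ...) {
  cat(sprintf(
    "%s  [niche engagement (perpendicular, tail in niche): %s; reaches base depth: %s (final depth %.2f A)]\n",
    x$classification, x$niche_engagement, x$reaches_base, x$final_depth))
  invisible(x)
}
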