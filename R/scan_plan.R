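# Scan planning: the ordered sequence of cubic search boxes descending the
# pocket, the in-box membership predicate, and the per-step inclusion table.

#' Scan configuration
#'
#' Defaults mirror the standard tomographic protocol: an 18 A cubic search
#' space advanced in 1 A steps, 100 independent docking repetitions per step
#' with search exhaustiveness 16.
#'
#' @param edge cube edge length, angstrom.
#' @param step depth increment between consecutive boxes, angstrom.
#' @param repetitions independent docking runs per step.
#' @param exhaustiveness engine sampling effort per run.
#' @param seed base random seed; each (step, repetition) derives its own
#'   seed as `seed + 1000 * step + repetition`.
#' @param heavy_atoms_only count only heavy atoms in inclusion tables?
#' @param start_margin extra clearance (angstrom) added above the deepest
#'   mouth-reference atom when placing the first box.
#' @export
scan_config <- function(edge = 18, step = 1, repetitions = 100,
                        exhaustiveness = 16, seed = 1,
                        heavy_atoms_only = TRUE, start_margin = 0) {
  stopifnot(edge > 0, step > 0, repetitions >= 1, exhaustiveness >= 1,
            start_margin >= 0)
  if (edge < 8)
    warning("box edge ", edge, " A is below the 8 A engine interaction ",
            "cutoff; interactions may be truncated")
  structure(list(edge = edge, step = step,
                 repetitions = as.integer(repetitions),
                 exhaustiveness = as.integer(exhaustiveness),
                 seed = as.integer(seed),
                 heavy_atoms_only = isTRUE(heavy_atoms_only),
                 start_margin = start_margin),
            class = "scan_config")
}

#' Cubic search box
#' @param center length-3 center, angstrom.
#' @param edge edge length, angstrom.
#' @param step_index 1-based position in the scan.
#' @export
search_box <- function(center, edge, step_index = 1L) {
  structure(list(center = as.numeric(center), edge = as.numeric(edge),
                 step_index = as.integer(step_index)),
            class = "search_box")
}

#' Atoms inside a search box
#'
#' Closed-boundary membership: an atom is in the box iff all three
#' `|coord - center| <= edge / 2`, so atoms exactly on a face count.
#'
#' @param s a `tomo_structure` (or coordinate matrix).
#' @param box a [search_box()].
#' @param heavy_only exclude hydrogens?
#' @return integer vector of atom row indices.
#' @export
atoms_in_box <- function(s, box, heavy_only = TRUE) {
  xyz <- if (is.matrix(s)) s else coords(s)
  half <- box$edge / 2
  d <- abs(sweep(xyz, 2L, box$center))
  inside <- d[, 1] <= half & d[, 2] <= half & d[, 3] <= half
  if (heavy_only && !is.matrix(s)) inside <- inside & s$element != "H"
  which(inside)
}

#' Build the tomographic scan plan
#'
#' Places box 1 so that its leading (deepest, +z) face is tangent to the
#' deepest mouth-reference atom (plus `start_margin`), with the lateral
#' center on the mouth-reference centroid, then advances the box by
#' `cfg$step` in +z until the first box whose interior contains every
#' bottom-reference atom. The receptor must already be in the aligned frame
#' ([align_to_axis()]), i.e. scan axis = +z, mouth centroid at the origin.
#'
#' @param receptor_aligned aligned receptor `tomo_structure`.
#' @param pocket a [pocket_definition()].
#' @param cfg a [scan_config()].
#' @param lateral_center optional length-2 (x, y) override of the lateral
#'   box center; default mouth-reference centroid.
#' @return object of class `scan_plan` with `boxes` (list of [search_box()]),
#'   `config`, and `n_steps`.
#' @export
build_scan <- function(receptor_aligned, pocket, cfg = scan_config(),
                       lateral_center = NULL) {
  mouth_idx <- resolve_ref(receptor_aligned, pocket$mouth_ref)
  bottom_idx <- resolve_ref(receptor_aligned, pocket$bottom_ref)
  xyz <- coords(receptor_aligned)
  z_lead1 <- max(xyz[mouth_idx, 3]) + cfg$start_margin
  ctr_xy <- if (is.null(lateral_center))
    colMeans(xyz[mouth_idx, 1:2, drop = FALSE]) else as.numeric(lateral_center)
  depth_span <- max(xyz[bottom_idx, 3]) - min(xyz[mouth_idx, 3])
  max_steps <- max(4L, ceiling(10 * max(depth_span, cfg$edge) / cfg$step))
  boxes <- list()
  k <- 0L
  done_at <- NA_integer_
  repeat {
    k <- k + 1L
    center <- c(ctr_xy, z_lead1 - cfg$edge / 2 + (k - 1L) * cfg$step)
    boxes[[k]] <- search_box(center, cfg$edge, k)
    inb <- atoms_in_box(xyz[bottom_idx, , drop = FALSE], boxes[[k]],
                        heavy_only = FALSE)
    if (length(inb) == length(bottom_idx)) { done_at <- k; break }
    if (k >= max_steps)
      stop("bottom reference ", format(pocket$bottom_ref),
           " never fully enters the search box within ", max_steps,
           " steps; the scan axis is likely misoriented")
  }
  if (done_at < 2L) {   # minimum scan of two steps
    boxes[[2L]] <- search_box(boxes[[1L]]$center + c(0, 0, cfg$step),
                              cfg$edge, 2L)
    done_at <- 2L
  }
  structure(list(boxes = boxes, config = cfg, n_steps = done_at,
                 mouth_z = z_lead1 - cfg$start_margin),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  zs <- vapply(x$boxes, function(b) b$center[3], numeric(1))
  cat(sprintf(
    "<scan_plan: %d steps, edge %.1f A, step %.1f A, leading face z %.2f..%.2f A>\n",
    x$n_steps, x$config$edge, x$config$step,
    zs[1] + x$config$edge / 2, zs[x$n_steps] + x$config$edge / 2))
  invisible(x)
}

#' Single static box for conventional docking
#'
#' The conventional-docking baseline: one cube centered on the centroid of
#' the pocket-lining atoms, encompassing the whole pocket.
#'
#' @inheritParams build_scan
#' @param edge cube edge, angstrom.
#' @export
static_box <- function(receptor_aligned, pocket, edge = 18) {
  lining <- select_residues(receptor_aligned, pocket$lining)
  ctr <- colMeans(coords(lining))
  box <- search_box(ctr, edge, 1L)
  if (length(atoms_in_box(lining, box, heavy_only = FALSE)) < nrow(lining))
    warning("static box of edge ", edge,
            " A does not contain all pocket-lining atoms")
  box
}

#' Per-step atom inclusion table
#'
#' For every pocket-lining atom, records the first scan step at which it
#' enters the search box, plus a per-residue aggregation of newly included
#' atom counts per step. Atoms never included get sentinel step 0.
#'
#' @param receptor_aligned aligned receptor.
#' @param plan a [build_scan()] result.
#' @param pocket optional [pocket_definition()]; when given, the table is
#'   restricted to the pocket-lining residues.
#' @param heavy_only count heavy atoms only (default from the plan's config).
#' @return object of class `inclusion_table`: list with `atoms` (data.frame:
#'   chain, resi, resn, name, element, first_step) and `residues`
#'   (data.frame: step, chain, resi, resn, n_new).
#' @export
inclusion_table <- function(receptor_aligned, plan, pocket = NULL,
                            heavy_only = plan$config$heavy_atoms_only) {
  s <- if (is.null(pocket)) receptor_aligned
       else select_residues(receptor_aligned, pocket$lining)
  if (heavy_only) {
    s <- structure(as.data.frame(s)[s$element != "H", , drop = FALSE],
                   id = attr(s, "id"), class = c("tomo_structure", "data.frame"))
  }
  first <- rep(0L, nrow(s))
  remaining <- seq_len(nrow(s))
  xyz <- coords(s)
  for (k in seq_len(plan$n_steps)) {
    if (!length(remaining)) break
    inb <- atoms_in_box(xyz[remaining, , drop = FALSE], plan$boxes[[k]],
                        heavy_only = FALSE)
    if (length(inb)) {
      first[remaining[inb]] <- k
      remaining <- remaining[-inb]
    }
  }
  atoms <- data.frame(chain = s$chain, resi = s$resi, resn = s$resn,
                      name = s$name, element = s$element,
                      first_step = first, stringsAsFactors = FALSE)
  inc <- atoms[atoms$first_step > 0L, , drop = FALSE]
  agg <- if (nrow(inc)) {
    a <- stats::aggregate(rep(1L, nrow(inc)),
                          by = list(step = inc$first_step, chain = inc$chain,
                                    resi = inc$resi, resn = inc$resn),
                          FUN = sum)
    names(a)[5] <- "n_new"
    a[order(a$step, a$chain, a$resi), , drop = FALSE]
  } else {
    data.frame(step = integer(), chain = character(), resi = integer(),
               resn = character(), n_new = integer())
  }
  rownames(agg) <- NULL
  structure(list(atoms = atoms, residues = agg, n_steps = plan$n_steps),
            class = "inclusion_table")
}

#' @export
print.inclusion_table <- function(x, ...) {
  cat(sprintf("<inclusion_table: %d atoms over %d steps (%d never included)>\n",
              nrow(x$atoms), x$n_steps, sum(x$atoms$first_step == 0L)))
  invisible(x)
}

#' Export an inclusion table as TSV
#'
#' Writes the per-atom table (`first_inclusion` column uses `"none"` for
#' never-included atoms) and the per-residue new-atom counts side by side.
#'
#' @param x an [inclusion_table()].
#' @param atoms_path,residues_path output TSV paths (either may be `NULL`).
#' @export
write_inclusion_table <- function(x, atoms_path = NULL, residues_path = NULL) {
  if (!is.null(atoms_path)) {
    a <- x$atoms
    a$first_inclusion <- ifelse(a$first_step == 0L, "none",
                                as.character(a$first_step))
    a$first_step <- NULL
    utils::write.table(a, atoms_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(residues_path))
    utils::write.table(x$residues, residues_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}
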