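# Pocket geometry: principal axes of inertia, scan-axis selection, pocket
# depth, and alignment of the working frame so the scan axis is +z.

# Standard atomic masses (u) for the elements that occur in protein/ligand
# structures; unknown elements fall back to carbon.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.9,
                  Mg = 24.305, Mn = 54.938, Zn = 65.38, Ca = 40.078,
                  Fe = 55.845, Na = 22.99, K = 39.098, Se = 78.971)

atom_masses <- function(s) {
  m <- ELEMENT_MASS[s$element]
  m[is.na(m)] <- ELEMENT_MASS[["C"]]
  unname(m)
}

#' Principal axes of inertia of a structure
#'
#' Assembles the inertia tensor about the (mass-weighted) centroid and
#' returns its eigenvectors sorted by ascending moment. For an elongated
#' molecule the smallest-moment axis is the long axis.
#'
#' @param s a `tomo_structure`.
#' @param mass_weighted use element masses (default) or unit masses.
#' @return list with `axes` (3x3 matrix, one orthonormal axis per column,
#'   ascending moment), `moments` (length 3), and `centroid`.
#' @export
principal_axes <- function(s, mass_weighted = TRUE) {
  xyz <- coords(s)
  if (nrow(xyz) < 3L) stop("need at least 3 atoms for principal axes")
  m <- if (mass_weighted) atom_masses(s) else rep(1, nrow(xyz))
  ctr <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2L, ctr)
  # inertia tensor I = sum m (|r|^2 I3 - r r^T)
  r2 <- rowSums(r^2)
  I3 <- diag(3) * sum(m * r2) - crossprod(r * sqrt(m))
  # degeneracy: collinear atoms give a rank-<2 centered cloud
  if (qr(r, tol = 1e-9)$rank < 2L)
    stop("degenerate (collinear) structure: principal axes undefined")
  e <- eigen(I3, symmetric = TRUE)
  ord <- order(e$values)
  axes <- e$vectors[, ord, drop = FALSE]
  # deterministic sign convention: largest-|component| entry positive
  for (j in 1:3) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  list(axes = axes, moments = e$values[ord], centroid = ctr)
}

#' Definition of a deep binding pocket
#'
#' @param lining list of [residue_range()] objects for the pocket-lining
#'   residues.
#' @param mouth_ref [residue_ref()] marking the pocket mouth.
#' @param bottom_ref [residue_ref()] marking the pocket bottom.
#' @param axis_override optional length-3 vector; when given it replaces the
#'   principal-axis choice in [scan_axis()].
#' @export
pocket_definition <- function(lining, mouth_ref, bottom_ref,
                              axis_override = NULL) {
  if (inherits(lining, "residue_range")) lining <- list(lining)
  stopifnot(length(lining) >= 1L, inherits(mouth_ref, "residue_ref"),
            inherits(bottom_ref, "residue_ref"))
  if (!is.null(axis_override)) {
    axis_override <- as.numeric(axis_override)
    stopifnot(length(axis_override) == 3L)
    if (sqrt(sum(axis_override^2)) < 1e-12) stop("axis_override is zero")
  }
  structure(list(lining = lining, mouth_ref = mouth_ref,
                 bottom_ref = bottom_ref, axis_override = axis_override),
            class = "pocket_definition")
}

#' Read a pocket definition from a YAML file
#'
#' Expected keys: `chain`, `ranges` (list of `[start, end]` pairs),
#' `mouth_ref` and `bottom_ref` (each `{resi, resn?, chain?}`), optional
#' `axis_override` (3-vector).
#' @param path YAML file path.
#' @export
read_pocket <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- y$chain %||% NA_character_
  lining <- lapply(y$ranges, function(r)
    residue_range(ch, r[[1]], r[[2]]))
  mk_ref <- function(r) residue_ref(r$chain %||% ch, r$resi, r$resn)
  pocket_definition(lining, mk_ref(y$mouth_ref), mk_ref(y$bottom_ref),
                    axis_override = y$axis_override)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ref_centroid <- function(s, ref, heavy_only = TRUE, convention = "centroid") {
  idx <- resolve_ref(s, ref)
  if (convention == "ca") {
    ca <- idx[s$name[idx] == "CA"]
    if (!length(ca)) stop("no CA atom in residue ", format(ref))
    idx <- ca
  } else if (heavy_only) {
    hv <- idx[s$element[idx] != "H"]
    if (length(hv)) idx <- hv
  }
  colMeans(coords(s)[idx, , drop = FALSE])
}

#' Determine the scan axis of a pocket
#'
#' Selects the principal axis of inertia of the receptor with the largest
#' absolute cosine to the mouth-to-bottom centroid vector, sign-oriented so
#' it points from the mouth toward the bottom. When
#' `pocket$axis_override` is set, that direction is used instead (also
#' sign-oriented toward the bottom).
#'
#' @param receptor a `tomo_structure`.
#' @param pocket a [pocket_definition()].
#' @param mass_weighted passed to [principal_axes()].
#' @return list of class `scan_axis`: `direction` (unit vector, mouth to
#'   bottom), `origin` (mouth reference centroid).
#' @export
scan_axis <- function(receptor, pocket, mass_weighted = TRUE) {
  mouth <- ref_centroid(receptor, pocket$mouth_ref)
  bottom <- ref_centroid(receptor, pocket$bottom_ref)
  u <- bottom - mouth
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("mouth and bottom references coincide")
  u <- u / nu
  if (!is.null(pocket$axis_override)) {
    d <- pocket$axis_override / sqrt(sum(pocket$axis_override^2))
  } else {
    pa <- principal_axes(receptor, mass_weighted = mass_weighted)
    cosines <- abs(drop(t(pa$axes) %*% u))
    ord <- order(cosines, decreasing = TRUE)
    if (cosines[ord[1]] - cosines[ord[2]] < 1e-6)
      stop("ambiguous scan axis: two principal axes are equally aligned ",
           "with the mouth-to-bottom vector; set axis_override in the ",
           "pocket definition")
    # a degenerate moment makes the chosen eigendirection itself arbitrary
    mom <- pa$moments
    if (any(abs(mom[ord[1]] - mom[-ord[1]]) <= 1e-6 * max(abs(mom))))
      stop("ambiguous scan axis: the inertia moment of the selected ",
           "principal axis is degenerate; set axis_override in the pocket ",
           "definition")
    d <- pa$axes[, ord[1]]
  }
  if (sum(d * u) < 0) d <- -d   # point toward the bottom
  structure(list(direction = d / sqrt(sum(d^2)), origin = mouth),
            class = "scan_axis")
}

#' Pocket depth between the mouth and bottom reference residues
#'
#' @param receptor a `tomo_structure`.
#' @param pocket a [pocket_definition()].
#' @param convention `"centroid"` (heavy-atom residue centroids, default) or
#'   `"ca"` (CA-to-CA distance).
#' @return depth in angstrom (non-negative).
#' @export
pocket_depth <- function(receptor, pocket,
                         convention = c("centroid", "ca")) {
  convention <- match.arg(convention)
  a <- ref_centroid(receptor, pocket$mouth_ref, convention = convention)
  b <- ref_centroid(receptor, pocket$bottom_ref, convention = convention)
  sqrt(sum((a - b)^2))
}

# Rotation taking unit vector a onto unit vector b (Rodrigues formula).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-18) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: rotate about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- p - sum(p * a) * a
    w <- w / sqrt(sum(w^2))
    return(2 * tcrossprod(w) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Align receptor and ligand so the scan axis is +z
#'
#' Rotates and translates the working frame so the scan-axis direction is
#' exactly (0, 0, 1) and the mouth centroid sits at the origin; search boxes
#' can then stay world-axis-aligned while their centers advance purely in z.
#' The transform is returned so all outputs can be mapped back.
#'
#' @param receptor,ligand `tomo_structure` objects (ligand may be `NULL`).
#' @param axis a [scan_axis()].
#' @return list with `receptor`, `ligand`, and the `rigid_transform` applied.
#' @export
align_to_axis <- function(receptor, ligand, axis) {
  stopifnot(inherits(axis, "scan_axis"))
  R <- rotation_between(axis$direction, c(0, 0, 1))
  tr <- rigid_transform(R, -drop(R %*% axis$origin))
  list(receptor = apply_transform(receptor, tr),
       ligand = if (is.null(ligand)) NULL else apply_transform(ligand, tr),
       transform = tr)
}
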