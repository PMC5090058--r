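#' @keywords internal
"_PACKAGE"

# A tomo_structure is a data.frame of atom records, one row per atom, with
# columns: serial, name, altloc, resn, chain, resi, icode, x, y, z, occupancy,
# bfactor, element, charge, hetero, label.  `label` is the pharmacophore
# class used by the built-in scoring function (donor/acceptor/aromatic/apolar).

STRUCT_COLS <- c("serial", "name", "altloc", "resn", "chain", "resi", "icode",
                 "x", "y", "z", "occupancy", "bfactor", "element", "charge",
                 "hetero", "label")

#' Construct a molecular structure from an atom table
#'
#' Builds the atom-table container used throughout the package. Most users
#' will obtain structures with [parse_structure()] or the fixture generators
#' rather than calling this directly.
#'
#' @param atoms data.frame with at least columns `name`, `resn`, `chain`,
#'   `resi`, `x`, `y`, `z`, `element`. Missing optional columns are filled
#'   with defaults.
#' @param id character label for the structure.
#' @return An object of class `tomo_structure` (a data.frame subclass).
#' @export
tomo_structure <- function(atoms, id = "structure") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L)
    stop("a tomo_structure must contain at least one atom")
  need <- c("name", "resn", "chain", "resi", "x", "y", "z", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  defaults <- list(serial = seq_len(nrow(atoms)), altloc = "", icode = "",
                   occupancy = 1, bfactor = 0, charge = NA_real_,
                   hetero = FALSE, label = NA_character_)
  for (nm in names(defaults))
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  atoms <- atoms[, STRUCT_COLS]
  atoms$resi <- as.integer(atoms$resi)
  for (nm in c("x", "y", "z")) atoms[[nm]] <- as.numeric(atoms[[nm]])
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$element)))
    stop("every atom must carry a non-empty element symbol")
  key <- paste(atoms$chain, atoms$resi, atoms$icode, atoms$name, atoms$altloc)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resi, icode, name, altloc): ",
         key[duplicated(key)][1L])
  if (is.na(id) || !nzchar(id)) id <- "structure"
  rownames(atoms) <- NULL
  structure(atoms, id = id, class = c("tomo_structure", "data.frame"))
}

#' @export
print.tomo_structure <- function(x, ...) {
  nres <- nrow(unique(as.data.frame(x)[, c("chain", "resi", "icode")]))
  cat(sprintf("<tomo_structure '%s': %d atoms, %d residues, %d chain(s)>\n",
              attr(x, "id"), nrow(x), nres, length(unique(x$chain))))
  invisible(x)
}

#' Atom coordinates as a numeric matrix
#' @param s a `tomo_structure`.
#' @return n x 3 numeric matrix of coordinates (angstrom).
#' @export
coords <- function(s) {
  m <- as.matrix(as.data.frame(s)[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

`coords<-` <- function(s, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(s), ncol(value) == 3L)
  s$x <- value[, 1L]; s$y <- value[, 2L]; s$z <- value[, 3L]
  s
}

#' Reference to a single residue
#'
#' @param chain one-character chain identifier.
#' @param resi integer residue sequence number.
#' @param resn optional 3-letter residue name; when given it is validated
#'   against the structure at resolution time.
#' @return An object of class `residue_ref`.
#' @export
residue_ref <- function(chain, resi, resn = NULL) {
  structure(list(chain = as.character(chain), resi = as.integer(resi),
                 resn = resn), class = "residue_ref")
}

#' @export
format.residue_ref <- function(x, ...) {
  sprintf("%s%s-%d", if (is.null(x$resn)) "" else paste0(x$resn, " "),
          x$chain, x$resi)
}

#' @export
print.residue_ref <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Inclusive residue range on one chain
#' @param chain chain id (or NA to match any chain).
#' @param start,end inclusive residue numbers.
#' @export
residue_range <- function(chain, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) stop("residue_range: end < start")
  structure(list(chain = as.character(chain), start = start, end = end),
            class = "residue_range")
}

#' Resolve a residue reference to atom row indices
#' @param s a `tomo_structure`.
#' @param ref a `residue_ref`.
#' @return integer vector of row indices (always non-empty).
#' @export
resolve_ref <- function(s, ref) {
  stopifnot(inherits(ref, "residue_ref"))
  idx <- which(s$chain == ref$chain & s$resi == ref$resi)
  if (!length(idx))
    stop("residue ", format(ref), " resolves to no atom in '",
         attr(s, "id"), "'")
  if (!is.null(ref$resn) && !all(s$resn[idx] == ref$resn))
    stop("residue ", ref$chain, "-", ref$resi, " is ",
         unique(s$resn[idx])[1L], ", not the expected ", ref$resn)
  idx
}

#' Select residues from a structure
#'
#' Subsets a structure to the atoms of the given residue ranges and/or single
#' residue references, preserving atom order and never duplicating atoms.
#'
#' @param s a `tomo_structure`.
#' @param ranges a list of `residue_range` and/or `residue_ref` objects; a
#'   single such object is also accepted.
#' @return A `tomo_structure` containing the matching atoms.
#' @export
select_residues <- function(s, ranges) {
  if (inherits(ranges, c("residue_range", "residue_ref"))) ranges <- list(ranges)
  keep <- rep(FALSE, nrow(s))
  for (r in ranges) {
    if (inherits(r, "residue_ref")) {
      hit <- s$chain == r$chain & s$resi == r$resi
      if (!any(hit)) stop("range matches no atoms: ", format(r))
    } else if (inherits(r, "residue_range")) {
      hit <- s$resi >= r$start & s$resi <= r$end
      if (!is.na(r$chain)) hit <- hit & s$chain == r$chain
      if (!any(hit))
        stop(sprintf("range matches no atoms: chain %s %d-%d",
                     r$chain, r$start, r$end))
    } else stop("ranges must be residue_range or residue_ref objects")
    keep <- keep | hit
  }
  out <- as.data.frame(s)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, id = attr(s, "id"),
            class = c("tomo_structure", "data.frame"))
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid-body transform (proper rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix has determinant -1 (improper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), -drop(t(t$rotation) %*% t$translation))
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b `rigid_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param s a `tomo_structure` or an n x 3 coordinate matrix.
#' @param t a `rigid_transform`.
#' @return Same type as `s`, with `coords' = R coords + t`; all annotation is
#'   unchanged.
#' @export
apply_transform <- function(s, t) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.matrix(s))
    return(sweep(s %*% t(t$rotation), 2L, t$translation, "+"))
  m <- coords(s) %*% t(t$rotation)
  m <- sweep(m, 2L, t$translation, "+")
  coords(s) <- m
  s
}

# ---- PDB / PDBQT parsing ----------------------------------------------------

# AutoDock atom types -> element. "A" is aromatic carbon.
AD_TYPE_ELEMENT <- c(A = "C", C = "C", N = "N", NA. = "N", NS = "N", OA = "O",
                     OS = "O", SA = "S", S = "S", HD = "H", HS = "H", H = "H",
                     P = "P", F = "F", Cl = "Cl", CL = "Cl", Br = "Br",
                     BR = "Br", I = "I", Mg = "Mg", MG = "Mg", Mn = "Mn",
                     Zn = "Zn", ZN = "Zn", Ca = "Ca", CA = "Ca", Fe = "Fe",
                     FE = "Fe")

element_from_name <- function(name) {
  # PDB convention: columns 13-14 hold the element, right-justified
  nm <- gsub("[0-9'\"]", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("CL", "BR", "MG", "ZN", "FE", "MN", "NA", "CA", "SE")
  ifelse(two %in% known2 & nchar(nm) > 1 & substr(name, 1, 1) != " ",
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         toupper(substr(nm, 1, 1)))
}

substr_num <- function(line, a, b, what, lineno) {
  v <- suppressWarnings(as.numeric(substr(line, a, b)))
  if (is.na(v))
    stop(sprintf("unparseable %s in columns %d-%d at line %d: '%s'",
                 what, a, b, lineno, substr(line, a, b)), call. = FALSE)
  v
}

#' Parse a PDB or PDBQT structure file
#'
#' Reads ATOM/HETATM records from a PDB v3.3 or AutoDock PDBQT file into a
#' [tomo_structure()]. PDBQT partial charges (columns 67-76) and AutoDock atom
#' types are parsed when `format = "pdbqt"`; ROOT/BRANCH torsion-tree records
#' are tolerated and ignored. Only the first MODEL of a multi-model file is
#' read (use [read_pose_model()] for pose series).
#'
#' @param path file path.
#' @param format `"pdb"` or `"pdbqt"`; default guessed from the file
#'   extension.
#' @param strip_water drop water residues (HOH/WAT/TIP3)? Default `TRUE`.
#' @param keep_altloc how to treat alternate locations: `"best"` (default)
#'   keeps the highest-occupancy conformer per atom (first wins on ties),
#'   `"all"` keeps every record.
#' @param id structure label; defaults to the file name.
#' @return A `tomo_structure`. Aromatic-carbon PDBQT atoms (type `A`) get
#'   pharmacophore label `"aromatic"`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "pdbqt"),
                            strip_water = TRUE, keep_altloc = c("best", "all"),
                            id = NULL) {
  format <- match.arg(format)
  keep_altloc <- match.arg(keep_altloc)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # stop at the end of the first model
  endm <- which(trimws(rec) %in% c("ENDMDL"))
  if (length(endm)) is_atom[seq_along(lines) > endm[1L]] <- FALSE
  idx <- which(is_atom)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  n <- length(idx)
  parse_one <- function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("truncated ATOM/HETATM record at line ", i, call. = FALSE)
    list(
      serial = as.integer(substr_num(ln, 7, 11, "serial", i)),
      name = trimws(substr(ln, 13, 16)),
      altloc = trimws(substr(ln, 17, 17)),
      resn = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resi = as.integer(substr_num(ln, 23, 26, "residue number", i)),
      icode = trimws(substr(ln, 27, 27)),
      x = substr_num(ln, 31, 38, "x coordinate", i),
      y = substr_num(ln, 39, 46, "y coordinate", i),
      z = substr_num(ln, 47, 54, "z coordinate", i),
      occupancy = if (nchar(ln) >= 60)
        suppressWarnings(as.numeric(substr(ln, 55, 60))) else NA_real_,
      bfactor = if (nchar(ln) >= 66)
        suppressWarnings(as.numeric(substr(ln, 61, 66))) else NA_real_,
      el_col = if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else "",
      charge_q = if (format == "pdbqt" && nchar(ln) >= 76)
        suppressWarnings(as.numeric(substr(ln, 67, 76))) else NA_real_,
      ad_type = if (format == "pdbqt" && nchar(ln) >= 78)
        trimws(substr(ln, 78, 79)) else "",
      hetero = substr(ln, 1, 6) == "HETATM")
  }
  recs <- lapply(idx, parse_one)
  at <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (format == "pdbqt") {
    el <- AD_TYPE_ELEMENT[at$ad_type]
    at$element <- ifelse(!is.na(el) & nzchar(at$ad_type), unname(el),
                         element_from_name(at$name))
    at$charge <- at$charge_q
    at$label <- ifelse(at$ad_type == "A", "aromatic", NA_character_)
  } else {
    at$element <- ifelse(nzchar(at$el_col),
                         paste0(toupper(substr(at$el_col, 1, 1)),
                                tolower(substr(at$el_col, 2, 2))),
                         element_from_name(at$name))
    at$charge <- NA_real_
    at$label <- NA_character_
  }
  at$occupancy[is.na(at$occupancy)] <- 1
  at$bfactor[is.na(at$bfactor)] <- 0
  if (strip_water) at <- at[!at$resn %in% c("HOH", "WAT", "TIP3", "TIP"), ,
                            drop = FALSE]
  if (nrow(at) == 0L) stop("structure is empty after water stripping: ", path)
  if (keep_altloc == "best" && any(nzchar(at$altloc))) {
    at$.row <- seq_len(nrow(at))
    key <- paste(at$chain, at$resi, at$icode, at$name)
    at <- at[order(key, -at$occupancy, at$.row), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resi, at$icode, at$name)), ,
             drop = FALSE]
    at <- at[order(at$.row), , drop = FALSE]   # restore file order
    at$.row <- NULL
    at$altloc <- ""
  }
  at$el_col <- NULL; at$charge_q <- NULL; at$ad_type <- NULL
  # restore pharmacophore labels from a sidecar written by write_structure()
  sidecar <- paste0(path, ".labels.tsv")
  if (file.exists(sidecar)) {
    lt <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    key <- paste(at$chain, at$resi, at$name)
    hit <- match(key, paste(lt$chain, lt$resi, lt$name))
    at$label[!is.na(hit)] <- lt$label[hit[!is.na(hit)]]
  }
  tomo_structure(at, id = if (is.null(id)) basename(path) else id)
}

# ---- PDB writing ------------------------------------------------------------

fmt_atom_line <- function(a) {
  name <- a$name
  # PDB alignment: 1-3 char names start in column 14 unless 4 chars
  name_f <- if (nchar(name) >= 4L) substr(name, 1, 4) else paste0(" ", name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (isTRUE(a$hetero)) "HETATM" else "ATOM",
          a$serial %% 100000L, name_f,
          if (nzchar(a$altloc)) a$altloc else " ", a$resn, a$chain,
          a$resi %% 10000L, if (nzchar(a$icode)) a$icode else " ",
          a$x, a$y, a$z, a$occupancy, a$bfactor,
          toupper(substr(a$element, 1, 2)))
}

structure_pdb_lines <- function(s) {
  df <- as.data.frame(s)
  vapply(seq_len(nrow(df)), function(i) fmt_atom_line(df[i, ]), character(1))
}

#' Write a structure to a single-model PDB file
#'
#' When the structure carries pharmacophore labels (its `label` column), a
#' sidecar table `<path>.labels.tsv` is written next to the PDB file, and
#' [parse_structure()] restores the labels from it automatically -- the PDB
#' format itself has no field for them.
#'
#' @param s a `tomo_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  writeLines(c(structure_pdb_lines(s), "END"), path)
  if (any(!is.na(s$label))) {
    utils::write.table(
      as.data.frame(s)[, c("chain", "resi", "name", "label")],
      paste0(path, ".labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}

#' Write docking poses as a multi-model PDB file
#'
#' One MODEL block per pose, in input order, with the docking score recorded
#' on a `REMARK TOMODOCK SCORE` line inside each block. The file re-parses
#' with [read_pose_model()] to the same coordinates within PDB format
#' precision (0.001 angstrom).
#'
#' @param poses list of poses (as returned by docking functions; each has
#'   `coords` and `score`).
#' @param ligand the ligand `tomo_structure` providing atom annotation; all
#'   poses must share its atom ordering.
#' @param path output path.
#' @export
write_pose_model <- function(poses, ligand, path) {
  if (!length(poses)) stop("no poses to write")
  n <- nrow(ligand)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    if (nrow(p$coords) != n)
      stop("pose ", i, " has ", nrow(p$coords), " atoms; ligand has ", n)
    s <- ligand
    coords(s) <- p$coords
    writeLines(c(sprintf("MODEL %8d", i),
                 sprintf("REMARK TOMODOCK SCORE %10.4f", p$score),
                 structure_pdb_lines(s), "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read poses back from a multi-model PDB file
#' @param path file written by [write_pose_model()].
#' @param ligand optional ligand structure; when given, atom counts are
#'   checked against it.
#' @return list of poses with `coords` and `score`.
#' @export
read_pose_model <- function(path, ligand = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) != length(ends) || !length(starts))
    stop("not a multi-model pose file: ", path)
  lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    sc <- grep("^REMARK TOMODOCK SCORE", blk, value = TRUE)
    score <- if (length(sc)) as.numeric(sub("^REMARK TOMODOCK SCORE", "", sc[1])) else NA_real_
    at <- blk[substr(blk, 1, 6) %in% c("ATOM  ", "HETATM")]
    m <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
    if (!is.null(ligand) && nrow(m) != nrow(ligand))
      stop("pose ", i, " atom count differs from ligand")
    list(coords = m, score = score)
  })
}
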