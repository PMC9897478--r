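#' Atomic structure container
#'
#' A `structure_model` holds an ordered atom table plus an `n x 3` coordinate
#' matrix in Angstrom. It is the common currency of all geometry, scattering
#' and pore operations in the package.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `altloc`, `occupancy`, `is_hetero`, and
#'   optionally `segid` (domain label) and `b` (explicit per-atom scattering
#'   weight, fm, used by the toy generator).
#' @param xyz numeric matrix, `nrow(atoms)` rows, 3 columns (Angstrom).
#' @param title free-form description.
#' @param source_path file the model came from, or `""`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, title = "", source_path = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "altloc", "occupancy", "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (!"segid" %in% names(atoms)) atoms$segid <- ""
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, title = title,
                 source_path = source_path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chains%s\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a `structure_model`
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Subset a structure by atom indices
#'
#' @param x a `structure_model`
#' @param idx integer index vector (order preserved)
#' @return A `structure_model` with the chosen atoms.
#' @export
subset_structure <- function(x, idx) {
  structure_model(x$atoms[idx, , drop = FALSE], x$xyz[idx, , drop = FALSE],
                  title = x$title, source_path = x$source_path)
}

#' Replace coordinates of a structure
#' @param x a `structure_model`
#' @param xyz new `n x 3` coordinate matrix
#' @export
set_coords <- function(x, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == n_atoms(x), ncol(xyz) == 3)
  x$xyz <- xyz
  dimnames(x$xyz) <- list(NULL, c("x", "y", "z"))
  x
}

# element guess from a PDB atom name when the element column is absent
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- c("CA", "NA", "CL", "MG", "ZN", "FE", "SE", "BR", "MN", "CU", "K")
  # hetero ion names arrive as the full name ("CA", "ZN"); within residues the
  # first alphabetic character is the element for C/N/O/S/P/H
  first <- sub("^[0-9']*", "", nm)
  ifelse(nm %in% two & nchar(nm) <= 2, nm, substr(first, 1, 1))
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parsing is delegated to \pkg{bio3d}; the result is normalized into a
#' [structure_model()]. Ions and other HETATM records are retained (waters are
#' dropped). Alternate locations are resolved per `altloc_policy`.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param altloc_policy `"highest-occupancy"` (default; ties broken by altloc
#'   letter order), `"first"`, or `"all"` (keep every altloc record).
#' @param multi if `TRUE` and the file has MODEL records, return a
#'   [trajectory()] over all models; otherwise the first model only.
#' @param keep_waters retain HOH/WAT records (default `FALSE`).
#' @return A `structure_model` (or a `trajectory` when `multi = TRUE`).
#' @export
read_structure <- function(path, altloc_policy = c("highest-occupancy", "first", "all"),
                           multi = FALSE, keep_waters = FALSE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  is_cif <- grepl("\\.cif$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = multi, rm.alt = FALSE,
                                verbose = FALSE) else
      bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unparsable coordinate file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  elem <- if (!is.null(a$elesy) && any(nzchar(trimws(a$elesy)))) {
    ifelse(nzchar(trimws(a$elesy)), toupper(trimws(a$elesy)),
           .element_from_name(a$elety))
  } else .element_from_name(a$elety)
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = elem,
    resname = trimws(a$resid),
    resno = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  xyz <- cbind(a$x, a$y, a$z)
  if (!keep_waters) {
    keep <- !(atoms$resname %in% c("HOH", "WAT", "DOD"))
    atoms <- atoms[keep, , drop = FALSE]; xyz <- xyz[keep, , drop = FALSE]
  }
  if (altloc_policy != "all" && any(nzchar(atoms$altloc))) {
    key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name)
    ord <- switch(altloc_policy,
      "highest-occupancy" = order(key, -atoms$occupancy, atoms$altloc),
      "first" = order(key, seq_len(nrow(atoms))))
    keep_rows <- ord[!duplicated(key[ord])]
    keep_rows <- sort(keep_rows)   # restore file order
    atoms <- atoms[keep_rows, , drop = FALSE]
    xyz <- xyz[keep_rows, , drop = FALSE]
  }
  unknown <- !(atoms$element %in% names(.b_coh_fm))
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(atoms$element[unknown]), collapse = ", "),
            ": retained with zero scattering length")
  }
  model <- structure_model(atoms, xyz,
                           title = if (!is.null(pdb$header)) paste(pdb$header, collapse = " ") else "",
                           source_path = path)
  if (multi && !is.null(pdb$xyz) && nrow(pdb$xyz) > 1) {
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(i)
      matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
    if (!keep_waters || altloc_policy != "all") {
      # bio3d frames carry every parsed atom; realign to the kept rows
      sel <- match(paste(atoms$serial, atoms$name), paste(a$eleno, trimws(a$elety)))
      frames <- lapply(frames, function(m) m[sel, , drop = FALSE])
    }
    return(trajectory(model, frames))
  }
  model
}

.fmt_pdb_atom <- function(a, xyz, i) {
  nm <- a$name[i]
  # PDB column-13 convention: 1-3 character names start in column 14
  nm_f <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (a$is_hetero[i]) "HETATM" else "ATOM",
          a$serial[i] %% 100000, nm_f, a$altloc[i],
          substr(a$resname[i], 1, 3), substr(a$chain[i], 1, 1),
          a$resno[i] %% 10000, xyz[i, 1], xyz[i, 2], xyz[i, 3],
          a$occupancy[i], 0, a$element[i])
}

#' Write a structure (or trajectory) as PDB text
#'
#' A minimal fixed-width PDB writer. Given a [trajectory()], frames are
#' wrapped in MODEL/ENDMDL records.
#'
#' @param x a `structure_model` or `trajectory`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_one <- function(model, xyz) {
    a <- model$atoms
    lines <- vapply(seq_len(nrow(a)), function(i) .fmt_pdb_atom(a, xyz, i), "")
    writeLines(lines, con)
  }
  if (inherits(x, "trajectory")) {
    for (f in seq_along(x$frames)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      write_one(x$topology, x$frames[[f]])
      writeLines("ENDMDL", con)
    }
  } else {
    if (nzchar(x$title)) writeLines(paste0("TITLE     ", substr(x$title, 1, 70)), con)
    write_one(x, x$xyz)
  }
  writeLines("END", con)
  invisible(path)
}
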