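# Standard atomic weights (amu) for elements commonly found in protein
# structures and small-molecule ligands.
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, MN = 54.938,
  FE = 55.845, ZN = 65.38, CU = 63.546, SE = 78.971
)

#' Resolve atomic masses from element symbols
#'
#' Unknown symbols fall back to the mass of carbon with a warning; residue and
#' ligand centres of mass are insensitive to the occasional exotic atom.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  mass <- .element_masses[key]
  unknown <- is.na(mass)
  if (any(unknown)) {
    warning(
      "Unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
      "; using the mass of carbon.",
      call. = FALSE
    )
    mass[unknown] <- .element_masses[["C"]]
  }
  unname(mass)
}

# Infer the element symbol from a PDB atom name when columns 77-78 are blank.
# Two-letter element candidates are only accepted when the name starts in
# column 13 (i.e. the raw 4-character field has no leading blank).
.element_from_name <- function(name_raw) {
  nm <- toupper(name_raw)
  two <- substr(trimws(nm), 1, 2)
  lead <- substr(nm, 1, 1)
  first <- substr(trimws(nm), 1, 1)
  out <- ifelse(
    lead != " " & two %in% names(.element_masses) & !(two %in% c("CA", "CD", "CE", "NA", "ND", "NE", "HD", "HE", "HG")),
    two, first
  )
  # strip leading digits (e.g. "1HB")
  ifelse(grepl("^[0-9]", out), substr(trimws(gsub("^[0-9]+", "", trimws(nm))), 1, 1), out)
}

.num_field <- function(x, lines_idx, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !grepl("^\\s*$", x)
  bad <- bad | (is.na(out) & what %in% c("x", "y", "z"))
  if (any(is.na(out[what %in% c("x", "y", "z")]) | bad)) {
    i <- which(is.na(out) | bad)[1]
    stop(
      "Malformed PDB record at line ", lines_idx[i],
      ": cannot parse ", what, " field '", x[i], "'.",
      call. = FALSE
    )
  }
  out
}

#' Parse a protein structure from PDB-format text
#'
#' Reads `ATOM`/`HETATM` fixed-column records into a tidy atom table. Element
#' symbols come from columns 77-78 when present, otherwise from the atom name;
#' masses are resolved from a built-in standard atomic-weight table. When a
#' `CRYST1` record is present its cell lengths are kept as the (orthorhombic)
#' box. Alternate locations are reduced to the highest-occupancy conformer;
#' insertion codes are rejected.
#'
#' @param pdb Either PDB-format text (single string or character vector of
#'   lines) or the path to a PDB file.
#' @return A tibble of class `structure_model` with one row per atom and
#'   columns `record`, `atom_id`, `name`, `altloc`, `residue_name`, `chain`,
#'   `residue_id`, `x`, `y`, `z`, `occupancy`, `bfactor`, `element`, `mass`
#'   (coordinates in Angstrom, masses in amu). The box, if any, is stored in
#'   `attr(, "box")` as three lengths in Angstrom.
#' @export
#' @examples
#' pdb <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C"
#' parse_structure(pdb)
parse_structure <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    stop("No ATOM/HETATM records found: empty structure.", call. = FALSE)
  }
  idx <- which(is_atom)
  al <- lines[idx]
  short <- nchar(al) < 54
  if (any(short)) {
    stop(
      "Malformed PDB record at line ", idx[short][1],
      ": ATOM/HETATM line shorter than 54 columns.",
      call. = FALSE
    )
  }
  al <- formatC(al, width = 80, flag = "-")

  icode <- substr(al, 27, 27)
  if (any(icode != " ")) {
    stop(
      "Insertion codes are not supported (line ", idx[icode != " "][1],
      "); renumber the structure first.",
      call. = FALSE
    )
  }

  atoms <- tibble::tibble(
    record = trimws(substr(al, 1, 6)),
    atom_id = as.integer(.num_field(substr(al, 7, 11), idx, "atom serial")),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    residue_name = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    residue_id = as.integer(.num_field(substr(al, 23, 26), idx, "residue id")),
    x = .num_field(substr(al, 31, 38), idx, "x"),
    y = .num_field(substr(al, 39, 46), idx, "y"),
    z = .num_field(substr(al, 47, 54), idx, "z"),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(al, 55, 60)))
      ifelse(is.na(o), 1, o)
    },
    bfactor = {
      b <- suppressWarnings(as.numeric(substr(al, 61, 66)))
      ifelse(is.na(b), 0, b)
    },
    element = {
      e <- trimws(substr(al, 77, 78))
      ifelse(e == "", .element_from_name(substr(al, 13, 16)), toupper(e))
    }
  )

  # alternate locations: keep the highest-occupancy conformer of each atom
  if (any(atoms$altloc != " ")) {
    atoms <- atoms |>
      dplyr::group_by(.data$chain, .data$residue_id, .data$name) |>
      dplyr::slice_max(.data$occupancy, n = 1L, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$atom_id)
  }
  if (anyDuplicated(atoms$atom_id)) {
    stop("Duplicate atom serial numbers in structure.", call. = FALSE)
  }
  atoms$mass <- element_mass(atoms$element)

  box <- NULL
  cry <- lines[substr(lines, 1, 6) == "CRYST1"]
  if (length(cry) >= 1L) {
    box <- as.numeric(c(
      substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33)
    ))
    if (anyNA(box) || any(box <= 0)) box <- NULL
  }
  new_structure_model(atoms, box = box)
}

#' @rdname parse_structure
#' @param atoms A data frame with the columns listed under [parse_structure()]
#'   (`altloc`, `occupancy`, `element`, `mass` are filled with defaults when
#'   missing).
#' @param box Optional orthorhombic box: three lengths in Angstrom.
#' @export
new_structure_model <- function(atoms, box = NULL) {
  atoms <- tibble::as_tibble(atoms)
  if (!all(c("atom_id", "name", "chain", "residue_id", "residue_name",
             "x", "y", "z") %in% names(atoms))) {
    stop("Atom table is missing required columns.", call. = FALSE)
  }
  if (!"record" %in% names(atoms)) atoms$record <- "ATOM"
  if (!"altloc" %in% names(atoms)) atoms$altloc <- " "
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0
  if (!"element" %in% names(atoms)) atoms$element <- "C"
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  if (anyDuplicated(atoms$atom_id)) {
    stop("atom_id values must be unique.", call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("All coordinates must be finite.", call. = FALSE)
  }
  if (any(atoms$mass <= 0)) stop("All masses must be positive.", call. = FALSE)
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3L, all(box > 0))
  }
  structure(
    atoms,
    box = box,
    class = c("structure_model", class(tibble::tibble()))
  )
}

#' Write a structure as PDB-format text
#'
#' Emits fixed-column `ATOM`/`HETATM` records (and a `CRYST1` record when a
#' box is attached). B-factors are written to the standard 6.2F column, so the
#' stored precision is 0.01.
#'
#' @param structure A `structure_model`.
#' @param path Optional output path; when `NULL` the text is only returned.
#' @param bfactor Optional numeric vector (one per atom) overriding the
#'   `bfactor` column.
#' @return The PDB text, invisibly when `path` is given.
#' @export
write_structure <- function(structure, path = NULL, bfactor = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  b <- if (is.null(bfactor)) structure$bfactor else bfactor
  stopifnot(length(b) == nrow(structure))
  if (any(b > 999.99)) {
    warning("B-factor values > 999.99 clipped to fit the PDB column.",
            call. = FALSE)
    b <- pmin(b, 999.99)
  }
  b <- pmax(b, -99.99)
  # atom names of 1-3 characters conventionally start in column 14
  nm <- ifelse(nchar(structure$name) >= 4L,
               substr(structure$name, 1, 4),
               sprintf(" %-3s", structure$name))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    structure$record, structure$atom_id, nm, structure$altloc,
    structure$residue_name, structure$chain, structure$residue_id, " ",
    structure$x, structure$y, structure$z, structure$occupancy, b,
    formatC(structure$element, width = 2)
  )
  box <- attr(structure, "box")
  if (!is.null(box)) {
    lines <- c(
      sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
              box[1], box[2], box[3], 90, 90, 90),
      lines
    )
  }
  text <- paste(c(lines, "END"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Select analysis atoms from a structure
#'
#' @param structure A `structure_model`.
#' @param selection One of `"calpha"` (default; one CA atom per protein
#'   residue), `"backbone"` (N, CA, C, O), `"heavy"` (all non-hydrogen
#'   protein atoms) or `"all"`.
#' @return The subset of rows of `structure` matching the selection.
#' @export
select_atoms <- function(structure,
                         selection = c("calpha", "backbone", "heavy", "all")) {
  selection <- match.arg(selection)
  prot <- structure$record == "ATOM"
  keep <- switch(
    selection,
    calpha = prot & structure$name == "CA",
    backbone = prot & structure$name %in% c("N", "CA", "C", "O"),
    heavy = prot & !(structure$element %in% c("H", "D")),
    all = rep(TRUE, nrow(structure))
  )
  out <- structure[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("Atom selection '", selection, "' matched no atoms.", call. = FALSE)
  }
  out
}

#' @export
print.structure_model <- function(x, ...) {
  box <- attr(x, "box")
  cat("<structure_model> ", nrow(x), " atoms, ",
      dplyr::n_distinct(x$chain), " chain(s)",
      if (!is.null(box)) paste0(", box ", paste(round(box, 1), collapse = " x "), " A"),
      "\n", sep = "")
  NextMethod()
}
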