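#' Read a macromolecular structure from a PDB file
#'
#' Parses ATOM/HETATM records into a flat atom table (one row per atom).
#' Alternate locations are resolved by keeping the highest-occupancy copy of
#' each atom (ties go to altloc "A"), waters are dropped by default, and
#' hydrogens are dropped by default because the downstream surface-area and
#' contact analyses are heavy-atom analyses.
#'
#' @param path Path to a PDB file.
#' @param keep_waters Keep water residues (HOH/WAT/DOD/H2O)? Default `FALSE`.
#' @param keep_hydrogens Keep hydrogen atoms? Default `FALSE`.
#' @param source_id Free-text identifier stored on the result (defaults to the
#'   file name without extension, e.g. a PDB code).
#'
#' @return A tibble of class `dp_structure` with columns `serial`, `atom_name`,
#'   `element`, `residue_name`, `chain_id`, `residue_number`, `x`, `y`, `z`,
#'   `vdw_radius` (all `NA` until [assign_radii()] is called) and `record`
#'   ("ATOM" or "HETATM"), ordered by chain then residue number then serial.
#' @seealso [write_structure()], [split_complex()], [assign_radii()]
#' @export
#' @examples
#' pdb <- system.file("extdata", "toy_pocket.pdb", package = "dualprofiler")
#' read_structure(pdb)
read_structure <- function(path, keep_waters = FALSE, keep_hydrogens = FALSE,
                           source_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read structure: file does not exist: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(at, .data$type %in% c("ATOM", "HETATM"))
  if (nrow(at) == 0L) {
    stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)
  }

  s <- tibble::tibble(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = infer_element(at$elesy, at$elety),
    residue_name = trimws(at$resid),
    chain_id = dplyr::coalesce(at$chain, " "),
    residue_number = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    record = at$type,
    occupancy = dplyr::coalesce(at$o, 1),
    altloc = dplyr::coalesce(at$alt, "")
  )

  # altloc resolution: one copy per (residue, atom name); highest occupancy
  # wins, ties broken towards altloc "A" ("" sorts before letters already).
  s <- s |>
    dplyr::arrange(
      .data$chain_id, .data$residue_number, .data$atom_name,
      dplyr::desc(.data$occupancy), .data$altloc
    ) |>
    dplyr::distinct(
      .data$chain_id, .data$residue_number, .data$residue_name,
      .data$atom_name, .keep_all = TRUE
    )

  if (!keep_waters) {
    s <- dplyr::filter(s, !.data$residue_name %in% c("HOH", "WAT", "DOD", "H2O"))
  }
  if (!keep_hydrogens) {
    s <- dplyr::filter(s, !.data$element %in% c("H", "D"))
  }
  if (nrow(s) == 0L) {
    stop("empty structure: no atoms left after filtering in ", path,
         call. = FALSE)
  }
  s <- dplyr::select(s, -"occupancy", -"altloc")
  s$vdw_radius <- NA_real_
  if (is.null(source_id)) {
    source_id <- sub("\\.[^.]*$", "", basename(path))
  }
  as_structure(s, source_id = source_id)
}

#' @keywords internal
#' @noRd
infer_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back to the atom name: strip digits/primes, take the leading letter
    # (two-letter guesses from names are unreliable without column alignment)
    nm <- gsub("[^A-Za-z]", "", trimws(elety[miss]))
    el[miss] <- toupper(substr(nm, 1, 1))
  }
  # normalise two-letter symbols to title case (e.g. "BR" -> "Br")
  two <- nchar(el) == 2
  el[two] <- paste0(substr(el[two], 1, 1), tolower(substr(el[two], 2, 2)))
  el
}

#' @keywords internal
#' @noRd
as_structure <- function(df, source_id = "") {
  df <- dplyr::arrange(df, .data$chain_id, .data$residue_number, .data$serial)
  if (anyDuplicated(df$serial)) {
    stop("invalid structure: duplicated atom serial numbers", call. = FALSE)
  }
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  attr(df, "source_id") <- source_id
  class(df) <- unique(c("dp_structure", class(tibble::as_tibble(df))))
  df
}

#' Write a structure back to PDB format
#'
#' @param s A structure tibble as returned by [read_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
  rec <- if ("record" %in% names(s)) s$record else rep("ATOM", nrow(s))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rec, resno = s$residue_number,
    chain = s$chain_id, resid = s$residue_name, eleno = s$serial,
    elety = s$atom_name, elesy = s$element,
    o = rep(1, nrow(s)), b = rep(0, nrow(s))
  )
  invisible(path)
}

#' Split a docked complex into protein and ligand parts
#'
#' Selects the ligand either by residue name (e.g. `"LIG"`) or by a
#' `chain:number` string (e.g. `"B:1"`); the selector must match exactly one
#' residue. Everything else that is not water becomes the protein part.
#'
#' @param s A structure tibble (the docked complex).
#' @param ligand_selector Residue name, or `"chain:resno"` string.
#' @param keep_hetero Keep non-selected HETATM residues in the protein part?
#'   Default `FALSE` (they are dropped, as for cofactor-free analyses).
#'
#' @return A list of class `complex_pair` with elements `protein`, `ligand`
#'   and `complex` (their union), each a `dp_structure` tibble.
#' @export
split_complex <- function(s, ligand_selector, keep_hetero = FALSE) {
  if (grepl(":", ligand_selector, fixed = TRUE)) {
    parts <- strsplit(ligand_selector, ":", fixed = TRUE)[[1]]
    sel <- s$chain_id == parts[1] & s$residue_number == as.integer(parts[2])
  } else {
    sel <- s$residue_name == ligand_selector
  }
  keys <- unique(s[sel, c("chain_id", "residue_number", "residue_name")])
  if (nrow(keys) != 1L) {
    stop("ligand selector '", ligand_selector, "' matches ", nrow(keys),
         " residues (must match exactly 1)", call. = FALSE)
  }
  ligand <- s[sel, , drop = FALSE]
  protein <- s[!sel, , drop = FALSE]
  if (!keep_hetero && "record" %in% names(protein)) {
    protein <- dplyr::filter(protein, .data$record == "ATOM")
  }
  src <- attr(s, "source_id") %||% ""
  pair <- list(
    protein = as_structure(protein, source_id = src),
    ligand = as_structure(ligand, source_id = src),
    complex = as_structure(dplyr::bind_rows(protein, ligand), source_id = src)
  )
  stopifnot(nrow(pair$complex) == nrow(pair$protein) + nrow(pair$ligand))
  class(pair) <- "complex_pair"
  pair
}

#' @export
print.complex_pair <- function(x, ...) {
  cat("<complex_pair> protein: ", nrow(x$protein), " atoms / ",
      nrow(dplyr::distinct(x$protein, .data$chain_id, .data$residue_number)),
      " residues; ligand: ", nrow(x$ligand), " atoms (",
      x$ligand$residue_name[1], ")\n", sep = "")
  invisible(x)
}

#' Chothia-style van der Waals radius set
#'
#' Element-keyed heavy-atom radii in Angstrom, in the style used by classic
#' accessible-surface programs (carbon 1.87, nitrogen 1.65, oxygen 1.40,
#' sulfur 1.85, phosphorus 1.90). Elements not in the table fall back to the
#' 1.80 A default of [assign_radii()].
#'
#' @return Named numeric vector of radii (A).
#' @export
chothia_radii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90)
}

#' Assign van der Waals radii to every atom
#'
#' @param s A structure tibble.
#' @param radius_set Named numeric vector mapping element symbols to radii in
#'   Angstrom; defaults to [chothia_radii()].
#' @param default Radius (A) for elements absent from `radius_set`; a warning
#'   lists the affected elements. Default 1.80 A.
#' @return `s` with the `vdw_radius` column filled (all values > 0).
#' @export
assign_radii <- function(s, radius_set = chothia_radii(), default = 1.80) {
  r <- unname(radius_set[s$element])
  unknown <- unique(s$element[is.na(r)])
  if (length(unknown) > 0) {
    warning("no radius for element(s) ", paste(unknown, collapse = ", "),
            "; using default ", default, " A", call. = FALSE)
    r[is.na(r)] <- default
  }
  stopifnot(all(r > 0))
  s$vdw_radius <- r
  s
}

#' Render a residue key as a field-style label
#'
#' @param residue_name 3-letter residue code(s).
#' @param residue_number Residue sequence number(s).
#' @return Character vector like `"Lys-890"`.
#' @export
residue_label <- function(residue_name, residue_number) {
  nm <- paste0(toupper(substr(residue_name, 1, 1)),
               tolower(substr(residue_name, 2, nchar(residue_name))))
  paste0(nm, "-", residue_number)
}

#' Parse labels like "Lys-890" back into name and number
#'
#' @param label Character vector of `"Xxx-123"` labels.
#' @return Tibble with `residue_name` (upper-case 3-letter code) and
#'   `residue_number`.
#' @export
parse_residue_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)-([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("unparsable residue label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    residue_name = toupper(vapply(m, `[`, "", 2)),
    residue_number = as.integer(vapply(m, `[`, "", 3))
  )
}
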