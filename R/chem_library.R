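#' Define a substituent set for combinatorial enumeration
#'
#' @param label Attachment-point label, `"R1"` or `"R2"`.
#' @param members Character vector of SMILES fragments written so that
#'   splicing them into the scaffold at the attachment marker yields valid
#'   SMILES (one attachment point, ring-closure digits that do not collide
#'   with the scaffold's; the shipped defaults use digit 9).
#' @return A list of class `substituent_set`.
#' @export
substituent_set <- function(label, members) {
  stopifnot(label %in% c("R1", "R2"), length(members) >= 1,
            !anyDuplicated(members))
  structure(list(label = label, members = as.character(members)),
            class = "substituent_set")
}

#' @export
print.substituent_set <- function(x, ...) {
  cat("<substituent_set ", x$label, "> ", length(x$members), " fragments: ",
      paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default scaffold and substituent configuration
#'
#' A documented, editable placeholder configuration in the 9 x 5 layout:
#' a synthetic quinoxaline-sulfonamide-like toy scaffold with two attachment
#' markers, nine generic R1 fragments, and the five classic small R2 groups
#' (-OCH3, -OH, -NH2, -F, -Br). The R1 fragments and the scaffold are
#' synthetic stand-ins — real projects supply their own line notation via
#' [substituent_set()] — while the R2 set is the standard small-group set.
#'
#' @return A list with `scaffold` (character), `r1` and `r2`
#'   ([substituent_set()] objects).
#' @export
default_library_config <- function() {
  list(
    scaffold = "O=S(=O)(Nc8cnc(nc8[R2])c8ccccc8)c8ccc([R1])cc8",
    r1 = substituent_set("R1", c(
      "C", "OC", "N", "C(F)(F)F", "c9ccccc9", "c9ccncc9", "N9CCOCC9",
      "C(=O)N", "S(=O)(=O)C"
    )),
    r2 = substituent_set("R2", c("OC", "O", "N", "F", "Br"))
  )
}

# Canonical SMILES via openbabel; "" or failure marks an invalid structure.
#' @noRd
canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  trimws(sub("\t.*", "", out))
}

#' Enumerate a scaffold + R-group combinatorial library
#'
#' Replaces the `[R1]` and `[R2]` markers of the scaffold with every pairing
#' of fragments, canonicalizes each product, and names the compounds with
#' sequential integers in systematic substitution order: R1 is the outer
#' loop and R2 the inner one, so compound number
#' `(r1_index - 1) * |R2| + r2_index`. The 9 x 5 default configuration
#' therefore yields compounds 1 to 45.
#'
#' @param scaffold SMILES string containing exactly one `[R1]` and one
#'   `[R2]` marker.
#' @param r1,r2 [substituent_set()] objects.
#' @return A tibble of class `compound_library`: `compound`, `r1_index`,
#'   `r2_index`, `r1`, `r2`, `smiles`, `canonical`.
#' @export
#' @examples
#' cfg <- default_library_config()
#' lib <- enumerate_library(cfg$scaffold, cfg$r1, cfg$r2)
#' nrow(lib) # 45
enumerate_library <- function(scaffold, r1, r2) {
  stopifnot(inherits(r1, "substituent_set"), inherits(r2, "substituent_set"))
  n1 <- lengths(regmatches(scaffold, gregexpr("[R1]", scaffold, fixed = TRUE)))
  n2 <- lengths(regmatches(scaffold, gregexpr("[R2]", scaffold, fixed = TRUE)))
  if (n1 != 1L || n2 != 1L) {
    stop("scaffold must contain exactly one [R1] and one [R2] marker",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(r1_index = seq_along(r1$members),
                             r2_index = seq_along(r2$members))
  out <- grid |>
    dplyr::mutate(
      compound = (.data$r1_index - 1L) * length(r2$members) + .data$r2_index,
      r1 = r1$members[.data$r1_index],
      r2 = r2$members[.data$r2_index],
      smiles = purrr::map2_chr(.data$r1, .data$r2, \(a, b) {
        sub("[R2]", b, sub("[R1]", a, scaffold, fixed = TRUE), fixed = TRUE)
      }),
      canonical = purrr::map_chr(.data$smiles, canonical_smiles)
    ) |>
    dplyr::relocate("compound") |>
    dplyr::arrange(.data$compound)
  bad <- out[!nzchar(out$canonical), ]
  if (nrow(bad) > 0L) {
    stop("invalid chemistry for fragment pairing(s): ",
         paste0("(R1='", bad$r1, "', R2='", bad$r2, "')", collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(out$canonical)) {
    stop("enumeration produced duplicate structures; fragment sets are not ",
         "distinct under this scaffold", call. = FALSE)
  }
  class(out) <- unique(c("compound_library", class(out)))
  out
}

# Heavy-atom element and bond tables of one parsed SMILES, via openbabel's
# V2000 molblock (the standard SDF container trips over single-heavy-atom
# molecules, so the fixed-width atom/bond lines are read directly).
#' @noRd
parse_mol_graph <- function(smiles) {
  mol <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) ""
  )
  lines <- strsplit(mol, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) {
    stop("unparsable structure: '", smiles, "'", call. = FALSE)
  }
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(natoms) || natoms < 1L) {
    stop("unparsable structure: '", smiles, "'", call. = FALSE)
  }
  atom_lines <- lines[4 + seq_len(natoms)]
  atoms <- tibble::tibble(
    idx = seq_len(natoms),
    element = trimws(substr(atom_lines, 32, 34))
  )
  bonds <- if (nbonds >= 1L) {
    bond_lines <- lines[4 + natoms + seq_len(nbonds)]
    tibble::tibble(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
  } else {
    tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  list(atoms = atoms, bonds = bonds)
}

# rotatable bonds: non-ring single bonds between heavy atoms that each carry
# at least one further heavy neighbour; amide C-N excluded
#' @noRd
count_rotatable <- function(smiles) {
  g <- parse_mol_graph(smiles)
  if (nrow(g$bonds) == 0L) return(0L)
  ig <- igraph::graph_from_edgelist(as.matrix(g$bonds[, c("a1", "a2")]),
                                    directed = FALSE)
  bridge_ids <- igraph::bridges(ig)
  # map igraph edge ids back to bond rows (same construction order)
  in_ring <- !(seq_len(nrow(g$bonds)) %in% as.integer(bridge_ids))
  deg <- igraph::degree(ig)
  deg <- c(deg, rep(0L, max(0L, nrow(g$atoms) - length(deg))))
  el <- g$atoms$element

  is_amide_cn <- function(a, b) {
    # carbon double-bonded to oxygen on one end, nitrogen on the other
    for (pr in list(c(a, b), c(b, a))) {
      cc <- pr[1]; nn <- pr[2]
      if (el[cc] == "C" && el[nn] == "N") {
        dbl_o <- with(g$bonds, (a1 == cc | a2 == cc) & order == 2L)
        partners <- ifelse(g$bonds$a1 == cc, g$bonds$a2, g$bonds$a1)
        if (any(dbl_o & el[partners] == "O")) return(TRUE)
      }
    }
    FALSE
  }

  rot <- 0L
  for (i in seq_len(nrow(g$bonds))) {
    b <- g$bonds[i, ]
    if (b$order != 1L || in_ring[i]) next
    if (deg[b$a1] < 2L || deg[b$a2] < 2L) next
    if (is_amide_cn(b$a1, b$a2)) next
    rot <- rot + 1L
  }
  rot
}

#' Drug-likeness descriptors for line-notation structures
#'
#' Computes, per structure: molecular weight (standard atomic masses
#' including implicit hydrogens), hydrogen-bond donors (N/O bearing at least
#' one hydrogen), hydrogen-bond acceptors (N plus O count, the classic
#' rule-of-five definition), rotatable bonds (non-ring single bonds between
#' heavy atoms each bearing a further heavy neighbour, amide C-N excluded)
#' and logP by Wildman-Crippen atomic contributions. Parsing, mass summation
#' and logP come from openbabel; the rotatable-bond rule is applied on the
#' molecular graph directly so that the documented rule is exactly the one
#' computed.
#'
#' @param structures Character vector of SMILES, or a `compound_library`
#'   tibble (its `smiles` column is used and identity columns are kept).
#' @return A tibble with `smiles`, `mol_weight` (Da), `hbd`, `hba`,
#'   `rotatable_bonds`, `logp` (plus library identity columns when a library
#'   was supplied).
#' @export
#' @examples
#' compute_descriptors("CCO") # ethanol: MW 46.07, HBD 1, HBA 1, 0 rotatable
compute_descriptors <- function(structures) {
  lib <- NULL
  if (inherits(structures, "data.frame")) {
    lib <- structures
    structures <- lib$smiles
  }
  stopifnot(is.character(structures), length(structures) >= 1)
  rows <- purrr::map(structures, function(smi) {
    props <- tryCatch(
      ChemmineOB::forEachMol("SMILES", smi, ChemmineOB::prop_OB)[[1]],
      error = function(e) NULL
    )
    g <- parse_mol_graph(smi)  # errors with the offending string
    if (is.null(props) || nrow(props) == 0L) {
      stop("unparsable structure: '", smi, "'", call. = FALSE)
    }
    tibble::tibble(
      smiles = smi,
      mol_weight = props$MW,
      hbd = as.integer(props$HBD),
      hba = sum(g$atoms$element %in% c("N", "O")),
      rotatable_bonds = count_rotatable(smi),
      logp = props$logP
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(lib)) {
    out <- dplyr::bind_cols(
      dplyr::select(tibble::as_tibble(lib),
                    dplyr::any_of(c("compound", "r1_index", "r2_index",
                                    "r1", "r2", "canonical"))),
      out
    )
  }
  out
}

#' Rule-of-five verdicts for a descriptor table
#'
#' Applies the five drug-likeness rules with strict "<" comparisons against
#' the desired values: molecular weight < 500 Da, H-bond donors < 5, H-bond
#' acceptors < 10, rotatable bonds < 10, logP < 5. A compound passes overall
#' only when all five rules pass; a value exactly at a limit fails (the
#' desired-value notation is strict, unlike the classic "no more than"
#' phrasing).
#'
#' @param d Descriptor tibble from [compute_descriptors()] (or any tibble
#'   with columns `mol_weight`, `hbd`, `hba`, `rotatable_bonds`, `logp`).
#' @return `d` with logical columns `mw_ok`, `hbd_ok`, `hba_ok`, `rot_ok`,
#'   `logp_ok` and `pass`.
#' @export
lipinski_evaluate <- function(d) {
  d |>
    tibble::as_tibble() |>
    dplyr::mutate(
      mw_ok = .data$mol_weight < 500,
      hbd_ok = .data$hbd < 5,
      hba_ok = .data$hba < 10,
      rot_ok = .data$rotatable_bonds < 10,
      logp_ok = .data$logp < 5,
      pass = .data$mw_ok & .data$hbd_ok & .data$hba_ok & .data$rot_ok &
        .data$logp_ok
    )
}
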