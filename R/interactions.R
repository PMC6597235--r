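#' Geometric cutoffs for contact and hydrogen-bond detection
#'
#' Defaults follow the conventions of classic 2-D interaction-diagram
#' software: non-bonded contacts are heavy-atom pairs between 2.9 and 3.9 A,
#' hydrogen bonds are donor-acceptor heavy-atom pairs within 3.35 A. With no
#' hydrogens in docked crystal-derived structures, H-bond detection is
#' distance + element chemistry only (no angular term).
#'
#' @param contact_min,contact_max Non-bonded contact window (A).
#' @param hbond_max Donor-acceptor heavy-atom distance cutoff (A).
#' @param donor_elements,acceptor_elements Element symbols treated as H-bond
#'   capable.
#' @return A list of class `contact_params`.
#' @export
contact_params <- function(contact_min = 2.9, contact_max = 3.9,
                           hbond_max = 3.35,
                           donor_elements = c("N", "O", "S"),
                           acceptor_elements = c("N", "O", "S")) {
  stopifnot(contact_min > 0, contact_min < contact_max,
            hbond_max <= contact_max)
  structure(
    list(contact_min = contact_min, contact_max = contact_max,
         hbond_max = hbond_max, donor_elements = donor_elements,
         acceptor_elements = acceptor_elements),
    class = "contact_params"
  )
}

# All protein x ligand atom pairs with their distances.
#' @noRd
cross_pairs <- function(pair) {
  p <- tibble::as_tibble(pair$protein)
  l <- tibble::as_tibble(pair$ligand)
  if (nrow(l) == 0L || nrow(p) == 0L) {
    return(tibble::tibble())
  }
  g <- tidyr::expand_grid(pi_ = seq_len(nrow(p)), li_ = seq_len(nrow(l)))
  tibble::tibble(
    chain_id = p$chain_id[g$pi_],
    residue_number = p$residue_number[g$pi_],
    residue_name = p$residue_name[g$pi_],
    protein_serial = p$serial[g$pi_],
    protein_atom = p$atom_name[g$pi_],
    protein_element = p$element[g$pi_],
    ligand_serial = l$serial[g$li_],
    ligand_atom = l$atom_name[g$li_],
    ligand_element = l$element[g$li_],
    distance = sqrt((p$x[g$pi_] - l$x[g$li_])^2 +
                    (p$y[g$pi_] - l$y[g$li_])^2 +
                    (p$z[g$pi_] - l$z[g$li_])^2)
  )
}

#' Hydrogen bonds between protein and ligand
#'
#' Heavy-atom criterion: both atoms must be H-bond capable elements and the
#' pair distance must not exceed `hbond_max`.
#'
#' @param pair A [split_complex()] result.
#' @param params A [contact_params()] object.
#' @return Tibble of donor/acceptor candidate pairs with residue identity,
#'   atom names and `distance` (A, reported to 2 decimals in printed tables).
#' @export
find_hbonds <- function(pair, params = contact_params()) {
  cp <- cross_pairs(pair)
  if (nrow(cp) == 0L) return(cp)
  capable <- union(params$donor_elements, params$acceptor_elements)
  cp |>
    dplyr::filter(
      .data$distance <= params$hbond_max,
      .data$protein_element %in% capable,
      .data$ligand_element %in% capable
    ) |>
    dplyr::arrange(.data$chain_id, .data$residue_number, .data$distance)
}

#' Non-bonded contacts between protein and ligand
#'
#' Heavy-atom pairs with `contact_min <= d <= contact_max`. Pairs that
#' already qualify as hydrogen bonds under the same parameters are excluded,
#' so the two listings never double-count an atom pair.
#'
#' @inheritParams find_hbonds
#' @return Tibble of contact pairs with residue identity, atom names and
#'   `distance` (A).
#' @export
find_contacts <- function(pair, params = contact_params()) {
  cp <- cross_pairs(pair)
  if (nrow(cp) == 0L) return(cp)
  hb <- find_hbonds(pair, params)
  out <- dplyr::filter(cp, .data$distance >= params$contact_min,
                       .data$distance <= params$contact_max)
  if (nrow(hb) > 0L) {
    out <- dplyr::anti_join(out, hb,
                            by = c("protein_serial", "ligand_serial"))
  }
  dplyr::arrange(out, .data$chain_id, .data$residue_number, .data$distance)
}

#' Per-residue interaction counts
#'
#' Groups contact and hydrogen-bond lists from the same complex by protein
#' residue. Totals are conserved: the `n_nonbonded` column sums to the number
#' of contact pairs and `n_hbonds` to the number of H-bond pairs.
#'
#' @param contacts Output of [find_contacts()].
#' @param hbonds Output of [find_hbonds()].
#' @return Tibble with `chain_id`, `residue_number`, `residue_name`,
#'   `residue`, `n_nonbonded`, `n_hbonds` and a list-column `hbond_lengths`
#'   (A), ordered by residue number.
#' @export
per_residue_counts <- function(contacts, hbonds = NULL) {
  keys <- c("chain_id", "residue_number", "residue_name")
  empty <- tibble::tibble(
    chain_id = character(), residue_number = integer(),
    residue_name = character()
  )
  cn <- if (is.null(contacts) || nrow(contacts) == 0L) empty else
    dplyr::count(contacts, dplyr::across(dplyr::all_of(keys)),
                 name = "n_nonbonded")
  hb <- if (is.null(hbonds) || nrow(hbonds) == 0L) {
    dplyr::mutate(empty, n_hbonds = integer(),
                  hbond_lengths = list())
  } else {
    hbonds |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(n_hbonds = dplyr::n(),
                       hbond_lengths = list(round(.data$distance, 2)),
                       .groups = "drop")
  }
  out <- dplyr::full_join(cn, hb, by = keys)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      chain_id = character(), residue_number = integer(),
      residue_name = character(), residue = character(),
      n_nonbonded = integer(), n_hbonds = integer(), hbond_lengths = list()
    ))
  }
  out |>
    dplyr::mutate(
      n_nonbonded = dplyr::coalesce(.data$n_nonbonded, 0L),
      n_hbonds = dplyr::coalesce(.data$n_hbonds, 0L),
      hbond_lengths = purrr::map(.data$hbond_lengths,
                                 \(x) x %||% numeric()),
      residue = residue_label(.data$residue_name, .data$residue_number)
    ) |>
    dplyr::arrange(.data$chain_id, .data$residue_number) |>
    dplyr::relocate("residue", .after = "residue_name")
}
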