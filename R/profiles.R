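#' Merge interaction counts and buried-area losses into a binding profile
#'
#' Outer-joins per-residue interaction records and a buried-area map on the
#' residue key, the way published per-residue tables combine the contact
#' listing with the surface-area run; residues present in only one input get
#' zero for the missing quantity.
#'
#' @param records Per-residue counts from [per_residue_counts()] (may be
#'   `NULL`/empty).
#' @param dasa_map A [delta_asa()] map, or any tibble with the residue key
#'   columns and `delta_asa` (may be `NULL`/empty).
#' @param ligand_id,target_id Identifiers stored on the profile.
#' @return A tibble of class `binding_profile` with `residue`,
#'   `residue_name`, `residue_number`, `chain_id`, `n_nonbonded`, `n_hbonds`,
#'   `delta_asa`, ordered by residue number.
#' @export
build_profile <- function(records, dasa_map, ligand_id = "", target_id = "") {
  keys <- c("chain_id", "residue_number", "residue_name")
  blank <- tibble::tibble(
    chain_id = character(), residue_number = integer(),
    residue_name = character()
  )
  r <- if (is.null(records) || nrow(records) == 0L) {
    dplyr::mutate(blank, n_nonbonded = integer(), n_hbonds = integer())
  } else {
    dplyr::select(tibble::as_tibble(records), dplyr::all_of(keys),
                  "n_nonbonded", "n_hbonds")
  }
  d <- if (is.null(dasa_map) || nrow(dasa_map) == 0L) {
    dplyr::mutate(blank, delta_asa = numeric())
  } else {
    dplyr::select(tibble::as_tibble(dasa_map), dplyr::all_of(keys),
                  "delta_asa")
  }
  out <- dplyr::full_join(r, d, by = keys) |>
    dplyr::mutate(
      n_nonbonded = dplyr::coalesce(.data$n_nonbonded, 0L),
      n_hbonds = dplyr::coalesce(.data$n_hbonds, 0L),
      delta_asa = dplyr::coalesce(.data$delta_asa, 0)
    ) |>
    dplyr::arrange(.data$chain_id, .data$residue_number)
  if (nrow(out) > 0L) {
    out$residue <- residue_label(out$residue_name, out$residue_number)
    out <- dplyr::relocate(out, "residue")
  } else {
    out$residue <- character()
  }
  new_binding_profile(out, ligand_id, target_id)
}

#' @noRd
new_binding_profile <- function(df, ligand_id, target_id) {
  if (anyDuplicated(df[, c("chain_id", "residue_number", "residue_name")])) {
    stop("duplicate residue keys in binding profile", call. = FALSE)
  }
  attr(df, "ligand_id") <- ligand_id
  attr(df, "target_id") <- target_id
  class(df) <- unique(c("binding_profile", class(tibble::as_tibble(df))))
  df
}

#' Build a binding profile from a published-style residue table
#'
#' Convenience constructor for tables shaped like the per-residue listings of
#' interaction papers: residue labels such as `"Lys-890"` plus counts and/or
#' buried areas.
#'
#' @param df Tibble with a `residue` label column and optionally
#'   `n_nonbonded`, `n_hbonds`, `delta_asa`.
#' @param ligand_id,target_id Identifiers stored on the profile.
#' @param chain_id Chain assigned to all rows (labels carry none).
#' @return A `binding_profile` tibble.
#' @export
as_binding_profile <- function(df, ligand_id = "", target_id = "",
                               chain_id = "A") {
  parsed <- parse_residue_label(df$residue)
  out <- tibble::tibble(
    residue = df$residue,
    chain_id = chain_id,
    residue_number = parsed$residue_number,
    residue_name = parsed$residue_name,
    n_nonbonded = as.integer(df[["n_nonbonded"]] %||% rep(0L, nrow(df))),
    n_hbonds = as.integer(df[["n_hbonds"]] %||% rep(0L, nrow(df))),
    delta_asa = as.numeric(df[["delta_asa"]] %||% rep(0, nrow(df)))
  ) |>
    dplyr::arrange(.data$residue_number)
  new_binding_profile(out, ligand_id, target_id)
}

#' Key residues of a binding profile
#'
#' Reports the residue(s) with maximal buried surface area and, separately,
#' the residue(s) with the most non-bonded interactions; all ties are
#' reported. These are the two criteria by which a binding study singles out
#' its key residues.
#'
#' @param p A `binding_profile`.
#' @return A list of class `key_residue_report` with tibbles `max_dasa` and
#'   `max_contacts` (columns `residue`, value).
#' @export
key_residues <- function(p) {
  if (nrow(p) == 0L) stop("empty binding profile", call. = FALSE)
  md <- p[p$delta_asa == max(p$delta_asa),
          c("residue", "delta_asa")]
  mc <- p[p$n_nonbonded == max(p$n_nonbonded),
          c("residue", "n_nonbonded")]
  structure(
    list(max_dasa = tibble::as_tibble(md),
         max_contacts = tibble::as_tibble(mc),
         ligand_id = attr(p, "ligand_id"), target_id = attr(p, "target_id")),
    class = "key_residue_report"
  )
}

#' @export
print.key_residue_report <- function(x, ...) {
  cat("Key residues",
      if (nzchar(x$ligand_id %||% "")) paste0(" for ", x$ligand_id), ":\n",
      sep = "")
  cat("  max buried area: ",
      paste0(x$max_dasa$residue, " (", round(x$max_dasa$delta_asa, 2),
             " A^2)", collapse = ", "), "\n", sep = "")
  cat("  max non-bonded contacts: ",
      paste0(x$max_contacts$residue, " (", x$max_contacts$n_nonbonded, ")",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy key_residue_report
#' @export
tidy.key_residue_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(criterion = "max_delta_asa", residue = x$max_dasa$residue,
                   value = x$max_dasa$delta_asa),
    tibble::tibble(criterion = "max_contacts",
                   residue = x$max_contacts$residue,
                   value = as.numeric(x$max_contacts$n_nonbonded))
  )
}

# interacting = takes part in >=1 contact or H-bond (membership criterion of
# comparative residue tables; looser than the buried-area rule)
#' @noRd
interacting_set <- function(p) {
  dplyr::filter(tibble::as_tibble(p),
                .data$n_nonbonded >= 1L | .data$n_hbonds >= 1L)
}

#' Interacting residues common to two ligands of the same target
#'
#' Intersects the interacting-residue sets (residues with at least one
#' contact or hydrogen bond) of two binding profiles, ordered by residue
#' number. Symmetric in its arguments.
#'
#' @param p1,p2 `binding_profile` objects for the same target.
#' @param check_target Error if the profiles' `target_id`s differ? Default
#'   `TRUE` (skipped when either is empty).
#' @return Tibble of the common residues (`residue`, `residue_number`).
#' @export
common_residues <- function(p1, p2, check_target = TRUE) {
  t1 <- attr(p1, "target_id") %||% ""
  t2 <- attr(p2, "target_id") %||% ""
  if (check_target && nzchar(t1) && nzchar(t2) && !identical(t1, t2)) {
    stop("profiles are for different targets: '", t1, "' vs '", t2, "'",
         call. = FALSE)
  }
  a <- interacting_set(p1)
  b <- interacting_set(p2)
  joined <- dplyr::inner_join(
    a[, c("residue", "residue_number", "residue_name")],
    b[, c("residue", "residue_number", "residue_name")],
    by = c("residue", "residue_number", "residue_name")
  ) |>
    dplyr::arrange(.data$residue_number)
  tibble::tibble(residue = joined$residue,
                 residue_number = joined$residue_number,
                 residue_name = joined$residue_name)
}

#' @method tidy binding_profile
#' @export
tidy.binding_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance binding_profile
#' @export
glance.binding_profile <- function(x, ...) {
  tibble::tibble(
    ligand_id = attr(x, "ligand_id") %||% "",
    target_id = attr(x, "target_id") %||% "",
    n_residues = nrow(x),
    total_nonbonded = sum(x$n_nonbonded),
    total_hbonds = sum(x$n_hbonds),
    total_delta_asa = sum(x$delta_asa)
  )
}

#' Plot a binding profile
#'
#' Bars of buried surface area per residue, coloured by the number of
#' non-bonded interactions, with the participation threshold drawn as a
#' dashed line.
#'
#' @param object A `binding_profile`.
#' @param threshold Buried-area rule threshold (A^2), drawn as a reference
#'   line. Default 10.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot binding_profile
#' @export
autoplot.binding_profile <- function(object, threshold = 10, ...) {
  df <- tibble::as_tibble(object)
  df$residue <- factor(df$residue,
                       levels = df$residue[order(df$residue_number)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$delta_asa,
                                   fill = .data$n_nonbonded)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = expression(Delta * ASA ~ (ring(A)^2)),
      fill = "Non-bonded\ninteractions",
      title = attr(object, "ligand_id") %||% NULL,
      subtitle = attr(object, "target_id") %||% NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
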