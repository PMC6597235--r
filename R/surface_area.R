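#' Parameters for accessible-surface-area calculations
#'
#' @param probe_radius Solvent probe radius in Angstrom (water, 1.4 A).
#' @param n_sphere_points Number of test points per atom sphere. Points are
#'   placed on a deterministic generalized-spiral (golden-angle) lattice, so
#'   results are exactly reproducible; 960 points gives accuracy comparable to
#'   classic surface programs.
#' @return A list of class `asa_params`.
#' @export
asa_params <- function(probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 12)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "asa_params")
}

# Deterministic golden-angle spiral lattice on the unit sphere.
#' @noRd
sphere_lattice <- function(n) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley accessible surface area per atom
#'
#' For each atom, `n_sphere_points` test points are placed on a sphere of
#' radius `vdw_radius + probe_radius`; a point is solvent-accessible if it
#' lies outside the expanded sphere of every other atom. The atom's ASA is
#' the accessible fraction times the full expanded-sphere area.
#'
#' @param s A structure tibble with radii assigned (see [assign_radii()]).
#' @param params An [asa_params()] object.
#' @return A tibble: one row per atom with the structure's identity columns
#'   plus `asa` (Angstrom^2).
#' @export
#' @examples
#' one <- tibble::tibble(
#'   serial = 1L, atom_name = "C1", element = "C", residue_name = "LIG",
#'   chain_id = "A", residue_number = 1L, x = 0, y = 0, z = 0,
#'   vdw_radius = 1.9
#' )
#' shrake_rupley(one, asa_params())$asa # ~ 4*pi*(1.9+1.4)^2
shrake_rupley <- function(s, params = asa_params()) {
  if (any(is.na(s$vdw_radius))) {
    stop("radii not assigned; call assign_radii() first", call. = FALSE)
  }
  n <- nrow(s)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rext <- s$vdw_radius + params$probe_radius
  pts <- sphere_lattice(params$n_sphere_points)

  asa <- numeric(n)
  # neighbour lists from one distance matrix; systems here are pocket-sized
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (rext[i] + rext)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    test <- sweep(pts * rext[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(test))
    for (j in nb) {
      if (!any(exposed)) break
      dx <- test[, 1] - xyz[j, 1]
      dy <- test[, 2] - xyz[j, 2]
      dz <- test[, 3] - xyz[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz > rext[j]^2)
    }
    asa[i] <- mean(exposed) * 4 * pi * rext[i]^2
  }
  out <- dplyr::select(
    tibble::as_tibble(s),
    "serial", "atom_name", "element", "residue_name", "chain_id",
    "residue_number"
  )
  out$asa <- asa
  out
}

#' Aggregate per-atom ASA to per-residue ASA
#'
#' @param atom_asa Output of [shrake_rupley()].
#' @return Tibble with `chain_id`, `residue_number`, `residue_name`,
#'   `residue` (label) and `asa`, summed over member atoms; the residue total
#'   equals the atom total.
#' @export
residue_asa <- function(atom_asa) {
  atom_asa |>
    dplyr::group_by(.data$chain_id, .data$residue_number, .data$residue_name) |>
    dplyr::summarise(asa = sum(.data$asa), .groups = "drop") |>
    dplyr::mutate(residue = residue_label(.data$residue_name,
                                          .data$residue_number)) |>
    dplyr::arrange(.data$chain_id, .data$residue_number)
}

#' Per-residue loss of accessible surface area on ligand binding
#'
#' Computes, for every protein residue, `delta_asa = ASA(free) -
#' ASA(in complex)`. The free state is the protein alone; in the bound state
#' the ligand atoms act purely as additional occluders, so with identical
#' point lattices every residue's loss is non-negative. The protein
#' conformation is the as-docked one for both states (rigid assumption).
#'
#' @param free Protein structure in the unbound state. Pass `pair$protein`
#'   for the standard rigid workflow.
#' @param pair A [split_complex()] result for the bound state.
#' @param params An [asa_params()] object.
#' @param threshold Buried-area cutoff (A^2) carried to
#'   [classify_interacting()]; a residue participates in binding when it
#'   loses strictly more than this. Default 10.
#' @return A tibble of class `delta_asa_map`: `chain_id`, `residue_number`,
#'   `residue_name`, `residue`, `asa_free`, `asa_bound`, `delta_asa`.
#' @export
delta_asa <- function(free, pair, params = asa_params(), threshold = 10) {
  key <- function(df) paste(df$chain_id, df$residue_number, df$residue_name)
  free_keys <- unique(key(free))
  prot_keys <- unique(key(pair$protein))
  if (!identical(sort(free_keys), sort(prot_keys))) {
    stop("residue keys of the free protein do not match the complexed protein",
         call. = FALSE)
  }
  asa_f <- residue_asa(shrake_rupley(free, params))
  bound_atoms <- shrake_rupley(pair$complex, params)
  # keep only protein atoms when summing the bound state
  lig_serials <- pair$ligand$serial
  asa_b <- residue_asa(dplyr::filter(bound_atoms,
                                     !.data$serial %in% lig_serials))
  out <- dplyr::inner_join(
    dplyr::rename(asa_f, asa_free = "asa"),
    dplyr::select(dplyr::rename(asa_b, asa_bound = "asa"),
                  -"residue"),
    by = c("chain_id", "residue_number", "residue_name")
  ) |>
    dplyr::mutate(delta_asa = .data$asa_free - .data$asa_bound) |>
    dplyr::arrange(.data$chain_id, .data$residue_number)
  attr(out, "threshold") <- threshold
  class(out) <- unique(c("delta_asa_map", class(out)))
  out
}

#' Residues taking part in binding by the buried-area rule
#'
#' A residue participates in ligand binding when it loses strictly more than
#' `threshold` Angstrom^2 of accessible surface area on binding (default
#' 10 A^2, strict ">").
#'
#' @param d A `delta_asa_map` from [delta_asa()], or any tibble with columns
#'   `residue` and `delta_asa`.
#' @param threshold Buried-area cutoff in A^2; defaults to the map's own
#'   threshold attribute, else 10.
#' @return Tibble of the passing residues sorted by `delta_asa` descending.
#' @export
classify_interacting <- function(d, threshold = NULL) {
  threshold <- threshold %||% attr(d, "threshold") %||% 10
  d |>
    tibble::as_tibble() |>
    dplyr::filter(.data$delta_asa > threshold) |>
    dplyr::arrange(dplyr::desc(.data$delta_asa))
}
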