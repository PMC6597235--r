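#' Specification for a synthetic binding pocket
#'
#' Describes a toy protein-ligand complex with exactly planted geometric
#' features, standing in for docked poses. Residues are small alanine-like
#' heavy-atom templates (serine-like where a hydroxyl is needed as hydrogen
#' bond partner) spaced widely on a ring so that the only protein-ligand
#' atom pairs inside any detection window are the planted ones; the
#' generator verifies this and refuses unsatisfiable specs.
#'
#' @param n_residues Number of protein residues (default 6).
#' @param planted_contacts Tibble with `residue_number`, `count`, `distance`
#'   (A, within the 2.9-3.9 contact window): non-bonded contacts to plant as
#'   ligand carbon atoms near that residue's CB.
#' @param planted_hbonds Tibble with `residue_number`, `ligand_element`
#'   ("N" or "O"), `distance` (A, at most 3.35): hydrogen bonds to plant
#'   against a serine-like OG oxygen.
#' @param planted_burial Integer vector of residue numbers to bury under a
#'   cap of sub-contact-range (2.6 A) carbon occluders, guaranteeing a
#'   buried-area loss well above the 10 A^2 participation rule without
#'   registering any contact.
#' @param seed Stored on the spec; generation itself is fully deterministic.
#' @return A list of class `pocket_spec`.
#' @export
pocket_spec <- function(n_residues = 6, planted_contacts = NULL,
                        planted_hbonds = NULL, planted_burial = integer(),
                        seed = 1L) {
  pc <- planted_contacts %||%
    tibble::tibble(residue_number = integer(), count = integer(),
                   distance = numeric())
  ph <- planted_hbonds %||%
    tibble::tibble(residue_number = integer(), ligand_element = character(),
                   distance = numeric())
  stopifnot(n_residues >= 1,
            all(pc$residue_number %in% seq_len(n_residues)),
            all(ph$residue_number %in% seq_len(n_residues)),
            all(planted_burial %in% seq_len(n_residues)),
            all(pc$distance >= 2.9 & pc$distance <= 3.9),
            all(pc$count >= 1),
            all(ph$distance > 0 & ph$distance <= 3.35),
            all(ph$ligand_element %in% c("N", "O")))
  if (length(intersect(pc$residue_number, ph$residue_number)) > 0) {
    stop("unsatisfiable spec: a residue cannot carry both planted contacts ",
         "and planted hydrogen bonds", call. = FALSE)
  }
  structure(list(n_residues = as.integer(n_residues), planted_contacts = pc,
                 planted_hbonds = ph,
                 planted_burial = as.integer(planted_burial),
                 seed = as.integer(seed)),
            class = "pocket_spec")
}

# rotate the local +x axis onto the in-plane direction at angle theta
#' @noRd
rot_xy <- function(local, theta) {
  cbind(local[, 1] * cos(theta) - local[, 2] * sin(theta),
        local[, 1] * sin(theta) + local[, 2] * cos(theta),
        local[, 3])
}

# unit vector in a cone of half-angle alpha around in-plane direction theta,
# azimuth phi about that axis
#' @noRd
cone_dir <- function(theta, alpha, phi) {
  u <- c(cos(theta), sin(theta), 0)   # axis
  t <- c(-sin(theta), cos(theta), 0)  # in-plane perpendicular
  zz <- c(0, 0, 1)
  u * cos(alpha) + (t * sin(phi) + zz * cos(phi)) * sin(alpha)
}

GOLDEN <- pi * (3 - sqrt(5))

#' Generate a toy pocket complex with a ground-truth ledger
#'
#' Builds the protein and ligand described by a [pocket_spec()], returning
#' the complex as a `complex_pair` (radii already assigned) together with a
#' ledger listing every planted feature. The construction is deterministic:
#' the same spec always yields byte-identical structures. After placement
#' the generator audits every protein-ligand atom pair and errors if any
#' non-planted pair falls inside (or near) a detection window.
#'
#' @param spec A [pocket_spec()].
#' @return A list of class `pocket_complex` with elements `pair`
#'   (`complex_pair`), `ledger` (tibble: `feature`, `residue_number`,
#'   `residue`, `count`, `distance`, `ligand_element`) and `spec`.
#' @export
#' @examples
#' spec <- pocket_spec(
#'   n_residues = 4,
#'   planted_contacts = tibble::tibble(residue_number = 2, count = 3,
#'                                     distance = 3.5)
#' )
#' pocket <- make_pocket_complex(spec)
#' pocket$ledger
make_pocket_complex <- function(spec) {
  stopifnot(inherits(spec, "pocket_spec"))
  n <- spec$n_residues
  ring_r <- max(12, 7.5 / sin(pi / max(n, 2)))
  thetas <- 2 * pi * (seq_len(n) - 1) / n
  hb_res <- unique(spec$planted_hbonds$residue_number)

  # alanine-like heavy-atom template, +x pointing radially outward
  ala <- rbind(
    N = c(-1.45, 0.90, 0), CA = c(0, 0, 0), C = c(-0.90, -1.20, 0),
    O = c(-1.95, -1.80, 0), CB = c(1.53, 0, 0)
  )
  ser <- rbind(ala, OG = c(2.25, 1.25, 0))

  prot <- purrr::map_dfr(seq_len(n), function(i) {
    tmpl <- if (i %in% hb_res) ser else ala
    xyz <- rot_xy(tmpl, thetas[i])
    ctr <- ring_r * c(cos(thetas[i]), sin(thetas[i]), 0)
    tibble::tibble(
      atom_name = rownames(tmpl),
      element = substr(rownames(tmpl), 1, 1),
      residue_name = if (i %in% hb_res) "SER" else "ALA",
      chain_id = "A", residue_number = i,
      x = unname(xyz[, 1] + ctr[1]), y = unname(xyz[, 2] + ctr[2]),
      z = unname(xyz[, 3] + ctr[3]), record = "ATOM"
    )
  })
  prot$serial <- seq_len(nrow(prot))

  prot_at <- function(i, nm) {
    row <- prot[prot$residue_number == i & prot$atom_name == nm, ]
    c(row$x, row$y, row$z)
  }

  lig <- list()
  ledger <- list()
  add_lig <- function(el, pos) {
    lig[[length(lig) + 1]] <<- tibble::tibble(
      element = el, x = pos[1], y = pos[2], z = pos[3])
  }

  for (r in seq_len(nrow(spec$planted_contacts))) {
    pc <- spec$planted_contacts[r, ]
    cb <- prot_at(pc$residue_number, "CB")
    for (m in seq_len(pc$count)) {
      alpha <- if (m == 1) 0 else 20 * pi / 180
      v <- cone_dir(thetas[pc$residue_number], alpha, m * GOLDEN)
      add_lig("C", cb + pc$distance * v)
    }
    ledger[[length(ledger) + 1]] <- tibble::tibble(
      feature = "contact", residue_number = pc$residue_number,
      count = pc$count, distance = pc$distance, ligand_element = "C")
  }

  for (r in seq_len(nrow(spec$planted_hbonds))) {
    ph <- spec$planted_hbonds[r, ]
    og <- prot_at(ph$residue_number, "OG")
    ca <- prot_at(ph$residue_number, "CA")
    v <- (og - ca) / sqrt(sum((og - ca)^2))
    add_lig(ph$ligand_element, og + ph$distance * v)
    ledger[[length(ledger) + 1]] <- tibble::tibble(
      feature = "hbond", residue_number = ph$residue_number, count = 1L,
      distance = ph$distance, ligand_element = ph$ligand_element)
  }

  for (i in spec$planted_burial) {
    cb <- prot_at(i, "CB")
    for (m in 1:6) {
      v <- cone_dir(thetas[i], 25 * pi / 180 * (m %% 3 + 1) / 3, m * GOLDEN)
      add_lig("C", cb + 2.6 * v)
    }
    ledger[[length(ledger) + 1]] <- tibble::tibble(
      feature = "burial", residue_number = i, count = 6L, distance = 2.6,
      ligand_element = "C")
  }

  if (length(lig) == 0L) {
    stop("empty spec: nothing planted, no ligand to build", call. = FALSE)
  }
  lig <- dplyr::bind_rows(lig)
  lig <- tibble::tibble(
    serial = nrow(prot) + seq_len(nrow(lig)),
    atom_name = paste0(lig$element, seq_len(nrow(lig))),
    element = lig$element, residue_name = "LIG", chain_id = "L",
    residue_number = 1L, x = round(lig$x, 3), y = round(lig$y, 3),
    z = round(lig$z, 3), record = "HETATM"
  )
  prot <- dplyr::mutate(prot, x = round(.data$x, 3), y = round(.data$y, 3),
                        z = round(.data$z, 3))
  prot <- prot[, names(lig)]

  complex <- as_structure(dplyr::bind_rows(prot, lig),
                          source_id = paste0("synthetic-pocket-", spec$seed))
  complex$vdw_radius <- NA_real_
  pair <- split_complex(assign_radii(complex), "LIG")

  audit_pocket(pair, spec)

  ledger <- dplyr::bind_rows(ledger)
  ledger$residue <- residue_label(
    ifelse(ledger$residue_number %in% hb_res, "SER", "ALA"),
    ledger$residue_number)
  structure(list(pair = pair, ledger = ledger, spec = spec),
            class = "pocket_complex")
}

# every cross pair must be a planted feature or safely outside all windows
#' @noRd
audit_pocket <- function(pair, spec) {
  cp <- cross_pairs(pair)
  planted_contact <- cp$distance >= 2.9 & cp$distance <= 3.9 &
    cp$protein_atom == "CB" & cp$ligand_element == "C"
  planted_hbond <- cp$distance <= 3.35 & cp$protein_atom == "OG" &
    cp$ligand_element %in% c("N", "O")
  occluder <- cp$distance < 2.85 & cp$ligand_element == "C" &
    cp$protein_atom == "CB"
  safe <- cp$distance > 3.95
  bad <- !(planted_contact | planted_hbond | occluder | safe)
  if (any(bad)) {
    stop("unsatisfiable pocket spec: ", sum(bad), " unplanned atom pair(s) ",
         "fall inside a detection window (clash)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Specification for a synthetic virtual screen
#'
#' Decoy scores are drawn from Normal(`base_score`, `noise_sd`) and active
#' scores from Normal(`base_score + score_shift`, `noise_sd`); a negative
#' shift makes actives score better (more negative). Only rank order matters
#' to enrichment statistics, so the Gaussian choice is a convenience. The
#' default layout is the classic decoy protocol: 100 decoys per active, six
#' actives.
#'
#' @param n_actives Number of planted active compounds (default 6).
#' @param decoys_per_active Decoys generated per active (default 100).
#' @param score_shift Mean score shift of actives, score units (default -5).
#' @param noise_sd Score noise standard deviation (default 2).
#' @param base_score Decoy mean score (default -35, a typical grid-score
#'   magnitude).
#' @param targets Character vector of target ids to score (default
#'   `"target1"`).
#' @param seed RNG seed; the same spec always yields the same table.
#' @return A list of class `screen_spec`.
#' @export
screen_spec <- function(n_actives = 6, decoys_per_active = 100,
                        score_shift = -5, noise_sd = 2, base_score = -35,
                        targets = "target1", seed = 1L) {
  stopifnot(n_actives >= 1, decoys_per_active >= 1, noise_sd >= 0)
  structure(list(n_actives = as.integer(n_actives),
                 decoys_per_active = as.integer(decoys_per_active),
                 n_decoys = as.integer(n_actives * decoys_per_active),
                 score_shift = score_shift, noise_sd = noise_sd,
                 base_score = base_score, targets = targets,
                 seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a synthetic dock-score table with planted actives
#'
#' @param spec A [screen_spec()].
#' @return A list with `scores` (tibble `compound_id`, `target_id`,
#'   `dock_score`) and `labels` (tibble `compound_id`, `class` in
#'   {"active","decoy"}), both seeded and reproducible.
#' @export
make_score_table <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  ids <- c(sprintf("ACT%03d", seq_len(spec$n_actives)),
           sprintf("DEC%04d", seq_len(spec$n_decoys)))
  cls <- c(rep("active", spec$n_actives), rep("decoy", spec$n_decoys))
  mu <- ifelse(cls == "active", spec$base_score + spec$score_shift,
               spec$base_score)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  scores <- purrr::map_dfr(spec$targets, \(tg) tibble::tibble(
    compound_id = ids, target_id = tg,
    dock_score = rnorm(length(ids), mean = mu, sd = spec$noise_sd)
  ))
  list(scores = scores,
       labels = tibble::tibble(compound_id = ids, class = cls))
}

# curated fragment lists for synthetic substituent sets; splice-ready SMILES
# (ring digit 9 only, so they never collide with scaffold ring numbering)
.dp_curated_r1 <- c(
  "C", "OC", "N", "C(F)(F)F", "c9ccccc9", "c9ccncc9", "N9CCOCC9",
  "C(=O)N", "S(=O)(=O)C", "Cl", "C#N", "CC"
)
.dp_curated_r2 <- c("OC", "O", "N", "F", "Br", "C", "Cl", "C#N")

#' Draw synthetic substituent sets from the curated fragment lists
#'
#' Emulates the 9 + 5 substituent configuration at arbitrary sizes by
#' drawing (seeded, without replacement) from small curated lists of valid
#' splice-ready fragments.
#'
#' @param n_r1,n_r2 Set sizes (defaults 9 and 5). Must not exceed the
#'   curated list lengths (12 and 8).
#' @param seed RNG seed.
#' @return A list with [substituent_set()] elements `r1` and `r2`.
#' @export
make_substituent_sets <- function(n_r1 = 9, n_r2 = 5, seed = 1L) {
  if (n_r1 > length(.dp_curated_r1) || n_r2 > length(.dp_curated_r2)) {
    stop("requested substituent set exceeds the curated list (max ",
         length(.dp_curated_r1), " R1, ", length(.dp_curated_r2), " R2)",
         call. = FALSE)
  }
  stopifnot(n_r1 >= 1, n_r2 >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  list(
    r1 = substituent_set("R1", sample(.dp_curated_r1, n_r1)),
    r2 = substituent_set("R2", sample(.dp_curated_r2, n_r2))
  )
}
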