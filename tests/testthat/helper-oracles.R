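# Independent oracles and small builders used across the suite.

# Build an atom tibble directly (radii already set), bypassing PDB I/O.
atoms_tbl <- function(element, x, y, z, residue_number = 1L,
                      residue_name = "ALA", chain_id = "A", serial_from = 1L,
                      radius_set = chothia_radii(), default_r = 1.80) {
  n <- length(x)
  el <- rep_len(element, n)
  r <- unname(radius_set[el])
  r[is.na(r)] <- default_r
  tibble::tibble(
    serial = serial_from + seq_len(n) - 1L,
    atom_name = paste0(el, seq_len(n)),
    element = el,
    residue_name = rep_len(residue_name, n),
    chain_id = rep_len(chain_id, n),
    residue_number = as.integer(rep_len(residue_number, n)),
    x = x, y = y, z = z,
    record = "ATOM",
    vdw_radius = r
  )
}

# Assemble a complex_pair from two atom tibbles without touching disk.
make_pair <- function(protein, ligand) {
  ligand$serial <- max(protein$serial) + seq_len(nrow(ligand))
  structure(list(protein = protein, ligand = ligand,
                 complex = dplyr::bind_rows(protein, ligand)),
            class = "complex_pair")
}

# Monte-Carlo per-atom accessible-surface oracle: random directions, not a
# lattice, so it is independent of the implementation under test.
mc_asa <- function(s, probe = 1.4, n_samples = 1e5, seed = 1) {
  set.seed(seed)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rext <- s$vdw_radius + probe
  vapply(seq_len(nrow(s)), function(i) {
    dirs <- matrix(rnorm(3 * n_samples), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- sweep(dirs * rext[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_samples)
    for (j in seq_len(nrow(s))[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > rext[j]^2
    }
    mean(exposed) * 4 * pi * rext[i]^2
  }, numeric(1))
}

# Exhaustive O(n^2) scan over every protein x ligand atom pair with plain
# loops; returns serial pairs within [dmin, dmax], optionally restricted to
# H-bond-capable elements on both sides.
oracle_pairs <- function(pair, dmin, dmax, capable_only = FALSE,
                         capable = c("N", "O", "S")) {
  p <- pair$protein
  l <- pair$ligand
  hits <- list()
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(l))) {
      d <- sqrt((p$x[i] - l$x[j])^2 + (p$y[i] - l$y[j])^2 +
                  (p$z[i] - l$z[j])^2)
      if (d >= dmin && d <= dmax) {
        if (capable_only &&
            !(p$element[i] %in% capable && l$element[j] %in% capable)) next
        hits[[length(hits) + 1]] <- c(p$serial[i], l$serial[j])
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(protein_serial = integer(),
                          ligand_serial = integer()))
  }
  m <- do.call(rbind, hits)
  dplyr::arrange(tibble::tibble(protein_serial = m[, 1],
                                ligand_serial = m[, 2]),
                 protein_serial, ligand_serial)
}

# sorted (protein, ligand) serial pairs of a detection result
serial_pairs <- function(df) {
  if (nrow(df) == 0) {
    return(tibble::tibble(protein_serial = integer(),
                          ligand_serial = integer()))
  }
  dplyr::arrange(df[, c("protein_serial", "ligand_serial")],
                 protein_serial, ligand_serial)
}

# a small pocket spec family, parameterised by seed, used in property tests
random_pocket_spec <- function(seed) {
  set.seed(seed)
  n <- sample(3:7, 1)
  n_contact_res <- sample.int(n - 1, 1)
  contact_res <- sort(sample.int(n, n_contact_res))
  hb_pool <- setdiff(seq_len(n), contact_res)
  hb_res <- if (length(hb_pool) > 0 && runif(1) < 0.7) {
    hb_pool[sample.int(length(hb_pool),
                       min(length(hb_pool), sample.int(2, 1)))]
  } else {
    integer()
  }
  pocket_spec(
    n_residues = n,
    planted_contacts = tibble::tibble(
      residue_number = contact_res,
      count = sample(1:4, n_contact_res, replace = TRUE),
      distance = round(runif(n_contact_res, 2.95, 3.85), 2)
    ),
    planted_hbonds = if (length(hb_res) > 0) {
      tibble::tibble(
        residue_number = hb_res,
        ligand_element = sample(c("N", "O"), length(hb_res), replace = TRUE),
        distance = round(runif(length(hb_res), 2.6, 3.3), 2)
      )
    } else {
      NULL
    },
    seed = seed
  )
}
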