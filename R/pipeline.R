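# expected md5 checksums of the packaged fixture tables
.dp_fixture_md5 <- c(
  binding_strengths.tsv           = "8da884a6c885ce0a4f4a074bdd9bd50e",
  dual_dock_scores_synthetic.tsv  = "1bf05552bf8a0a7c2b434787777d0a56",
  mtor_residue_membership.tsv     = "60f1ad4178f9d5e6bf26f4155909006e",
  pi3k_residue_membership.tsv     = "1a201e9d2f50452cc51b2a752d626864",
  rule_of_five_reference.tsv      = "b07a506effe9732a415e3c0abdf27c06",
  xl765_mtor_profile.tsv          = "3f93271129cb7758b2794428cd5e13fe",
  xl765_pi3k_profile.tsv          = "08c754f34a29c2fb1b20a76aa22edfbd"
)

#' Load the packaged reference tables
#'
#' Reads the machine-readable reference tables for the XL765 dual-target
#' study conditions: the two per-residue binding profiles, the
#' binding-strength table, the rule-of-five descriptor table, the two
#' comparative residue-membership matrices, and the 45-compound dual-target
#' dock-score table (a synthetic stand-in: the six proposed compounds carry
#' their reference scores and per-target ranks, the filler compounds are
#' synthetic — see the file header). Each file's md5 checksum and row count
#' is validated before use.
#'
#' @return A named list of tibbles: `pi3k_profile` (10 residues),
#'   `mtor_profile` (11 residues), `binding_strengths`, `rule_of_five`,
#'   `pi3k_membership`, `mtor_membership`, `dock_scores` (45 compounds,
#'   wide) and `dock_scores_long` (compound x target).
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "dualprofiler")
  read1 <- function(file) {
    path <- file.path(dir, file)
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.dp_fixture_md5[[file]]))) {
      stop("fixture integrity error: checksum mismatch for ", file,
           call. = FALSE)
    }
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  }
  fx <- list(
    pi3k_profile = read1("xl765_pi3k_profile.tsv"),
    mtor_profile = read1("xl765_mtor_profile.tsv"),
    binding_strengths = read1("binding_strengths.tsv"),
    rule_of_five = read1("rule_of_five_reference.tsv"),
    pi3k_membership = read1("pi3k_residue_membership.tsv"),
    mtor_membership = read1("mtor_residue_membership.tsv"),
    dock_scores = read1("dual_dock_scores_synthetic.tsv")
  )
  stopifnot(nrow(fx$pi3k_profile) == 10L, nrow(fx$mtor_profile) == 11L,
            nrow(fx$dock_scores) == 45L, nrow(fx$rule_of_five) == 7L,
            nrow(fx$binding_strengths) == 16L)
  fx$dock_scores_long <- fx$dock_scores |>
    tidyr::pivot_longer(dplyr::starts_with("dock_score_"),
                        names_to = "target_id", names_prefix = "dock_score_",
                        values_to = "dock_score") |>
    dplyr::mutate(
      target_id = dplyr::recode(.data$target_id, pi3k = "PI3Kgamma",
                                mtor = "mTOR"),
      compound_id = as.character(.data$compound), .keep = "unused"
    ) |>
    dplyr::relocate("compound_id")
  fx
}

#' Turn a residue-membership matrix column into a binding profile
#'
#' Comparative residue tables mark, per compound column, which residues
#' interact. This helper lifts one column into a minimal
#' [as_binding_profile()] object (membership recorded as one non-bonded
#' interaction) so set operations like [common_residues()] apply.
#'
#' @param membership Tibble with a `residue` column plus one 0/1 column per
#'   compound.
#' @param compound Name of the column to extract.
#' @param target_id Target identifier for the profile.
#' @return A `binding_profile`.
#' @export
profile_from_membership <- function(membership, compound, target_id = "") {
  stopifnot(compound %in% names(membership))
  rows <- membership[membership[[compound]] == 1, "residue"]
  as_binding_profile(
    tibble::tibble(residue = rows$residue, n_nonbonded = 1L),
    ligand_id = compound, target_id = target_id
  )
}

#' Configuration for a full pipeline run
#'
#' @param output_dir Directory for the report bundle (created if missing).
#' @param complexes Optional tibble/data.frame with columns `path` (PDB
#'   file), `ligand` (selector for [split_complex()]), `ligand_id`,
#'   `target_id`: docked complexes to profile geometrically. `NULL` runs the
#'   geometry stage on a seeded synthetic pocket instead.
#' @param score_table Optional long score tibble (`compound_id`,
#'   `target_id`, `dock_score`); defaults to the packaged synthetic
#'   45-compound table.
#' @param asa An [asa_params()] object.
#' @param contacts A [contact_params()] object.
#' @param dasa_threshold Buried-area participation rule (A^2), default 10.
#' @param k Consensus depth (default 20).
#' @param fraction Enrichment subset level (default 0.2).
#' @param screen A [screen_spec()] for the synthetic enrichment stage.
#' @param library_config Scaffold + substituent configuration, as from
#'   [default_library_config()].
#' @param seed Seed recorded in the log and used for synthetic stages.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("dualprofiler-run-"),
                            complexes = NULL, score_table = NULL,
                            asa = asa_params(), contacts = contact_params(),
                            dasa_threshold = 10, k = 20, fraction = 0.2,
                            screen = NULL, library_config = NULL,
                            seed = 1L) {
  stopifnot(k >= 1, fraction > 0, fraction <= 1, dasa_threshold >= 0)
  if (!is.null(complexes)) {
    missing <- !file.exists(complexes$path)
    if (any(missing)) {
      stop("configured complex file(s) not found: ",
           paste(complexes$path[missing], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(output_dir = output_dir, complexes = complexes,
         score_table = score_table, asa = asa, contacts = contacts,
         dasa_threshold = dasa_threshold, k = k, fraction = fraction,
         screen = screen %||% screen_spec(seed = seed),
         library_config = library_config %||% default_library_config(),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @noRd
write_report_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list), \(col) purrr::map_chr(col, paste, collapse = ",")))
  readr::write_tsv(df, path, progress = FALSE)
  path
}

#' Run the full post-docking analysis pipeline
#'
#' Orchestrates the stages in sequence: (1) geometry — per-residue binding
#' profiles (buried area + contacts + H-bonds) and key residues for each
#' configured complex, or for a seeded synthetic pocket when none is
#' configured; (2) screening — per-target rankings, dual-target top-k
#' consensus, and pKd conversion of any binding energies in the packaged
#' binding-strength table; (3) library — combinatorial enumeration with
#' rule-of-five verdicts; (4) enrichment — EF and cumulative curve on a
#' seeded synthetic screen. Every stage writes a TSV into the output
#' directory and the run log records all parameters; a failing stage aborts
#' with an error naming the stage.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `profiles`
#'   (list of `binding_profile`), `key_residues`, `consensus`, `pkd_table`,
#'   `library`, `enrichment` and `files` (paths written), invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log <- c(
    "dualprofiler run log",
    paste0("seed: ", cfg$seed),
    paste0("asa: probe ", cfg$asa$probe_radius, " A, ",
           cfg$asa$n_sphere_points, " sphere points"),
    paste0("contacts: ", cfg$contacts$contact_min, "-",
           cfg$contacts$contact_max, " A; hbond <= ",
           cfg$contacts$hbond_max, " A"),
    paste0("delta-ASA participation threshold: > ", cfg$dasa_threshold,
           " A^2"),
    paste0("consensus depth k: ", cfg$k),
    paste0("enrichment fraction: ", cfg$fraction),
    paste0("fixture checksums: ",
           paste(names(.dp_fixture_md5), .dp_fixture_md5, sep = "=",
                 collapse = "; "))
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- stage: geometry ----------------------------------------------------
  profiles <- stage("geometry", {
    pairs <- if (is.null(cfg$complexes)) {
      spec <- pocket_spec(
        n_residues = 6,
        planted_contacts = tibble::tibble(residue_number = c(1, 2, 4),
                                          count = c(3L, 1L, 2L),
                                          distance = c(3.4, 3.1, 3.6)),
        planted_hbonds = tibble::tibble(residue_number = 3,
                                        ligand_element = "N",
                                        distance = 2.9),
        planted_burial = 5L, seed = cfg$seed
      )
      list(list(pair = make_pocket_complex(spec)$pair,
                ligand_id = "synthetic-ligand", target_id = "synthetic"))
    } else {
      purrr::pmap(cfg$complexes, function(path, ligand, ligand_id,
                                          target_id, ...) {
        s <- assign_radii(read_structure(path))
        list(pair = split_complex(s, ligand), ligand_id = ligand_id,
             target_id = target_id)
      })
    }
    purrr::map(pairs, function(p) {
      hb <- find_hbonds(p$pair, cfg$contacts)
      ct <- find_contacts(p$pair, cfg$contacts)
      rec <- per_residue_counts(ct, hb)
      dm <- delta_asa(p$pair$protein, p$pair, cfg$asa,
                      threshold = cfg$dasa_threshold)
      build_profile(rec, dm, ligand_id = p$ligand_id,
                    target_id = p$target_id)
    })
  })
  for (p in profiles) {
    nm <- paste0("profile_", attr(p, "ligand_id"), "_",
                 attr(p, "target_id"), ".tsv")
    files <- c(files, write_report_tsv(tibble::as_tibble(p),
                                       cfg$output_dir, nm))
  }
  keyres <- purrr::map(profiles, key_residues)
  files <- c(files, write_report_tsv(
    purrr::map_dfr(keyres, \(k) dplyr::mutate(tidy(k),
                                              ligand_id = k$ligand_id)),
    cfg$output_dir, "key_residues.tsv"))

  # --- stage: screening ---------------------------------------------------
  fx <- stage("screening", load_fixtures())
  score_table <- cfg$score_table %||% fx$dock_scores_long
  consensus <- stage("screening", consensus_topk(score_table, k = cfg$k))
  files <- c(files, write_report_tsv(consensus$intersection,
                                     cfg$output_dir, "consensus.tsv"))
  pkd_table <- stage("screening", {
    dplyr::mutate(fx$binding_strengths,
                  pkd_computed = energy_to_pkd(.data$binding_energy))
  })
  files <- c(files, write_report_tsv(pkd_table, cfg$output_dir,
                                     "binding_strengths.tsv"))

  # --- stage: library -----------------------------------------------------
  library_tbl <- stage("library", {
    lc <- cfg$library_config
    enumerate_library(lc$scaffold, lc$r1, lc$r2) |>
      compute_descriptors() |>
      lipinski_evaluate()
  })
  files <- c(files, write_report_tsv(library_tbl, cfg$output_dir,
                                     "library_rule_of_five.tsv"))

  # --- stage: enrichment --------------------------------------------------
  enrich <- stage("enrichment", {
    st <- make_score_table(cfg$screen)
    ranking <- rank_compounds(st$scores, cfg$screen$targets[1])
    lbl <- st$labels$class[match(ranking$compound_id,
                                 st$labels$compound_id)]
    enrichment_factor(lbl, cfg$fraction)
  })
  files <- c(files, write_report_tsv(glance(enrich), cfg$output_dir,
                                     "enrichment_summary.tsv"))
  files <- c(files, write_report_tsv(enrich$curve, cfg$output_dir,
                                     "enrichment_curve.tsv"))

  writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  files <- c(files, file.path(cfg$output_dir, "run_log.txt"))

  invisible(structure(
    list(profiles = profiles, key_residues = keyres, consensus = consensus,
         pkd_table = pkd_table, library = library_tbl, enrichment = enrich,
         files = files),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$profiles), " profile(s); consensus: ",
      paste(x$consensus$intersection$compound_id, collapse = ", "),
      "; EF(", x$enrichment$fraction_level * 100, "%) = ",
      round(x$enrichment$ef, 2), "\n", sep = "")
  cat(length(x$files), "report files written\n")
  invisible(x)
}
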