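#' Rank compounds by dock score for one target
#'
#' More negative dock scores are better, so compounds are ordered by
#' ascending score; ties break deterministically by compound id.
#'
#' @param scores Tibble with columns `compound_id`, `target_id`,
#'   `dock_score`.
#' @param target_id Target to rank.
#' @return Tibble `rank`, `compound_id`, `dock_score`.
#' @export
rank_compounds <- function(scores, target_id) {
  rows <- dplyr::filter(tibble::as_tibble(scores),
                        .data$target_id == .env$target_id)
  if (nrow(rows) == 0L) {
    stop("no score rows for target '", target_id, "'", call. = FALSE)
  }
  if (anyDuplicated(rows$compound_id)) {
    stop("duplicate compound ids for target '", target_id, "'",
         call. = FALSE)
  }
  stopifnot(all(is.finite(rows$dock_score)))
  rows |>
    dplyr::arrange(.data$dock_score, .data$compound_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "compound_id", "dock_score")
}

#' Dual-target (or multi-target) consensus selection
#'
#' Intersects the top-`k` ranked compounds of every target; the classic
#' dual-target workflow takes the compounds common to both targets' top 20.
#' The intersection is ordered by mean rank across targets.
#'
#' @param scores Score tibble (`compound_id`, `target_id`, `dock_score`)
#'   covering at least two targets, or a named list of pre-computed
#'   [rank_compounds()] tables.
#' @param k Depth of each target's ranking to intersect (default 20). Values
#'   beyond the library size are clamped with a warning.
#' @return A list of class `consensus_result`: `k`, `rankings` (named list),
#'   and `intersection` (tibble `compound_id`, `mean_rank`, plus one
#'   `rank_<target>` column per target).
#' @export
consensus_topk <- function(scores, k = 20) {
  stopifnot(k >= 1)
  if (inherits(scores, "data.frame")) {
    targets <- unique(scores$target_id)
    if (length(targets) < 2L) {
      stop("consensus selection needs >= 2 targets", call. = FALSE)
    }
    rankings <- purrr::map(setNames(targets, targets),
                           \(tg) rank_compounds(scores, tg))
  } else {
    rankings <- scores
    if (length(rankings) < 2L) {
      stop("consensus selection needs >= 2 targets", call. = FALSE)
    }
  }
  n_min <- min(vapply(rankings, nrow, 1L))
  if (k > n_min) {
    warning("k = ", k, " exceeds the library size (", n_min,
            "); clamping", call. = FALSE)
    k <- n_min
  }
  tops <- purrr::map(rankings, \(r) r$compound_id[r$rank <= k])
  common <- Reduce(intersect, tops)
  rank_cols <- purrr::imap(rankings, \(r, nm) {
    tibble::tibble(compound_id = r$compound_id) |>
      dplyr::mutate(!!paste0("rank_", nm) := r$rank)
  })
  inter <- tibble::tibble(compound_id = common)
  for (rc in rank_cols) inter <- dplyr::left_join(inter, rc, by = "compound_id")
  if (nrow(inter) > 0L) {
    inter$mean_rank <- rowMeans(inter[, -1, drop = FALSE])
    inter <- dplyr::arrange(inter, .data$mean_rank, .data$compound_id)
  } else {
    inter$mean_rank <- numeric()
  }
  structure(list(k = k, rankings = rankings, intersection = inter),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> top-", x$k, " intersection over ",
      length(x$rankings), " targets: ",
      if (nrow(x$intersection)) paste(x$intersection$compound_id,
                                      collapse = ", ") else "(empty)",
      "\n", sep = "")
  invisible(x)
}

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) x$intersection

# ln(10) * R * T at R = 1.9872e-3 kcal/mol/K
ln10_rt <- function(temperature) 2.302585093 * 1.9872e-3 * temperature

#' Convert binding free energy to pKd
#'
#' Thermodynamic conversion `pKd = -dG / (ln10 * R * T)` with the gas
#' constant R = 1.9872e-3 kcal/mol/K; at 298 K the denominator is
#' 1.3638 kcal/mol, so e.g. -9.14 kcal/mol gives pKd 6.70.
#'
#' @param dg Binding free energy in kcal/mol (negative for favourable
#'   binding; positive values return a negative pKd with a warning).
#' @param temperature Temperature in Kelvin (default 298).
#' @param digits Decimal places for the reported value (default 2, as
#'   printed in binding-strength tables); `NULL` for full precision.
#' @return Numeric vector of pKd values.
#' @export
#' @examples
#' energy_to_pkd(c(-9.14, -9.98)) # 6.70, 7.32
energy_to_pkd <- function(dg, temperature = 298, digits = 2) {
  if (any(dg > 0)) {
    warning("positive binding free energy yields negative pKd",
            call. = FALSE)
  }
  pkd <- -dg / ln10_rt(temperature)
  if (!is.null(digits)) pkd <- round(pkd, digits)
  pkd
}

# normalise ranked labels to logical actives
#' @noRd
as_active <- function(ranked_labels) {
  if (is.logical(ranked_labels)) return(ranked_labels)
  if (is.numeric(ranked_labels)) return(ranked_labels != 0)
  tolower(as.character(ranked_labels)) %in% c("active", "1", "true", "yes")
}

#' Enrichment factor of a ranked screen
#'
#' EF at a fraction level is the ratio of the active rate in the top
#' `floor(fraction * N)` compounds to the active rate in the whole database:
#' `EF = (hits_sample / n_sample) / (hits_database / n_database)`. Random
#' ranking gives EF = 1 in expectation; 0 means no active was retrieved in
#' the subset.
#'
#' @param ranked_labels Active/decoy flags in rank order (best first):
#'   logical, 0/1, or `"active"`/`"decoy"` strings.
#' @param fraction Subset level as a proportion of the database (default
#'   0.2, the classic 20% level).
#' @return A list of class `enrichment_result` with `fraction_level`,
#'   `hits_sample`, `n_sample`, `hits_database`, `n_database`, `ef` and the
#'   cumulative `curve` (see [enrichment_curve()]).
#' @export
#' @examples
#' labels <- c(rep(TRUE, 6), rep(FALSE, 600)) # perfect ranking
#' enrichment_factor(labels, 0.2)$ef # ~5.01
enrichment_factor <- function(ranked_labels, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  act <- as_active(ranked_labels)
  n_db <- length(act)
  hits_db <- sum(act)
  if (hits_db == 0L) {
    stop("enrichment factor undefined: no active compounds in the database",
         call. = FALSE)
  }
  n_sample <- max(1L, floor(fraction * n_db))
  hits_sample <- sum(act[seq_len(n_sample)])
  ef <- (hits_sample / n_sample) / (hits_db / n_db)
  structure(
    list(fraction_level = fraction, hits_sample = hits_sample,
         n_sample = n_sample, hits_database = hits_db, n_database = n_db,
         ef = ef, curve = enrichment_curve(act)),
    class = "enrichment_result"
  )
}

#' Cumulative enrichment curve
#'
#' At every rank, the fraction of the database screened so far against the
#' fraction of all actives already recovered. The curve is non-decreasing
#' and ends at (1, 1); a perfect screen recovers every active within the
#' first `hits/N` of the database, and a random one tracks the diagonal.
#'
#' @inheritParams enrichment_factor
#' @return Tibble with `fraction_screened` and `fraction_actives_found`.
#' @export
enrichment_curve <- function(ranked_labels) {
  act <- as_active(ranked_labels)
  n <- length(act)
  stopifnot(n >= 1)
  hits <- sum(act)
  tibble::tibble(
    fraction_screened = seq_len(n) / n,
    fraction_actives_found = if (hits > 0) cumsum(act) / hits else
      rep(0, n)
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> EF = ", round(x$ef, 2), " at the ",
      x$fraction_level * 100, "% level (", x$hits_sample, "/", x$n_sample,
      " actives in subset; ", x$hits_database, "/", x$n_database,
      " in database)\n", sep = "")
  invisible(x)
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) x$curve

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    fraction_level = x$fraction_level, ef = x$ef,
    hits_sample = x$hits_sample, n_sample = x$n_sample,
    hits_database = x$hits_database, n_database = x$n_database
  )
}

#' Plot an enrichment curve
#'
#' @param object An `enrichment_result`.
#' @param ... Ignored.
#' @return A ggplot object with the cumulative recovery curve and the
#'   random-screen diagonal.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fraction_screened,
                               y = .data$fraction_actives_found)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Fraction of database screened",
                  y = "Fraction of actives recovered",
                  title = sprintf("EF(%g%%) = %.2f",
                                  object$fraction_level * 100, object$ef)) +
    ggplot2::theme_minimal()
}
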