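# Per-clade presence/absence and motif residue-composition rollups.

#' Per-clade prevalence of GH99 proteins
#'
#' For each requested clade: the number of searched species (from the
#' taxonomy's species universe), the number of species with at least one
#' surviving clustered record, and their ratio. Species are counted once
#' no matter how many records or clusters they contribute. Following the
#' convention of identity-clustered surveys, a species counts as "with
#' hit" when it owns at least one cluster representative — clustering can
#' therefore only lower prevalence, never raise it. Clades whose species
#' universe is unknown (no searched species recorded) are flagged rather
#' than given a fraction.
#'
#' @param assignment A `cluster_assignment` (see [greedy_cluster()]).
#' @param records Protein record tibble the assignment was built from
#'   (provides the id -> species join).
#' @param tax Taxonomy tibble.
#' @param clades Character vector of clade names to report.
#' @return Tibble: `clade`, `species_searched`, `species_with_hit`,
#'   `fraction` (NA when the universe is unknown), `universe_unknown`.
#' @export
presence_absence <- function(assignment, records, tax, clades) {
  universe <- clade_universe(tax)
  known_clades <- unique(unlist(tax$clade_path))
  bad <- setdiff(clades, known_clades)
  if (length(bad)) stop("clade '", bad[1], "' absent from taxonomy")
  reps <- cluster_representatives(assignment)
  sp_of <- setNames(records$species, records$id)
  hit_species <- unique(stats::na.omit(sp_of[reps]))
  unresolved <- reps[is.na(sp_of[reps]) | !(sp_of[reps] %in% tax$species)]
  if (length(unresolved)) {
    stop("species of record '", unresolved[1], "' cannot be resolved")
  }
  rows <- lapply(clades, function(cl) {
    in_clade <- vapply(tax$clade_path, function(p) cl %in% p, logical(1))
    searched <- universe$n_species[match(cl, universe$clade)]
    searched <- if (is.na(searched)) 0L else searched
    with_hit <- sum(hit_species %in% tax$species[in_clade])
    unknown <- searched == 0L
    tibble::tibble(clade = cl,
                   species_searched = searched,
                   species_with_hit = with_hit,
                   fraction = if (unknown) NA_real_ else with_hit / searched,
                   universe_unknown = unknown)
  })
  do.call(rbind, rows)
}

# residue read out of an annotation table at one motif position
residue_at_position <- function(annotations, position) {
  mp <- motif_positions()
  if (position == mp$P189) return(annotations$p189)
  if (position == mp$P323) return(annotations$p323)
  if (position %in% mp$LOOP) {
    return(substr(annotations$loop, match(position, mp$LOOP),
                  match(position, mp$LOOP)))
  }
  if (position %in% mp$HEPY) {
    return(substr(annotations$hepy, match(position, mp$HEPY),
                  match(position, mp$HEPY)))
  }
  if (position %in% mp$ACTSITE) {
    return(substr(annotations$actsite, match(position, mp$ACTSITE),
                  match(position, mp$ACTSITE)))
  }
  stop("position ", position, " is not inside any diagnostic motif")
}

#' Residue composition at a motif position within a clade
#'
#' Counts each residue observed at the given reference position among the
#' annotated records whose species falls inside the clade, and reports
#' percentages (rounded to 0.1) among determined calls only; undetermined
#' (`?`) calls — partial sequences where the residue is missing — are
#' reported separately and excluded from the denominator.
#'
#' @param annotations Tibble from [annotate_cohort()].
#' @param records Protein record tibble (id -> species join).
#' @param tax Taxonomy tibble.
#' @param clade Clade name.
#' @param position Reference position inside one of the diagnostic motifs.
#' @return Tibble: `clade`, `position`, `residue`, `count`, `percent`
#'   (NA for the `?` row and when no call is determined), sorted by count
#'   descending.
#' @export
residue_composition <- function(annotations, records, tax, clade, position) {
  sp_of <- setNames(records$species, records$id)
  in_clade <- vapply(tax$clade_path, function(p) clade %in% p, logical(1))
  clade_species <- tax$species[in_clade]
  keep <- sp_of[annotations$id] %in% clade_species
  res <- residue_at_position(annotations[keep, , drop = FALSE], position)
  tab <- table(res)
  determined <- sum(tab[names(tab) != "?"])
  rows <- lapply(names(sort(tab, decreasing = TRUE)), function(r) {
    n <- as.integer(tab[[r]])
    tibble::tibble(clade = clade, position = position, residue = r, count = n,
                   percent = if (r == "?" || determined == 0) NA_real_
                             else round(100 * n / determined, 1))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(clade = character(0), position = integer(0),
                          residue = character(0), count = integer(0),
                          percent = numeric(0))
  }
  out
}
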