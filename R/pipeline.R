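# End-to-end pipeline: cluster -> decontaminate -> annotate -> classify ->
# prevalence, writing every intermediate artifact plus a run manifest.

#' Run the full GH99 survey pipeline
#'
#' Chains the package stages in the order a clade survey uses them:
#' identity clustering of the input records, phylogeny-based
#' decontamination of the cluster representatives, motif annotation of the
#' survivors, optional ohnolog classification (when three profile models
#' are supplied), and per-clade prevalence plus residue-189 composition
#' rollups. Every intermediate table is written under `out_dir`, along
#' with a machine-readable JSON manifest of inputs, parameters and seed.
#' Existing outputs are not overwritten unless `overwrite = TRUE`.
#'
#' @param records Protein record tibble.
#' @param tax Taxonomy tibble.
#' @param out_dir Output directory (created if needed).
#' @param clades Clades for the prevalence table (default: every top-level
#'   taxogroup in the taxonomy).
#' @param models Optional list of three `profile_model`s for ohnolog
#'   classification.
#' @param c,s Clustering thresholds (cd-hit style; defaults 0.95 / 0.5).
#' @param k,level,max_rounds Decontamination parameters.
#' @param delta Classification margin in bits.
#' @param min_identity Reference-mapping identity floor.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents upstream data generation).
#' @param overwrite Allow overwriting existing artifacts.
#' @return Invisibly, a list with every stage result (`clusters`,
#'   `decontamination`, `annotations`, `classification`, `prevalence`,
#'   `composition189`, `manifest`).
#' @export
run_pipeline <- function(records, tax, out_dir,
                         clades = NULL, models = NULL,
                         c = 0.95, s = 0.5, k = 3, level = 1, max_rounds = 5,
                         delta = 2, min_identity = 0.15, seed = NA,
                         overwrite = FALSE) {
  stopifnot(c > 0, c <= 1, s > 0, s <= 1, k >= 1, max_rounds >= 1, delta >= 0)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifact <- function(name) {
    path <- file.path(out_dir, name)
    if (file.exists(path) && !overwrite) {
      stop("output ", path, " exists; use overwrite = TRUE")
    }
    path
  }
  if (is.null(clades)) {
    clades <- unique(vapply(tax$clade_path, `[[`, character(1), 1))
  }
  clusters <- greedy_cluster(records, c = c, s = s)
  write_cluster_tsv(clusters, artifact("clusters.tsv"))

  reps <- cluster_representatives(clusters)
  rep_records <- records[match(reps, records$id), , drop = FALSE]
  decon <- NULL
  surviving <- rep_records
  if (nrow(rep_records) >= 3) {
    D <- pairwise_distance(rep_records)
    decon <- flag_contaminants(D, tax,
                               species_of = setNames(rep_records$species,
                                                     rep_records$id),
                               k = k, level = level, max_rounds = max_rounds)
    write_contamination_tsv(decon, artifact("contamination.tsv"))
    surviving <- rep_records[rep_records$id %in% decon$surviving, , drop = FALSE]
  }

  annotations <- annotate_cohort(surviving, min_identity = min_identity)
  utils::write.table(as.data.frame(annotations),
                     artifact("annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  classification <- NULL
  if (!is.null(models)) {
    classification <- classify_cohort(surviving, models, delta = delta)
    utils::write.table(as.data.frame(classification),
                       artifact("ohnolog_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  surv_clusters <- clusters[clusters$representative %in% surviving$id, ,
                            drop = FALSE]
  prevalence <- presence_absence(surv_clusters, records, tax, clades)
  utils::write.table(as.data.frame(prevalence), artifact("prevalence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  composition <- do.call(rbind, lapply(clades, function(cl) {
    residue_composition(annotations, records, tax, cl, 189L)
  }))
  utils::write.table(as.data.frame(composition),
                     artifact("residue189_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "gh99evo",
    version = as.character(utils::packageVersion("gh99evo")),
    n_records = nrow(records), n_species = length(unique(records$species)),
    parameters = list(c = c, s = s, k = k, level = level,
                      max_rounds = max_rounds, delta = delta,
                      min_identity = min_identity),
    seed = seed,
    clades = clades,
    stages = c("cluster", "decontaminate", "annotate",
               if (!is.null(models)) "classify", "prevalence"))
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(clusters = clusters, decontamination = decon,
                 annotations = annotations, classification = classification,
                 prevalence = prevalence, composition189 = composition,
                 manifest = manifest))
}
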