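# Position-specific scoring profiles for MANEA / MANEAL / CMANEAL
# discrimination.

#' Build a position-specific scoring profile from seed sequences
#'
#' Seeds are stacked into reference-anchored columns over the catalytic
#' domain (full-length reference positions 98 onward, the span whose
#' numbering is shifted by -97 in domain coordinates). Per position j and
#' residue a the log-odds score is
#' `log2( ((c_aj + alpha * q_a) / (n_j + alpha)) / q_a )` with `q` the
#' background frequencies — a Dirichlet-smoothed estimate against the
#' background null. With `alpha > 0` all scores are finite; columns with no
#' observations score 0 everywhere.
#'
#' @param seed_records Protein record tibble with at least 2 rows.
#' @param name Model name (e.g. `"MANEA"`).
#' @param alpha Pseudocount mass (default 0.5).
#' @param background Background frequencies (default [aa_background()]).
#' @param reference Reference record or sequence.
#' @param span Reference positions to model; default 98:reference length.
#' @param gap_open,gap_extend Profile-to-sequence gap penalties.
#' @return Object of class `profile_model`.
#' @export
build_profile <- function(seed_records, name, alpha = 0.5,
                          background = aa_background(),
                          reference = gh99_reference(), span = NULL,
                          gap_open = default_gap_open(),
                          gap_extend = default_gap_extend()) {
  if (nrow(seed_records) < 2) stop("need at least 2 seed sequences")
  ref_seq <- if (is.character(reference)) reference else reference$sequence[1]
  if (is.null(span)) span <- seq(DOMAIN_OFFSET + 1L, nchar(ref_seq))
  cols <- stack_reference_columns(seed_records, positions = span,
                                  reference = ref_seq)
  aa <- amino_acids()
  q <- background[aa]
  scores <- matrix(0, nrow = length(span), ncol = 20,
                   dimnames = list(span, aa))
  for (jj in seq_along(span)) {
    col <- cols[, jj]
    obs <- col[col %in% aa]
    n <- length(obs)
    c_a <- as.numeric(table(factor(obs, levels = aa)))
    scores[jj, ] <- log2(((c_a + alpha * q) / (n + alpha)) / q)
  }
  structure(list(name = name, scores = scores, alpha = alpha,
                 background = q, span = span,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Profile model '", x$name, "': ", nrow(x$scores),
      " positions, alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Score a sequence against a profile
#'
#' Optimal global profile-to-sequence alignment score in bits, under the
#' model's per-position scores and affine gap penalties. `X` residues score
#' 0 (background-neutral) at every position. Deterministic; record
#' metadata is ignored.
#'
#' @param model A `profile_model`.
#' @param record One-row protein record tibble or sequence string.
#' @return Numeric bit score.
#' @export
score_profile <- function(model, record) {
  seq <- if (is.character(record)) record else record$sequence[1]
  profile_align_cpp(model$scores, aa_encode(seq),
                    model$gap_open, model$gap_extend)
}

#' Classify a record among the three vertebrate ohnologs
#'
#' Scores the record on the MANEA, MANEAL and CMANEAL profiles and labels
#' it with the best-scoring model when the margin over the runner-up is at
#' least `delta` bits, else `unclassified`. The full pairwise
#' score-difference table is retained — the same signal the two-dimensional
#' score-delta scatter separates into per-ohnolog clusters. Non-gnathostome
#' single-copy (ancestral) sequences are expected to fall into the MANEA
#' cluster; no fourth class exists.
#'
#' @param record One-row protein record tibble or sequence string.
#' @param models List of exactly three `profile_model`s with distinct names.
#' @param delta Decision margin in bits (default 2).
#' @return Object of class `ohnolog_call`: list with named `scores`,
#'   `label`, `margin`, and `deltas` (pairwise score differences).
#' @export
classify_ohnolog <- function(record, models, delta = 2) {
  stopifnot(length(models) == 3)
  nms <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("profile models must have distinct names")
  scores <- vapply(models, score_profile, numeric(1), record = record)
  names(scores) <- nms
  ord <- order(scores, decreasing = TRUE)
  margin <- scores[ord[1]] - scores[ord[2]]
  label <- if (margin >= delta) nms[ord[1]] else "unclassified"
  pairs <- utils::combn(nms, 2)
  deltas <- apply(pairs, 2, function(p) scores[p[1]] - scores[p[2]])
  names(deltas) <- apply(pairs, 2, paste, collapse = "_minus_")
  structure(list(scores = scores, label = label,
                 margin = unname(margin), deltas = deltas),
            class = "ohnolog_call")
}

#' Classify a cohort and return the score-delta table
#'
#' @param records Protein record tibble.
#' @param models List of three `profile_model`s.
#' @param delta Decision margin in bits.
#' @return Tibble: id, one score column per model, pairwise deltas,
#'   `margin`, `label`.
#' @export
classify_cohort <- function(records, models, delta = 2) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    cl <- classify_ohnolog(records$sequence[i], models, delta)
    tibble::as_tibble(c(list(id = records$id[i]),
                        as.list(setNames(cl$scores, paste0("score_", names(cl$scores)))),
                        as.list(cl$deltas),
                        list(margin = cl$margin, label = cl$label)))
  })
  do.call(rbind, rows)
}

#' Serialize a profile model to JSON
#' @param model A `profile_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(model, path) {
  jsonlite::write_json(
    list(name = model$name, alpha = model$alpha,
         span = model$span,
         gap_open = model$gap_open, gap_extend = model$gap_extend,
         background = as.list(model$background),
         scores = apply(model$scores, 1, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
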