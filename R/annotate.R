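# Rule engine: motif call -> predicted activity, catalytic status, variants.

ACTSITE_CLASSES <- c("EWHE", "EWGE", "DYGE", "KWHE")

annotate_from_call <- function(call) {
  p189 <- call$p189
  substrate <- if (p189 == "?") "undetermined"
    else if (p189 == "Y") "glc_minus2"
    else if (p189 == "W") "man_minus2"
    else "other_residue"
  minimal <- switch(substrate,
                    glc_minus2 = "GlcMan3",
                    man_minus2 = "Man4",
                    "unknown")
  act <- call$actsite
  e404 <- substr(act, 1, 1)
  e407 <- substr(act, 4, 4)
  activesite_class <- if (grepl("?", act, fixed = TRUE)) "undetermined"
    else if (act %in% ACTSITE_CLASSES) act
    else "other"
  catalytic <- if (e404 == "?" || e407 == "?") "undetermined"
    else if (e404 == "E" && e407 == "E") "predicted_active"
    else if (activesite_class == "DYGE") "undetermined" # no activity evidence either way
    else "predicted_inactive"
  p197 <- substr(call$loop, 3, 3)
  n197h <- if (p197 == "?") "undetermined" else if (p197 == "H") "present" else "absent"
  list(substrate_preference = substrate,
       predicted_minimal_substrate = minimal,
       catalytic_status = catalytic,
       activesite_class = activesite_class,
       n197h = n197h)
}

#' Annotate a GH99 protein from its diagnostic motifs
#'
#' Maps the record onto the reference, extracts the five motifs and applies
#' the functional-inference rules:
#' \itemize{
#'   \item substrate preference: Y189 -> `glc_minus2` (endomannosidase-like,
#'     minimal substrate GlcMan3); W189 -> `man_minus2` (endomannanase-like,
#'     minimal substrate Man4); any other mapped residue ->
#'     `other_residue`; unmapped -> `undetermined`.
#'   \item catalytic status: both catalytic glutamates present (E404 and
#'     E407) -> `predicted_active`; either mapped and non-E ->
#'     `predicted_inactive` (covers E404Q and the KWHE variant); either
#'     unmapped -> `undetermined`. The DYGE active-site class is left
#'     `undetermined` — the motif occurs in related hydrolases without
#'     direct activity evidence, so activity is not asserted either way.
#'   \item active-site class: the 404-407 string matched against EWHE,
#'     EWGE, DYGE, KWHE, else `other`.
#'   \item N197H loop variant flagged when position 197 reads H.
#' }
#' Unmappable records return every field `undetermined` with a warning,
#' never an error.
#'
#' @param record One-row protein record tibble or sequence string.
#' @param reference Reference record or sequence (default packaged).
#' @param min_identity Mapping identity floor.
#' @return Object of class `gh99_annotation`: list of the fields above plus
#'   the raw `motif_call`.
#' @export
annotate <- function(record, reference = gh99_reference(), min_identity = 0.15) {
  seq <- if (is.character(record)) record else record$sequence[1]
  refmap <- build_reference_map(seq, reference, min_identity = min_identity)
  if (!refmap$mappable) {
    warning("record is unmappable to the reference (identity ",
            sprintf("%.1f%%", 100 * refmap$identity_shorter),
            "); annotation undetermined")
  }
  call <- extract_motifs(seq, refmap = refmap)
  out <- annotate_from_call(call)
  out$motif_call <- call
  structure(out, class = "gh99_annotation")
}

#' @export
print.gh99_annotation <- function(x, ...) {
  cat("GH99 annotation\n",
      " substrate preference: ", x$substrate_preference,
      " (minimal substrate ", x$predicted_minimal_substrate, ")\n",
      " catalytic status:     ", x$catalytic_status,
      "  active site ", x$motif_call$actsite,
      " [", x$activesite_class, "]\n",
      " N197H loop variant:   ", x$n197h, "\n", sep = "")
  invisible(x)
}

#' Annotate a cohort of records into a tidy table
#'
#' @param records Protein record tibble.
#' @param reference,min_identity As in [annotate()].
#' @return Tibble with one row per record: id, the five motif strings, and
#'   every annotation field.
#' @export
annotate_cohort <- function(records, reference = gh99_reference(),
                            min_identity = 0.15) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    a <- suppressWarnings(annotate(records$sequence[i], reference, min_identity))
    tibble::tibble(id = records$id[i],
                   p189 = a$motif_call$p189, loop = a$motif_call$loop,
                   hepy = a$motif_call$hepy, p323 = a$motif_call$p323,
                   actsite = a$motif_call$actsite,
                   substrate_preference = a$substrate_preference,
                   predicted_minimal_substrate = a$predicted_minimal_substrate,
                   catalytic_status = a$catalytic_status,
                   activesite_class = a$activesite_class,
                   n197h = a$n197h)
  })
  do.call(rbind, rows)
}

#' Write per-record annotations as JSON
#' @param annotations Tibble from [annotate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_json <- function(annotations, path) {
  jsonlite::write_json(annotations, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
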