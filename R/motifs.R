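# Motif extraction in reference coordinates, position frequency matrices,
# information content and threshold consensus.

#' Read residues at reference positions through a reference map
#'
#' @param sequence Query sequence string.
#' @param refmap A `reference_map` for that query.
#' @param positions Integer vector of reference positions.
#' @return Character vector of residues, `"?"` where the position is
#'   unmapped or the map is unmappable.
#' @export
residues_at <- function(sequence, refmap, positions) {
  out <- rep("?", length(positions))
  if (!refmap$mappable) return(out)
  inside <- positions >= 1 & positions <= length(refmap$r2q)
  q <- rep(NA_integer_, length(positions))
  q[inside] <- refmap$r2q[positions[inside]]
  ok <- !is.na(q)
  if (any(ok)) out[ok] <- substring(sequence, q[ok], q[ok])
  out
}

#' Extract the five diagnostic motifs of a GH99 protein
#'
#' Reads the residues at the five diagnostic spans (see
#' [motif_positions()]) through the query's reference map. Partial
#' sequences never error: positions the map does not cover are reported as
#' `"?"` (undetermined), mirroring how partial transcript-derived proteins
#' are handled in clade surveys.
#'
#' @param record One-row protein record tibble or a sequence string.
#' @param refmap Optional precomputed `reference_map`; built against the
#'   packaged reference when omitted.
#' @param reference Reference passed to [build_reference_map()] when
#'   `refmap` is missing.
#' @return Object of class `motif_call`: list with single-character `p189`
#'   and `p323`, and strings `loop` (5), `hepy` (5), `actsite` (4);
#'   attribute `mappable`.
#' @export
extract_motifs <- function(record, refmap = NULL, reference = gh99_reference()) {
  seq <- if (is.character(record)) record else record$sequence[1]
  if (is.null(refmap)) refmap <- build_reference_map(seq, reference)
  mp <- motif_positions()
  call <- list(
    p189 = residues_at(seq, refmap, mp$P189),
    loop = paste(residues_at(seq, refmap, mp$LOOP), collapse = ""),
    hepy = paste(residues_at(seq, refmap, mp$HEPY), collapse = ""),
    p323 = residues_at(seq, refmap, mp$P323),
    actsite = paste(residues_at(seq, refmap, mp$ACTSITE), collapse = "")
  )
  structure(call, class = "motif_call", mappable = refmap$mappable)
}

#' Stack query residues into reference-anchored columns
#'
#' Builds a character matrix with one row per record and one column per
#' requested reference position by mapping each record independently onto
#' the reference. This is the column definition used for logos, consensus
#' sequences and profiles; no multiple alignment is inferred.
#'
#' @param records Protein record tibble.
#' @param positions Reference positions (default: every reference position).
#' @param reference Reference record or sequence.
#' @param min_identity Identity floor for [build_reference_map()].
#' @return Character matrix (rows = record ids, columns = positions) with
#'   `"?"` at unmapped positions.
#' @export
stack_reference_columns <- function(records, positions = NULL,
                                    reference = gh99_reference(),
                                    min_identity = 0.15) {
  ref_seq <- if (is.character(reference)) reference else reference$sequence[1]
  if (is.null(positions)) positions <- seq_len(nchar(ref_seq))
  out <- matrix("?", nrow = nrow(records), ncol = length(positions),
                dimnames = list(records$id, positions))
  for (i in seq_len(nrow(records))) {
    rm_i <- build_reference_map(records$sequence[i], ref_seq,
                                min_identity = min_identity)
    out[i, ] <- residues_at(records$sequence[i], rm_i, positions)
  }
  out
}

#' Position frequency matrix with information content
#'
#' Counts residues per column, excluding gaps (`-`) and undetermined
#' positions (`?`). Frequencies use a flat per-letter pseudocount:
#' `f_a = (c_a + pc) / (n + 20 pc)`. The per-column information content is
#' `IC = log2(20) - H` with `H` the Shannon entropy of the column
#' frequencies in bits; columns with zero observations get `NA` IC (not 0).
#'
#' @param columns Character matrix as from [stack_reference_columns()], or
#'   a list of `motif_call`s for one motif via [motif_column_matrix()].
#' @param pseudocount Non-negative flat pseudocount.
#' @return Object of class `gh99_pfm`: list with `counts` (20 x L),
#'   `gap_counts`, `freqs`, `ic` (bits), `pseudocount`.
#' @export
build_pfm <- function(columns, pseudocount = 0) {
  stopifnot(is.matrix(columns), nrow(columns) >= 1, pseudocount >= 0)
  aa <- amino_acids()
  L <- ncol(columns)
  counts <- matrix(0L, nrow = 20, ncol = L, dimnames = list(aa, colnames(columns)))
  gap_counts <- integer(L)
  for (j in seq_len(L)) {
    col <- columns[, j]
    gap_counts[j] <- sum(col %in% c("-", "?", "X"))
    tab <- table(factor(col[col %in% aa], levels = aa))
    counts[, j] <- as.integer(tab)
  }
  n <- colSums(counts)
  freqs <- sweep(counts + pseudocount, 2, n + 20 * pseudocount, "/")
  ic <- vapply(seq_len(L), function(j) {
    if (n[j] == 0) return(NA_real_)
    f <- freqs[, j]
    f <- f[f > 0]
    log2(20) + sum(f * log2(f))
  }, numeric(1))
  structure(list(counts = counts, gap_counts = gap_counts, freqs = freqs,
                 ic = ic, pseudocount = pseudocount),
            class = "gh99_pfm")
}

#' Column matrix of one motif across a set of motif calls
#' @param calls List of `motif_call` objects.
#' @param motif One of `"P189"`, `"LOOP"`, `"HEPY"`, `"P323"`, `"ACTSITE"`.
#' @return Character matrix, one row per call.
#' @export
motif_column_matrix <- function(calls, motif = "P189") {
  mp <- motif_positions()
  stopifnot(motif %in% names(mp))
  field <- c(P189 = "p189", LOOP = "loop", HEPY = "hepy",
             P323 = "p323", ACTSITE = "actsite")[[motif]]
  rows <- lapply(calls, function(cl) strsplit(cl[[field]], "")[[1]])
  out <- do.call(rbind, rows)
  colnames(out) <- mp[[motif]]
  out
}

#' Threshold consensus of reference-anchored columns
#'
#' Per column: frequencies over non-gap observations; the modal residue is
#' reported when its frequency reaches `t`, else `X`. Columns where gaps or
#' undetermined positions are the majority are dropped from the consensus
#' string and listed in `dropped`. Raising `t` can only turn letters into
#' `X`, never the reverse.
#'
#' @param columns Character matrix (rows = sequences).
#' @param t Identity threshold in (0.5, 1].
#' @return Object of class `gh99_consensus`: list with `consensus` string,
#'   `t`, `coverage` (observations per kept column), `positions` (kept
#'   column names), `dropped` (majority-gap column names).
#' @export
consensus_sequence <- function(columns, t = 0.9) {
  stopifnot(is.matrix(columns))
  if (nrow(columns) == 0) stop("empty column set")
  if (!(t > 0.5 && t <= 1)) stop("threshold t must lie in (0.5, 1]")
  aa <- amino_acids()
  L <- ncol(columns)
  keep <- logical(L)
  letters_out <- character(L)
  coverage <- integer(L)
  for (j in seq_len(L)) {
    col <- columns[, j]
    obs <- col[col %in% aa]
    n_gap <- length(col) - length(obs)
    if (n_gap > length(obs) || length(obs) == 0) next # majority-gap: drop
    keep[j] <- TRUE
    coverage[j] <- length(obs)
    tab <- sort(table(obs), decreasing = TRUE)
    letters_out[j] <- if (tab[1] / length(obs) >= t) names(tab)[1] else "X"
  }
  nm <- colnames(columns)
  structure(list(consensus = paste(letters_out[keep], collapse = ""),
                 t = t,
                 coverage = coverage[keep],
                 positions = if (is.null(nm)) which(keep) else nm[keep],
                 dropped = if (is.null(nm)) which(!keep) else nm[!keep]),
            class = "gh99_consensus")
}

#' Export a PFM and its information-content track as TSV
#' @param pfm A `gh99_pfm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- as.data.frame(t(pfm$counts))
  df <- cbind(position = rownames(df), df,
              gaps = pfm$gap_counts, ic_bits = pfm$ic)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export sequence-logo data (per-column letter heights in bits) as JSON
#'
#' Letter height = column IC times letter frequency, the standard logo
#' parameterisation; rendering is left to the caller.
#'
#' @param pfm A `gh99_pfm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_json <- function(pfm, path) {
  heights <- sweep(pfm$freqs, 2, pfm$ic, "*")
  cols <- lapply(seq_len(ncol(heights)), function(j) {
    h <- heights[, j]
    as.list(h[!is.na(h) & h > 1e-12])
  })
  names(cols) <- colnames(pfm$counts)
  jsonlite::write_json(list(ic_bits = pfm$ic, letter_heights = cols),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
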