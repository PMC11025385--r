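# Global pairwise alignment and the reference coordinate map.

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch / Gotoh global alignment. A gap of length k costs
#' `gap_open + k * gap_extend` (penalties are subtracted from the score).
#' The traceback is deterministic: on ties, diagonal moves are preferred
#' over vertical (gap in `b`) over horizontal (gap in `a`).
#'
#' @param a,b Amino-acid sequences (strings over the 20 standard letters
#'   plus X).
#' @param matrix Substitution matrix with dimnames covering the alphabet;
#'   default [blosum62()].
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return An object of class `gh99_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `gap_open`,
#'   `gap_extend`, `identity_columns` (matches / aligned columns) and
#'   `identity_shorter` (matches / length of the shorter input).
#' @export
global_align <- function(a, b, matrix = blosum62(),
                         gap_open = default_gap_open(),
                         gap_extend = default_gap_extend()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  stopifnot(gap_open >= 0, gap_extend >= 0)
  ab <- aa_alphabet()
  m <- matrix[ab, ab]
  res <- nw_align_cpp(aa_encode(a), aa_encode(b), m, gap_open, gap_extend)
  ca <- res$a
  cb <- res$b
  matches <- sum(ca >= 0 & cb >= 0 & ca == cb)
  structure(list(
    aligned_a = aa_decode(ca),
    aligned_b = aa_decode(cb),
    score = res$score,
    gap_open = gap_open,
    gap_extend = gap_extend,
    identity_columns = matches / length(ca),
    identity_shorter = matches / min(nchar(a), nchar(b))
  ), class = "gh99_alignment")
}

#' @export
print.gh99_alignment <- function(x, ...) {
  cat("Global alignment  score:", x$score,
      sprintf(" identity: %.1f%% (columns), %.1f%% (shorter)\n",
              100 * x$identity_columns, 100 * x$identity_shorter))
  cat(substr(x$aligned_a, 1, 70), "\n")
  cat(substr(x$aligned_b, 1, 70), "\n")
  invisible(x)
}

#' Build the coordinate map between a query and the reference numbering
#'
#' Globally aligns the query to the reference and records every
#' match/mismatch column as a bidirectional position correspondence
#' (1-based on both sides); gap columns are unmapped. If the fractional
#' identity over the shorter sequence falls below `min_identity` the map is
#' returned with `mappable = FALSE` rather than failing, so partial or
#' foreign sequences degrade to undetermined annotations downstream.
#'
#' @param query Query sequence string, or a one-row protein record tibble.
#' @param reference Reference sequence string, or a one-row record tibble;
#'   defaults to the packaged reference (see [gh99_reference()]).
#' @param min_identity Identity floor below which the query is declared
#'   unmappable.
#' @param ... Passed to [global_align()].
#' @return Object of class `reference_map`: list with integer vectors
#'   `q2r` (length = query length) and `r2q` (length = reference length),
#'   NA where unmapped; `identity_shorter`; logical `mappable`.
#' @export
build_reference_map <- function(query, reference = gh99_reference(),
                                min_identity = 0.15, ...) {
  q <- if (is.character(query)) query else query$sequence[1]
  r <- if (is.character(reference)) reference else reference$sequence[1]
  aln <- global_align(q, r, ...)
  qa <- strsplit(aln$aligned_a, "")[[1]]
  ra <- strsplit(aln$aligned_b, "")[[1]]
  qpos <- as.integer(cumsum(qa != "-"))
  rpos <- as.integer(cumsum(ra != "-"))
  both <- qa != "-" & ra != "-"
  q2r <- rep(NA_integer_, nchar(q))
  r2q <- rep(NA_integer_, nchar(r))
  q2r[qpos[both]] <- rpos[both]
  r2q[rpos[both]] <- qpos[both]
  mappable <- aln$identity_shorter >= min_identity
  structure(list(q2r = q2r, r2q = r2q,
                 identity_shorter = aln$identity_shorter,
                 mappable = mappable),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat("Reference map:", sum(!is.na(x$r2q)), "of", length(x$r2q),
      "reference positions mapped;",
      sprintf("identity %.1f%%;", 100 * x$identity_shorter),
      if (x$mappable) "mappable\n" else "UNMAPPABLE\n")
  invisible(x)
}

#' Convert between catalytic-domain and full-length MANEA numbering
#'
#' Catalytic-domain residue numbering is shifted by -97 relative to
#' full-length human MANEA numbering.
#'
#' @param pos Positive integer position(s).
#' @param direction `"domain_to_full"` (adds 97) or `"full_to_domain"`
#'   (subtracts 97).
#' @return Shifted position(s); error if any result is < 1.
#' @export
shift_numbering <- function(pos, direction = c("domain_to_full", "full_to_domain")) {
  direction <- match.arg(direction)
  stopifnot(all(pos >= 1))
  out <- if (direction == "domain_to_full") pos + DOMAIN_OFFSET else pos - DOMAIN_OFFSET
  if (any(out < 1)) {
    stop("position ", pos[which(out < 1)[1]],
         " has no counterpart in domain numbering (result < 1)")
  }
  out
}
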