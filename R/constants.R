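# Alphabet, background frequencies, substitution matrix, motif coordinates.

#' The 20 standard amino-acid one-letter codes
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# alphabet accepted in sequences: 20 standard letters plus ambiguity X
aa_alphabet <- function() c(amino_acids(), "X")

#' Background amino-acid frequencies
#'
#' Robinson & Robinson composition frequencies, renormalised to sum to 1.
#' Used as the null model for profile log-odds scores and as the sampling
#' distribution of the synthetic-sequence generator.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
aa_background <- function() {
  bg <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
          Q = 0.0426, E = 0.0632, G = 0.0738, H = 0.0219, I = 0.0514,
          L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
          S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)
  bg / sum(bg)
}

.gh99_env <- new.env(parent = emptyenv())

#' Default substitution matrix (BLOSUM62, 20 amino acids + X)
#'
#' Pulled from the matrices packaged with Biostrings and subset to the
#' alphabet this package accepts. Symmetric; X has defined scores against
#' every partner.
#'
#' @return Numeric 21 x 21 matrix with dimnames over `aa_alphabet()`.
#' @export
blosum62 <- function() {
  if (is.null(.gh99_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- aa_alphabet()
    .gh99_env$blosum62 <- unname(e$BLOSUM62)[match(ab, rownames(e$BLOSUM62)),
                                             match(ab, colnames(e$BLOSUM62))]
    dimnames(.gh99_env$blosum62) <- list(ab, ab)
  }
  .gh99_env$blosum62
}

#' Diagnostic motif positions in human MANEA numbering
#'
#' The five diagnostic spans of the GH99 catalytic domain, in full-length
#' human MANEA coordinates (1-based): the substrate-preference residue 189
#' (Tyr in endomannosidases, Trp in endomannanases), the -2 loop 195-199
#' (consensus D\[E/D\]NGE), the HxEPY motif 222-226, the conserved residue
#' 323, and the catalytic motif 404-407 (consensus EW\[H/G\]E carrying the
#' catalytic glutamates E404 and E407).
#'
#' @return Named list of integer vectors.
#' @export
motif_positions <- function() {
  list(P189 = 189L,
       LOOP = 195:199,
       HEPY = 222:226,
       P323 = 323L,
       ACTSITE = 404:407)
}

# offset between catalytic-domain numbering and full-length MANEA numbering
DOMAIN_OFFSET <- 97L

# conventional protein alignment gap penalties (subtractive; a gap of
# length k costs gap_open + k * gap_extend)
default_gap_open <- function() 11
default_gap_extend <- function() 1

#' Packaged GH99 reference sequence
#'
#' Returns the reference protein record used to anchor all coordinates.
#' The packaged default is a synthetic 462-residue stand-in for human MANEA
#' carrying the five canonical motifs at their MANEA positions (Y189,
#' 195-199 DENGE, 222-226 HIEPY, Y323, 404-407 EWHE); it preserves the
#' coordinate semantics of the real protein without shipping third-party
#' data.
#'
#' @return A one-row protein record tibble (see [read_fasta()]).
#' @export
gh99_reference <- function() {
  if (is.null(.gh99_env$reference)) {
    path <- system.file("extdata", "synthetic_manea_reference.fasta",
                        package = "gh99evo", mustWork = TRUE)
    .gh99_env$reference <- read_fasta(path)
  }
  .gh99_env$reference
}

# integer encoding: A..V -> 0..19, X -> 20 (matches src/align.cpp)
aa_encode <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], aa_alphabet()) - 1L
  if (anyNA(codes)) {
    stop("sequence contains non amino-acid letters at position ",
         which(is.na(codes))[1])
  }
  codes
}

aa_decode <- function(codes) {
  out <- rep("-", length(codes))
  ok <- codes >= 0
  out[ok] <- aa_alphabet()[codes[ok] + 1L]
  paste(out, collapse = "")
}
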