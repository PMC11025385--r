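# FASTA and taxonomy I/O with strict record validation.

validate_sequence <- function(seq, id) {
  if (nchar(seq) == 0) stop("empty sequence for record '", id, "'")
  # terminal stop codons from translated transcripts are tolerated
  seq <- sub("\\*$", "", seq)
  if (nchar(seq) == 0) stop("empty sequence for record '", id, "'")
  bad <- regexpr(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), seq)
  if (bad > 0) {
    stop("illegal character '", substr(seq, bad, bad), "' at position ",
         bad, " in record '", id, "'")
  }
  seq
}

#' Read protein records from a FASTA file
#'
#' The id is the header token before the first whitespace. A `species=` key
#' in the remaining header text sets the species (its value runs to the end
#' of the header); other header text is ignored.
#' Sequences are upper-cased; a single terminal `*` is stripped; any other
#' non amino-acid character (outside the 20 standard letters and X) is an
#' error reporting its position.
#'
#' @param path Path to a FASTA file (wrapped lines allowed).
#' @return A tibble with columns `id`, `sequence`, `species` (NA when no
#'   `species=` key is present), one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(ids == "")) stop("FASTA header with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate record id '", dup[1], "'")
  species <- rep(NA_character_, length(ids))
  has <- grepl("species=", headers, fixed = TRUE)
  vals <- trimws(sub("^.*species=", "", headers[has]))
  species[has] <- ifelse(nzchar(vals), vals, NA_character_)
  seqs <- toupper(as.character(set))
  seqs <- vapply(seq_along(seqs), function(i) validate_sequence(seqs[i], ids[i]),
                 character(1))
  tibble::tibble(id = unname(ids), sequence = unname(seqs),
                 species = unname(species))
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id species=<species>` when a
#' species is recorded, else just `id`.
#'
#' @param records Protein record tibble (`id`, `sequence`, optional `species`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    sp <- if ("species" %in% names(records)) records$species[i] else NA
    hdr <- if (!is.na(sp)) paste0(">", records$id[i], " species=", sp)
           else paste0(">", records$id[i])
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(hdr, substring(s, starts, pmin(starts + width - 1, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read a species-to-clade-path taxonomy table
#'
#' Tab-separated file with columns `species`, `clade_path`
#' (semicolon-separated, root first) and an optional logical `searched`
#' column marking species that were actually surveyed (defaults to TRUE).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `species`, `clade_path` (list of character
#'   vectors) and `searched`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("species", "clade_path") %in% names(df))) {
    stop("taxonomy file must have columns 'species' and 'clade_path'")
  }
  dup <- df$species[duplicated(df$species)]
  if (length(dup)) stop("repeated species row '", dup[1], "'")
  paths <- strsplit(df$clade_path, ";", fixed = TRUE)
  paths <- lapply(paths, function(p) trimws(p[nzchar(trimws(p))]))
  empty <- lengths(paths) == 0
  if (any(empty)) stop("empty clade path for species '", df$species[empty][1], "'")
  searched <- if ("searched" %in% names(df)) as.logical(df$searched) else TRUE
  tibble::tibble(species = df$species, clade_path = paths,
                 searched = rep_len(searched, nrow(df)))
}

#' Write a taxonomy table to TSV
#' @param tax Taxonomy tibble as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  df <- data.frame(species = tax$species,
                   clade_path = vapply(tax$clade_path, paste, character(1),
                                       collapse = ";"),
                   searched = tax$searched)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Species universe counts per clade
#'
#' For every clade name occurring in any path, the number of distinct
#' searched species whose clade path contains that clade. Counts are
#' monotone: an ancestor clade's count is at least each descendant's.
#'
#' @param tax Taxonomy tibble.
#' @return Tibble with columns `clade` and `n_species`.
#' @export
clade_universe <- function(tax) {
  use <- tax[tax$searched, , drop = FALSE]
  long <- data.frame(
    clade = unlist(use$clade_path),
    species = rep(use$species, lengths(use$clade_path)))
  long <- unique(long)
  agg <- stats::aggregate(species ~ clade, long, length)
  tibble::tibble(clade = agg$clade, n_species = agg$species)
}
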