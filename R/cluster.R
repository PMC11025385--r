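# Greedy identity clustering with cd-hit semantics.

#' Greedy incremental identity clustering
#'
#' Re-implements the clustering semantics of cd-hit run with
#' `-c <c> -s <s> -g 1`: records are sorted by length descending (ties by
#' id ascending) and processed in order. Each record joins the best
#' eligible existing cluster — the representative with the highest
#' identity, provided that identity is at least `c` and the record's
#' length is at least `s` times the representative's length — otherwise it
#' founds a new cluster as representative. Identity is computed from a full
#' global alignment as matches / length of the shorter sequence (cd-hit's
#' short-word heuristic is an accelerator, not part of the definition, and
#' is not reproduced). Ties between equally good clusters go to the
#' representative with the lexicographically smallest id. The sort rule
#' makes the result invariant to input order.
#'
#' @param records Protein record tibble.
#' @param c Identity threshold in (0, 1]; default 0.95.
#' @param s Length-difference cutoff in (0, 1]; default 0.5.
#' @param ... Passed to [global_align()].
#' @return Object of class `cluster_assignment`: tibble with columns
#'   `cluster_id`, `representative`, `member`, `identity` (1 for the
#'   representative itself); attributes `c` and `s`.
#' @export
greedy_cluster <- function(records, c = 0.95, s = 0.5, ...) {
  stopifnot(c > 0, c <= 1, s > 0, s <= 1)
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, , drop = FALSE]
  rep_id <- character(0)
  rep_seq <- character(0)
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    id_i <- recs$id[i]
    seq_i <- recs$sequence[i]
    best <- NA_integer_
    best_ident <- -Inf
    eligible <- which(nchar(seq_i) >= s * nchar(rep_seq))
    for (k in eligible) {
      ident <- global_align(seq_i, rep_seq[k], ...)$identity_shorter
      if (ident >= c &&
          (ident > best_ident ||
           (ident == best_ident && rep_id[k] < rep_id[best]))) {
        best <- k
        best_ident <- ident
      }
    }
    if (is.na(best)) {
      rep_id <- c(rep_id, id_i)
      rep_seq <- c(rep_seq, seq_i)
      rows[[i]] <- tibble::tibble(representative = id_i, member = id_i,
                                  identity = 1)
    } else {
      rows[[i]] <- tibble::tibble(representative = rep_id[best],
                                  member = id_i, identity = best_ident)
    }
  }
  out <- do.call(rbind, rows)
  cluster_id <- match(out$representative, rep_id)
  out <- tibble::tibble(cluster_id = cluster_id, out)
  out <- out[order(out$cluster_id, out$member != out$representative, out$member), ]
  structure(out, class = c("cluster_assignment", class(out)), c = c, s = s)
}

#' Cluster representatives
#' @param assignment A `cluster_assignment`.
#' @return Character vector of representative ids, one per cluster.
#' @export
cluster_representatives <- function(assignment) {
  unique(assignment$representative)
}

#' Write a cluster assignment as TSV
#' @param assignment A `cluster_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
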