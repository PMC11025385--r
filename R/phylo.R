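# Pairwise distances, neighbor joining, and phylogeny-based decontamination.

#' Pairwise alignment distance matrix
#'
#' `d = 1 - fractional identity` where identity is computed over aligned
#' columns (matches / alignment length) of the global pairwise alignment.
#' Each pair is aligned once; the matrix is symmetric with a zero diagonal.
#'
#' @param records Protein record tibble with >= 3 rows.
#' @param ... Passed to [global_align()].
#' @return Symmetric numeric matrix with record ids as dimnames.
#' @export
pairwise_distance <- function(records, ...) {
  n <- nrow(records)
  if (n < 3) stop("need at least 3 records for a distance matrix")
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- 1 - global_align(records$sequence[i], records$sequence[j],
                            ...)$identity_columns
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Saitou-Nei with the usual Q criterion and
#' branch-length formulas), exact on additive distance matrices. Ties in
#' the Q criterion are broken deterministically by the lexicographically
#' smallest pair of subtree labels. Negative branch lengths are clamped to
#' zero and counted in the `clamped` attribute.
#'
#' @param D Symmetric distance matrix with labelled rows/columns, n >= 3.
#' @return An unrooted `ape::phylo` tree; attribute `clamped` gives the
#'   number of negative branch lengths set to zero.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) stop("distance matrix must have row labels")
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  # active nodes held as newick fragments; first-leaf label used for tie-breaks
  sub <- as.list(labels)
  first_leaf <- labels
  D <- unname(D)
  while (length(sub) > 3) {
    m <- length(sub)
    r <- rowSums(D)
    # Q(i,j) = (m-2) d(i,j) - r_i - r_j
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        key <- sort(c(first_leaf[i], first_leaf[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(q = q, i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    bi <- cl(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- cl(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_sub <- sprintf("(%s:%.10g,%s:%.10g)", sub[[i]], bi, sub[[j]], bj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], new_sub)
    first_leaf <- c(first_leaf[keep], min(best$key))
    D <- D2
  }
  # final three-point join
  b1 <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 sub[[1]], b1, sub[[2]], b2, sub[[3]], b3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# tip sets of every node of a rooted tree, indexed by node number
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", max(tree$edge))
  for (t in seq_len(n_tip)) desc[[t]] <- t
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    nd <- ord$edge[e, 1]
    desc[[nd]] <- c(desc[[nd]], desc[[ord$edge[e, 2]]])
  }
  desc
}

# ancestor chain (node numbers, nearest first) of a tip in a rooted tree
ancestor_chain <- function(tree, tip) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  chain <- integer(0)
  nd <- tip
  while (parent[nd] != 0) {
    nd <- parent[nd]
    chain <- c(chain, nd)
  }
  chain
}

#' Flag contaminant leaves by taxonomic incongruence
#'
#' Operationalizes phylogeny-based decontamination for transcriptome-mixed
#' data sets: per round, a neighbor-joining tree is built from the current
#' distance matrix and midpoint-rooted, and a leaf is flagged when its
#' smallest enclosing clade with at least `k` leaves (walking up its
#' ancestor chain) has a majority taxogroup — taken at depth `level` of
#' the clade path — different from the leaf's own, and the leaf's group is
#' a strict minority there. Midpoint rooting makes "enclosing clade" well
#' defined and keeps a long-branch foreign clade from polluting the
#' neighborhoods of the leaves it happens to attach next to. As a
#' safeguard, a round never removes every member of a taxogroup with at
#' least `k` leaves. Flagged leaves are removed, the matrix is subset, the
#' tree rebuilt; rounds stop when nothing is flagged or `max_rounds` is
#' reached, which makes the procedure idempotent on the surviving set.
#'
#' @param D Symmetric distance matrix over record ids.
#' @param tax Taxonomy tibble (see [read_taxonomy()]); the join is by
#'   species name in `species_of`, or by id when `species_of` is NULL and
#'   ids are species names.
#' @param species_of Named character vector mapping record id -> species;
#'   NULL means ids are used directly.
#' @param k Minimum enclosing-clade size (default 3).
#' @param level Clade-path depth at which taxogroups are compared
#'   (default 1, the top taxogroup).
#' @param max_rounds Maximum decontamination rounds (default 5).
#' @return Object of class `contamination_report`: list with `flagged`
#'   (tibble: id, round, leaf_group, majority_group, clade_size),
#'   `surviving` ids, `rounds` run, and `criterion` metadata describing
#'   the rule (this rule is this package's explicit operationalization;
#'   sources describing decontamination rarely define one).
#' @export
flag_contaminants <- function(D, tax, species_of = NULL, k = 3, level = 1,
                              max_rounds = 5) {
  ids <- rownames(D)
  sp <- if (is.null(species_of)) setNames(ids, ids) else species_of[ids]
  miss <- ids[!(sp %in% tax$species)]
  if (length(miss)) stop("leaf '", miss[1], "' is missing from the taxonomy")
  group_of <- vapply(sp, function(s) {
    p <- tax$clade_path[[match(s, tax$species)]]
    p[min(level, length(p))]
  }, character(1))
  names(group_of) <- ids
  flagged <- list()
  current <- ids
  round <- 0L
  repeat {
    round <- round + 1L
    tree <- neighbor_joining(D[current, current, drop = FALSE])
    tree <- phangorn::midpoint(tree)
    tips <- tree$tip.label
    grp <- group_of[tips]
    tip_sets <- node_tip_sets(tree)
    n_tip <- length(tips)
    this_round <- character(0)
    detail <- list()
    for (t in seq_len(n_tip)) {
      # smallest ancestor clade holding at least k leaves
      best_set <- NULL
      for (anc in ancestor_chain(tree, t)) {
        if (length(tip_sets[[anc]]) >= k) {
          best_set <- tip_sets[[anc]]
          break
        }
      }
      if (is.null(best_set)) next
      tab <- sort(table(grp[best_set]), decreasing = TRUE)
      maj <- names(tab)[1]
      own <- grp[t]
      if (maj != own && (!own %in% names(tab) || tab[[own]] < tab[[1]])) {
        this_round <- c(this_round, tips[t])
        detail[[tips[t]]] <- tibble::tibble(
          id = tips[t], round = round, leaf_group = unname(own),
          majority_group = maj, clade_size = length(best_set))
      }
    }
    # safeguard: never wipe out a taxogroup that has >= k leaves
    for (g in unique(grp[this_round])) {
      members <- tips[grp == g]
      if (length(members) >= k && all(members %in% this_round)) {
        this_round <- setdiff(this_round, members)
        detail[members] <- NULL
      }
    }
    if (length(this_round) == 0 || length(current) - length(this_round) < 3) break
    flagged <- c(flagged, detail)
    current <- setdiff(current, this_round)
    if (round >= max_rounds) break
  }
  structure(list(
    flagged = if (length(flagged)) do.call(rbind, unname(flagged))
              else tibble::tibble(id = character(0), round = integer(0),
                                  leaf_group = character(0),
                                  majority_group = character(0),
                                  clade_size = integer(0)),
    surviving = current,
    rounds = round,
    criterion = paste("minority leaf in smallest enclosing clade of >=", k,
                      "leaves (midpoint-rooted NJ tree) whose majority",
                      "taxogroup (clade-path depth", level,
                      ") differs; package-defined rule")),
    class = "contamination_report")
}

#' Write a contamination report as TSV
#' @param report A `contamination_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contamination_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report$flagged), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
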