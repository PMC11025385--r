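# Independent oracles used across the suite.

# Brute-force affine-gap global alignment score by plain enumeration of
# every gapped alignment (no dynamic programming). A gap run of length k
# costs go + k * ge. Feasible for lengths up to ~6.
bf_align_score <- function(a, b, S, go, ge) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- ge + if (last != "X") go else 0
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- ge + if (last != "Y") go else 0
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# re-score an alignment's gapped strings under the affine model; checks the
# reported score is consistent with the returned alignment
rescore_alignment <- function(aln, S) {
  av <- strsplit(aln$aligned_a, "")[[1]]
  bv <- strsplit(aln$aligned_b, "")[[1]]
  score <- 0
  last <- "M"
  for (k in seq_along(av)) {
    if (av[k] == "-" ) {
      score <- score - aln$gap_extend - if (last != "Y") aln$gap_open else 0
      last <- "Y"
    } else if (bv[k] == "-") {
      score <- score - aln$gap_extend - if (last != "X") aln$gap_open else 0
      last <- "X"
    } else {
      score <- score + S[av[k], bv[k]]
      last <- "M"
    }
  }
  score
}

random_seq <- function(len, alphabet = c("A", "R", "N", "D")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# additive distance matrix from a random tree with positive branch lengths
random_additive <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# small fixed cohort used by several suites
toy_records <- function() {
  tibble::tibble(
    id = c("r1", "r2", "r3"),
    sequence = c("MKTAYIAKQR", "MKTAYIAKQR", "MKTWYIGKQR"),
    species = c("Homo sapiens", "Mus musculus", "Danio rerio"))
}

toy_taxonomy <- function() {
  tibble::tibble(
    species = c("Homo sapiens", "Mus musculus", "Danio rerio"),
    clade_path = list(c("Opisthokonta", "Metazoa", "Mammalia"),
                      c("Opisthokonta", "Metazoa", "Mammalia"),
                      c("Opisthokonta", "Metazoa", "Actinopterygii")),
    searched = TRUE)
}
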