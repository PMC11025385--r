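# Synthetic GH99-like cohort generator with planted ground truth.

#' Specify one synthetic subfamily
#'
#' @param name Subfamily name (e.g. `"MANEA"`).
#' @param n Number of emitted records.
#' @param divergence Per-site substitution probability applied along each
#'   edge of the subfamily tree (with the default depth-1 star, the total
#'   per-site divergence of every leaf from the subfamily ancestor).
#' @param taxogroup Taxogroup label given to the subfamily's species.
#' @param p189,p197 Planted residues at reference positions 189 and 197.
#' @param actsite Planted 404-407 string (e.g. `"EWHE"`, `"QWHE"` for the
#'   E404Q variant, `"KWHE"`).
#' @return A subfamily specification list.
#' @export
subfamily_spec <- function(name, n, divergence = 0.15, taxogroup = name,
                           p189 = "Y", p197 = "N", actsite = "EWHE") {
  stopifnot(n >= 0, divergence >= 0, divergence <= 1,
            nchar(p189) == 1, nchar(p197) == 1, nchar(actsite) == 4)
  list(name = name, n = n, divergence = divergence, taxogroup = taxogroup,
       p189 = p189, p197 = p197, actsite = actsite)
}

#' Simulation configuration
#'
#' Defaults describe the three-ohnolog study condition: three subfamilies
#' of 100 records each descended from one root (the packaged reference),
#' subfamily ancestors diverged from the root at 0.25 per site, leaves
#' diverged 0.15 per site from their ancestor on a depth-1 star, MANEA and
#' MANEAL with the canonical Y189 / N197 / EWHE states and CMANEAL with
#' its two hallmark substitutions N197H and E404Q.
#'
#' @param subfamilies List of [subfamily_spec()]s.
#' @param seed Mandatory integer seed; every stochastic run must set one.
#' @param root Root sequence (default: packaged reference sequence).
#' @param p_ancestor Per-site substitution probability on each root ->
#'   subfamily-ancestor edge.
#' @param depth Balanced tree depth within a subfamily (default 1: a star;
#'   the per-edge probability is the subfamily `divergence`).
#' @param contaminants List with `count`, `subfamily` (the true subfamily
#'   the sequences are generated in) and `taxogroup` (the wrong label they
#'   carry), or NULL.
#' @param indels If TRUE, each leaf suffers one geometric-length deletion
#'   at a uniform position (stress testing only; reference mapping is then
#'   no longer exact).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(subfamilies = list(
                                subfamily_spec("MANEA", 100),
                                subfamily_spec("MANEAL", 100),
                                subfamily_spec("CMANEAL", 100, p197 = "H",
                                               actsite = "QWHE")),
                              seed,
                              root = NULL,
                              p_ancestor = 0.25,
                              depth = 1L,
                              contaminants = NULL,
                              indels = FALSE) {
  if (missing(seed)) stop("a seed is mandatory for any stochastic run")
  if (is.null(root)) root <- gh99_reference()$sequence[1]
  stopifnot(p_ancestor >= 0, p_ancestor <= 1, depth >= 1)
  structure(list(subfamilies = subfamilies, seed = as.integer(seed),
                 root = root, p_ancestor = p_ancestor,
                 depth = as.integer(depth),
                 contaminants = contaminants, indels = indels),
            class = "sim_config")
}

# substitute each site independently with probability p, drawing the
# replacement uniformly from the 19 other letters
mutate_sequence <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    aa <- amino_acids()
    for (i in hit) {
      alt <- aa[aa != chars[i]]
      chars[i] <- alt[sample.int(19L, 1L)]
    }
  }
  chars
}

plant_states <- function(chars, spec) {
  mp <- motif_positions()
  chars[mp$P189] <- spec$p189
  chars[mp$LOOP[3]] <- spec$p197 # position 197
  chars[mp$ACTSITE] <- strsplit(spec$actsite, "")[[1]]
  chars
}

evolve_leaves <- function(anc_chars, n, p, depth) {
  if (depth == 1L) {
    return(lapply(seq_len(n), function(i) mutate_sequence(anc_chars, p)))
  }
  # balanced binary tree: evolve down levels, then take the first n leaves
  level <- list(anc_chars)
  for (d in seq_len(depth)) {
    level <- unlist(lapply(level, function(ch) {
      list(mutate_sequence(ch, p), mutate_sequence(ch, p))
    }), recursive = FALSE)
    if (length(level) >= n && d == depth) break
  }
  level[seq_len(min(n, length(level)))]
}

#' Simulate a GH99-like cohort with planted truth
#'
#' Evolves the root along the configured trees (each site substitutes
#' independently with the edge probability, replacement uniform over the
#' 19 alternatives), then writes the planted motif states onto their
#' positions so ground truth is guaranteed, and finally emits any
#' contaminants: sequences generated inside their true subfamily but
#' labelled with the wrong taxogroup. Fully reproducible for a given seed.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List with `records` (protein record tibble), `taxonomy`
#'   (taxonomy tibble: clade path `taxogroup;species`), and `truth`
#'   (tibble: id, subfamily, taxogroup label, true taxogroup, contaminant
#'   flag, planted states).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  root_chars <- strsplit(config$root, "")[[1]]
  recs <- list()
  truth <- list()
  taxonomy <- list()
  emit <- function(chars, id, species, taxogroup, subfam, true_group,
                   contaminant, spec) {
    chars <- plant_states(chars, spec)
    if (isTRUE(config$indels)) {
      len <- stats::rgeom(1, 0.5) + 1L
      at <- sample.int(length(chars) - len, 1L)
      chars <- chars[-(at:(at + len - 1L))]
    }
    recs[[id]] <<- tibble::tibble(id = id, sequence = paste(chars, collapse = ""),
                                  species = species)
    taxonomy[[id]] <<- tibble::tibble(species = species,
                                      clade_path = list(c(taxogroup, species)),
                                      searched = TRUE)
    truth[[id]] <<- tibble::tibble(id = id, subfamily = subfam,
                                   taxogroup = taxogroup,
                                   true_taxogroup = true_group,
                                   contaminant = contaminant,
                                   planted_p189 = spec$p189,
                                   planted_p197 = spec$p197,
                                   planted_actsite = spec$actsite)
  }
  ancestors <- list()
  for (spec in config$subfamilies) {
    anc <- mutate_sequence(root_chars, config$p_ancestor)
    ancestors[[spec$name]] <- anc
    leaves <- evolve_leaves(anc, spec$n, spec$divergence, config$depth)
    for (i in seq_along(leaves)) {
      id <- sprintf("%s_%03d", spec$name, i)
      species <- sprintf("%s sp. %03d", spec$name, i)
      emit(leaves[[i]], id, species, spec$taxogroup, spec$name,
           spec$taxogroup, FALSE, spec)
    }
  }
  cont <- config$contaminants
  if (!is.null(cont) && cont$count > 0) {
    spec <- NULL
    for (s in config$subfamilies) if (s$name == cont$subfamily) spec <- s
    if (is.null(spec)) stop("contaminant subfamily '", cont$subfamily,
                            "' is not configured")
    anc <- ancestors[[spec$name]]
    for (i in seq_len(cont$count)) {
      id <- sprintf("contam_%03d", i)
      species <- sprintf("%s sp. c%02d", cont$taxogroup, i)
      emit(mutate_sequence(anc, spec$divergence), id, species,
           cont$taxogroup, spec$name, spec$taxogroup, TRUE, spec)
    }
  }
  list(records = do.call(rbind, unname(recs)),
       taxonomy = do.call(rbind, unname(taxonomy)),
       truth = do.call(rbind, unname(truth)))
}
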