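make_cohort <- function() {
  # 3 searched species, two of which have records; one species has 5 records
  # falling into 2 clusters; the mouse sequence is distinct enough (< 95%)
  # to keep its own cluster representative
  recs <- tibble::tibble(
    id = c(sprintf("hs%d", 1:5), "mm1"),
    sequence = c(rep("MKTAYIAKQRQISFVKSHFSRQ", 3),
                 rep("WHEDCNGPSVDELMNKWHEDCN", 2),
                 "MKTAYIAKQRWISFVKAHFSSQ"),
    species = c(rep("Homo sapiens", 5), "Mus musculus"))
  tax <- tibble::tibble(
    species = c("Homo sapiens", "Mus musculus", "Danio rerio"),
    clade_path = list(c("Metazoa", "Mammalia"), c("Metazoa", "Mammalia"),
                      c("Metazoa", "Actinopterygii")),
    searched = TRUE)
  list(recs = recs, tax = tax)
}

test_that("presence/absence counts species once and fractions correctly", {
  x <- make_cohort()
  cl <- greedy_cluster(x$recs, c = 0.95)
  pa <- presence_absence(cl, x$recs, x$tax, c("Metazoa", "Mammalia"))
  expect_equal(pa$species_searched, c(3L, 2L))
  expect_equal(pa$species_with_hit, c(2L, 2L))
  expect_equal(pa$fraction, c(2 / 3, 1))
  expect_false(any(pa$universe_unknown))
  expect_error(presence_absence(cl, x$recs, x$tax, "Cnidaria"),
               "absent from taxonomy")
})

test_that("unknown universes are flagged, not fractioned", {
  x <- make_cohort()
  x$tax$searched <- c(FALSE, FALSE, TRUE) # mammals present but never searched
  cl <- greedy_cluster(x$recs, c = 0.95)
  pa <- presence_absence(cl, x$recs, x$tax, "Mammalia")
  expect_true(pa$universe_unknown)
  expect_true(is.na(pa$fraction))
  expect_equal(pa$species_with_hit, 2L)
})

test_that("prevalence equals a brute-force tally on a synthetic cohort", {
  cfg <- simulation_config(subfamilies = list(
    subfamily_spec("G1", 8, divergence = 0.03),
    subfamily_spec("G2", 6, divergence = 0.03)), seed = 83)
  sim <- simulate_family(cfg)
  cl <- greedy_cluster(sim$records, c = 0.95)
  pa <- presence_absence(cl, sim$records, sim$taxonomy, c("G1", "G2"))
  reps <- cluster_representatives(cl)
  rep_species <- sim$records$species[match(reps, sim$records$id)]
  for (g in c("G1", "G2")) {
    in_g <- vapply(sim$taxonomy$clade_path, function(p) g %in% p, logical(1))
    expect_equal(pa$species_with_hit[pa$clade == g],
                 length(intersect(rep_species, sim$taxonomy$species[in_g])))
    expect_equal(pa$species_searched[pa$clade == g], sum(in_g))
  }
  # clustering can only lower with-hit counts relative to raw records
  raw_hits <- length(unique(sim$records$species))
  expect_lte(sum(pa$species_with_hit), raw_hits)
})

test_that("residue composition percentages and undetermined handling", {
  ref <- gh99_reference()$sequence
  put189 <- function(ch) {
    chars <- strsplit(ref, "")[[1]]; chars[189] <- ch
    paste(chars, collapse = "")
  }
  recs <- tibble::tibble(
    id = sprintf("r%d", 1:5),
    sequence = c(put189("Y"), put189("Y"), put189("Y"), put189("W"),
                 substr(ref, 300, 462)), # truncated: 189 missing
    species = sprintf("Sp %d", 1:5))
  tax <- tibble::tibble(species = recs$species,
                        clade_path = lapply(recs$species,
                                            function(s) c("CladeZ", s)),
                        searched = TRUE)
  ann <- annotate_cohort(recs)
  comp <- residue_composition(ann, recs, tax, "CladeZ", 189L)
  expect_equal(comp$count[comp$residue == "Y"], 3L)
  expect_equal(comp$percent[comp$residue == "Y"], 75.0)
  expect_equal(comp$percent[comp$residue == "W"], 25.0)
  expect_true(is.na(comp$percent[comp$residue == "?"]))
  # all-undetermined clade: counts but no percentages
  recs2 <- recs[5, ]
  tax2 <- tax[5, ]
  comp2 <- residue_composition(annotate_cohort(recs2), recs2, tax2,
                               "CladeZ", 189L)
  expect_true(all(is.na(comp2$percent)))
  # positions must fall inside a diagnostic motif
  expect_error(residue_composition(ann, recs, tax, "CladeZ", 200L),
               "not inside")
})

test_that("composition is invariant to record order", {
  cfg <- simulation_config(subfamilies = list(
    subfamily_spec("G", 6, p189 = "W"),
    subfamily_spec("G2", 3, taxogroup = "G", p189 = "Y")), seed = 97)
  sim <- simulate_family(cfg)
  ann <- annotate_cohort(sim$records)
  c1 <- residue_composition(ann, sim$records, sim$taxonomy, "G", 189L)
  ord <- rev(seq_len(nrow(ann)))
  c2 <- residue_composition(ann[ord, ], sim$records, sim$taxonomy, "G", 189L)
  expect_equal(c1, c2)
  expect_equal(c1$percent[c1$residue == "W"], round(100 * 6 / 9, 1))
})
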