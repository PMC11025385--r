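test_that("pairwise distances: closed forms and recompute oracle", {
  recs <- tibble::tibble(
    id = c("same1", "same2", "diff"),
    sequence = c("MKTAYIAKQR", "MKTAYIAKQR", "WHEDCNGPSV"),
    species = NA_character_)
  D <- pairwise_distance(recs)
  expect_equal(D["same1", "same2"], 0)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_true(isSymmetric(D))
  expect_error(pairwise_distance(recs[1:2, ]), "at least 3")

  set.seed(31)
  rand <- tibble::tibble(
    id = sprintf("r%d", 1:5),
    sequence = vapply(1:5, function(i) random_seq(40, amino_acids()), ""),
    species = NA_character_)
  D5 <- pairwise_distance(rand)
  for (i in 1:4) for (j in (i + 1):5) {
    aln <- global_align(rand$sequence[i], rand$sequence[j])
    expect_equal(D5[i, j], 1 - aln$identity_columns)
  }
})

test_that("three-taxon NJ matches the closed-form star", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers a constructed additive four-taxon tree exactly", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  D <- ape::cophenetic.phylo(true)
  tr <- neighbor_joining(D)
  expect_true(same_unrooted_topology(tr, true))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
})

test_that("NJ is exact on seeded additive matrices and agrees with ape", {
  set.seed(47)
  for (rep in 1:15) {
    inst <- random_additive(sample(5:8, 1))
    tr <- neighbor_joining(inst$D)
    expect_true(same_unrooted_topology(tr, inst$tree))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(inst$D), colnames(inst$D)],
                 inst$D, tolerance = 1e-8)
    # independent implementation oracle on the same matrix
    expect_true(same_unrooted_topology(tr, ape::nj(inst$D)))
  }
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2)), "symmetric|3 taxa")
})

test_that("NJ agrees with exhaustive least-squares topology search", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (rep in 1:5) {
    inst <- random_additive(5)
    tr <- neighbor_joining(inst$D)
    topos <- phangorn::allTrees(5, rooted = FALSE,
                                tip.label = rownames(inst$D))
    ss <- vapply(topos, function(tp) {
      fit <- phangorn::nnls.tree(inst$D, tp, method = "unrooted")
      sum((ape::cophenetic.phylo(fit)[rownames(inst$D), colnames(inst$D)]
           - inst$D)^2)
    }, numeric(1))
    best <- topos[[which.min(ss)]]
    expect_true(same_unrooted_topology(tr, best))
  }
})

test_that("homogeneous and well-separated cohorts are never flagged", {
  cfg <- simulation_config(subfamilies = list(
    subfamily_spec("A", 6, divergence = 0.08)), seed = 61)
  sim <- simulate_family(cfg)
  D <- pairwise_distance(sim$records)
  rep1 <- flag_contaminants(D, sim$taxonomy,
                            species_of = setNames(sim$records$species,
                                                  sim$records$id))
  expect_equal(nrow(rep1$flagged), 0)
  expect_equal(rep1$rounds, 1)

  cfg2 <- simulation_config(subfamilies = list(
    subfamily_spec("A", 5, divergence = 0.05),
    subfamily_spec("B", 5, divergence = 0.05)), seed = 67)
  sim2 <- simulate_family(cfg2)
  D2 <- pairwise_distance(sim2$records)
  for (k in c(2, 3, 4)) {
    rep2 <- flag_contaminants(D2, sim2$taxonomy, k = k,
                              species_of = setNames(sim2$records$species,
                                                    sim2$records$id))
    expect_equal(nrow(rep2$flagged), 0, info = paste("k =", k))
  }
})

test_that("a planted cross-group contaminant is flagged, and only it", {
  cfg <- simulation_config(
    subfamilies = list(subfamily_spec("A", 11, divergence = 0.08),
                       subfamily_spec("B", 6, divergence = 0.08)),
    contaminants = list(count = 1, subfamily = "A", taxogroup = "B"),
    seed = 71)
  sim <- simulate_family(cfg)
  D <- pairwise_distance(sim$records)
  rep <- flag_contaminants(D, sim$taxonomy, k = 3,
                           species_of = setNames(sim$records$species,
                                                 sim$records$id))
  expect_equal(rep$flagged$id, "contam_001")
  expect_equal(rep$flagged$leaf_group, "B")
  expect_equal(rep$flagged$majority_group, "A")
  # idempotence: rerun on the survivors flags nothing
  surv <- rep$surviving
  rep2 <- flag_contaminants(D[surv, surv], sim$taxonomy, k = 3,
                            species_of = setNames(sim$records$species,
                                                  sim$records$id))
  expect_equal(nrow(rep2$flagged), 0)
})

test_that("missing taxonomy entries name the offending leaf", {
  cfg <- simulation_config(subfamilies = list(
    subfamily_spec("A", 4, divergence = 0.05)), seed = 73)
  sim <- simulate_family(cfg)
  D <- pairwise_distance(sim$records)
  tax <- sim$taxonomy[-2, ]
  expect_error(flag_contaminants(D, tax,
                                 species_of = setNames(sim$records$species,
                                                       sim$records$id)),
               sim$records$id[2])
})
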