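test_that("profile log-odds match the hand-computed single column", {
  # column {E,E,E,Q}, alpha = 0, uniform background:
  # score(E) = log2(0.75 / 0.05)
  q <- setNames(rep(0.05, 20), amino_acids())
  counts <- c(E = 3, Q = 1)
  n <- 4
  score_e <- log2(((counts[["E"]] + 0) / (n + 0)) / q[["E"]])
  expect_equal(score_e, log2(15))
  # through build_profile on a toy reference of 98 + 1 positions
  ref <- paste(c(rep("A", 97), "E"), collapse = "")
  seeds <- tibble::tibble(id = paste0("s", 1:4),
                          sequence = c(rep(ref, 3), sub("E$", "Q", ref)),
                          species = NA_character_)
  m <- build_profile(seeds, "toy", alpha = 0, background = q, reference = ref)
  expect_equal(nrow(m$scores), 1)
  expect_equal(m$scores["98", "E"], log2(15))
  expect_equal(m$scores["98", "Q"], log2(5))
})

test_that("identical seeds put the modal residue on top everywhere", {
  ref <- gh99_reference()
  seeds <- tibble::tibble(id = c("a", "b"),
                          sequence = rep(ref$sequence, 2),
                          species = NA_character_)
  m <- build_profile(seeds, "self", alpha = 1)
  chars <- strsplit(ref$sequence, "")[[1]][m$span]
  top <- colnames(m$scores)[apply(m$scores, 1, which.max)]
  expect_equal(top, chars)
  expect_true(all(is.finite(m$scores)))
  expect_error(build_profile(seeds[1, ], "one"), "at least 2")
})

test_that("large pseudocount drives all scores to zero", {
  ref <- gh99_reference()
  seeds <- tibble::tibble(id = c("a", "b"), sequence = rep(ref$sequence, 2),
                          species = NA_character_)
  m <- build_profile(seeds, "flat", alpha = 1e7)
  expect_lt(max(abs(m$scores)), 1e-4)
})

test_that("scoring favours the home profile and tolerates X", {
  cfg <- simulation_config(subfamilies = list(
    subfamily_spec("A", 6, divergence = 0.1),
    subfamily_spec("B", 6, divergence = 0.1)), seed = 91)
  sim <- simulate_family(cfg)
  recs <- function(g) sim$records[sim$truth$subfamily == g, ]
  mA <- build_profile(recs("A"), "A")
  mB <- build_profile(recs("B"), "B")
  seedA <- recs("A")[1, ]
  expect_gt(score_profile(mA, seedA), score_profile(mB, seedA))
  # all-X record scores the X policy (0 per position minus end gaps), finite
  xrec <- paste(rep("X", 50), collapse = "")
  sx <- score_profile(mA, xrec)
  expect_true(is.finite(sx))
  # score ignores metadata
  expect_equal(score_profile(mA, seedA),
               score_profile(mA, seedA$sequence))
})

test_that("classification labels, margins and delta invariances", {
  cfg <- simulation_config(subfamilies = list(
    subfamily_spec("MANEA", 10, divergence = 0.1),
    subfamily_spec("MANEAL", 10, divergence = 0.1),
    subfamily_spec("CMANEAL", 10, divergence = 0.1, p197 = "H",
                   actsite = "QWHE")), seed = 17)
  sim <- simulate_family(cfg)
  recs <- function(g) sim$records[sim$truth$subfamily == g, ]
  models <- lapply(c("MANEA", "MANEAL", "CMANEAL"),
                   function(g) build_profile(recs(g)[1:5, ], g))
  # held-in self-consistency at delta = 0
  for (g in c("MANEA", "MANEAL", "CMANEAL")) {
    for (i in 1:5) {
      expect_equal(classify_ohnolog(recs(g)$sequence[i], models, delta = 0)$label, g)
    }
  }
  # raising delta can only move labels to unclassified
  held_out <- do.call(rbind, lapply(c("MANEA", "MANEAL", "CMANEAL"),
                                    function(g) recs(g)[6:10, ]))
  lo <- classify_cohort(held_out, models, delta = 0)
  hi <- classify_cohort(held_out, models, delta = 8)
  changed <- lo$label != hi$label
  expect_true(all(hi$label[changed] == "unclassified"))
  # score differences invariant to a constant added to every position
  shifted <- models
  shifted[[1]]$scores <- shifted[[1]]$scores + 3
  rec1 <- held_out$sequence[1]
  d0 <- classify_ohnolog(rec1, models)$scores
  d1 <- classify_ohnolog(rec1, shifted)$scores
  expect_equal(d1[["MANEA"]] - d0[["MANEA"]] > 0, TRUE)
  expect_equal(d1[["MANEAL"]], d0[["MANEAL"]])
})

test_that("ties are unclassified at any positive delta", {
  ref <- gh99_reference()
  seeds <- tibble::tibble(id = c("a", "b"), sequence = rep(ref$sequence, 2),
                          species = NA_character_)
  m1 <- build_profile(seeds, "M1")
  m2 <- build_profile(seeds, "M2") # identical scores, different name
  m3 <- build_profile(seeds, "M3")
  m3$scores <- m3$scores - 1
  cl <- classify_ohnolog(ref$sequence, list(m1, m2, m3), delta = 0.01)
  expect_equal(cl$label, "unclassified")
  expect_equal(cl$margin, 0)
})

test_that("profile JSON serialization round-trips the scores", {
  ref <- gh99_reference()
  seeds <- tibble::tibble(id = c("a", "b"), sequence = rep(ref$sequence, 2),
                          species = NA_character_)
  m <- build_profile(seeds, "self")
  f <- withr::local_tempfile(fileext = ".json")
  write_profile_json(m, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$name, "self")
  expect_equal(length(back$scores), nrow(m$scores))
  expect_equal(back$scores[[1]]$A, m$scores[1, "A"])
})
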