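test_that("reference reads out its own canonical motifs", {
  ref <- gh99_reference()
  call <- extract_motifs(ref)
  expect_equal(call$p189, "Y")
  expect_equal(call$loop, "DENGE")
  expect_equal(call$hepy, "HIEPY")
  expect_equal(call$p323, "Y")
  expect_equal(call$actsite, "EWHE")
})

test_that("truncated sequences give undetermined, not errors", {
  ref <- gh99_reference()$sequence
  call <- extract_motifs(substr(ref, 1, 280))
  expect_equal(call$p323, "?")
  expect_equal(call$actsite, "????")
  expect_equal(call$p189, "Y") # still mapped
})

test_that("planted motif states are recovered through the reference map", {
  cfg <- simulation_config(
    subfamilies = list(subfamily_spec("A", 5, divergence = 0.1, p189 = "W")),
    seed = 21)
  sim <- simulate_family(cfg)
  for (i in seq_len(5)) {
    expect_equal(extract_motifs(sim$records$sequence[i])$p189, "W")
  }
})

test_that("information content closed forms hold", {
  col_w <- matrix(rep("W", 10), ncol = 1)
  expect_equal(build_pfm(col_w, pseudocount = 0)$ic, log2(20))
  col_u <- matrix(amino_acids(), ncol = 1)
  expect_equal(build_pfm(col_u, pseudocount = 0)$ic, 0)
  col_yw <- matrix(c("Y", "Y", "Y", "W"), ncol = 1)
  pfm <- build_pfm(col_yw, pseudocount = 0)
  expect_equal(pfm$ic, log2(20) - (-(0.75 * log2(0.75) + 0.25 * log2(0.25))),
               tolerance = 1e-12)
  # zero observations -> missing, not zero
  col_gap <- matrix(c("?", "-", "?"), ncol = 1)
  expect_true(is.na(build_pfm(col_gap)$ic))
  # frequencies sum to one with and without pseudocount
  expect_equal(unname(colSums(build_pfm(col_yw, pseudocount = 2)$freqs)), 1)
})

test_that("adding a copy of the modal residue never decreases IC", {
  set.seed(5)
  for (rep in 1:20) {
    col <- sample(amino_acids(), sample(3:12, 1), replace = TRUE)
    modal <- names(sort(table(col), decreasing = TRUE))[1]
    ic0 <- build_pfm(matrix(col, ncol = 1), 0)$ic
    ic1 <- build_pfm(matrix(c(col, modal), ncol = 1), 0)$ic
    expect_gte(ic1, ic0 - 1e-12)
  }
})

test_that("consensus thresholds behave at the boundary", {
  cols <- matrix(rep("E", 10), ncol = 1)
  cols[10] <- "Q" # 9:1 column
  expect_equal(consensus_sequence(cols, t = 0.9)$consensus, "E")
  expect_equal(consensus_sequence(cols, t = 0.95)$consensus, "X")
  ident <- matrix(rep(strsplit("MKTAY", "")[[1]], each = 10), nrow = 10)
  expect_equal(consensus_sequence(ident, t = 0.9)$consensus, "MKTAY")
  expect_error(consensus_sequence(ident[0, , drop = FALSE]), "empty")
  expect_error(consensus_sequence(ident, t = 0.5), "0.5")
})

test_that("raising t only ever turns letters into X", {
  set.seed(8)
  cols <- matrix(sample(c("E", "Q", "D"), 200, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)), nrow = 20)
  lo <- strsplit(consensus_sequence(cols, 0.6)$consensus, "")[[1]]
  hi <- strsplit(consensus_sequence(cols, 0.9)$consensus, "")[[1]]
  changed <- lo != hi
  expect_true(all(hi[changed] == "X"))
})

test_that("majority-gap columns are dropped and recorded", {
  cols <- cbind(rep("E", 6), c(rep("-", 4), "K", "K"))
  colnames(cols) <- c("10", "11")
  cs <- consensus_sequence(cols, 0.9)
  expect_equal(cs$consensus, "E")
  expect_equal(cs$dropped, "11")
})

test_that("family consensus at low divergence recovers the ancestor", {
  cfg <- simulation_config(
    subfamilies = list(subfamily_spec("A", 200, divergence = 0.05)),
    seed = 33, p_ancestor = 0)
  sim <- simulate_family(cfg)
  ancestor <- plant <- gh99_reference()$sequence # p_ancestor 0: ancestor = root
  cols <- stack_reference_columns(sim$records)
  cs <- consensus_sequence(cols, t = 0.9)
  anc_chars <- strsplit(ancestor, "")[[1]]
  got <- strsplit(cs$consensus, "")[[1]]
  kept <- as.integer(cs$positions)
  agree <- mean(got == anc_chars[kept] | got == "X") # X = below threshold, not wrong
  exact <- mean(got == anc_chars[kept])
  expect_gte(exact, 0.99)
})

test_that("PFM and logo exports write well-formed files", {
  cols <- stack_reference_columns(toy_records(), positions = 1:5,
                                  reference = "MKTAYIAKQR")
  pfm <- build_pfm(cols, pseudocount = 1)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_pfm_tsv(pfm, f1)
  tab <- read.delim(f1)
  expect_equal(nrow(tab), 5)
  write_logo_json(pfm, f2)
  expect_silent(jsonlite::read_json(f2))
})
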