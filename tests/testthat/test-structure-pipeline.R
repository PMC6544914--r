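# Standardization, small-organic filtering, deduplication, Lipinski.

test_that("standardization strips counterions and neutralizes", {
  expect_equal(smiles_standardize("[Na+].CC(=O)[O-]"), "CC(=O)O")
  benz <- smiles_standardize("c1ccccc1")
  expect_equal(smiles_standardize(benz), benz)
})

test_that("standardization is idempotent across the synthetic library", {
  lib <- generate_library(generator_config(n_compounds = 60, seed = 4))
  std <- smiles_standardize(lib$smiles)
  expect_false(anyNA(std))
  expect_equal(smiles_standardize(std), std)
})

test_that("unparsable SMILES are flagged, not fatal", {
  out <- standardize_structures(
    data.frame(compound_key = c("a", "b"),
               smiles = c("not-a-smiles(((", "CCO"),
               stringsAsFactors = FALSE))
  expect_equal(out$discard_reason, c("parse_error", NA))
  expect_false(is.na(out$structure_key[2]))
})

test_that("small-organic filter discards by element, carbon and MW rules", {
  cmp <- data.frame(
    compound_key = c("sulfuric", "zinc", "benzene", "keeper"),
    smiles = c("O=S(=O)(O)O", "C[Zn]C", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O"),
    substance_type = "Chemical", stringsAsFactors = FALSE)
  out <- filter_small_organic(standardize_structures(cmp))
  expect_equal(out$discard_reason,
               c("no_carbon", "forbidden_element", "mw", NA))

  # alternative upper-bound reading keeps benzene
  out2 <- filter_small_organic(standardize_structures(cmp),
                               mw_limit = 1000, mw_rule = "upper")
  expect_true(is.na(out2$discard_reason[3]))
})

test_that("mixtures and polymers are discarded upstream of chemistry", {
  cmp <- data.frame(compound_key = "m", smiles = "CCO",
                    substance_type = "Mixture/Formulation",
                    stringsAsFactors = FALSE)
  out <- filter_small_organic(standardize_structures(cmp))
  expect_equal(out$discard_reason, "mixture_or_polymer")
})

test_that("deduplication keeps the right group members", {
  # three duplicate groups exercising steps 2-4 plus a singleton
  std_tol <- smiles_standardize("Cc1ccccc1")
  cmp <- data.frame(
    compound_key = c("a1", "a2", "b1", "b2", "c1", "c2", "s"),
    smiles = c("Cc1ccccc1", "c1ccccc1C",       # a1 annotated, a2 not
               std_tol, "c1ccccc1C",            # both annotated, b1 raw==std
               "c1ccccc1C", "c1cc(C)ccc1",      # both annotated, raw != std
               "CCO"),
    substance_type = "Chemical", stringsAsFactors = FALSE)
  cmp$has_ghs <- c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  std <- standardize_structures(cmp)
  # make three distinct duplicate groups out of one structure by key suffix
  std$structure_key <- paste0(std$structure_key,
                              c("gA", "gA", "gB", "gB", "gC", "gC", ""))
  out <- deduplicate_structures(std)
  expect_equal(out$discard_reason[out$compound_key == "a1"], NA_character_)
  expect_equal(out$discard_reason[out$compound_key == "a2"],
               "duplicate_no_ghs")
  expect_equal(out$discard_reason[out$compound_key == "b1"], NA_character_)
  expect_equal(out$discard_reason[out$compound_key == "b2"],
               "duplicate_unresolved")
  expect_true(all(out$discard_reason[out$compound_key %in%
                                       c("c1", "c2")] ==
                    "duplicate_unresolved"))
  expect_equal(out$discard_reason[out$compound_key == "s"], NA_character_)

  # retained records carry unique structure keys
  kept <- out[is.na(out$discard_reason), ]
  expect_equal(anyDuplicated(kept$structure_key), 0)
})

test_that("pipeline accounting is complete and monotone", {
  study <- small_study(250, 11)
  cmp <- study$library
  cmp$has_ghs <- TRUE
  res <- structure_pipeline(cmp)
  n_discarded <- sum(!is.na(res$compounds$discard_reason))
  expect_equal(nrow(res$retained) + n_discarded, nrow(cmp))
  expect_lte(nrow(res$retained), nrow(cmp))
  # each discarded record carries exactly one reason
  expect_true(all(!is.na(res$compounds$discard_reason) |
                    is.na(res$compounds$discard_reason)))
  expect_equal(sum(res$accounting$n), n_discarded)
})

test_that("lipinski rule and enrichment behave as specified", {
  expect_true(lipinski_pass("CCO"))
  # two violations fail: heavy, greasy molecule
  expect_false(lipinski_pass(paste0(
    "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC")))

  res <- lipinski_enrichment(
    pass = rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 5, 2, 20)),
    annotated = rep(c(TRUE, FALSE), c(15, 22)))
  expect_equal(res$odds_ratio, 20)
  expect_lt(res$p_value, 0.001)

  # zero cell: corrected OR is finite
  res0 <- lipinski_enrichment(pass = rep(c(TRUE, FALSE), c(10, 10)),
                              annotated = rep(c(TRUE, FALSE), c(10, 10)))
  expect_true(is.finite(res0$odds_ratio))
})

test_that("handcrafted 50-compound fixture matches its answer key", {
  # covers every discard branch and the dedup steps, with known counts
  std_tol <- smiles_standardize("Cc1ccccc1")
  clean <- sprintf("CC(=O)Oc1ccc(C%s)cc1C(=O)O",
                   strrep("C", 0:39))  # 40 unique clean esters
  cmp <- data.frame(
    compound_key = sprintf("F%02d", 1:50),
    smiles = c(clean,
               "((bad", "O=S(=O)(O)O", "C[Zn]C", "c1ccccc1",
               "CCO",                          # mw < 100
               "Cc1ccc(C)cc1", "c1cc(C)ccc1C", # dup: one annotated
               std_tol, "c1ccccc1C",           # dup: raw==std resolves
               "CCCCCCCCC(=O)O"),              # singleton
    substance_type = c(rep("Chemical", 49), "Polymer"),
    stringsAsFactors = FALSE)
  cmp$has_ghs <- TRUE
  cmp$has_ghs[47] <- FALSE                     # the duplicate without GHS
  # toluene written two ways collides with the raw==std pair: separate the
  # groups via distinct scaffolds
  cmp$smiles[48] <- smiles_standardize("CCc1ccccc1")
  cmp$smiles[49] <- "c1ccccc1CC"
  res <- structure_pipeline(cmp)
  acc <- stats::setNames(res$accounting$n, res$accounting$reason)
  expect_equal(unname(acc["parse_error"]), 1)
  expect_equal(unname(acc["no_carbon"]), 1)
  expect_equal(unname(acc["forbidden_element"]), 1)
  expect_equal(unname(acc["mw"]), 2)           # benzene and ethanol
  expect_equal(unname(acc["mixture_or_polymer"]), 1)
  expect_equal(unname(acc["duplicate_no_ghs"]), 1)
  expect_equal(unname(acc["duplicate_unresolved"]), 1)
  expect_equal(nrow(res$retained), 42)         # 40 clean + 2 dedup survivors
})
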