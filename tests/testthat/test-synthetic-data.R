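# Synthetic study generator: validity, determinism, and the generative link.

test_that("generator config validation rejects bad inputs", {
  expect_error(generator_config(n_compounds = 5), "n_compounds")
  expect_error(generator_config(label_noise = 1.5), "rate/coverage")
  expect_error(generator_config(toxicity_coefficients = numeric(0)),
               "non-empty")
  expect_error(generator_config(plant_rates = c(frag_thiourea = 0.9,
                                                frag_nitroso = 0.2)),
               "sum")
})

test_that("library SMILES are unique, parsable and deterministic", {
  cfg <- generator_config(n_compounds = 100, seed = 1)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), 100)
  expect_equal(anyDuplicated(lib$smiles), 0)
  expect_true(all(!is.na(smiles_canonical(lib$smiles))))
  expect_identical(lib, generate_library(cfg))
})

test_that("planted fragment rate matches its binomial expectation", {
  rates <- c(frag_thiourea = 0.1, frag_nitroso = 0.06,
             frag_thiophosphate = 0.06, frag_gem_dihalo = 0.06,
             frag_thiocarbonyl = 0.06)
  lib <- generate_library(generator_config(n_compounds = 2000, seed = 8,
                                           plant_rates = rates))
  obs <- mean(lib$frag == "frag_thiourea")
  se <- sqrt(0.1 * 0.9 / 2000)
  expect_lt(abs(obs - 0.1), 3 * se)
})

test_that("latent toxicity probability follows the logistic link", {
  cfg <- generator_config(n_compounds = 100, seed = 2)
  lib <- generate_library(cfg)

  zero <- generator_config(
    n_compounds = 100, seed = 2, intercept = 0,
    toxicity_coefficients = c(frag_thiourea = 0, target_1 = 0))
  truth <- generate_ground_truth(lib, zero)
  expect_true(all(truth$p_toxic == 0.5))

  deep <- generator_config(
    n_compounds = 100, seed = 2, intercept = -50,
    toxicity_coefficients = c(frag_thiourea = 0))
  truth <- generate_ground_truth(lib, deep)
  expect_true(all(truth$class == "nontoxic"))

  bad <- generator_config(
    n_compounds = 100, seed = 2,
    toxicity_coefficients = c(not_a_feature = 1))
  expect_error(generate_ground_truth(lib, bad), "unknown feature")
})

test_that("carrier and non-carrier class rates match the logistic model", {
  # Monte-Carlo check of the generative link at n = 5000: one fragment with
  # coefficient 3 and intercept -1.5 gives carrier/non-carrier toxicity
  # rates of plogis(1.5) and plogis(-1.5)
  n <- 5000
  set.seed(31)
  frag <- ifelse(stats::runif(n) < 0.4, "frag_thiourea", "none")
  lib <- synthetic_library_frame(n, frag, seed = 31)
  cfg <- generator_config(n_compounds = n, seed = 31, intercept = -1.5,
                          toxicity_coefficients = c(frag_thiourea = 3))
  truth <- generate_ground_truth(lib, cfg)
  carrier <- frag == "frag_thiourea"
  for (grp in list(list(idx = carrier, p = stats::plogis(1.5)),
                   list(idx = !carrier, p = stats::plogis(-1.5)))) {
    rate <- mean(truth$class[grp$idx] == "toxic")
    se <- sqrt(grp$p * (1 - grp$p) / sum(grp$idx))
    expect_lt(abs(rate - grp$p), 3 * se)
  }
  # class/category consistency invariant
  expect_true(all(truth$category[truth$class == "toxic"] %in% 1:3))
  expect_true(all(truth$category[truth$class == "nontoxic"] %in% c(5L, 6L)))
})

test_that("ghs observations honour coverage and noise settings", {
  lib <- synthetic_library_frame(400, "none", seed = 5)
  base <- generator_config(n_compounds = 400, seed = 5, n_sources = 2,
                           source_coverage = 1, label_noise = 0,
                           notification_coverage = 0)
  truth <- generate_ground_truth(lib, base)
  obs <- generate_ghs_observations(truth, base)
  # noise-free full coverage: both sources state the identical category
  by_src <- split(obs, obs$source_id)
  expect_equal(length(by_src), 2)
  m <- merge(by_src[[1]], by_src[[2]], by = "compound_key")
  expect_true(all(m$category.x == m$category.y |
                    (is.na(m$category.x) & is.na(m$category.y))))

  none <- generator_config(n_compounds = 400, seed = 5, n_sources = 2,
                           source_coverage = 0, label_noise = 0,
                           notification_coverage = 0)
  expect_null(generate_ghs_observations(truth, none))
})

test_that("pairwise source agreement matches a Monte-Carlo oracle", {
  n <- 5000
  lib <- synthetic_library_frame(n, "none", seed = 6)
  cfg <- generator_config(n_compounds = n, seed = 6, n_sources = 2,
                          source_coverage = 1, label_noise = 0.2,
                          notification_coverage = 0)
  truth <- generate_ground_truth(lib, cfg)
  obs <- generate_ghs_observations(truth, cfg)
  by_src <- split(obs, obs$source_id)
  m <- merge(by_src[[1]], by_src[[2]], by = "compound_key")
  cat_x <- ifelse(is.na(m$category.x), 6L, m$category.x)
  cat_y <- ifelse(is.na(m$category.y), 6L, m$category.y)
  observed <- mean(cat_x == cat_y)

  # independent oracle: simulate the same +-1 clamped perturbation rule
  set.seed(99)
  sim_once <- function(ct) {
    if (ct == 6L) return(ct)
    if (stats::runif(1) < 0.2)
      ct <- min(5L, max(1L, ct + sample(c(-1L, 1L), 1)))
    ct
  }
  agree <- replicate(20000, {
    ct <- sample(truth$category, 1)
    sim_once(ct) == sim_once(ct)
  })
  expect_lt(abs(observed - mean(agree)), 0.02)
})

test_that("assay scores respect qHTS semantics and duplication rates", {
  study <- small_study(300, 42)
  cfg <- study$config
  truth <- study$truth
  active_pairs <- 0L
  # active (compound, assay) pairs score in [40, 100]
  link <- (seq_len(cfg$n_assays) - 1L) %% cfg$n_targets + 1L
  for (j in seq_len(cfg$n_assays)) {
    aid <- sprintf("assay_%03d", j)
    rows <- study$assay[study$assay$assay_id == aid, ]
    act <- truth$compound_key[truth$target_activity[, link[j]] == 1L]
    sc <- rows$score[rows$compound_key %in% act]
    expect_true(all(sc >= 40 & sc <= 100))
    active_pairs <- active_pairs + length(sc)
  }
  expect_gt(active_pairs, 0)
  expect_true(all(study$assay$score >= 0 & study$assay$score <= 100))

  # duplicated-measurement fraction within 3 binomial SDs of its setting
  first <- study$assay[study$assay$replicate == 1L, ]
  dup_frac <- sum(study$assay$replicate == 2L) / nrow(first)
  se <- sqrt(cfg$assay_repeat_rate * (1 - cfg$assay_repeat_rate) /
               nrow(first))
  expect_lt(abs(dup_frac - cfg$assay_repeat_rate), 3 * se)

  # missing_rate = 1 empties the table
  cfg_empty <- generator_config(n_compounds = 100, seed = 3,
                                assay_missing_rate = 1)
  lib <- generate_library(cfg_empty)
  tr <- generate_ground_truth(lib, cfg_empty)
  attr(tr, "library") <- lib
  atd <- generate_assay_and_target_data(tr, cfg_empty)
  expect_equal(nrow(atd$assay), 0)
})

test_that("full study generation is byte-deterministic", {
  cfg <- generator_config(n_compounds = 120, seed = 77)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  for (el in c("library", "observations", "assay", "target_train",
               "known_actives"))
    expect_identical(s1[[el]], s2[[el]])
})

test_that("study CSVs round-trip through write_study", {
  study <- small_study(250, 11)
  dir <- withr::local_tempdir()
  paths <- write_study(study, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["compounds"]], stringsAsFactors = FALSE)
  expect_equal(back$smiles, study$library$smiles)
})
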