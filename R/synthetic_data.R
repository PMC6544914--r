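## Synthetic study generator.
##
## Emits a complete synthetic acute-oral-toxicity study with known ground
## truth: a compound library assembled from a packaged SMILES grammar,
## multi-source authoritative GHS observations plus notification count
## tables, a sparse qHTS assay-score matrix, and per-target bioactivity
## training sets. The generative model is a logistic link from planted
## structural fragments and target activities to a latent toxicity
## probability, so every downstream stage of the pipeline can be checked
## against truth.

#' Generator configuration
#'
#' Builds and validates the configuration for [generate_study()] and the
#' individual `generate_*` stages. Defaults define the package's reference
#' synthetic study: five toxicophore fragments planted at rate 0.06 each,
#' strong logistic coefficients (+8 structural, +6 target-mediated,
#' intercept -3.5, Bayes-optimal ROC AUC about 0.99, toxic prevalence about
#' a third), four authoritative sources with partial coverage, an ECHA-style
#' notification table, and an assay matrix with the 0 / (0,40) / [40,100]
#' score semantics, 11% missing cells and 36% duplicated measurements.
#'
#' @param n_compounds number of library compounds (>= 10).
#' @param seed integer master seed; all stages derive private substreams.
#' @param n_sources number of authoritative GHS sources.
#' @param source_coverage per-source probability that a compound is present
#'   in that source (recycled to `n_sources`).
#' @param notification_coverage probability a compound has a notification
#'   count record.
#' @param label_noise probability that an authoritative observation of a
#'   categorised compound is perturbed by one category (clamped to 1..5;
#'   implied nontoxics are never perturbed).
#' @param n_targets number of protein targets.
#' @param n_assays number of qHTS assays.
#' @param assay_missing_rate fraction of compound-assay cells missing.
#' @param assay_inconclusive_rate fraction of inactive cells scored in the
#'   open interval (0,40) rather than 0.
#' @param assay_repeat_rate fraction of present cells with a duplicated
#'   (replicate) measurement.
#' @param toxicity_coefficients named numeric vector of logistic weights
#'   over feature names (`frag_*`, `target_<i>`).
#' @param intercept logistic intercept.
#' @param plant_rates named numeric vector of per-fragment planting rates
#'   (mutually exclusive categorical draw; must sum to < 1).
#' @param cat_probs_toxic probabilities of GHS categories 1..3 given toxic.
#' @param cat_probs_nontoxic probabilities of category 5 vs implied
#'   nontoxic given nontoxic.
#' @param notification_fidelity probability mass a notification places on
#'   the true category.
#' @param notifications_mean mean number of notifications per covered
#'   compound.
#' @param n_train_per_target size of each target's external training set.
#' @param known_active_rate fraction of structurally canonical active query
#'   compounds recorded as known actives per linked target.
#' @param mixture_rate fraction of library rows labelled
#'   "Mixture/Formulation" (discarded upstream by the structure pipeline).
#' @return a validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_compounds = 2000,
                             seed = 1L,
                             n_sources = 4L,
                             source_coverage = c(0.45, 0.40, 0.35, 0.30),
                             notification_coverage = 0.5,
                             label_noise = 0.1,
                             n_targets = 6L,
                             n_assays = 24L,
                             assay_missing_rate = 0.11,
                             assay_inconclusive_rate = 0.05,
                             assay_repeat_rate = 0.36,
                             toxicity_coefficients = c(
                               frag_thiourea = 8, frag_nitroso = 8,
                               frag_thiophosphate = 8, frag_gem_dihalo = 8,
                               frag_thiocarbonyl = 8,
                               target_1 = 6, target_2 = 6),
                             intercept = -3.5,
                             plant_rates = c(
                               frag_thiourea = 0.06, frag_nitroso = 0.06,
                               frag_thiophosphate = 0.06,
                               frag_gem_dihalo = 0.06,
                               frag_thiocarbonyl = 0.06),
                             cat_probs_toxic = c(0.20, 0.35, 0.45),
                             cat_probs_nontoxic = c(0.40, 0.60),
                             notification_fidelity = 0.65,
                             notifications_mean = 20,
                             n_train_per_target = 80L,
                             known_active_rate = 0.5,
                             mixture_rate = 0) {
  cfg <- list(n_compounds = as.integer(n_compounds), seed = as.integer(seed),
              n_sources = as.integer(n_sources),
              source_coverage = rep_len(source_coverage, n_sources),
              notification_coverage = notification_coverage,
              label_noise = label_noise,
              n_targets = as.integer(n_targets),
              n_assays = as.integer(n_assays),
              assay_missing_rate = assay_missing_rate,
              assay_inconclusive_rate = assay_inconclusive_rate,
              assay_repeat_rate = assay_repeat_rate,
              toxicity_coefficients = toxicity_coefficients,
              intercept = intercept,
              plant_rates = plant_rates,
              cat_probs_toxic = cat_probs_toxic / sum(cat_probs_toxic),
              cat_probs_nontoxic = cat_probs_nontoxic / sum(cat_probs_nontoxic),
              notification_fidelity = notification_fidelity,
              notifications_mean = notifications_mean,
              n_train_per_target = as.integer(n_train_per_target),
              known_active_rate = known_active_rate,
              mixture_rate = mixture_rate)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  assert_that(cfg$n_compounds >= 10, "n_compounds must be >= 10")
  fracs <- c(cfg$source_coverage, cfg$notification_coverage, cfg$label_noise,
             cfg$assay_missing_rate, cfg$assay_inconclusive_rate,
             cfg$assay_repeat_rate, cfg$known_active_rate, cfg$mixture_rate)
  assert_that(all(fracs >= 0 & fracs <= 1),
              "all rate/coverage parameters must lie in [0, 1]")
  assert_that(length(cfg$toxicity_coefficients) > 0 &&
                !is.null(names(cfg$toxicity_coefficients)),
              "toxicity_coefficients must be a non-empty named vector")
  assert_that(sum(cfg$plant_rates) < 1,
              "plant_rates must sum to < 1 (fragments are mutually exclusive)")
  assert_that(all(names(cfg$plant_rates) %in%
                    paste0("frag_", grammar_substituents()$feature_short[
                      grammar_substituents()$role == "toxicophore"])),
              "plant_rates names must match packaged toxicophore fragments")
  invisible(cfg)
}

# --- packaged grammar -------------------------------------------------------

grammar_scaffolds <- function() {
  utils::read.csv(system.file("extdata", "generator_scaffolds.csv",
                              package = "ghstox"), stringsAsFactors = FALSE)
}

grammar_substituents <- function() {
  s <- utils::read.csv(system.file("extdata", "generator_substituents.csv",
                                   package = "ghstox"),
                       stringsAsFactors = FALSE)
  s$feature_short <- sub("^frag_", "", s$feature)
  s
}

#' Generate the synthetic compound library
#'
#' Compounds are assembled as scaffold x substituent x substituent products
#' from the packaged grammar (15 core ring scaffolds, 30 substituents, 5
#' toxicophore fragments). Each compound carries at most one planted
#' toxicophore fragment, drawn from `plant_rates` as a mutually exclusive
#' categorical; otherwise the second position receives a plain substituent.
#' Assembly rejects duplicates so SMILES are unique; all grammar products
#' are syntactically valid by construction (and re-validated downstream).
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `compound_key`, `cas_key`, `smiles`,
#'   `substance_type`, and generative annotations `scaffold_id`, `sub1_id`,
#'   `sub2_id`, `frag` (fragment feature name or `"none"`).
#' @export
generate_library <- function(config) {
  validate_generator_config(config)
  set.seed(stage_seed(config$seed, "library"))
  sc <- grammar_scaffolds()
  sc <- sc[sc$set == "core", ]
  su <- grammar_substituents()
  plain <- su[su$role %in% c("plain", "pharmacophore"), ]
  tox <- su[su$role == "toxicophore", ]
  tox <- tox[match(names(config$plant_rates), tox$feature), ]

  n <- config$n_compounds
  frag_levels <- c(names(config$plant_rates), "none")
  frag_probs <- c(config$plant_rates, 1 - sum(config$plant_rates))

  seen <- new.env(hash = TRUE, parent = emptyenv())
  rows <- vector("list", n)
  for (filled in seq_len(n)) {
    # the fragment decision is drawn first and kept through duplicate
    # rejection, so planting rates stay Bernoulli-exact
    frag <- sample(frag_levels, 1L, prob = frag_probs)
    if (frag == "none") {
      s2 <- sample.int(nrow(plain), 1L)
      sub2_id <- plain$sub_id[s2]
      sub2_smi <- plain$smiles[s2]
    } else {
      sub2_id <- tox$sub_id[match(frag, tox$feature)]
      sub2_smi <- tox$smiles[match(frag, tox$feature)]
    }
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > 2000L)
        stop("could not assemble ", n,
             " unique compounds from the grammar", call. = FALSE)
      si <- sample.int(nrow(sc), 1L)
      s1 <- sample.int(nrow(plain), 1L)
      if (frag == "none") {
        s2 <- sample.int(nrow(plain), 1L)
        sub2_id <- plain$sub_id[s2]
        sub2_smi <- plain$smiles[s2]
      }
      smi <- sprintf(sc$template[si], plain$smiles[s1], sub2_smi)
      if (is.null(seen[[smi]])) break
    }
    assign(smi, TRUE, envir = seen)
    rows[[filled]] <- data.frame(
      scaffold_id = sc$scaffold_id[si], sub1_id = plain$sub_id[s1],
      sub2_id = sub2_id, frag = frag, smiles = smi,
      stringsAsFactors = FALSE)
  }
  lib <- do.call(rbind, rows)
  lib$compound_key <- sprintf("C%05d", seq_len(n))
  lib$cas_key <- sprintf("50-%05d-%d", seq_len(n), seq_len(n) %% 10)
  lib$substance_type <- "Chemical"
  if (config$mixture_rate > 0) {
    mix <- stats::runif(n) < config$mixture_rate
    lib$substance_type[mix] <- "Mixture/Formulation"
  }
  lib[, c("compound_key", "cas_key", "smiles", "substance_type",
          "scaffold_id", "sub1_id", "sub2_id", "frag")]
}

# target design: linked targets cycle through the pharmacophore substituents;
# the last two targets (when n_targets >= 3) are a dissimilar-chemistry
# target and a chemotype-mismatched target, built to fail the reliability
# filter by construction.
target_design <- function(config) {
  su <- grammar_substituents()
  pharm <- su[su$role == "pharmacophore", ]
  nt <- config$n_targets
  n_special <- if (nt >= 3) 2L else 0L
  type <- c(rep("linked", nt - n_special),
            if (n_special) c("dissimilar", "mismatched"))
  data.frame(
    target_id = paste0("target_", seq_len(nt)),
    type = type,
    pharmacophore = ifelse(
      type == "linked",
      pharm$sub_id[(seq_len(nt) - 1L) %% nrow(pharm) + 1L],
      pharm$sub_id[(seq_len(nt) - 1L) %% nrow(pharm) + 1L]),
    stringsAsFactors = FALSE)
}

#' Generate ground truth for a synthetic library
#'
#' The latent toxicity probability is
#' `plogis(intercept + sum(coefficients * features))` over planted fragment
#' indicators and target-activity indicators; the binary class is a
#' Bernoulli draw from it, and the true GHS oral category is drawn
#' conditional on the class (toxic: categories 1-3; nontoxic: category 5 or
#' implied nontoxic, encoded 6). Target activities for linked targets follow
#' the compound's pharmacophore substituents (P(active) = 0.92 for carriers,
#' 0.04 otherwise); unlinked targets are background-rate Bernoulli(0.05).
#'
#' @param library output of [generate_library()].
#' @param config the same [generator_config()].
#' @return list of class `"ghs_ground_truth"` with elements `features`
#'   (binary matrix), `p_toxic`, `class` ("toxic"/"nontoxic"),
#'   `category` (1:5 or 6 = implied nontoxic), `target_activity` (binary
#'   matrix), `frag`, `compound_key`, `design` (target design table).
#' @export
generate_ground_truth <- function(library, config) {
  assert_that(nrow(library) > 0, "library must be non-empty")
  set.seed(stage_seed(config$seed, "truth"))
  n <- nrow(library)
  su <- grammar_substituents()
  design <- target_design(config)

  frag_names <- paste0("frag_",
                       su$feature_short[su$role == "toxicophore"])
  frag_mat <- sapply(frag_names, function(f) as.integer(library$frag == f))

  carrier <- function(sub_id)
    as.integer(library$sub1_id == sub_id | library$sub2_id == sub_id)
  tact <- matrix(0L, n, config$n_targets,
                 dimnames = list(library$compound_key, design$target_id))
  for (j in seq_len(config$n_targets)) {
    if (design$type[j] == "linked") {
      p <- ifelse(carrier(design$pharmacophore[j]) == 1L, 0.92, 0.04)
    } else {
      p <- rep(0.05, n)
    }
    tact[, j] <- as.integer(stats::runif(n) < p)
  }

  features <- cbind(frag_mat, tact)
  rownames(features) <- library$compound_key
  coefs <- config$toxicity_coefficients
  unknown <- setdiff(names(coefs), colnames(features))
  if (length(unknown))
    stop("toxicity_coefficients reference unknown features: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  eta <- config$intercept +
    features[, names(coefs), drop = FALSE] %*% coefs
  p_toxic <- stats::plogis(as.numeric(eta))
  cls <- ifelse(stats::runif(n) < p_toxic, "toxic", "nontoxic")

  category <- integer(n)
  is_tox <- cls == "toxic"
  category[is_tox] <- sample(1:3, sum(is_tox), replace = TRUE,
                             prob = config$cat_probs_toxic)
  category[!is_tox] <- sample(c(5L, 6L), sum(!is_tox), replace = TRUE,
                              prob = config$cat_probs_nontoxic)

  structure(list(features = features, p_toxic = p_toxic, class = cls,
                 category = category, target_activity = tact,
                 frag = library$frag, compound_key = library$compound_key,
                 design = design),
            class = "ghs_ground_truth")
}

#' Generate multi-source GHS observations
#'
#' Each authoritative source covers a Bernoulli subset of the library; for
#' covered, categorised compounds the observed category is the true one
#' perturbed by one level with probability `label_noise` (clamped to 1..5),
#' while implied nontoxics appear in the source without an oral category
#' (category `NA`, noise-free). Notification records place multinomial
#' counts over categories and "none", with mass `notification_fidelity` on
#' the true category and the remainder on adjacent categories and "none".
#'
#' @param truth output of [generate_ground_truth()].
#' @param config the same [generator_config()].
#' @return data.frame with columns `compound_key`, `source_id`, `tier`,
#'   `route`, `category` (NA for presence-without-category and for
#'   notification rows) and `notif_1`..`notif_5`, `notif_none`.
#' @export
generate_ghs_observations <- function(truth, config) {
  assert_that(inherits(truth, "ghs_ground_truth"), "truth must be present")
  set.seed(stage_seed(config$seed, "observations"))
  n <- length(truth$compound_key)
  out <- list()

  for (s in seq_len(config$n_sources)) {
    covered <- which(stats::runif(n) < config$source_coverage[s])
    if (!length(covered)) next
    cat_true <- truth$category[covered]
    obs_cat <- ifelse(cat_true == 6L, NA_integer_, cat_true)
    noisy <- !is.na(obs_cat) & stats::runif(length(covered)) < config$label_noise
    step <- sample(c(-1L, 1L), length(covered), replace = TRUE)
    obs_cat[noisy] <- pmin(5L, pmax(1L, obs_cat[noisy] + step[noisy]))
    out[[length(out) + 1L]] <- data.frame(
      compound_key = truth$compound_key[covered],
      source_id = sprintf("AUTH%02d", s), tier = "authoritative",
      route = "oral", category = obs_cat,
      notif_1 = NA_integer_, notif_2 = NA_integer_, notif_3 = NA_integer_,
      notif_4 = NA_integer_, notif_5 = NA_integer_, notif_none = NA_integer_,
      stringsAsFactors = FALSE)
  }

  covered <- which(stats::runif(n) < config$notification_coverage)
  if (length(covered)) {
    counts <- t(vapply(truth$category[covered], function(ct) {
      total <- 1L + stats::rpois(1, config$notifications_mean)
      probs <- notification_probs(ct, config$notification_fidelity)
      as.integer(stats::rmultinom(1, total, probs))
    }, integer(6)))
    out[[length(out) + 1L]] <- data.frame(
      compound_key = truth$compound_key[covered],
      source_id = "NOTIF", tier = "notification", route = "oral",
      category = NA_integer_,
      notif_1 = counts[, 1], notif_2 = counts[, 2], notif_3 = counts[, 3],
      notif_4 = counts[, 4], notif_5 = counts[, 5], notif_none = counts[, 6],
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  obs
}

# probability vector over categories 1..5 and "none" for one notification
notification_probs <- function(cat_true, fidelity) {
  p <- numeric(6)
  if (cat_true == 6L) {
    p[6] <- 0.85
    p[4:5] <- 0.075
  } else {
    p[cat_true] <- fidelity
    spread <- (1 - fidelity - 0.15) / 2
    lo <- max(1L, cat_true - 1L); hi <- min(5L, cat_true + 1L)
    # spread that would fall outside 1..5 collapses onto the true category
    p[lo] <- p[lo] + spread
    p[hi] <- p[hi] + spread
    p[6] <- 0.15
  }
  p / sum(p)
}

#' Generate the qHTS assay table and per-target bioactivity sets
#'
#' Assay scores follow the qHTS convention: actives score Uniform(40,100),
#' a stated fraction of inactives score inconclusive in (0,40), and the rest
#' score 0. Activity of assay `j` is the planted activity of its linked
#' target (assays cycle over targets). A fraction of cells is missing
#' (dropped from the long table) and a fraction carries a duplicated
#' replicate measurement. Target training sets are sized and composed so
#' that linked targets pass the downstream reliability filter while the
#' dissimilar-chemistry and chemotype-mismatched targets fail it.
#'
#' @param truth output of [generate_ground_truth()].
#' @param config the same [generator_config()].
#' @return list with `assay` (long data.frame: `compound_key`, `assay_id`,
#'   `score`, `replicate`), `assay_meta` (`assay_id`, `flag`),
#'   `target_train` (`target_id`, `compound_key`, `smiles`, `label`),
#'   `known_actives` (`compound_key`, `target_id`) and `design`.
#' @export
generate_assay_and_target_data <- function(truth, config) {
  assert_that(inherits(truth, "ghs_ground_truth"), "truth must be present")
  set.seed(stage_seed(config$seed, "assays"))
  n <- length(truth$compound_key)
  design <- truth$design

  ## assay long table
  assay_ids <- sprintf("assay_%03d", seq_len(config$n_assays))
  link <- (seq_len(config$n_assays) - 1L) %% config$n_targets + 1L
  rows <- list()
  for (j in seq_len(config$n_assays)) {
    active <- truth$target_activity[, link[j]] == 1L
    score <- numeric(n)
    score[active] <- stats::runif(sum(active), 40, 100)
    inact <- which(!active)
    inc <- inact[stats::runif(length(inact)) < config$assay_inconclusive_rate]
    score[inc] <- stats::runif(length(inc), 0.001, 39.999)
    present <- stats::runif(n) >= config$assay_missing_rate
    idx <- which(present)
    if (!length(idx)) next
    rows[[j]] <- data.frame(compound_key = truth$compound_key[idx],
                            assay_id = assay_ids[j], score = score[idx],
                            replicate = 1L, stringsAsFactors = FALSE)
    dup <- idx[stats::runif(length(idx)) < config$assay_repeat_rate]
    if (length(dup)) {
      s2 <- numeric(length(dup))
      act2 <- truth$target_activity[dup, link[j]] == 1L
      s2[act2] <- stats::runif(sum(act2), 40, 100)
      was_inc <- !act2 & score[dup] > 0
      s2[was_inc] <- stats::runif(sum(was_inc), 0.001, 39.999)
      rows[[config$n_assays + j]] <- data.frame(
        compound_key = truth$compound_key[dup], assay_id = assay_ids[j],
        score = s2, replicate = 2L, stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  assay <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_key = character(0), assay_id = character(0),
               score = numeric(0), replicate = integer(0))
  rownames(assay) <- NULL

  ## assay metadata: every sixth assay flagged for removal downstream
  flag <- rep("none", config$n_assays)
  flagged <- which(seq_len(config$n_assays) %% 6L == 0L)
  flag[flagged] <- rep(c("counter_screen", "autofluorescence",
                         "confirmatory_superseded"),
                       length.out = length(flagged))
  assay_meta <- data.frame(assay_id = assay_ids, flag = flag,
                           stringsAsFactors = FALSE)

  ## per-target bioactivity training sets
  train_rows <- list()
  ka_rows <- list()
  for (j in seq_len(config$n_targets)) {
    tid <- design$target_id[j]
    type <- design$type[j]
    pharm <- design$pharmacophore[j]
    set_name <- if (type == "dissimilar") "exotic" else "core"
    ext <- make_training_molecules(config$n_train_per_target, pharm,
                                   set_name,
                                   stage_seed(config$seed,
                                              paste0("train_", tid)))
    ext$target_id <- tid
    ext$compound_key <- sprintf("%s_ext%03d", tid, seq_len(nrow(ext)))
    train_rows[[length(train_rows) + 1L]] <-
      ext[, c("target_id", "compound_key", "smiles", "label")]

    if (type == "linked") {
      is_carrier <- truth$target_activity[, j] == 1L &
        carrier_of(truth, pharm)
      known <- which(is_carrier &
                       stats::runif(n) < config$known_active_rate)
      if (length(known)) {
        ka_rows[[length(ka_rows) + 1L]] <- data.frame(
          compound_key = truth$compound_key[known], target_id = tid,
          stringsAsFactors = FALSE)
        train_rows[[length(train_rows) + 1L]] <- data.frame(
          target_id = tid, compound_key = truth$compound_key[known],
          smiles = NA_character_, label = "active",
          stringsAsFactors = FALSE)
      }
    } else if (type == "mismatched") {
      # known actives whose structures do not carry the target's chemotype:
      # the model cannot transfer, so its recall fails by construction
      non_carrier <- which(!carrier_of(truth, pharm) &
                             truth$target_activity[, j] == 0L)
      known <- sample(non_carrier, min(15L, length(non_carrier)))
      ka_rows[[length(ka_rows) + 1L]] <- data.frame(
        compound_key = truth$compound_key[known], target_id = tid,
        stringsAsFactors = FALSE)
      train_rows[[length(train_rows) + 1L]] <- data.frame(
        target_id = tid, compound_key = truth$compound_key[known],
        smiles = NA_character_, label = "active", stringsAsFactors = FALSE)
    } else {
      # dissimilar: a handful of query actives overlap, but the exotic
      # training chemistry keeps the mean NN Tanimoto below threshold
      act <- which(truth$target_activity[, j] == 1L)
      known <- act[seq_len(min(5L, length(act)))]
      if (length(known)) {
        ka_rows[[length(ka_rows) + 1L]] <- data.frame(
          compound_key = truth$compound_key[known], target_id = tid,
          stringsAsFactors = FALSE)
        train_rows[[length(train_rows) + 1L]] <- data.frame(
          target_id = tid, compound_key = truth$compound_key[known],
          smiles = NA_character_, label = "active", stringsAsFactors = FALSE)
      }
    }
  }
  target_train <- do.call(rbind, train_rows)
  rownames(target_train) <- NULL
  known_actives <- if (length(ka_rows)) do.call(rbind, ka_rows) else
    data.frame(compound_key = character(0), target_id = character(0))
  rownames(known_actives) <- NULL

  list(assay = assay, assay_meta = assay_meta, target_train = target_train,
       known_actives = known_actives, design = design)
}

carrier_of <- function(truth, sub_id) {
  lib <- attr(truth, "library")
  if (is.null(lib)) stop("truth lacks library annotations", call. = FALSE)
  lib$sub1_id == sub_id | lib$sub2_id == sub_id
}

# external training molecules for one target: half carry the target's
# pharmacophore (actives), half do not (inactives)
make_training_molecules <- function(n, pharm_sub, set_name, seed) {
  set.seed(seed)
  sc <- grammar_scaffolds()
  sc <- sc[sc$set == set_name, ]
  su <- grammar_substituents()
  plain <- su[su$role == "plain", ]
  pharm_smi <- su$smiles[su$sub_id == pharm_sub]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- sample.int(nrow(sc), 1L)
    s1 <- sample.int(nrow(plain), 1L)
    active <- i <= ceiling(n / 2)
    s2_smi <- if (active) pharm_smi else
      plain$smiles[sample.int(nrow(plain), 1L)]
    rows[[i]] <- data.frame(
      smiles = sprintf(sc$template[si], plain$smiles[s1], s2_smi),
      label = if (active) "active" else "inactive",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_library()],
#' [generate_ground_truth()], [generate_ghs_observations()] and
#' [generate_assay_and_target_data()] under one configuration.
#'
#' @param config a [generator_config()].
#' @return list of class `"ghs_study"` with elements `library`, `truth`,
#'   `observations`, `assay`, `assay_meta`, `target_train`,
#'   `known_actives`, `config`.
#' @export
generate_study <- function(config = generator_config()) {
  library <- generate_library(config)
  truth <- generate_ground_truth(library, config)
  attr(truth, "library") <- library
  truth$smiles <- library$smiles
  atd <- generate_assay_and_target_data(truth, config)
  # known-active overlap rows need the query structures
  atd$target_train$smiles[is.na(atd$target_train$smiles)] <-
    library$smiles[match(
      atd$target_train$compound_key[is.na(atd$target_train$smiles)],
      library$compound_key)]
  obs <- generate_ghs_observations(truth, config)
  structure(list(library = library, truth = truth, observations = obs,
                 assay = atd$assay, assay_meta = atd$assay_meta,
                 target_train = atd$target_train,
                 known_actives = atd$known_actives, config = config),
            class = "ghs_study")
}

#' Write a synthetic study to CSV files
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    compounds = file.path(dir, "compounds.csv"),
    observations = file.path(dir, "ghs_observations.csv"),
    assay = file.path(dir, "assay_scores.csv"),
    assay_meta = file.path(dir, "assay_meta.csv"),
    target_train = file.path(dir, "target_train.csv"),
    known_actives = file.path(dir, "known_actives.csv"))
  utils::write.csv(study$library, paths["compounds"], row.names = FALSE)
  utils::write.csv(study$observations, paths["observations"], row.names = FALSE)
  utils::write.csv(study$assay, paths["assay"], row.names = FALSE)
  utils::write.csv(study$assay_meta, paths["assay_meta"], row.names = FALSE)
  utils::write.csv(study$target_train, paths["target_train"], row.names = FALSE)
  utils::write.csv(study$known_actives, paths["known_actives"], row.names = FALSE)
  invisible(paths)
}
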