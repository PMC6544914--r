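## End-to-end pipeline orchestration and report bundle.

#' Run configuration
#'
#' Bundles the inputs (a generator configuration or a directory of CSVs in
#' the [write_study()] schema), the analysis thresholds, seeds, and the
#' output directory.
#'
#' @param generator a [generator_config()], or `NULL` when reading CSVs.
#' @param input_dir directory of study CSVs (ignored when `generator` is
#'   given).
#' @param out_dir report bundle directory.
#' @param seed master analysis seed.
#' @param notification_threshold cumulative notification fraction.
#' @param recall_min,tanimoto_min target-model reliability bounds.
#' @param alpha familywise significance level.
#' @param mw_limit,mw_rule molecular weight filter rule.
#' @param test_fraction test fraction for stratified splits.
#' @param ntree Random Forest size.
#' @param folds CV folds for threshold selection.
#' @param repeats number of repeated randomized splits (0 disables).
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(generator = generator_config(), input_dir = NULL,
                       out_dir = tempfile("ghstox_run_"), seed = 1,
                       notification_threshold = 0.10, recall_min = 0.5,
                       tanimoto_min = 0.25, alpha = 0.05, mw_limit = 100,
                       mw_rule = "lower", test_fraction = 0.2, ntree = 200,
                       folds = 5, repeats = 0) {
  assert_that(!is.null(generator) || !is.null(input_dir),
              "either a generator config or an input directory is required")
  if (!is.null(input_dir))
    assert_that(dir.exists(input_dir),
                paste("input directory does not exist:", input_dir))
  assert_that(notification_threshold > 0 && notification_threshold < 1,
              "notification_threshold must be in (0,1)")
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0,1)")
  structure(list(generator = generator, input_dir = input_dir,
                 out_dir = out_dir, seed = as.integer(seed),
                 notification_threshold = notification_threshold,
                 recall_min = recall_min, tanimoto_min = tanimoto_min,
                 alpha = alpha, mw_limit = mw_limit, mw_rule = mw_rule,
                 test_fraction = test_fraction, ntree = ntree,
                 folds = folds, repeats = repeats),
            class = "run_config")
}

read_study <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  list(library = rd("compounds.csv"),
       observations = rd("ghs_observations.csv"),
       assay = rd("assay_scores.csv"),
       assay_meta = rd("assay_meta.csv"),
       target_train = rd("target_train.csv"),
       known_actives = rd("known_actives.csv"))
}

#' Run the full analysis pipeline
#'
#' Executes collation, structure standardization, descriptor assembly,
#' toxicophore screening, class-separation analysis and predictive
#' modelling in order, writing each stage's artefacts and a manifest of
#' in/out counts to the bundle directory. Deterministic given the
#' configuration (two runs with the same config and seed produce
#' byte-identical manifests).
#'
#' @param config a [run_config()].
#' @return invisible list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = fnv1a_hex(paste(utils::capture.output(utils::str(
      config[setdiff(names(config), "out_dir")])), collapse = "\n")),
    seed = config$seed, stages = list())

  ## stage 0: inputs
  study <- if (!is.null(config$generator)) {
    generate_study(config$generator)
  } else {
    read_study(config$input_dir)
  }
  manifest$stages$inputs <- list(n_compounds = nrow(study$library),
                                 n_observations = nrow(study$observations))

  ## stage 1: GHS collation
  labels <- harmonize_labels(study$observations,
                             config$notification_threshold)
  auth <- study$observations[study$observations$tier == "authoritative", ]
  presence <- split(auth$compound_key, auth$source_id)
  overlap <- source_overlap_matrix(presence)
  lab_by_source <- lapply(split(auth, paste(auth$source_id, auth$route)),
                          function(d) {
                            cat <- ifelse(is.na(d$category), 6L, d$category)
                            stats::setNames(cat, d$compound_key)
                          })
  agreement <- label_agreement_matrix(lab_by_source)
  utils::write.csv(labels, file.path(config$out_dir, "harmonized_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(overlap, file.path(config$out_dir, "source_overlap.csv"))
  utils::write.csv(agreement, file.path(config$out_dir, "label_agreement.csv"))
  manifest$stages$collation <- list(n_labelled = nrow(labels))

  ## stage 2: structure pipeline
  compounds <- study$library
  oral <- labels[labels$route == "oral", ]
  compounds$has_ghs <- compounds$compound_key %in% oral$compound_key
  sp <- structure_pipeline(compounds, config$mw_limit, config$mw_rule)
  utils::write.csv(sp$compounds[!is.na(sp$compounds$discard_reason),
                                c("compound_key", "discard_reason")],
                   file.path(config$out_dir, "discard_log.csv"),
                   row.names = FALSE)
  manifest$stages$structures <- list(
    n_in = nrow(compounds), n_retained = nrow(sp$retained),
    discards = stats::setNames(as.list(sp$accounting$n),
                               sp$accounting$reason))

  ## stage 3: binary endpoint and modelling set
  retained <- sp$retained
  oral_cat <- oral$category[match(retained$compound_key, oral$compound_key)]
  binary <- binarize_oral(oral_cat[!is.na(oral_cat)])
  binary_keys <- retained$compound_key[!is.na(oral_cat)]
  modelling <- binary != "excluded"
  y <- stats::setNames(binary[modelling], binary_keys[modelling])
  manifest$stages$binarize <- list(
    n_toxic = sum(y == "toxic"), n_nontoxic = sum(y == "nontoxic"),
    n_excluded = sum(!modelling))

  smiles_all <- stats::setNames(retained$std_smiles, retained$compound_key)
  smiles <- smiles_all[names(y)]

  ## stage 4: descriptor assembly
  mol <- compute_molecular_block(smiles)
  query_fps <- ecfp_fingerprints(smiles_to_sdfset(smiles))
  cards <- list(); models <- list()
  for (tid in unique(study$target_train$target_id)) {
    tt <- study$target_train[study$target_train$target_id == tid, ]
    ev <- evaluate_target_model(tt, query_fps, tid,
                                seed = stage_seed(config$seed, tid))
    cards[[tid]] <- ev$card
    if (ev$card$retained) models[[tid]] <- ev$model
  }
  cards <- do.call(rbind, cards)
  utils::write.csv(cards, file.path(config$out_dir, "target_model_cards.csv"),
                   row.names = FALSE)
  target <- if (length(models))
    build_target_block(models, query_fps, study$known_actives) else NULL
  assay_keys <- intersect(names(y), unique(study$assay$compound_key))
  assay <- build_assay_block(study$assay, study$assay_meta, assay_keys)
  manifest$stages$descriptors <- list(
    n_molecular_features = ncol(mol$values),
    n_targets_retained = length(models),
    n_assays = ncol(assay$values),
    n_assay_compounds = nrow(assay$values))

  ## stage 5: toxicophore screening
  hits <- screen_alerts(smiles)
  outcome <- three_way_outcome(hits)
  enr <- alert_enrichment(hits[names(y), , drop = FALSE], unname(y),
                          alpha = config$alpha)
  utils::write.csv(enr, file.path(config$out_dir, "alert_enrichment.csv"),
                   row.names = FALSE)
  manifest$stages$toxicophores <- list(
    n_alerts = ncol(hits),
    n_significant = sum(enr$significant),
    outcome_counts = as.list(table(outcome)))

  ## stage 6: class separation
  mol_scaled <- center_scale(mol)
  separation <- list()
  blocks <- list(molecular = mol_scaled, assay = assay)
  if (!is.null(target)) blocks$target <- target
  for (tag in names(blocks)) {
    blk <- blocks[[tag]]
    keys <- intersect(rownames(blk$values), names(y))
    blk$values <- blk$values[keys, , drop = FALSE]
    nn <- nn_distances(blk, unname(y[keys]))
    ps <- paired_separation_stats(nn$intra, nn$inter)
    lda <- fit_lda(blk, unname(y[keys]))
    separation[[tag]] <- list(nn = ps, lda = lda)
  }
  manifest$stages$separation <- lapply(separation, function(s)
    list(nn_d = round(s$nn$d, 6), lda_d = round(s$lda$d, 6)))

  ## stage 7: predictive modelling
  combo_mats <- list(molecular = mol$values)
  if (!is.null(target)) {
    combo_mats$target <- target$values
    combo_mats$molecular_target <- cbind(
      mol$values, target$values[rownames(mol$values), , drop = FALSE])
  }
  combo_mats$assay <- assay$values

  splits <- list(
    random = random_split(y, config$test_fraction,
                          stage_seed(config$seed, "random_split")),
    rare_scaffolds = rare_scaffold_split(smiles),
    single_source = tryCatch(
      single_source_split(y, authoritative_source_counts(study$observations,
                                                         names(y)),
                          config$test_fraction,
                          stage_seed(config$seed, "single_source")),
      error = function(e) NULL))
  splits <- splits[!vapply(splits, is.null, logical(1))]

  reports <- list()
  for (sname in names(splits)) {
    for (combo in names(combo_mats)) {
      x <- combo_mats[[combo]]
      keys <- intersect(rownames(x), names(y))
      x <- x[keys, , drop = FALSE]
      fit <- run_split_model(x, y[keys], splits[[sname]], combo,
                             ntree = config$ntree, k = config$folds,
                             seed = stage_seed(config$seed,
                                               paste(sname, combo)))
      reports[[paste(sname, combo)]] <- fit$report
    }
  }
  report_table <- do.call(rbind, reports)
  rownames(report_table) <- NULL
  utils::write.csv(report_table,
                   file.path(config$out_dir, "model_performance.csv"),
                   row.names = FALSE)
  manifest$stages$modelling <- list(
    n_models = nrow(report_table),
    best_auc = round(max(report_table$roc_auc, na.rm = TRUE), 6))

  if (config$repeats > 0) {
    rep_sum <- repeat_splits(combo_mats$molecular, y, "random",
                             n = config$repeats,
                             base_seed = stage_seed(config$seed, "repeats"),
                             fraction = config$test_fraction,
                             ntree = config$ntree, k = config$folds)
    utils::write.csv(rep_sum$summary,
                     file.path(config$out_dir, "repeat_split_summary.csv"),
                     row.names = FALSE)
    manifest$stages$repeats <- list(
      n = config$repeats,
      mean_auc = round(rep_sum$summary$mean[
        rep_sum$summary$metric == "roc_auc"], 6))
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(study = study, labels = labels, overlap = overlap,
                 agreement = agreement, structures = sp, y = y,
                 blocks = list(molecular = mol, molecular_scaled = mol_scaled,
                               target = target, assay = assay),
                 target_cards = cards, enrichment = enr,
                 separation = separation, splits = splits,
                 reports = report_table, manifest = manifest,
                 manifest_path = manifest_path))
}

#' Authoritative source counts per compound
#'
#' @param observations observation table.
#' @param keys compound keys to report (defaults to all observed).
#' @return named integer vector: number of distinct authoritative sources
#'   covering each compound (0 for uncovered keys).
#' @export
authoritative_source_counts <- function(observations, keys = NULL) {
  auth <- observations[observations$tier == "authoritative", ]
  counts <- tapply(auth$source_id, auth$compound_key,
                   function(s) length(unique(s)))
  if (is.null(keys)) keys <- names(counts)
  out <- stats::setNames(integer(length(keys)), keys)
  hit <- intersect(keys, names(counts))
  out[hit] <- as.integer(counts[hit])
  out
}
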