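## Descriptor blocks: open 2D molecular descriptors, reliability-filtered
## protein-target probabilities, and qHTS activity-score features.

#' Construct a descriptor block
#'
#' A descriptor block is a dense compound x feature matrix tagged with its
#' domain (`molecular`, `target` or `assay`), the distance metric
#' appropriate to it, and its scaling state.
#'
#' @param values numeric matrix with compound keys as rownames and feature
#'   names as colnames; no missing values.
#' @param tag one of `"molecular"`, `"target"`, `"assay"`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param scaling_state `"raw"` or `"centered_scaled"`.
#' @return object of class `"descriptor_block"`.
#' @export
descriptor_block <- function(values, tag = c("molecular", "target", "assay"),
                             metric = c("euclidean", "cosine"),
                             scaling_state = "raw") {
  tag <- match.arg(tag)
  metric <- match.arg(metric)
  assert_that(is.matrix(values) && !is.null(rownames(values)) &&
                !is.null(colnames(values)),
              "values must be a matrix with row and column names")
  assert_that(!anyNA(values), "descriptor blocks may not contain missing values")
  structure(list(values = values, tag = tag, metric = metric,
                 scaling_state = scaling_state),
            class = "descriptor_block")
}

#' @export
print.descriptor_block <- function(x, ...) {
  cat(sprintf("<descriptor_block> tag=%s  %d compounds x %d features  metric=%s  scaling=%s\n",
              x$tag, nrow(x$values), ncol(x$values), x$metric,
              x$scaling_state))
  invisible(x)
}

# Pauling electronegativities for the charge-proxy descriptors
electronegativity <- function() {
  c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98, P = 2.19, S = 2.58,
    Cl = 3.16, Br = 2.96, I = 2.66, B = 2.04, Si = 1.90)
}

fg_smarts <- function() {
  c(fg_nitro = "[NX3](~[OX1])~[OX1]",
    fg_nitroso = "[NX3][NX2]=O",
    fg_thiocarbonyl = "[#6]=[SX1]",
    fg_thiourea = "NC(=S)N",
    fg_ps_bond = "[#15]=[#16]",
    fg_gem_dihalo = "[CX4](Cl)(Cl)",
    fg_prim_amine = "[NX3;H2][#6]",
    fg_tert_amine = "[NX3]([#6])([#6])[#6]",
    fg_carboxylic_acid = "C(=O)[OX2H1]",
    fg_ester = "C(=O)O[#6]",
    fg_amide = "C(=O)[NX3]",
    fg_nitrile = "C#N",
    fg_ether = "[#6][OX2][#6]",
    fg_phenol = "c[OX2H1]",
    fg_sulfonyl = "S(=O)(=O)",
    fg_aryl_halide = "c[F,Cl,Br,I]")
}

#' Compute the 2D molecular descriptor block
#'
#' An open descriptor set of about 160 raw features per compound (typically
#' just over 100 survive constant-dropping): constitutional counts, bond
#' and ring statistics, topological indices (Wiener, Randic, Zagreb, Kier
#' kappa shapes, graph diameter/radius), electronegativity charge proxies,
#' OpenBabel physicochemical properties (MW, logP, TPSA, MR, H-bond
#' donors/acceptors), functional-group SMARTS counts, and 96 hashed
#' radius-1 atom-environment counts. Feature names are namespaced by
#' family (`const_`, `bond_`, `topo_`, `chg_`, `prop_`, `fg_`, `env_`).
#' Constant-valued features are dropped and recorded in the
#' `"dropped_features"` attribute; structures that fail descriptor
#' generation are excluded and recorded in the `"failed"` attribute.
#'
#' @param smiles named character vector of standardized SMILES (names are
#'   compound keys).
#' @return a `"descriptor_block"` with tag `"molecular"`, metric euclidean.
#' @export
compute_molecular_block <- function(smiles) {
  assert_that(!is.null(names(smiles)), "smiles must be named by compound key")
  sdfset <- smiles_to_sdfset(smiles)
  keys <- ChemmineR::cid(sdfset)
  props <- mol_properties(smiles[keys])

  graph <- t(vapply(keys, function(k) graph_descriptors(sdfset[[k]]),
                    numeric(length(graph_descriptor_names()))))
  colnames(graph) <- graph_descriptor_names()

  mols <- ob_read_mols(smiles[keys])
  fg <- vapply(fg_smarts(), function(pat) {
    cnt <- smarts_count(mols, pat)
    out <- stats::setNames(integer(length(keys)), keys)
    out[names(cnt)] <- cnt
    out
  }, integer(length(keys)))
  if (length(keys) == 1) fg <- matrix(fg, 1, dimnames = list(keys, names(fg_smarts())))

  prop_cols <- c(MW = "MW", logP = "logP", TPSA = "TPSA", MR = "MR",
                 HBD = "HBD", HBA_lipinski = "HBA1", HBA = "HBA2", nF = "nF")
  pm <- as.matrix(props[keys, prop_cols, drop = FALSE])
  colnames(pm) <- paste0("prop_", names(prop_cols))

  values <- cbind(graph, pm, fg)
  rownames(values) <- keys
  bad_rows <- rowSums(!is.finite(values)) > 0
  failed <- c(attr(sdfset, "failed"), keys[bad_rows])
  values <- values[!bad_rows, , drop = FALSE]

  const <- apply(values, 2, function(x) max(x) == min(x))
  dropped <- colnames(values)[const]
  values <- values[, !const, drop = FALSE]

  blk <- descriptor_block(values, "molecular", "euclidean", "raw")
  attr(blk, "dropped_features") <- dropped
  attr(blk, "failed") <- failed
  blk
}

graph_descriptor_names <- function() {
  c("const_n_heavy", "const_n_C", "const_n_N", "const_n_O", "const_n_S",
    "const_n_P", "const_n_F", "const_n_Cl", "const_n_Br", "const_n_I",
    "const_n_hetero", "const_frac_hetero", "const_n_halogen",
    "const_frac_halogen",
    "bond_n", "bond_single", "bond_double", "bond_triple",
    "bond_mean_order", "bond_n_rings",
    "topo_deg1", "topo_deg2", "topo_deg3", "topo_deg4", "topo_mean_degree",
    "topo_wiener", "topo_mean_dist", "topo_diameter", "topo_radius",
    "topo_randic", "topo_zagreb1", "topo_zagreb2",
    "topo_kappa1", "topo_kappa2", "topo_kappa3",
    "topo_path2", "topo_path3",
    "chg_en_sum", "chg_en_mean", "chg_en_var", "chg_en_range",
    paste0("env_", sprintf("%02d", 0:95)))
}

graph_descriptors <- function(sdf) {
  elems <- atom_symbols(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- length(elems)
  if (is.null(bb) || !is.matrix(bb) || ncol(bb) < 3 || nrow(bb) == 0) {
    b1 <- integer(0); b2 <- integer(0); ord <- integer(0)
  } else {
    ok <- bb[, 1] > 0 & bb[, 2] > 0  # single-atom SDFs carry a dummy row
    b1 <- bb[ok, 1]; b2 <- bb[ok, 2]; ord <- bb[ok, 3]
  }
  deg <- tabulate(c(b1, b2), nbins = n)
  halogens <- c("F", "Cl", "Br", "I")

  # graph distances by BFS from every atom
  adj <- vector("list", n)
  for (i in seq_along(b1)) {
    adj[[b1[i]]] <- c(adj[[b1[i]]], b2[i])
    adj[[b2[i]]] <- c(adj[[b2[i]]], b1[i])
  }
  dm <- matrix(Inf, n, n)
  diag(dm) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dm[s, nxt] == Inf]
      dm[s, nxt] <- d
      frontier <- nxt
    }
  }
  finite <- dm[upper.tri(dm)][is.finite(dm[upper.tri(dm)])]
  ecc <- apply(dm, 1, function(r) max(r[is.finite(r)]))

  n_comp <- n - sum(vapply(seq_len(n), function(i) any(dm[i, seq_len(i - 1)] < Inf), logical(1)))
  n_rings <- length(b1) - n + n_comp

  randic <- if (length(b1)) sum(1 / sqrt(deg[b1] * deg[b2])) else 0
  zagreb1 <- sum(deg^2)
  zagreb2 <- if (length(b1)) sum(deg[b1] * deg[b2]) else 0
  p2 <- sum(choose(deg, 2))                    # paths of length 2
  p3 <- zagreb2 - p2                           # paths of length 3 (trees); proxy
  kappa1 <- if (length(b1)) n * (n - 1)^2 / length(b1)^2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0) {
    if (n %% 2 == 0) (n - 3) * (n - 2)^2 / p3^2 else (n - 1) * (n - 3)^2 / p3^2
  } else 0

  en <- electronegativity()[elems]
  en[is.na(en)] <- mean(electronegativity())

  env <- integer(96)
  elem_code <- match(elems, names(element_z()))
  elem_code[is.na(elem_code)] <- 0L
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    h <- (elem_code[i] * 131L + deg[i] * 17L +
            sum(elem_code[nb]) * 7L) %% 96L
    env[h + 1L] <- env[h + 1L] + 1L
  }

  c(n, sum(elems == "C"), sum(elems == "N"), sum(elems == "O"),
    sum(elems == "S"), sum(elems == "P"), sum(elems == "F"),
    sum(elems == "Cl"), sum(elems == "Br"), sum(elems == "I"),
    sum(!elems %in% c("C", "H")), mean(!elems %in% c("C", "H")),
    sum(elems %in% halogens), mean(elems %in% halogens),
    length(b1), sum(ord == 1), sum(ord == 2), sum(ord == 3),
    if (length(ord)) mean(ord) else 0, n_rings,
    sum(deg == 1), sum(deg == 2), sum(deg == 3), sum(deg >= 4), mean(deg),
    sum(finite), if (length(finite)) mean(finite) else 0,
    if (length(finite)) max(ecc) else 0,
    if (length(finite)) min(ecc) else 0,
    randic, zagreb1, zagreb2, kappa1, kappa2, kappa3, p2, p3,
    sum(en), mean(en), if (n > 1) stats::var(en) else 0, diff(range(en)),
    env)
}

#' Center and scale a descriptor block
#'
#' Each column is transformed to mean 0 and SD 1; zero-variance columns are
#' set to 0. The centering/scaling statistics are stored in attributes so
#' the transform is invertible.
#'
#' @param block a `"descriptor_block"` with `scaling_state == "raw"`.
#' @return the transformed block with `scaling_state = "centered_scaled"`.
#' @export
center_scale <- function(block) {
  assert_that(inherits(block, "descriptor_block"), "block required")
  assert_that(block$scaling_state == "raw",
              "block is already centered and scaled")
  mu <- colMeans(block$values)
  sdv <- apply(block$values, 2, stats::sd)
  scaled <- sweep(block$values, 2, mu, "-")
  nz <- sdv > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, sdv[nz], "/")
  scaled[, !nz] <- 0
  out <- descriptor_block(scaled, block$tag, block$metric, "centered_scaled")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' Fit and appraise one per-target bioactivity model
#'
#' Fits an ensemble-of-trees classifier on 2048-bit circular fingerprints
#' of the target's training molecules, Platt-calibrates it on out-of-fold
#' scores, and evaluates the two reliability criteria: recall on the
#' overlap (fraction of training actives that are also query compounds
#' receiving a calibrated out-of-fold probability of activity > 0.5) and
#' the mean nearest-neighbour Tanimoto similarity of the training set to
#' the query set. The model is retained only if recall >= 0.5 and mean NN
#' Tanimoto > 0.25 (strict).
#'
#' @param train data.frame with `compound_key`, `smiles`, `label`
#'   ("active"/"inactive") for one target.
#' @param query_fps binary fingerprint matrix of the query compounds
#'   (rownames are compound keys), from [ecfp_fingerprints()].
#' @param target_id identifier for reporting.
#' @param ntree trees in the ensemble.
#' @param seed RNG seed for fitting.
#' @return list with `card` (one-row data.frame: target_id,
#'   n_train_actives, n_train_inactives, recall_on_overlap,
#'   mean_nn_tanimoto, retained) and `model` (rf + Platt coefficients), or
#'   `retained = FALSE` with reason when the overlap is empty.
#' @export
evaluate_target_model <- function(train, query_fps, target_id = "target",
                                  ntree = 100, seed = 1) {
  assert_that(all(c("active", "inactive") %in% train$label),
              "training set must contain both classes")
  assert_that(nrow(query_fps) > 0, "query set must be non-empty")
  train <- train[!is.na(train$smiles), , drop = FALSE]
  fps <- ecfp_fingerprints(smiles_to_sdfset(
    stats::setNames(train$smiles, make.unique(train$compound_key))))
  y <- factor(train$label, levels = c("inactive", "active"))

  sim <- tanimoto_matrix(fps, query_fps)
  mean_nn_tan <- mean(apply(sim, 1, max))

  # out-of-fold scores for Platt calibration and honest recall
  folds <- stratified_folds(y, k = 5, seed = stage_seed(seed, target_id))
  oof <- rep(NA_real_, nrow(fps))
  set.seed(stage_seed(seed, paste0(target_id, "_fit")))
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    rf <- randomForest::randomForest(fps[tr, , drop = FALSE], y[tr],
                                     ntree = ntree)
    oof[!tr] <- stats::predict(rf, fps[!tr, , drop = FALSE],
                               type = "prob")[, "active"]
  }
  platt <- platt_fit(oof, y)
  oof_cal <- platt_apply(platt, oof)

  overlap <- which(train$label == "active" &
                     train$compound_key %in% rownames(query_fps))
  if (!length(overlap)) {
    recall <- NA_real_
    retained <- FALSE
  } else {
    recall <- mean(oof_cal[overlap] > 0.5, na.rm = TRUE)
    retained <- !is.na(recall) && recall >= 0.5 && mean_nn_tan > 0.25
  }

  rf_full <- randomForest::randomForest(fps, y, ntree = ntree)
  card <- data.frame(target_id = target_id,
                     n_train_actives = sum(y == "active"),
                     n_train_inactives = sum(y == "inactive"),
                     recall_on_overlap = recall,
                     mean_nn_tanimoto = mean_nn_tan,
                     retained = retained, stringsAsFactors = FALSE)
  list(card = card,
       model = list(rf = rf_full, platt = platt, target_id = target_id))
}

platt_fit <- function(score, y) {
  ok <- !is.na(score)
  if (sum(ok) < 4 || length(unique(y[ok])) < 2)
    return(c(a = 0, b = 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm((y == "active")[ok] ~ score[ok],
                                family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) return(c(a = 0, b = 1))
  cf <- stats::coef(fit)
  c(a = unname(cf[1]), b = unname(cf[2]))
}

platt_apply <- function(platt, score) {
  if (identical(unname(platt), c(0, 1))) return(score)
  stats::plogis(platt["a"] + platt["b"] * score)
}

#' Build the protein-target probability block
#'
#' Predicts calibrated probabilities of activity for every query compound
#' against each retained target model, then overrides cells listed as known
#' actives to exactly 1.0 (certainty).
#'
#' @param models list of retained model objects from
#'   [evaluate_target_model()] (`$model` entries).
#' @param query_fps fingerprint matrix of query compounds.
#' @param known_actives data.frame with `compound_key`, `target_id`.
#' @return a `"descriptor_block"` with tag `"target"`, metric euclidean,
#'   values in `[0, 1]`.
#' @export
build_target_block <- function(models, query_fps, known_actives = NULL) {
  assert_that(length(models) >= 1, "at least one retained model required")
  vals <- vapply(models, function(m) {
    raw <- stats::predict(m$rf, query_fps, type = "prob")[, "active"]
    p <- platt_apply(m$platt, raw)
    pmin(1, pmax(0, p))
  }, numeric(nrow(query_fps)))
  if (nrow(query_fps) == 1)
    vals <- matrix(vals, 1, dimnames = list(rownames(query_fps), NULL))
  colnames(vals) <- vapply(models, function(m) m$target_id, character(1))
  rownames(vals) <- rownames(query_fps)
  if (!is.null(known_actives) && nrow(known_actives)) {
    ka <- known_actives[known_actives$target_id %in% colnames(vals) &
                          known_actives$compound_key %in% rownames(vals), ,
                        drop = FALSE]
    vals[cbind(ka$compound_key, ka$target_id)] <- 1.0
  }
  descriptor_block(vals, "target", "euclidean", "raw")
}

#' Build the qHTS assay-score block
#'
#' Assays flagged `counter_screen`, `autofluorescence` or
#' `confirmatory_superseded` in the metadata are dropped first; repeated
#' (compound, assay) measurements are collapsed to the median score; cells
#' with no record are assumed inactive and assigned 0.
#'
#' @param assay long data.frame: `compound_key`, `assay_id`, `score`
#'   (in `[0, 100]`), `replicate`.
#' @param assay_meta data.frame: `assay_id`, `flag`.
#' @param compound_keys ordered compound keys for the block rows (defaults
#'   to the compounds present in `assay`).
#' @return a `"descriptor_block"` with tag `"assay"`, metric cosine.
#' @export
build_assay_block <- function(assay, assay_meta = NULL,
                              compound_keys = NULL) {
  bad <- which(assay$score < 0 | assay$score > 100)
  if (length(bad))
    stop("assay scores outside [0, 100] at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (!is.null(assay_meta)) {
    drop_ids <- assay_meta$assay_id[assay_meta$flag %in%
                                      c("counter_screen", "autofluorescence",
                                        "confirmatory_superseded")]
    assay <- assay[!assay$assay_id %in% drop_ids, , drop = FALSE]
  }
  if (is.null(compound_keys))
    compound_keys <- sort(unique(assay$compound_key))
  assay_ids <- sort(unique(assay$assay_id))
  med <- stats::aggregate(score ~ compound_key + assay_id, data = assay,
                          FUN = stats::median)
  vals <- matrix(0, length(compound_keys), length(assay_ids),
                 dimnames = list(compound_keys, assay_ids))
  keep <- med$compound_key %in% compound_keys
  vals[cbind(med$compound_key[keep], med$assay_id[keep])] <- med$score[keep]
  descriptor_block(vals, "assay", "cosine", "raw")
}
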