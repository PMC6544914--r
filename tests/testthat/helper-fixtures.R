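# Shared fixtures, generated in code at test time.

# small reference study, cached per session
small_study <- local({
  cache <- NULL
  function(n = 250, seed = 11, ...) {
    args <- list(n_compounds = n, seed = seed, ...)
    key <- paste(deparse(args), collapse = "")
    if (!is.null(cache) && identical(cache$key, key)) return(cache$study)
    study <- generate_study(do.call(generator_config, args))
    cache <<- list(key = key, study = study)
    study
  }
})

# modelling-ready labels and standardized SMILES from a study
modelling_data <- function(study) {
  lab <- harmonize_labels(study$observations)
  oral <- lab[lab$route == "oral", ]
  bin <- binarize_oral(oral$category)
  y <- stats::setNames(bin, oral$compound_key)[bin != "excluded"]
  smiles <- stats::setNames(study$library$smiles,
                            study$library$compound_key)[names(y)]
  std <- stats::setNames(smiles_standardize(smiles), names(smiles))
  list(y = y, smiles = smiles, std = std, labels = lab)
}

# library-shaped data.frame with arbitrary planted fragments, bypassing
# grammar assembly (for Monte-Carlo checks of the generative link)
synthetic_library_frame <- function(n, frag, seed = 1) {
  set.seed(seed)
  data.frame(compound_key = sprintf("K%05d", seq_len(n)),
             cas_key = sprintf("00-%05d-0", seq_len(n)),
             smiles = rep("c1ccccc1", n),
             substance_type = "Chemical",
             scaffold_id = "benzene",
             sub1_id = sample(c("methyl", "ethyl"), n, replace = TRUE),
             sub2_id = "methyl",
             frag = frag, stringsAsFactors = FALSE)
}

# deterministic two-class gaussian clouds for separation analyses
gaussian_blocks <- function(n_per_class, p, delta, seed = 1,
                            tag = "molecular") {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             sweep(matrix(stats::rnorm(n_per_class * p), ncol = p), 2,
                   c(delta, rep(0, p - 1)), "+"))
  rownames(x) <- sprintf("G%05d", seq_len(2 * n_per_class))
  colnames(x) <- sprintf("f%02d", seq_len(p))
  labels <- rep(c("nontoxic", "toxic"), each = n_per_class)
  list(block = descriptor_block(x, tag,
                                if (tag == "assay") "cosine" else "euclidean",
                                "centered_scaled"),
       labels = labels)
}

# brute-force nearest-neighbour oracle (O(n^2), all pairs)
nn_bruteforce <- function(x, labels, metric) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (metric == "euclidean") {
      d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    } else {
      ni <- sqrt(sum(x[i, ]^2)); nj <- sqrt(sum(x[j, ]^2))
      d[i, j] <- if (ni == 0 && nj == 0) 0 else if (ni == 0 || nj == 0) 1
      else 1 - sum(x[i, ] * x[j, ]) / (ni * nj)
    }
  }
  intra <- inter <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    diff <- which(labels != labels[i])
    intra[i] <- min(d[i, same])
    inter[i] <- min(d[i, diff])
  }
  list(intra = intra, inter = inter)
}
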