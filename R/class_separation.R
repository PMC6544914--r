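## Class-separation analyses: nearest-neighbour distance distributions,
## per-feature class tests, and a regularized two-class Fisher discriminant.

# pairwise distance matrix with the package's cosine conventions:
# the cosine distance of a zero vector against anything is 1 (orthogonality
# convention for all-inactive assay rows), and 0 against another zero vector.
pairwise_distances <- function(x, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    nrm <- sqrt(rowSums(x^2))
    ip <- x %*% t(x)
    d <- 1 - ip / outer(nrm, nrm)
    zero <- nrm == 0
    d[zero, ] <- 1
    d[, zero] <- 1
    d[zero, zero] <- 0
    diag(d) <- 0
    pmin(pmax(d, 0), 2)
  }
}

#' Intra- and inter-class nearest-neighbour distances
#'
#' For every compound, the distance to its nearest neighbour in its own
#' class (self excluded) and in the other class. The metric follows the
#' block tag: euclidean for molecular/target blocks (the molecular block
#' must be centered and scaled first), cosine for the sparse assay block.
#'
#' @param block a `"descriptor_block"`.
#' @param labels character vector (`"toxic"`/`"nontoxic"`) aligned with the
#'   block rows.
#' @return data.frame with `compound_key`, `label`, `intra`, `inter`.
#' @export
nn_distances <- function(block, labels) {
  assert_that(inherits(block, "descriptor_block"), "block required")
  assert_that(nrow(block$values) == length(labels),
              "labels must align with block rows")
  assert_that(all(table(labels) >= 2), "each class needs >= 2 members")
  if (block$tag == "molecular")
    assert_that(block$scaling_state == "centered_scaled",
                "molecular block must be centered and scaled first")
  d <- pairwise_distances(block$values, block$metric)
  diag(d) <- NA
  n <- nrow(d)
  same <- outer(labels, labels, "==")
  intra <- vapply(seq_len(n), function(i)
    min(d[i, same[i, ] & !is.na(d[i, ])]), numeric(1))
  inter <- vapply(seq_len(n), function(i)
    min(d[i, !same[i, ]]), numeric(1))
  data.frame(compound_key = rownames(block$values) %||% as.character(seq_len(n)),
             label = labels, intra = intra, inter = inter,
             stringsAsFactors = FALSE)
}

#' Paired separation statistics on nearest-neighbour distances
#'
#' Paired t test on (inter - intra) and Cohen's d with the equal-n pooled
#' standard deviation `sqrt((s1^2 + s2^2)/2)`. Positive d means inter-class
#' neighbours are farther than intra-class neighbours (neighbourhood
#' behaviour).
#'
#' @param intra,inter equal-length distance vectors (length >= 3).
#' @return list with `t`, `p`, `d` (`d` is `NA` with a `degenerate` flag
#'   when the pooled SD is zero).
#' @export
paired_separation_stats <- function(intra, inter) {
  assert_that(length(intra) == length(inter) && length(intra) >= 3,
              "need equal-length vectors of length >= 3")
  pooled <- sqrt((stats::var(intra) + stats::var(inter)) / 2)
  if (all(inter == intra)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(inter, intra, paired = TRUE)
  }
  d <- if (pooled == 0) NA_real_ else (mean(inter) - mean(intra)) / pooled
  list(t = unname(tt$statistic), p = tt$p.value, d = d,
       degenerate = pooled == 0)
}

#' Per-feature class difference tests
#'
#' For each feature, a two-sample (Welch) t test and a two-sample
#' Kolmogorov-Smirnov test between the classes; a feature is significant
#' when the larger of the two p values is below the Bonferroni-corrected
#' threshold `alpha / n_features`. Cohen's d uses the Bessel-corrected
#' pooled SD and is positive when the toxic mean exceeds the nontoxic mean.
#' Output is ranked by |d| among significant features, then the rest.
#'
#' @param block a `"descriptor_block"`.
#' @param labels `"toxic"`/`"nontoxic"` vector aligned with rows.
#' @param alpha familywise significance level.
#' @return data.frame: `feature_name`, `t_p`, `ks_p`, `cohens_d`,
#'   `significant`, `degenerate`.
#' @export
per_feature_class_tests <- function(block, labels, alpha = 0.05) {
  assert_that(all(c("toxic", "nontoxic") %in% labels),
              "both classes must be present")
  x <- block$values
  p <- ncol(x)
  tox <- labels == "toxic"
  out <- lapply(seq_len(p), function(j) {
    a <- x[tox, j]; b <- x[!tox, j]
    degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degenerate) {
      tp <- 1; kp <- 1; d <- 0
    } else {
      tp <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
      kp <- suppressWarnings(stats::ks.test(a, b)$p.value)
      sp <- sqrt(((length(a) - 1) * stats::var(a) +
                    (length(b) - 1) * stats::var(b)) /
                   (length(a) + length(b) - 2))
      d <- if (sp == 0) 0 else (mean(a) - mean(b)) / sp
    }
    data.frame(feature_name = colnames(x)[j], t_p = tp, ks_p = kp,
               cohens_d = d,
               significant = max(tp, kp) < alpha / p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(-res$significant, -abs(res$cohens_d), res$feature_name), ]
  rownames(res) <- NULL
  res
}

#' Two-class Fisher linear discriminant
#'
#' Computes the discriminant direction
#' `w = Sigma_pooled^-1 (mu_toxic - mu_nontoxic)` with an eigenvalue-floor
#' regularization of the pooled within-class covariance (eigenvalues are
#' floored at `floor_frac * trace/p`, which keeps near-singular assay
#' blocks invertible), projects the data onto it, and reports the unpaired
#' t test and Cohen's d (Bessel-corrected pooled SD) of the projected
#' classes. Weights are reported with an absolute-value ranking.
#'
#' @param block a `"descriptor_block"`.
#' @param labels `"toxic"`/`"nontoxic"` vector aligned with rows.
#' @param floor_frac eigenvalue floor as a fraction of `trace/p`.
#' @return list with `weights` (named, original feature order),
#'   `ranking` (data.frame by |weight|), `projection`, `t`, `p`, `d`.
#' @export
fit_lda <- function(block, labels, floor_frac = 1e-6) {
  x <- block$values
  assert_that(all(c("toxic", "nontoxic") %in% labels),
              "both classes must be present")
  tox <- labels == "toxic"
  n1 <- sum(tox); n2 <- sum(!tox)
  mu1 <- colMeans(x[tox, , drop = FALSE])
  mu2 <- colMeans(x[!tox, , drop = FALSE])
  s1 <- stats::cov(x[tox, , drop = FALSE])
  s2 <- stats::cov(x[!tox, , drop = FALSE])
  sw <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)

  eig <- eigen(sw, symmetric = TRUE)
  floor_val <- floor_frac * sum(diag(sw)) / ncol(x)
  vals <- pmax(eig$values, floor_val)
  if (all(vals <= 0))
    stop("pooled covariance singular even after eigenvalue floor ",
         floor_frac, call. = FALSE)
  w <- eig$vectors %*% ((t(eig$vectors) %*% (mu1 - mu2)) / vals)
  w <- as.numeric(w)
  names(w) <- colnames(x)

  proj <- as.numeric(x %*% w)
  a <- proj[tox]; b <- proj[!tox]
  tt <- stats::t.test(a, b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  d <- if (sp == 0) NA_real_ else (mean(a) - mean(b)) / sp
  ranking <- data.frame(feature_name = names(w), weight = w,
                        abs_weight = abs(w), stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$abs_weight, ranking$feature_name), ]
  rownames(ranking) <- NULL
  list(weights = w, ranking = ranking, projection = proj,
       t = unname(tt$statistic), p = tt$p.value, d = d)
}
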