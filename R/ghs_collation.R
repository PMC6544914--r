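## GHS label harmonization.
##
## Pools per-source GHS observations into one harmonized per-route label per
## compound. Authoritative sources take precedence over notification-derived
## labels; presence in an authoritative source without an acute-toxicity
## category for the route is read as implied nontoxicity (encoded as a
## hypothetical category 6); notification count vectors are converted to a
## category by the cumulative 10% rule.

CAT_IMPLIED_NONTOXIC <- 6L

#' Harmonize authoritative observations for one compound and route
#'
#' If no source covers the compound the result is `NULL`. If at least one
#' source covers it but none assigns a category for the route, the compound
#' is implied nontoxic (category 6). Conflicting categories between sources
#' are resolved to the most severe (numerically lowest) category, a
#' hazard-conservative policy.
#'
#' @param observations data.frame of authoritative observations sharing one
#'   `compound_key` and `route` (columns `compound_key`, `source_id`,
#'   `tier`, `route`, `category`; `category` `NA` denotes presence without
#'   an acute-toxicity category).
#' @return list with `category` (1:6) and `provenance = "authoritative"`,
#'   or `NULL` when no source covers the compound.
#' @export
derive_authoritative_label <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0) return(NULL)
  assert_that(length(unique(observations$compound_key)) == 1,
              "observations must share one compound_key")
  assert_that(length(unique(observations$route)) == 1,
              "observations must share one route")
  assert_that(all(observations$tier == "authoritative"),
              "observations must be authoritative tier")
  cats <- observations$category[!is.na(observations$category)]
  if (!length(cats)) {
    list(category = CAT_IMPLIED_NONTOXIC, provenance = "authoritative")
  } else {
    assert_that(all(cats %in% 1:5), "authoritative categories must be 1..5")
    list(category = min(cats), provenance = "authoritative")
  }
}

#' Derive a category from notification counts (cumulative 10% rule)
#'
#' A category `c` qualifies when at least `threshold` of all notifications
#' are at category `c` or more severe, i.e. the cumulative fraction
#' `f(c) = sum(counts[1..c]) / total >= threshold`; the most severe
#' qualifying category is returned. The comparison uses exact integer
#' arithmetic (counts scaled against the threshold as a rational number) so
#' boundary cases such as exactly 10% are never lost to floating point.
#' When no category qualifies the compound is implied nontoxic.
#'
#' @param counts named numeric vector with entries `"1"`..`"5"` and
#'   `"none"` (missing entries are treated as 0).
#' @param threshold qualifying fraction in (0, 1); default 0.10.
#' @return list with `category` (1:6) and `provenance = "notification"`.
#' @export
derive_notification_label <- function(counts, threshold = 0.10) {
  full <- stats::setNames(numeric(6), c(as.character(1:5), "none"))
  full[names(counts)] <- counts
  assert_that(all(full >= 0), "notification counts must be non-negative")
  total <- sum(full)
  assert_that(total > 0, "total notification count must be > 0")
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  # rational comparison: cum/total >= num/den  <=>  cum * den >= num * total
  den <- 1e6
  num <- round(threshold * den)
  cum <- cumsum(full[1:5])
  pass <- which(cum * den >= num * total)
  if (length(pass)) {
    list(category = as.integer(min(pass)), provenance = "notification")
  } else {
    list(category = CAT_IMPLIED_NONTOXIC, provenance = "notification")
  }
}

#' Merge authoritative and notification labels
#'
#' The authoritative label is preferred whenever present; the
#' notification-derived label is used only as a fallback.
#'
#' @param auth,notif label lists as returned by the `derive_*` functions,
#'   or `NULL`.
#' @return the preferred label list, or `NULL` if both are absent.
#' @export
merge_labels <- function(auth, notif) {
  if (!is.null(auth)) auth else notif
}

#' Harmonize a full observation table
#'
#' Applies [derive_authoritative_label()], [derive_notification_label()]
#' (counts summed over notification records) and [merge_labels()] per
#' compound and route.
#'
#' @param observations observation data.frame (schema of
#'   [generate_ghs_observations()]).
#' @param threshold notification qualifying fraction.
#' @return data.frame with columns `compound_key`, `route`, `category`
#'   (1:6) and `provenance`.
#' @export
harmonize_labels <- function(observations, threshold = 0.10) {
  key <- paste(observations$compound_key, observations$route, sep = "\r")
  out <- lapply(split(observations, key), function(d) {
    auth_rows <- d[d$tier == "authoritative", , drop = FALSE]
    auth <- derive_authoritative_label(
      if (nrow(auth_rows)) auth_rows else NULL)
    notif_rows <- d[d$tier == "notification", , drop = FALSE]
    notif <- NULL
    if (nrow(notif_rows)) {
      counts <- colSums(notif_rows[, c("notif_1", "notif_2", "notif_3",
                                       "notif_4", "notif_5", "notif_none")],
                        na.rm = TRUE)
      names(counts) <- c(as.character(1:5), "none")
      if (sum(counts) > 0)
        notif <- derive_notification_label(counts, threshold)
    }
    lab <- merge_labels(auth, notif)
    if (is.null(lab)) return(NULL)
    data.frame(compound_key = d$compound_key[1], route = d$route[1],
               category = lab$category, provenance = lab$provenance,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Pairwise source overlap (intersection over union)
#'
#' @param presence named list mapping source id to a character vector (set)
#'   of compound keys.
#' @return symmetric matrix of IoU fractions; unit diagonal for non-empty
#'   sources; entries involving two empty sources are `NA`.
#' @export
source_overlap_matrix <- function(presence) {
  assert_that(length(presence) >= 1, "at least one source required")
  ids <- names(presence)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    a <- unique(presence[[i]]); b <- unique(presence[[j]])
    u <- length(union(a, b))
    m[i, j] <- if (u == 0) NA_real_ else length(intersect(a, b)) / u
  }
  m
}

#' Pairwise label agreement between source-route label maps
#'
#' @param labels named list; each element is a named integer vector mapping
#'   compound key to category in 1..6 for one (source, route) pair.
#' @return square matrix: fraction of compounds common to both maps with
#'   identical category; `NA` where no compounds are common.
#' @export
label_agreement_matrix <- function(labels) {
  ids <- names(labels)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    common <- intersect(names(labels[[i]]), names(labels[[j]]))
    if (length(common))
      m[i, j] <- mean(labels[[i]][common] == labels[[j]][common])
  }
  m
}

#' Binarize a harmonized oral label
#'
#' Categories 1-3 (those requiring the "toxic" pictogram) map to the toxic
#' class; category 5 and implied nontoxicity (no pictogram) map to the
#' nontoxic class; category 4 ("harmful") is marginal and excluded from
#' binary analyses.
#'
#' @param category integer vector of harmonized categories in 1..6.
#' @return character vector: `"toxic"`, `"nontoxic"` or `"excluded"`.
#' @export
binarize_oral <- function(category) {
  assert_that(all(category %in% 1:6), "categories must be in 1..6")
  ifelse(category %in% 1:3, "toxic",
         ifelse(category %in% c(5L, 6L), "nontoxic", "excluded"))
}
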