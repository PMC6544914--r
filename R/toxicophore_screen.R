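## SMARTS-based toxicophore screening and class-enrichment statistics.

#' Load an alert set
#'
#' Reads a CSV/TSV alert file (columns `alert_id`, `smarts`, `severity`,
#' `description`, `source_label`) and validates that every SMARTS parses by
#' test-matching it against a probe molecule; unparsable SMARTS abort the
#' load with the offending alert ids.
#'
#' @param path alert file path; default is the packaged set of five
#'   reactive chemotypes (P=S bond, thiourea, nitroso, thiocarbonyl,
#'   gem-dihalo).
#' @return data.frame of alert definitions.
#' @export
read_alerts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "alerts_default.csv", package = "ghstox")
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  alerts <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  assert_that(all(c("alert_id", "smarts", "severity") %in% names(alerts)),
              "alert file must have alert_id, smarts, severity columns")
  probe <- ghstox_env$alert_probe
  if (is.null(probe)) {
    probe <- ob_read_mols(c(probe = "CC(=O)NC(=S)N"))
    ghstox_env$alert_probe <- probe
  }
  bad <- vapply(alerts$smarts, function(s)
    inherits(tryCatch(smarts_count(probe, s),
                      error = function(e) e), "error"), logical(1))
  if (any(bad))
    stop("unparsable SMARTS for alerts: ",
         paste(alerts$alert_id[bad], collapse = ", "), call. = FALSE)
  alerts
}

#' Screen structures against an alert set
#'
#' @param smiles named character vector of standardized SMILES.
#' @param alerts alert definition data.frame from [read_alerts()].
#' @return binary matrix, compounds x alerts; cell 1 iff the alert's
#'   substructure is present.
#' @export
screen_alerts <- function(smiles, alerts = read_alerts()) {
  mols <- ob_read_mols(smiles)
  hits <- vapply(alerts$smarts, function(pat)
    as.integer(smarts_count(mols, pat) > 0), integer(length(mols)))
  if (length(mols) == 1) hits <- matrix(hits, 1)
  dimnames(hits) <- list(names(mols), alerts$alert_id)
  hits
}

#' Three-way screening outcome for each compound
#'
#' Default policy: any high-severity alert hit rejects the compound; a
#' moderate hit with no high hit gives an intermediate outcome; no hits
#' accept it.
#'
#' @param hit_matrix binary compound x alert matrix from [screen_alerts()].
#' @param alerts alert definitions (supplies severities).
#' @return character vector (`accepted` / `intermediate` / `rejected`)
#'   named by compound.
#' @export
three_way_outcome <- function(hit_matrix, alerts = read_alerts()) {
  sev <- alerts$severity[match(colnames(hit_matrix), alerts$alert_id)]
  high <- hit_matrix[, sev == "high", drop = FALSE]
  mod <- hit_matrix[, sev == "moderate", drop = FALSE]
  out <- ifelse(rowSums(high) > 0, "rejected",
                ifelse(rowSums(mod) > 0, "intermediate", "accepted"))
  stats::setNames(out, rownames(hit_matrix))
}

#' Per-alert class enrichment
#'
#' For each alert, builds the 2x2 table of alert presence against the
#' binary toxicity class, computes the odds ratio (with the
#' Haldane-Anscombe +0.5 correction when a cell is zero, configurable off)
#' and the two-sided Fisher exact p value, and flags Bonferroni
#' significance at `alpha / n_alerts`. Output is ranked by descending odds
#' ratio among significant alerts, then the rest, ties broken by alert id.
#'
#' @param hit_matrix binary compound x alert matrix.
#' @param labels character vector (`"toxic"` / `"nontoxic"`) aligned with
#'   the rows (excluded compounds must be removed upstream).
#' @param alpha familywise significance level.
#' @param haldane apply the +0.5 zero-cell correction to the odds ratio.
#' @return data.frame: `alert_id`, `a`, `b`, `c`, `d` (toxic-with,
#'   toxic-without, nontoxic-with, nontoxic-without), `odds_ratio`,
#'   `p_value`, `significant`.
#' @export
alert_enrichment <- function(hit_matrix, labels, alpha = 0.05,
                             haldane = TRUE) {
  assert_that(all(labels %in% c("toxic", "nontoxic")),
              "labels must be toxic/nontoxic only")
  assert_that(nrow(hit_matrix) == length(labels),
              "hit matrix rows must align with labels")
  n_alerts <- ncol(hit_matrix)
  tox <- labels == "toxic"
  recs <- lapply(seq_len(n_alerts), function(j) {
    with_alert <- hit_matrix[, j] == 1
    a <- sum(tox & with_alert)
    b <- sum(tox & !with_alert)
    c_ <- sum(!tox & with_alert)
    d <- sum(!tox & !with_alert)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    data.frame(alert_id = colnames(hit_matrix)[j], a = a, b = b, c = c_,
               d = d, odds_ratio = haldane_or(a, b, c_, d, haldane),
               p_value = p, significant = p < alpha / n_alerts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, recs)
  res <- res[order(-res$significant, -res$odds_ratio, res$alert_id), ]
  rownames(res) <- NULL
  res
}
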