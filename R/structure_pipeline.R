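## Structure standardization, small-organic filtering, InChI-based
## deduplication and Lipinski diagnostics.

# atomic numbers excluded by the small-organic filter:
# 21-32 (Sc..Ge), 36-52 (Kr..Te), and everything above iodine (Z > 53)
forbidden_atomic_numbers <- function(zmax = 118L) {
  c(21:32, 36:52, 54:zmax)
}

element_z <- function() {
  c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9,
    Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17,
    Ar = 18, K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25,
    Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32,
    As = 33, Se = 34, Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40,
    Nb = 41, Mo = 42, Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47,
    Cd = 48, In = 49, Sn = 50, Sb = 51, Te = 52, I = 53, Xe = 54,
    Cs = 55, Ba = 56, Hg = 80, Pb = 82, Bi = 83, U = 92)
}

#' Standardize a compound table
#'
#' Applies [smiles_standardize()] to every record and derives the InChI
#' structure key from the standardized SMILES. Unparsable structures are
#' flagged (`discard_reason = "parse_error"`) rather than raising an error.
#'
#' @param compounds data.frame with `compound_key` and `raw_smiles` (or
#'   `smiles`, taken as raw) columns.
#' @return the input with columns `std_smiles`, `structure_key` (InChI) and
#'   `discard_reason` (`NA` for clean records) added.
#' @export
standardize_structures <- function(compounds) {
  raw <- compounds$raw_smiles %||% compounds$smiles
  assert_that(!is.null(raw), "compounds must have raw_smiles or smiles")
  compounds$raw_smiles <- raw
  compounds$std_smiles <- smiles_standardize(raw)
  compounds$structure_key <- NA_character_
  ok <- !is.na(compounds$std_smiles)
  compounds$structure_key[ok] <- smiles_inchi(compounds$std_smiles[ok])
  compounds$discard_reason <- ifelse(
    is.na(compounds$std_smiles) | is.na(compounds$structure_key),
    "parse_error", NA_character_)
  compounds
}

#' Small-organic filter
#'
#' Discards records that are mixtures/polymers/macromolecules (by
#' `substance_type`), contain no carbon atom, contain an element from the
#' forbidden set (atomic numbers 21-32, 36-52, > 53), or fail the molecular
#' weight rule. The printed-rule reading `mw_rule = "lower"` discards
#' MW < `mw_limit` (default 100 Da); the alternative reading
#' `mw_rule = "upper"` discards MW > `mw_limit`.
#'
#' @param compounds standardized compound table
#'   (from [standardize_structures()]).
#' @param mw_limit molecular weight bound in Da.
#' @param mw_rule `"lower"` (discard below) or `"upper"` (discard above).
#' @return the table with `discard_reason` filled in
#'   (`mixture_or_polymer`, `no_carbon`, `forbidden_element`, `mw`);
#'   records already discarded are left untouched.
#' @export
filter_small_organic <- function(compounds, mw_limit = 100,
                                 mw_rule = c("lower", "upper")) {
  mw_rule <- match.arg(mw_rule)
  live <- which(is.na(compounds$discard_reason))
  if (!is.null(compounds$substance_type)) {
    bad_type <- live[compounds$substance_type[live] %in%
                       c("Mixture/Formulation", "Polymer", "Macromolecule")]
    compounds$discard_reason[bad_type] <- "mixture_or_polymer"
    live <- setdiff(live, bad_type)
  }
  if (!length(live)) return(compounds)

  zs <- element_z()
  forbidden <- forbidden_atomic_numbers()
  sdfset <- smiles_to_sdfset(
    stats::setNames(compounds$std_smiles[live], compounds$compound_key[live]))
  props <- mol_properties(
    stats::setNames(compounds$std_smiles[live], compounds$compound_key[live]))
  for (i in live) {
    key <- compounds$compound_key[i]
    if (!key %in% ChemmineR::cid(sdfset) || is.na(props[key, "MW"])) {
      compounds$discard_reason[i] <- "parse_error"
      next
    }
    elems <- atom_symbols(sdfset[[key]])
    z <- zs[elems]
    if (any(is.na(z)) || any(z %in% forbidden)) {
      compounds$discard_reason[i] <- "forbidden_element"
    } else if (!any(elems == "C")) {
      compounds$discard_reason[i] <- "no_carbon"
    } else {
      mw <- props[key, "MW"]
      fail_mw <- if (mw_rule == "lower") mw < mw_limit else mw > mw_limit
      if (fail_mw) compounds$discard_reason[i] <- "mw"
    }
  }
  compounds
}

#' Deduplicate by structure key
#'
#' Groups kept records by InChI. Singleton groups are retained. Within a
#' duplicate group, members without a GHS annotation are dropped; if more
#' than one annotated member remains, the group is retained only if exactly
#' one member's raw SMILES equals its standardized SMILES (the closest
#' representation of the annotated substance), otherwise the whole group is
#' discarded.
#'
#' @param compounds standardized, filtered compound table with a logical
#'   `has_ghs` column.
#' @return the table with `discard_reason` set to `duplicate_no_ghs` or
#'   `duplicate_unresolved` for dropped members.
#' @export
deduplicate_structures <- function(compounds) {
  assert_that(!is.null(compounds$has_ghs), "compounds must have has_ghs")
  live <- which(is.na(compounds$discard_reason))
  groups <- split(live, compounds$structure_key[live])
  for (g in groups) {
    if (length(g) < 2) next
    annotated <- g[compounds$has_ghs[g]]
    compounds$discard_reason[setdiff(g, annotated)] <- "duplicate_no_ghs"
    if (length(annotated) > 1) {
      exact <- annotated[compounds$raw_smiles[annotated] ==
                           compounds$std_smiles[annotated]]
      if (length(exact) == 1) {
        compounds$discard_reason[setdiff(annotated, exact)] <-
          "duplicate_unresolved"
      } else {
        compounds$discard_reason[annotated] <- "duplicate_unresolved"
      }
    }
  }
  compounds
}

#' Lipinski rule-of-five pass
#'
#' A structure passes when it has at most one violation of MW <= 500,
#' logP <= 5, H-bond donors <= 5 and H-bond acceptors <= 10.
#'
#' @param smiles character vector of standardized SMILES.
#' @return logical vector (`NA` where the structure cannot be parsed).
#' @export
lipinski_pass <- function(smiles) {
  props <- mol_properties(stats::setNames(smiles,
                                          paste0("L", seq_along(smiles))))
  v <- (props$MW > 500) + (props$logP > 5) + (props$HBD > 5) +
    (props$HBA1 > 10)
  v <= 1
}

#' Lipinski enrichment between annotated and unannotated compounds
#'
#' Builds the 2x2 table (annotated vs not, pass vs fail) and reports the
#' odds ratio `ad/bc` (with the Haldane-Anscombe +0.5 correction applied
#' when any cell is zero) and the two-sided Fisher exact p value.
#'
#' @param pass logical vector of Lipinski outcomes.
#' @param annotated logical vector, same length: has a GHS annotation.
#' @return list with `table`, `odds_ratio`, `p_value`.
#' @export
lipinski_enrichment <- function(pass, annotated) {
  keep <- !is.na(pass) & !is.na(annotated)
  pass <- pass[keep]; annotated <- annotated[keep]
  assert_that(length(pass) > 0, "no complete observations")
  a <- sum(annotated & pass)
  b <- sum(annotated & !pass)
  c_ <- sum(!annotated & pass)
  d <- sum(!annotated & !pass)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("annotated", "unannotated"),
                                c("pass", "fail")))
  or <- haldane_or(a, b, c_, d)
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p_value = p)
}

# odds ratio a*d / (b*c); +0.5 on every cell when any cell is zero
haldane_or <- function(a, b, c_, d, correct = TRUE) {
  if (correct && any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

#' Run the full structure pipeline
#'
#' Standardize, filter, deduplicate; returns the annotated table plus a
#' discard accounting.
#'
#' @param compounds data.frame with `compound_key`, `smiles` (raw),
#'   optional `substance_type`, and `has_ghs`.
#' @inheritParams filter_small_organic
#' @return list with `compounds` (annotated table), `retained` (subset with
#'   no discard reason) and `accounting` (data.frame reason x count).
#' @export
structure_pipeline <- function(compounds, mw_limit = 100,
                               mw_rule = c("lower", "upper")) {
  mw_rule <- match.arg(mw_rule)
  out <- standardize_structures(compounds)
  out <- filter_small_organic(out, mw_limit, mw_rule)
  out <- deduplicate_structures(out)
  tab <- table(out$discard_reason[!is.na(out$discard_reason)])
  acc <- data.frame(reason = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  list(compounds = out,
       retained = out[is.na(out$discard_reason), , drop = FALSE],
       accounting = acc)
}
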