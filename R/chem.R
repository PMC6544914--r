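## Thin chemistry layer over ChemmineR / ChemmineOB (OpenBabel).
## All SMILES handling in the package funnels through these helpers so that
## toolkit conventions (canonicalization dialect, fingerprint folding) are
## decided in exactly one place.

#' Convert SMILES to canonical SMILES
#'
#' Canonicalization is OpenBabel's canonical SMILES writer. Unparsable input
#' yields `NA` rather than an error so callers can flag records.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where unparsable.
#' @export
smiles_canonical <- function(smiles) {
  vapply(smiles, function(s) ob_convert(s, "SMI", "CAN"), character(1),
         USE.NAMES = FALSE)
}

#' Standardize a SMILES string
#'
#' Applies the structure-normalization protocol used throughout the package:
#' retain the largest fragment (stripping counterions), neutralize charges
#' where a proton can be added or removed without a valence violation, and
#' emit OpenBabel canonical SMILES (which fixes a deterministic mesomer /
#' tautomer representation). Idempotent: standardizing an already-standard
#' SMILES returns it unchanged.
#'
#' @param smiles character vector of raw SMILES.
#' @return character vector of standardized canonical SMILES, `NA` where the
#'   input could not be parsed.
#' @export
smiles_standardize <- function(smiles) {
  opts <- data.frame(names = c("r", "neutralize"), args = c("", ""))
  vapply(smiles, function(s) ob_convert(s, "SMI", "CAN", opts), character(1),
         USE.NAMES = FALSE)
}

#' Convert SMILES to InChI structure keys
#'
#' @param smiles character vector of (standardized) SMILES.
#' @return character vector of standard InChI strings, `NA` where unparsable.
#' @export
smiles_inchi <- function(smiles) {
  vapply(smiles, function(s) ob_convert(s, "SMI", "INCHI"), character(1),
         USE.NAMES = FALSE)
}

# single-molecule OpenBabel conversion with error capture
ob_convert <- function(x, from, to, options = NULL) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  if (is.null(options)) options <- data.frame(names = character(0),
                                              args = character(0))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = x,
                                               options = options)),
    error = function(e) NA_character_
  )
  if (is.na(out) || !nzchar(trimws(out))) return(NA_character_)
  trimws(sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1]))
}

#' Parse SMILES into an SDFset
#'
#' @param smiles named character vector (names become compound ids).
#' @return a `ChemmineR::SDFset`; molecules that fail to parse are dropped and
#'   reported via the `"failed"` attribute (character vector of ids).
#' @export
smiles_to_sdfset <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- sprintf("cmp%05d", seq_along(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  parsed <- vector("list", sum(ok))
  good <- logical(sum(ok))
  sub <- smiles[ok]
  for (i in seq_along(sub)) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(sub[i])),
                    error = function(e) NULL)
    if (!is.null(sdf)) {
      parsed[[i]] <- sdf[[1]]
      good[i] <- TRUE
    }
  }
  sdfset <- methods::new(methods::getClassDef("SDFset", package = "ChemmineR"),
                         SDF = parsed[good], ID = names(sub)[good])
  attr(sdfset, "failed") <- c(names(smiles)[!ok], names(sub)[!good])
  sdfset
}

#' Physicochemical properties via OpenBabel
#'
#' Returns the OpenBabel property set (MW, logP, TPSA, MR, HBA1, HBA2, HBD,
#' nF) for each structure, computed directly from SMILES.
#'
#' @param smiles named character vector of SMILES (names are compound ids;
#'   generated when absent).
#' @return data.frame, one row per input (rownames = ids), numeric columns;
#'   `NA` rows where the structure could not be processed.
#' @export
mol_properties <- function(smiles) {
  if (is.null(names(smiles)))
    names(smiles) <- sprintf("cmp%05d", seq_along(smiles))
  fields <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  out <- matrix(NA_real_, length(smiles), length(fields),
                dimnames = list(names(smiles), fields))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    src <- paste(paste(smiles[ok], names(smiles)[ok]), collapse = "\n")
    opts <- data.frame(names = "append", args = paste(fields, collapse = " "))
    txt <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "TXT", source = src,
                                                 options = opts)),
      error = function(e) "")
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(parts) != length(fields) + 1) next
      id <- parts[1]
      if (id %in% rownames(out))
        out[id, ] <- suppressWarnings(as.numeric(parts[-1]))
    }
  }
  as.data.frame(out)
}

# Parse SMILES into OpenBabel molecule handles, named by compound id;
# unparsable entries are silently dropped (names reveal which survived).
ob_read_mols <- function(smiles) {
  if (is.null(names(smiles)))
    names(smiles) <- sprintf("cmp%05d", seq_along(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  sub <- smiles[ok]
  if (!length(sub)) return(list())
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste(sub, collapse = "\n"),
                           function(m) m),
    error = function(e) NULL)
  if (!is.null(mols) && length(mols) == length(sub)) {
    names(mols) <- names(sub)
    return(mols)
  }
  out <- list()
  for (i in seq_along(sub)) {
    m <- tryCatch(
      ChemmineOB::forEachMol("SMILES", sub[i], function(x) x)[[1]],
      error = function(e) NULL)
    if (!is.null(m)) out[[names(sub)[i]]] <- m
  }
  out
}

#' Count SMARTS matches per molecule
#'
#' @param smiles named character vector of SMILES, or a pre-parsed list of
#'   OpenBabel molecule handles (internal reuse).
#' @param smarts single SMARTS pattern.
#' @return integer vector of unique-match counts, named by compound id;
#'   unparsable structures are omitted.
#' @export
smarts_count <- function(smiles, smarts) {
  mols <- if (is.list(smiles)) smiles else ob_read_mols(smiles)
  if (!length(mols))
    return(stats::setNames(integer(0), character(0)))
  hits <- ChemmineOB::smartsSearch_OB(mols, smarts, uniqueMatches = TRUE)
  stats::setNames(as.integer(unlist(hits)), names(mols))
}

#' Circular (radius-2) fingerprints, folded to 2048 bits
#'
#' Morgan-style circular fingerprints computed on the molecular graph:
#' each atom's initial invariant combines its atomic number, degree and
#' valence (bond-order sum); two rounds of neighbourhood hashing extend the
#' environments to radius 2, and every (atom, radius) environment sets one
#' bit of a 2048-bit vector. The implementation is deterministic and
#' invariant to atom input order (neighbour contributions are sorted before
#' hashing).
#'
#' @param sdfset a `ChemmineR::SDFset`.
#' @param nbits folded fingerprint length.
#' @return binary matrix, rows = compounds (named), `nbits` columns.
#' @export
ecfp_fingerprints <- function(sdfset, nbits = 2048L) {
  keys <- ChemmineR::cid(sdfset)
  out <- matrix(0L, length(keys), nbits,
                dimnames = list(keys, sprintf("b%04d", seq_len(nbits) - 1L)))
  zs <- element_z()
  mix <- function(a, b) (a * 92821 + b * 8191 + 131) %% 2147483647
  for (i in seq_along(keys)) {
    sdf <- sdfset[[i]]
    elems <- atom_symbols(sdf)
    n <- length(elems)
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(bb) || !is.matrix(bb) || ncol(bb) < 3 || nrow(bb) == 0) {
      b1 <- integer(0); b2 <- integer(0); ord <- integer(0)
    } else {
      ok <- bb[, 1] > 0 & bb[, 2] > 0
      b1 <- bb[ok, 1]; b2 <- bb[ok, 2]; ord <- bb[ok, 3]
    }
    z <- zs[elems]; z[is.na(z)] <- 0
    deg <- tabulate(c(b1, b2), nbins = n)
    # ring-framework membership (atoms surviving terminal pruning)
    keep <- rep(TRUE, n)
    repeat {
      live <- keep[b1] & keep[b2]
      dg <- tabulate(c(b1[live], b2[live]), nbins = n)
      term <- keep & dg == 1
      if (!any(term)) break
      keep[term] <- FALSE
    }
    live <- keep[b1] & keep[b2]
    dg <- tabulate(c(b1[live], b2[live]), nbins = n)
    ring <- as.numeric(keep & dg >= 2)
    vsum <- numeric(n)
    for (e in seq_along(b1)) {
      vsum[b1[e]] <- vsum[b1[e]] + ord[e]
      vsum[b2[e]] <- vsum[b2[e]] + ord[e]
    }
    nb <- vector("list", n)
    for (e in seq_along(b1)) {
      nb[[b1[e]]] <- rbind(nb[[b1[e]]], c(b2[e], ord[e]))
      nb[[b2[e]]] <- rbind(nb[[b2[e]]], c(b1[e], ord[e]))
    }
    inv <- mix(mix(mix(z, deg), vsum), ring)
    bits <- inv
    for (r in 1:2) {
      inv <- vapply(seq_len(n), function(a) {
        if (is.null(nb[[a]])) return(mix(inv[a], 7))
        contrib <- sort(mix(nb[[a]][, 2], inv[nb[[a]][, 1]]))
        h <- inv[a]
        for (cc in contrib) h <- mix(h, cc)
        h
      }, numeric(1))
      bits <- c(bits, inv)
    }
    out[i, unique(as.integer(bits %% nbits)) + 1L] <- 1L
  }
  out
}

#' Tanimoto similarity between fingerprint matrices
#'
#' @param a,b binary matrices with the same number of columns.
#' @return `nrow(a)` x `nrow(b)` matrix of Tanimoto coefficients; pairs of
#'   all-zero fingerprints are defined to have similarity 0.
#' @export
tanimoto_matrix <- function(a, b) {
  inter <- a %*% t(b)
  ra <- rowSums(a)
  rb <- rowSums(b)
  uni <- outer(ra, rb, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  dimnames(sim) <- list(rownames(a), rownames(b))
  sim
}

#' Murcko framework of a molecule
#'
#' The scaffold is obtained by iteratively pruning terminal (degree-1) atoms
#' from the molecular graph until only ring systems and the linkers between
#' them remain, then writing the induced subgraph as OpenBabel canonical
#' SMILES. Acyclic molecules have the empty scaffold `""` (a single shared
#' scaffold string by convention).
#'
#' @param smiles character vector of SMILES.
#' @return character vector of scaffold SMILES ("" for acyclic molecules,
#'   `NA` where the input cannot be parsed).
#' @export
murcko_scaffold <- function(smiles) {
  vapply(smiles, murcko_one, character(1), USE.NAMES = FALSE)
}

murcko_one <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) return(NA_character_)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NA_character_)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  n <- nrow(ab)
  if (is.null(bb) || !is.matrix(bb) || ncol(bb) < 3 || nrow(bb) == 0)
    return("")
  ok <- bb[, 1] > 0 & bb[, 2] > 0  # single-atom SDFs carry a dummy row
  b1 <- bb[ok, 1]; b2 <- bb[ok, 2]; ord <- bb[ok, 3]
  if (!length(b1)) return("")
  keep <- rep(TRUE, n)
  repeat {
    live <- keep[b1] & keep[b2]
    deg <- tabulate(c(b1[live], b2[live]), nbins = n)
    term <- keep & deg == 1
    if (!any(term)) break
    keep[term] <- FALSE
  }
  if (!any(keep) || !any(keep[b1] & keep[b2])) return("")
  idx <- which(keep)
  remap <- match(seq_len(n), idx)
  bk <- keep[b1] & keep[b2]
  elems <- sub("_.*$", "", rownames(ab))
  mol <- c("scaffold", "  ghstox", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(idx), sum(bk)),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, elems[idx]),
           sprintf("%3d%3d%3d  0  0  0  0",
                   remap[b1[bk]], remap[b2[bk]], ord[bk]),
           "M  END", "$$$$")
  out <- ob_convert(paste(mol, collapse = "\n"), "MOL", "CAN")
  if (is.na(out)) NA_character_ else out
}

# element counts per molecule from the SDF atom block
atom_symbols <- function(sdf) sub("_.*$", "", rownames(ChemmineR::atomblock(sdf)))
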