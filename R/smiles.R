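#' @title SMILES parsing, canonicalization and standardization
#' @description SMILES and molfile interconversion is delegated to Open
#'   Babel (via ChemmineOB); the standardization pipeline itself —
#'   largest-organic-fragment selection, charge neutralization, and a
#'   bounded canonical-tautomer step — operates on the package's molecular
#'   graphs and is fully deterministic.
#' @name smiles
NULL

# Serialize mol_graphs to SDF text (via the package's SDF writer).
.sdf_text <- function(mols) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  write_sdf(mols, tf)
  paste0(paste(readLines(tf), collapse = "\n"), "\n")
}

#' Parse SMILES strings into molecular graphs
#'
#' Batch conversion through Open Babel. Unparsable entries yield `NULL`
#' with a warning; order and length of the input are preserved.
#'
#' @param smiles character vector of SMILES strings.
#' @return list of `mol_graph` (or `NULL`), same length as `smiles`.
#' @export
parse_smiles <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  src <- paste0(paste(smiles[ok], paste0("mlscreen_idx_", which(ok)),
                      sep = "\t", collapse = "\n"), "\n")
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = src),
    error = function(e) "")
  if (nzchar(sdf)) {
    recs <- .split_sdf_records(strsplit(sdf, "\n")[[1]])
    for (r in recs) {
      if (all(!nzchar(trimws(r)))) next
      idx <- suppressWarnings(as.integer(sub("^mlscreen_idx_", "", trimws(r[1]))))
      if (is.na(idx)) next
      out[[idx]] <- tryCatch(.parse_sdf_record(r), error = function(e) NULL)
      if (!is.null(out[[idx]])) out[[idx]]$name <- NULL
    }
  }
  # Open Babel may abort a batch at the first bad record; retry the
  # unresolved entries one at a time.
  retry <- which(ok & vapply(out, is.null, logical(1)))
  for (idx in retry) {
    sdf1 <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF",
                                source = paste0(smiles[idx], "\tm\n")),
      error = function(e) "")
    if (!nzchar(sdf1)) next
    rec <- .split_sdf_records(strsplit(sdf1, "\n")[[1]])
    if (length(rec) == 0) next
    out[[idx]] <- tryCatch(.parse_sdf_record(rec[[1]]), error = function(e) NULL)
    if (!is.null(out[[idx]])) out[[idx]]$name <- NULL
  }
  nbad <- sum(ok & vapply(out, is.null, logical(1)))
  if (nbad > 0) warning(sprintf("%d SMILES string(s) could not be parsed", nbad))
  out
}

#' Canonical SMILES of molecular graphs
#'
#' @param mols a `mol_graph` or list of them.
#' @return character vector of Open Babel canonical SMILES (`NA` on
#'   failure).
#' @export
canonical_smiles <- function(mols) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  named <- lapply(seq_along(mols), function(k) {
    m <- mols[[k]]; m$name <- paste0("mlscreen_idx_", k); m
  })
  can <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", source = .sdf_text(named)),
    error = function(e) "")
  out <- rep(NA_character_, length(mols))
  for (ln in strsplit(can, "\n")[[1]]) {
    tok <- strsplit(ln, "\t")[[1]]
    if (length(tok) < 2) next
    idx <- suppressWarnings(as.integer(sub("^mlscreen_idx_", "", trimws(tok[2]))))
    if (!is.na(idx)) out[idx] <- trimws(tok[1])
  }
  out
}

# Largest organic fragment: most heavy atoms, preferring fragments that
# contain carbon; deterministic tie-break on the lowest atom index.
.largest_organic_fragment <- function(mol) {
  fr <- fragments(mol)
  if (length(fr) <= 1) return(mol)
  nheavy <- vapply(fr, function(ix) sum(mol$atoms$element[ix] != "H"), numeric(1))
  hasC <- vapply(fr, function(ix) any(mol$atoms$element[ix] == "C"), logical(1))
  ord <- order(-hasC, -nheavy, vapply(fr, min, numeric(1)))
  subset_atoms(mol, fr[[ord[1]]])
}

# Neutralize simple charged sites when chemically valid: a positive N/S
# with an implicit hydrogen loses it; a negative N/O/S gains one. Atoms
# adjacent to an oppositely charged atom (e.g. nitro groups) are left as
# charge-separated forms.
.neutralize <- function(mol) {
  chg <- mol$atoms$charge
  if (all(chg == 0)) return(mol)
  b <- mol$bonds
  nbr_opposite <- function(a) {
    nb <- c(b$j[b$i == a], b$i[b$j == a])
    length(nb) > 0 && any(chg[nb] * chg[a] < 0)
  }
  ih <- implicit_h(mol)
  for (a in which(chg != 0)) {
    el <- mol$atoms$element[a]
    if (!el %in% c("N", "O", "S")) next
    if (nbr_opposite(a)) next
    if (chg[a] > 0 && ih[a] >= 1) mol$atoms$charge[a] <- chg[a] - 1L
    if (chg[a] < 0) mol$atoms$charge[a] <- chg[a] + 1L
  }
  mol
}

# One-step 1,3 hydrogen shifts over non-ring triads: for every X=Y-Z(H)
# with X, Z in {C, N, O} and at least one of X, Z a heteroatom (covers
# keto-enol and amide-imidol), produce X(H)-Y=Z. Implicit hydrogen counts
# follow from valence, so flipping the two bond orders moves the hydrogen.
.tautomer_neighbors <- function(mol) {
  out <- list()
  b <- mol$bonds
  if (nrow(b) < 2) return(out)
  ring <- in_ring(mol)
  el <- mol$atoms$element
  ih <- implicit_h(mol)
  chg <- mol$atoms$charge
  dbl <- which(b$order == 2)
  for (k in dbl) {
    for (dir in 1:2) {
      x <- if (dir == 1) b$i[k] else b$j[k]
      y <- if (dir == 1) b$j[k] else b$i[k]
      if (!el[x] %in% c("C", "N", "O") || chg[x] != 0 || ring[x]) next
      sgl <- which(b$order == 1 & (b$i == y | b$j == y))
      for (k2 in sgl) {
        z <- if (b$i[k2] == y) b$j[k2] else b$i[k2]
        if (z == x || !el[z] %in% c("C", "N", "O")) next
        if (el[x] == "C" && el[z] == "C") next
        if (chg[z] != 0 || ring[z] || ih[z] < 1) next
        m2 <- mol
        m2$bonds$order[k] <- 1
        m2$bonds$order[k2] <- 2
        out[[length(out) + 1]] <- m2
      }
    }
  }
  out
}

#' Canonical tautomer of a molecular graph
#'
#' Breadth-first enumeration of 1,3-shift tautomers (acyclic O/N triads
#' only), capped at `max_states` states; the representative is the
#' lexicographically smallest canonical SMILES. Deterministic; a bounded
#' substitute for exhaustive tautomer standardization.
#'
#' @param mol a `mol_graph`.
#' @param max_states enumeration cap (default 32).
#' @return list with `mol` (representative graph) and `smiles`.
#' @export
canonical_tautomer <- function(mol, max_states = 32) {
  states <- list(mol)
  keys <- canonical_smiles(mol)
  frontier <- states
  while (length(frontier) > 0 && length(states) < max_states) {
    nxt <- list()
    for (m in frontier) nxt <- c(nxt, .tautomer_neighbors(m))
    if (length(nxt) == 0) break
    smi <- canonical_smiles(nxt)
    fresh <- !is.na(smi) & !smi %in% keys & !duplicated(smi)
    nxt <- nxt[fresh]
    keys <- c(keys, smi[fresh])
    room <- max_states - length(states)
    if (length(nxt) > room) nxt <- nxt[seq_len(room)]
    states <- c(states, nxt)
    frontier <- nxt
  }
  best <- order(keys)[1]
  list(mol = states[[best]], smiles = keys[best])
}

#' Standardize chemical structures
#'
#' The open standardization pipeline applied before curation: parse, keep
#' the largest organic fragment (dropping metal counter-ions and salts),
#' neutralize charges where chemically valid, canonicalize the tautomer,
#' and emit Open Babel canonical SMILES. Deterministic; idempotent on
#' already-standard structures.
#'
#' @param smiles character vector of SMILES strings.
#' @param tautomers apply the canonical-tautomer step (default `TRUE`;
#'   the costliest step, switchable for large bulk runs).
#' @return character vector of canonical SMILES; `NA` for unparsable input
#'   (with a warning).
#' @export
#' @examples
#' \donttest{
#' standardize_structure("CCO.[Na+].[Cl-]")  # "CCO"
#' }
standardize_structure <- function(smiles, tautomers = TRUE) {
  mols <- suppressWarnings(parse_smiles(smiles))
  ok <- !vapply(mols, is.null, logical(1))
  if (any(!ok & !is.na(smiles) & nzchar(smiles))) {
    warning(sprintf("%d structure(s) rejected as unparsable",
                    sum(!ok & !is.na(smiles) & nzchar(smiles))))
  }
  out <- rep(NA_character_, length(smiles))
  cleaned <- lapply(mols[ok], function(m) .neutralize(.largest_organic_fragment(m)))
  if (length(cleaned) > 0) {
    if (tautomers) {
      out[ok] <- vapply(cleaned, function(m) canonical_tautomer(m)$smiles,
                        character(1))
    } else {
      out[ok] <- canonical_smiles(cleaned)
    }
  }
  out
}
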