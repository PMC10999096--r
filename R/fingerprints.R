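#' @title Circular fingerprints and similarity
#' @description Ligand-only Morgan (extended-connectivity) fingerprints,
#'   deterministic atom-environment identifiers, and Tanimoto similarity.
#'   Identifiers are FNV-1a hashes of invariant tuples, so every
#'   fingerprint is bit-identical across runs and platforms and invariant
#'   to the input atom ordering.
#' @name fingerprints
NULL

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                   S = 16, Cl = 17, Br = 35, I = 53, Na = 11, K = 19,
                   Mg = 12, Ca = 20, Zn = 30, Fe = 26)

.elem_code <- function(el) {
  z <- unname(ATOMIC_NUMBER[el])
  miss <- is.na(z)
  if (any(miss)) {
    z[miss] <- vapply(el[miss], function(s) 100 + hash_string(s) %% 1000,
                      numeric(1))
  }
  z
}

# Heavy-atom neighbor lists: per atom a list(nbr, order10, bond) where
# order10 = 10 * effective bond order (aromatic -> 15) and bond is the
# index into mol$bonds.
.neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  if (nrow(b) == 0) {
    return(rep(list(list(nbr = integer(0), order10 = integer(0),
                         bond = integer(0))), n))
  }
  heavy <- mol$atoms$element != "H"
  ord10 <- as.integer(round(ifelse(b$order == 4, 1.5, b$order) * 10))
  bidx <- seq_len(nrow(b))
  ii <- c(b$i, b$j); jj <- c(b$j, b$i)
  oo <- c(ord10, ord10); bb <- c(bidx, bidx)
  keep <- heavy[ii] & heavy[jj]
  f <- factor(ii[keep], levels = seq_len(n))
  js <- split(jj[keep], f); os <- split(oo[keep], f); bs <- split(bb[keep], f)
  lapply(seq_len(n), function(a) {
    list(nbr = js[[a]], order10 = os[[a]], bond = bs[[a]])
  })
}

.degree <- function(nbrs) vapply(nbrs, function(nb) length(nb$nbr), integer(1))

#' Atom-environment identifiers at increasing depth
#'
#' Depth-0 identifiers hash the atom-invariant tuple (element, heavy
#' degree, total hydrogen count, formal charge, aromaticity, ring
#' membership). The depth-d identifier of an atom hashes (d, its depth-(d-1)
#' identifier, the sorted (bond order, neighbor depth-(d-1) identifier)
#' pairs). Identifiers are independent of atom ordering.
#'
#' @param mol a `mol_graph`.
#' @param max_depth maximum environment depth (radius), >= 0.
#' @return numeric matrix, `n_atoms x (max_depth + 1)`; hydrogens get `NA`.
#' @export
atom_env_ids <- function(mol, max_depth) {
  stopifnot(max_depth >= 0)
  n <- n_atoms(mol)
  heavy <- mol$atoms$element != "H"
  nbrs <- .neighbor_list(mol)
  deg <- .degree(nbrs)
  inv <- cbind(.elem_code(mol$atoms$element), deg, total_h(mol),
               mol$atoms$charge, as.integer(mol$atoms$aromatic),
               as.integer(in_ring(mol)))
  ids <- matrix(NA_real_, n, max_depth + 1)
  ids[heavy, 1] <- hash_tuples(inv[heavy, , drop = FALSE])
  if (max_depth == 0) return(ids)
  hv <- which(heavy)
  for (d in seq_len(max_depth)) {
    prev <- ids[, d]
    # group atoms by degree so each group hashes as one matrix
    for (dg in unique(deg[hv])) {
      atoms_dg <- hv[deg[hv] == dg]
      if (dg == 0) { ids[atoms_dg, d + 1] <- prev[atoms_dg]; next }
      tup <- t(vapply(atoms_dg, function(a) {
        nb <- nbrs[[a]]
        pid <- prev[nb$nbr]
        o <- order(nb$order10, pid)
        c(d, prev[a], rbind(nb$order10[o], pid[o]))
      }, numeric(2 + 2 * dg)))
      ids[atoms_dg, d + 1] <- hash_tuples(tup)
    }
  }
  ids
}

#' Morgan (extended-connectivity) fingerprint of a molecule
#'
#' Environment identifiers over depths `0..radius` are deduplicated by the
#' standard circular-fingerprint rules (identical identifiers, and
#' environments covering an already-emitted bond set, are dropped) and
#' folded modulo `n_bits` into a binary vector.
#'
#' @param mol a `mol_graph` with at least one heavy atom.
#' @param n_bits fingerprint length (default 512, the featurization
#'   default; similarity calculations use 2048).
#' @param radius maximum environment depth (default 2, i.e. ECFP4).
#' @return a `feature_vector` of scheme `"MORGAN"`.
#' @export
#' @examples
#' eth <- mol_graph(data.frame(element = c("C", "C"), x = c(0, 1.54),
#'                             y = 0, z = 0),
#'                  data.frame(i = 1, j = 2, order = 1))
#' sum(morgan_fp(eth)$values)  # one depth-0 + one depth-1 environment
morgan_fp <- function(mol, n_bits = 512, radius = 2) {
  heavy <- which(mol$atoms$element != "H")
  if (length(heavy) == 0) stop("molecule has no heavy atoms")
  ids <- atom_env_ids(mol, radius)
  nbrs <- .neighbor_list(mol)
  # depth-0 environments are single atoms; deeper environments covering an
  # already-emitted bond set are duplicates and dropped. One incremental
  # breadth-first pass per atom records the bond-set key at every depth.
  out_ids <- ids[heavy, 1]
  if (radius > 0) {
    nb_total <- nrow(mol$bonds)
    keys <- matrix("", length(heavy), radius)
    for (hi in seq_along(heavy)) {
      a <- heavy[hi]
      seen_b <- logical(nb_total)
      seen_a <- logical(n_atoms(mol)); seen_a[a] <- TRUE
      frontier <- a
      for (d in seq_len(radius)) {
        nxt <- integer(0)
        for (v in frontier) {
          nb <- nbrs[[v]]
          seen_b[nb$bond] <- TRUE
          new <- nb$nbr[!seen_a[nb$nbr]]
          seen_a[new] <- TRUE
          nxt <- c(nxt, new)
        }
        frontier <- nxt
        keys[hi, d] <- paste(which(seen_b), collapse = ",")
      }
    }
    seen <- character(0)
    for (d in seq_len(radius)) {
      fresh <- !keys[, d] %in% seen
      if (any(fresh)) {
        # among atoms sharing a bond set, the smallest identifier is the
        # canonical representative (independent of atom order)
        rep_ids <- tapply(ids[heavy[fresh], d + 1], keys[fresh, d], min)
        out_ids <- c(out_ids, unname(rep_ids))
        seen <- c(seen, unique(keys[fresh, d]))
      }
    }
  }
  out_ids <- unique(out_ids)
  v <- integer(n_bits)
  v[(out_ids %% n_bits) + 1] <- 1L
  feature_vector("MORGAN", v,
                 config = list(n_bits = n_bits, radius = radius))
}

#' Construct a feature vector
#'
#' @param scheme one of `"MORGAN"`, `"PLEC"`, `"GRID"`, `"COMBINED"`.
#' @param values numeric vector (binary for fingerprint schemes).
#' @param config named list of featurizer settings.
#' @return object of class `feature_vector`.
#' @export
feature_vector <- function(scheme, values, config = list()) {
  scheme <- match.arg(scheme, c("MORGAN", "PLEC", "GRID", "COMBINED"))
  if (scheme %in% c("MORGAN", "PLEC") && !all(values %in% c(0L, 1L)))
    stop("binary scheme contains non-binary values")
  structure(list(scheme = scheme, length = length(values),
                 values = as.numeric(values), config = config),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector %s: length %d, %d nonzero>\n",
              x$scheme, x$length, sum(x$values != 0)))
  invisible(x)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both fingerprints are empty.
#'
#' @param fp_a,fp_b `feature_vector`s or binary numeric vectors of equal
#'   length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  a <- if (inherits(fp_a, "feature_vector")) fp_a$values else fp_a
  b <- if (inherits(fp_b, "feature_vector")) fp_b$values else fp_b
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("tanimoto requires binary fingerprints")
  un <- sum(a == 1 | b == 1)
  if (un == 0) return(0)
  sum(a == 1 & b == 1) / un
}

#' Concatenate two feature vectors of distinct schemes
#'
#' The canonical order is (MORGAN, PLEC); inputs given in the opposite
#' order are normalized.
#'
#' @param fv_a,fv_b `feature_vector`s of distinct schemes.
#' @return a `feature_vector` of scheme `"COMBINED"`.
#' @export
concat_features <- function(fv_a, fv_b) {
  stopifnot(inherits(fv_a, "feature_vector"), inherits(fv_b, "feature_vector"))
  if (fv_a$scheme == fv_b$scheme) stop("cannot concatenate same-scheme vectors")
  rank <- c(MORGAN = 1, PLEC = 2, GRID = 3, COMBINED = 4)
  if (rank[fv_a$scheme] > rank[fv_b$scheme]) { tmp <- fv_a; fv_a <- fv_b; fv_b <- tmp }
  structure(list(scheme = "COMBINED",
                 length = fv_a$length + fv_b$length,
                 values = c(fv_a$values, fv_b$values),
                 config = list(first = fv_a$config, second = fv_b$config,
                               schemes = c(fv_a$scheme, fv_b$scheme))),
            class = "feature_vector")
}
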