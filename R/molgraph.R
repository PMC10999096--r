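#' Molecular structure container
#'
#' `mol_graph` is the package's light-weight structure type: a data frame of
#' atoms (element, Cartesian coordinates in Angstrom, formal charge,
#' aromatic flag and — for receptors — residue annotations) plus a data
#' frame of bonds (1-based atom indices and bond order). It deliberately
#' carries no toolkit state so that structures can be built in code, read
#' from SDF/MOL2/PDB, and compared exactly.
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`; optional
#'   `charge` (formal charge, default 0), `aromatic` (logical, default
#'   FALSE), and receptor annotations `resname`, `resno`, `chain`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1-based indices
#'   into `atoms`); may have zero rows.
#' @param pose_score optional numeric docking score (lower = better pose).
#' @param name optional molecule name.
#' @return object of class `mol_graph`.
#' @export
#' @examples
#' m <- mol_graph(
#'   atoms = data.frame(element = c("C", "O"), x = c(0, 1.43),
#'                      y = 0, z = 0),
#'   bonds = data.frame(i = 1, j = 2, order = 1)
#' )
#' n_atoms(m)
mol_graph <- function(atoms, bonds = NULL, pose_score = NULL, name = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms$element <- as.character(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  n <- nrow(atoms)
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicated bond")
  }
  structure(list(atoms = atoms, bonds = bonds,
                 pose_score = pose_score, name = name),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph%s: %d atoms, %d bonds%s>\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$atoms), nrow(x$bonds),
              if (!is.null(x$pose_score))
                sprintf(", pose score %.3f", x$pose_score) else ""))
  invisible(x)
}

#' @rdname mol_graph
#' @param mol a `mol_graph`.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Coordinates matrix of a structure
#' @param mol a `mol_graph`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a `mol_graph`.
#' @keywords internal
heavy_atoms <- function(mol) which(mol$atoms$element != "H")

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                     F = 1, Cl = 1, Br = 1, I = 1, B = 3, H = 1)

# Effective bond-order sum per atom (aromatic order 4 counted as 1.5).
.order_sum <- function(mol) {
  out <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) == 0) return(out)
  ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
  for (k in seq_len(nrow(mol$bonds))) {
    out[mol$bonds$i[k]] <- out[mol$bonds$i[k]] + ord[k]
    out[mol$bonds$j[k]] <- out[mol$bonds$j[k]] + ord[k]
  }
  out
}

#' Implicit hydrogen count per atom
#'
#' Derived from default valences adjusted by formal charge (N+ 4, O- 1,
#' N- 2, O+ 3), minus explicit bond orders and explicit hydrogens. Elements
#' without a tabled valence get zero implicit hydrogens.
#'
#' @param mol a `mol_graph`.
#' @return integer vector, one entry per atom.
#' @export
implicit_h <- function(mol) {
  el <- mol$atoms$element
  val <- unname(DEFAULT_VALENCE[el])
  val[is.na(val)] <- 0
  chg <- mol$atoms$charge
  val <- val + ifelse(el %in% c("N", "P"), chg,
               ifelse(el %in% c("O", "S"), chg, 0))
  h <- val - .order_sum(mol)
  # explicit hydrogens already count through bonds
  pmax(0L, as.integer(round(h)))
}

#' Total hydrogen count (implicit + explicit neighbors)
#' @keywords internal
total_h <- function(mol) {
  h <- implicit_h(mol)
  if (nrow(mol$bonds) > 0) {
    isH <- mol$atoms$element == "H"
    for (k in seq_len(nrow(mol$bonds))) {
      if (isH[mol$bonds$j[k]]) h[mol$bonds$i[k]] <- h[mol$bonds$i[k]] + 1L
      if (isH[mol$bonds$i[k]]) h[mol$bonds$j[k]] <- h[mol$bonds$j[k]] + 1L
    }
  }
  h
}

# igraph view of the heavy-atom connectivity (all atoms, actually;
# vertices = atom indices).
.mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds) > 0) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

#' Ring-membership flag per atom
#'
#' An atom is in a ring iff it is incident to a bond that lies on a cycle
#' (i.e. a non-bridge edge of the connectivity graph).
#' @param mol a `mol_graph`.
#' @return logical vector.
#' @export
in_ring <- function(mol) {
  out <- rep(FALSE, n_atoms(mol))
  b <- mol$bonds
  if (nrow(b) == 0) return(out)
  # union-find fast path: a graph whose every edge joins two previously
  # disconnected components is a forest — no rings, skip bridge finding
  parent <- seq_len(n_atoms(mol))
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  acyclic <- TRUE
  for (k in seq_len(nrow(b))) {
    ra <- find(b$i[k]); rb <- find(b$j[k])
    if (ra == rb) { acyclic <- FALSE; break }
    parent[ra] <- rb
  }
  if (acyclic) return(out)
  g <- .mol_igraph(mol)
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(b)), as.integer(br))
  if (length(cyc) > 0) {
    out[unique(c(b$i[cyc], b$j[cyc]))] <- TRUE
  }
  out
}

#' Connected fragments of a structure
#' @param mol a `mol_graph`.
#' @return list of integer vectors of atom indices, largest first.
#' @export
fragments <- function(mol) {
  comp <- igraph::components(.mol_igraph(mol))
  idx <- split(seq_len(n_atoms(mol)), comp$membership)
  idx[order(-vapply(idx, length, integer(1)))]
}

#' Extract a sub-structure by atom indices
#' @param mol a `mol_graph`.
#' @param idx integer atom indices to keep.
#' @return `mol_graph` with bonds re-indexed.
#' @export
subset_atoms <- function(mol, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(n_atoms(mol)); map[idx] <- seq_along(idx)
  b <- mol$bonds
  keep <- b$i %in% idx & b$j %in% idx
  b <- b[keep, , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  rownames(b) <- NULL
  at <- mol$atoms[idx, , drop = FALSE]
  rownames(at) <- NULL
  mol_graph(at, b, pose_score = mol$pose_score, name = mol$name)
}

#' Rigidly transform a structure (for invariance testing)
#' @param mol a `mol_graph`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return transformed `mol_graph`.
#' @export
transform_structure <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(mol) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Permute atom order (for invariance testing)
#' @param mol a `mol_graph`.
#' @param perm permutation of `seq_len(n_atoms(mol))`; `perm[k]` is the old
#'   index placed at new position `k`.
#' @return permuted `mol_graph`.
#' @export
permute_atoms <- function(mol, perm) {
  stopifnot(sort(perm) == seq_len(n_atoms(mol)))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  at <- mol$atoms[perm, , drop = FALSE]; rownames(at) <- NULL
  b <- mol$bonds
  if (nrow(b) > 0) { b$i <- inv[b$i]; b$j <- inv[b$j] }
  mol_graph(at, b, pose_score = mol$pose_score, name = mol$name)
}

#' Infer covalent bonds from interatomic distances
#'
#' PDB records carry no connectivity, so receptor bonds are inferred with a
#' covalent-distance rule: heavy-atom pairs closer than 1.9 Angstrom are
#' bonded (2.1 for pairs involving sulfur); hydrogens bond below 1.2.
#' Orders are all single — adequate for environment hashing, which sorts on
#' (order, neighbor id) and sees consistent values receptor-side.
#'
#' @param atoms atom data frame (`element`, `x`, `y`, `z`).
#' @return bond data frame (`i`, `j`, `order`).
#' @export
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), order = numeric(0)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  el <- atoms$element
  cut <- matrix(1.9, n, n)
  hasS <- outer(el == "S", el == "S", "|")
  cut[hasS] <- 2.1
  hasH <- outer(el == "H", el == "H", "|")
  cut[hasH] <- 1.2
  sel <- which(d > 0 & d < cut & upper.tri(d), arr.ind = TRUE)
  data.frame(i = as.integer(sel[, 1]), j = as.integer(sel[, 2]),
             order = rep(1, nrow(sel)))
}
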