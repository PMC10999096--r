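#' @title Protein-ligand interaction featurizers
#' @description PLEC fingerprints (pairs of contacting ligand/protein
#'   circular environments, hashed and folded) and grid-style interaction
#'   features (folded environment counts, distance-binned contact-pair
#'   counts, hydrogen-bond and salt-bridge counts). Both depend only on
#'   interatomic distances and graph invariants, so they are invariant to
#'   rigid rototranslation of the complex.
#' @name plec-grid
NULL

#' Detect heavy-atom protein-ligand contacts
#'
#' All ligand/protein heavy-atom pairs with Euclidean distance less than or
#' equal to `cutoff` (closed boundary). Hydrogens are excluded.
#'
#' @param complex a `pl_complex`.
#' @param cutoff contact distance cutoff in Angstrom (> 0).
#' @return data.frame with columns `ligand_atom`, `protein_atom`,
#'   `distance` (atom indices into the respective structures).
#' @export
detect_contacts <- function(complex, cutoff = 4.5) {
  stopifnot(inherits(complex, "pl_complex"), cutoff > 0)
  li <- heavy_atoms(complex$ligand)
  pi_ <- heavy_atoms(complex$receptor)
  if (length(li) == 0 || length(pi_) == 0) {
    return(data.frame(ligand_atom = integer(0), protein_atom = integer(0),
                      distance = numeric(0)))
  }
  lxyz <- coords(complex$ligand)[li, , drop = FALSE]
  pxyz <- coords(complex$receptor)[pi_, , drop = FALSE]
  d2 <- outer(rowSums(lxyz^2), rep(1, nrow(pxyz))) +
    outer(rep(1, nrow(lxyz)), rowSums(pxyz^2)) - 2 * lxyz %*% t(pxyz)
  d2[d2 < 0] <- 0
  sel <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  out <- data.frame(ligand_atom = li[sel[, 1]], protein_atom = pi_[sel[, 2]],
                    distance = sqrt(d2[sel]))
  out[order(out$ligand_atom, out$protein_atom), , drop = FALSE]
}

#' Protein-ligand extended connectivity (PLEC) fingerprint
#'
#' For every heavy-atom contact, environment identifiers of the ligand atom
#' at depths `0..depth_ligand` are paired with those of the protein atom at
#' depths `0..depth_protein` (full cross product by default), each pair is
#' hashed and folded modulo `size`, and the resulting bits are set. A
#' contact-free complex yields a valid all-zero vector.
#'
#' @param complex a `pl_complex`.
#' @param depth_ligand ligand environment depth (default 1).
#' @param depth_protein protein environment depth (default 5).
#' @param size fingerprint length (default 4092).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param pairing `"cross"` (default) pairs all depth combinations;
#'   `"diagonal"` pairs only matching depth ranks
#'   (`min(depth_ligand, depth_protein) + 1` pairs per contact).
#' @return a `feature_vector` of scheme `"PLEC"`.
#' @export
plec_fp <- function(complex, depth_ligand = 1, depth_protein = 5,
                    size = 4092, cutoff = 4.5,
                    pairing = c("cross", "diagonal")) {
  pairing <- match.arg(pairing)
  stopifnot(depth_ligand >= 0, depth_protein >= 0, size > 0)
  cfg <- list(depth_ligand = depth_ligand, depth_protein = depth_protein,
              size = size, cutoff = cutoff, pairing = pairing)
  contacts <- detect_contacts(complex, cutoff)
  v <- integer(size)
  if (nrow(contacts) == 0) {
    return(feature_vector("PLEC", v, config = cfg))
  }
  lid <- atom_env_ids(complex$ligand, depth_ligand)
  pid <- atom_env_ids(complex$receptor, depth_protein)
  if (pairing == "cross") {
    combos <- expand.grid(i = 0:depth_ligand, j = 0:depth_protein)
  } else {
    k <- 0:min(depth_ligand, depth_protein)
    combos <- data.frame(i = k, j = k)
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
    cbind(lid[contacts$ligand_atom, combos$i[r] + 1],
          pid[contacts$protein_atom, combos$j[r] + 1])
  }))
  ids <- hash_tuples(pairs)
  v[unique(ids %% size) + 1] <- 1L
  feature_vector("PLEC", v, config = cfg)
}

# Rule-based hydrogen-bond typing: N/O with at least one hydrogen donates;
# N/O with a lone pair (not positively charged, and for N not
# tetra-substituted) accepts. No partial charges are used.
.hbond_flags <- function(mol) {
  el <- mol$atoms$element
  th <- total_h(mol)
  deg <- .degree(.neighbor_list(mol))
  no <- el %in% c("N", "O")
  donor <- no & th >= 1
  acceptor <- no & mol$atoms$charge <= 0 & !(el == "N" & (deg + th) >= 4)
  list(donor = donor, acceptor = acceptor)
}

#' Grid-style interaction features of a protein-ligand complex
#'
#' A fixed-length count vector composed, in order, of:
#' \itemize{
#'   \item `2^ecfp_power` folded counts of circular environments (depths
#'     0..2) of all ligand and protein heavy atoms inside the spherical
#'     neighborhood of diameter `voxel_width` centered on the ligand
#'     centroid (a sphere, so the features are rototranslation-invariant);
#'   \item three blocks of `2^splif_power` folded contact-pair environment
#'     counts, binned by contact distance into (0, 2.0], (2.0, 3.0] and
#'     (3.0, 4.5] Angstrom;
#'   \item three hydrogen-bond counts (donor/acceptor pairs) in the same
#'     distance bins;
#'   \item one salt-bridge count (formally charged N+/O- pairs within
#'     4.0 Angstrom).
#' }
#' With the default powers this gives 512 + 3*512 + 3 + 1 = 2052 features.
#'
#' @param complex a `pl_complex`.
#' @param ecfp_power log2 of the environment-count block length (default 9).
#' @param splif_power log2 of each contact-pair block length (default 9).
#' @param voxel_width edge of the environment-counting box in Angstrom
#'   (default 16.0).
#' @return a `feature_vector` of scheme `"GRID"`.
#' @export
grid_features <- function(complex, ecfp_power = 9, splif_power = 9,
                          voxel_width = 16.0) {
  stopifnot(inherits(complex, "pl_complex"))
  n_ecfp <- 2^ecfp_power
  n_splif <- 2^splif_power
  bins <- c(0, 2.0, 3.0, 4.5)

  lig <- complex$ligand; rec <- complex$receptor
  lh <- heavy_atoms(lig); ph <- heavy_atoms(rec)
  center <- colMeans(coords(lig)[lh, , drop = FALSE])
  half <- voxel_width / 2

  # spherical neighborhood of diameter voxel_width: unlike an axis-aligned
  # cube it is invariant under rigid rototranslation of the complex
  in_box <- function(xyz) {
    rowSums(sweep(xyz, 2, center)^2) <= half^2 + 1e-9
  }
  lid <- atom_env_ids(lig, 2)
  pid <- atom_env_ids(rec, 2)
  env_ids <- c(lid[lh[in_box(coords(lig)[lh, , drop = FALSE])], ],
               pid[ph[in_box(coords(rec)[ph, , drop = FALSE])], ])
  env_ids <- env_ids[!is.na(env_ids)]
  ecfp_block <- tabulate((env_ids %% n_ecfp) + 1, nbins = n_ecfp)

  contacts <- detect_contacts(complex, max(bins))
  splif_blocks <- matrix(0, nrow = 3, ncol = n_splif)
  hbond_counts <- numeric(3)
  if (nrow(contacts) > 0) {
    pair_ids <- hash_tuples(cbind(lid[contacts$ligand_atom, 2],
                                  pid[contacts$protein_atom, 2]))
    bin <- findInterval(contacts$distance, bins, left.open = TRUE,
                        rightmost.closed = TRUE)
    bin[contacts$distance <= bins[2]] <- 1
    fl <- .hbond_flags(lig); fr <- .hbond_flags(rec)
    is_hb <- (fl$donor[contacts$ligand_atom] & fr$acceptor[contacts$protein_atom]) |
      (fl$acceptor[contacts$ligand_atom] & fr$donor[contacts$protein_atom])
    for (k in 1:3) {
      sel <- bin == k
      if (any(sel)) {
        splif_blocks[k, ] <- tabulate((pair_ids[sel] %% n_splif) + 1,
                                      nbins = n_splif)
        hbond_counts[k] <- sum(is_hb & sel)
      }
    }
  }

  sb_contacts <- detect_contacts(complex, 4.0)
  salt <- 0
  if (nrow(sb_contacts) > 0) {
    lq <- lig$atoms$charge; pq <- rec$atoms$charge
    le <- lig$atoms$element; pe <- rec$atoms$element
    la <- sb_contacts$ligand_atom; pa <- sb_contacts$protein_atom
    salt <- sum((le[la] == "N" & lq[la] > 0 & pe[pa] == "O" & pq[pa] < 0) |
                  (le[la] == "O" & lq[la] < 0 & pe[pa] == "N" & pq[pa] > 0))
  }

  feature_vector("GRID",
                 c(ecfp_block, as.vector(t(splif_blocks)), hbond_counts, salt),
                 config = list(ecfp_power = ecfp_power,
                               splif_power = splif_power,
                               voxel_width = voxel_width))
}

#' Assign formal charges to receptor atoms from residue rules
#'
#' Rule-based stand-in for a charge-assignment step: lysine NZ nitrogens
#' and arginine NH2 nitrogens get +1; the carboxylate OD2/OE2 oxygens of
#' aspartate/glutamate get -1. Requires `resname` and (optionally)
#' `atom_name` columns; without atom names, the terminal N/O of charged
#' residues are used.
#'
#' @param receptor a `mol_graph` with residue annotations.
#' @return the receptor with its `charge` column updated.
#' @export
assign_receptor_charges <- function(receptor) {
  a <- receptor$atoms
  if (is.null(a$resname)) stop("receptor lacks residue annotations")
  nm <- if (!is.null(a$atom_name)) a$atom_name else ""
  pos <- (a$resname == "LYS" & a$element == "N" &
            (nm == "NZ" | !nzchar(nm))) |
    (a$resname == "ARG" & a$element == "N" & (nm == "NH2" | !nzchar(nm)))
  neg <- (a$resname %in% c("ASP", "GLU") & a$element == "O" &
            (nm %in% c("OD2", "OE2") | !nzchar(nm)))
  receptor$atoms$charge[pos] <- 1L
  receptor$atoms$charge[neg] <- -1L
  receptor
}
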