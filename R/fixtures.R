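#' @title Seed-controlled synthetic fixtures
#' @description Generators for activity tables, toy 3D molecules and
#'   protein-pocket complexes, property-matched decoys, and a complete
#'   planted-signal benchmark, so that every pipeline stage is testable
#'   offline. All randomness flows from one master seed through
#'   [split_seed()], so each artifact is reproducible in isolation. The
#'   generated chemistry is deliberately simple (acyclic C/N/O/S
#'   skeletons); it emulates the shape of screening data, not medicinal
#'   chemistry.
#' @name synthetic-fixtures
NULL

#' Specify a synthetic study
#'
#' The defaults mirror the composition of a target-specific screening
#' study: a biochemical training set with roughly 60% actives, a smaller
#' cellular test set, and property-matched decoys at 50 per test active.
#' Counts may be set directly, or derived from `n_compounds`,
#' `active_fraction` and `assay_mix` by largest-remainder allocation.
#'
#' @param seed master seed.
#' @param n_compounds total compounds when counts are derived (default
#'   200).
#' @param active_fraction fraction of actives within each assay group
#'   (default 0.6).
#' @param assay_mix proportions of biochemical-only / cellular /
#'   binding-only compounds (must sum to 1).
#' @param n_train_active,n_train_inactive,n_test_active,n_test_inactive,n_binding_only
#'   explicit composition overrides.
#' @param decoy_ratio decoys per test active (default 50).
#' @param n_missing_smiles rows planted with empty SMILES (dropped at
#'   load; default 5).
#' @param n_uncertain extra rows with relation "<" (dropped by the
#'   relation filter; default 5).
#' @param n_overdispersed extra compounds whose replicates exceed the
#'   dispersion filter (rejected at aggregation; default 3).
#' @param replicate_fraction fraction of kept compounds carrying 2-3
#'   well-behaved replicate rows (default 0.2).
#' @param gt_fraction fraction of inactives reported as censored ">"
#'   records (default 0.3).
#' @param heavy_atoms inclusive range of molecule sizes (default
#'   `c(8, 18)`).
#' @param pocket_size number of pseudo-residues in generated pockets
#'   (default 8).
#' @param signal_strength association between planted pocket signal and
#'   activity, in `[0, 1]`: labels follow the signal except for flips
#'   with probability `(1 - signal_strength) / 2`, so 1 is deterministic
#'   and 0 is independence (default 0.9).
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         n_compounds = 200,
                         active_fraction = 0.6,
                         assay_mix = c(biochemical = 0.70, cellular = 0.25,
                                       binding = 0.05),
                         n_train_active = NULL, n_train_inactive = NULL,
                         n_test_active = NULL, n_test_inactive = NULL,
                         n_binding_only = NULL,
                         decoy_ratio = 50,
                         n_missing_smiles = 5, n_uncertain = 5,
                         n_overdispersed = 3,
                         replicate_fraction = 0.2, gt_fraction = 0.3,
                         heavy_atoms = c(8, 18),
                         pocket_size = 8, signal_strength = 0.9) {
  stopifnot(abs(sum(assay_mix) - 1) < 1e-9, decoy_ratio >= 1,
            signal_strength >= 0, signal_strength <= 1)
  # largest-remainder allocation keeps the totals exact
  alloc <- function(n, p) {
    raw <- n * p
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    base
  }
  groups <- alloc(n_compounds, assay_mix)
  n_bio <- groups[1]; n_cell <- groups[2]; n_bind <- groups[3]
  bio_split <- alloc(n_bio, c(active_fraction, 1 - active_fraction))
  cell_split <- alloc(n_cell, c(active_fraction, 1 - active_fraction))
  spec <- list(
    seed = seed, active_fraction = active_fraction,
    n_train_active = n_train_active %||% bio_split[1],
    n_train_inactive = n_train_inactive %||% bio_split[2],
    n_test_active = n_test_active %||% cell_split[1],
    n_test_inactive = n_test_inactive %||% cell_split[2],
    n_binding_only = n_binding_only %||% n_bind,
    decoy_ratio = decoy_ratio,
    n_missing_smiles = n_missing_smiles, n_uncertain = n_uncertain,
    n_overdispersed = n_overdispersed,
    replicate_fraction = replicate_fraction, gt_fraction = gt_fraction,
    heavy_atoms = heavy_atoms, pocket_size = pocket_size,
    signal_strength = signal_strength)
  structure(spec, class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(paste0("<fixture_spec seed %d: train %d+%d, test %d+%d, ",
                     "decoy ratio %d, signal %.2f>\n"),
              x$seed, x$n_train_active, x$n_train_inactive,
              x$n_test_active, x$n_test_inactive, x$decoy_ratio,
              x$signal_strength))
  invisible(x)
}

#' Generate a random, chemically sane molecule
#'
#' A connected, valence-respecting acyclic C/N/O/S skeleton with 3D
#' coordinates from an incremental distance-geometry embed (bond lengths
#' 1.3-1.6 Angstrom, non-bonded atoms kept at least 1.2 apart where
#' feasible). Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_heavy number of heavy atoms (>= 1).
#' @param n_hetero number of N/O heteroatoms to place (default: random
#'   20-35% of atoms). Used by the decoy generator to steer donor and
#'   acceptor counts.
#' @param embed compute 3D coordinates (default `TRUE`; graph-only uses
#'   can skip the embed).
#' @return a `mol_graph`.
#' @export
gen_molecule <- function(seed, n_heavy, n_hetero = NULL, embed = TRUE) {
  stopifnot(n_heavy >= 1)
  set.seed(seed)
  if (n_heavy == 1) {
    return(mol_graph(data.frame(element = "C", x = 0, y = 0, z = 0)))
  }
  # grow a random tree over carbon, respecting valence 4
  parent <- integer(n_heavy)
  free <- rep(4L, n_heavy)
  order2 <- logical(n_heavy)
  for (k in 2:n_heavy) {
    open <- which(free[seq_len(k - 1)] >= 1)
    p <- open[sample.int(length(open), 1)]
    parent[k] <- p
    dbl <- free[p] >= 2 && stats::runif(1) < 0.12
    ord <- if (dbl) 2L else 1L
    order2[k] <- dbl
    free[p] <- free[p] - ord
    free[k] <- free[k] - ord
  }
  element <- rep("C", n_heavy)
  deg <- tabulate(parent[-1], nbins = n_heavy) + (parent > 0)
  if (is.null(n_hetero)) {
    n_hetero <- round(n_heavy * stats::runif(1, 0.2, 0.35))
  }
  n_hetero <- min(n_hetero, n_heavy - 1)
  if (n_hetero > 0) {
    # heteroatoms only where valence allows: degree <= 2, and no double
    # bond for divalent O/S (to parent or to any child)
    has_dbl <- order2
    for (k in which(order2)) has_dbl[parent[k]] <- TRUE
    cand <- which(deg <= 2 & seq_len(n_heavy) > 1)
    cand <- cand[seq_len(min(length(cand), n_hetero))]
    for (a in cand) {
      el <- sample(c("N", "O", "S"), 1, prob = c(0.45, 0.45, 0.10))
      if (el %in% c("O", "S") && (has_dbl[a] || deg[a] > 2)) el <- "N"
      element[a] <- el
    }
  }
  bonds <- data.frame(i = parent[-1], j = 2:n_heavy,
                      order = ifelse(order2[-1], 2, 1))
  atoms <- data.frame(element = element, x = 0, y = 0, z = 0)
  if (embed) {
    xyz <- matrix(0, n_heavy, 3)
    for (k in 2:n_heavy) {
      p <- parent[k]
      len <- if (order2[k]) 1.33 else stats::runif(1, 1.43, 1.58)
      best <- NULL; best_min <- -Inf
      for (try in 1:30) {
        v <- stats::rnorm(3)
        pos <- xyz[p, ] + len * v / sqrt(sum(v^2))
        others <- setdiff(seq_len(k - 1), p)
        dmin <- if (length(others) == 0) Inf else
          sqrt(min(rowSums((xyz[others, , drop = FALSE] -
                              matrix(pos, length(others), 3,
                                     byrow = TRUE))^2)))
        if (dmin > best_min) { best_min <- dmin; best <- pos }
        if (dmin >= 1.8) break
      }
      xyz[k, ] <- best
    }
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  mol_graph(atoms, bonds)
}

# Count hydrogen-bond donors (N/O with >= 1 H) and acceptors (N/O).
.hbond_counts <- function(mol) {
  el <- mol$atoms$element
  th <- total_h(mol)
  no <- el %in% c("N", "O")
  c(donors = sum(no & th >= 1), acceptors = sum(no))
}

#' Count simple molecular properties used for decoy matching
#'
#' @param mol a `mol_graph`.
#' @return named vector: `heavy_atoms`, `donors`, `acceptors`.
#' @export
molecular_properties <- function(mol) {
  hb <- .hbond_counts(mol)
  c(heavy_atoms = length(heavy_atoms(mol)), hb)
}

#' Generate property-matched decoys for a set of actives
#'
#' For each template active, emits `ratio` molecules matching its heavy
#' atom count (within 1) and hydrogen-bond donor and acceptor counts
#' (within 1) while remaining structurally dissimilar (Tanimoto < 0.4 on
#' Morgan fingerprints, 2048 bits, radius 2) — a deliberately simple
#' property-matching stand-in for graph-generative decoy construction.
#'
#' @param actives list of `mol_graph` templates (>= 1).
#' @param ratio decoys per active (default 50).
#' @param seed master seed.
#' @param max_attempts per-decoy rejection budget (default 40).
#' @param embed give decoys 3D coordinates (default `FALSE`; the
#'   benchmark embeds only what it docks).
#' @return list of `mol_graph` decoys with a `template` attribute
#'   (integer template index per decoy). If the attempt budget is
#'   exhausted, fewer decoys are returned with a warning.
#' @export
gen_property_matched_decoys <- function(actives, ratio = 50, seed = 1,
                                        max_attempts = 40, embed = FALSE) {
  stopifnot(length(actives) >= 1, ratio >= 1)
  out <- list(); templ <- integer(0); short <- 0L
  for (t in seq_along(actives)) {
    tmpl <- actives[[t]]
    props <- molecular_properties(tmpl)
    tfp <- morgan_fp(tmpl, n_bits = 2048, radius = 2)
    for (k in seq_len(ratio)) {
      found <- FALSE
      for (att in seq_len(max_attempts)) {
        s <- split_seed(seed, sprintf("decoy-%d-%d-%d", t, k, att))
        nh <- props["heavy_atoms"] + sample(c(-1L, 0L, 1L), 1)
        cand <- gen_molecule(s, max(2, nh),
                             n_hetero = props["acceptors"] +
                               sample(c(-1L, 0L, 1L), 1),
                             embed = embed)
        cp <- molecular_properties(cand)
        if (any(abs(cp - props) > 1)) next
        if (tanimoto(morgan_fp(cand, 2048, 2), tfp) >= 0.4) next
        out[[length(out) + 1L]] <- cand
        templ <- c(templ, t)
        found <- TRUE
        break
      }
      if (!found) short <- short + 1L
    }
  }
  if (short > 0) {
    warning(sprintf("decoy budget exhausted: %d decoy(s) not generated",
                    short))
  }
  attr(out, "template") <- templ
  out
}

#' Generate a pseudo protein pocket around a docked ligand
#'
#' Places `pocket_size` small pseudo-residues (amide-like N-C=O triads
#' plus a side-chain atom) on a shell around the ligand: two in the
#' contact shell (3.6-4.4 Angstrom from the nearest ligand atom) and the
#' rest further out (5-8). When `plant_signal` is `TRUE`, an anchor triad
#' is added within hydrogen-bond distance (~3.2 Angstrom) of the
#' designated ligand anchor atoms, giving interaction fingerprints a
#' learnable activity signal.
#'
#' @param seed integer seed.
#' @param ligand a `mol_graph` with 3D coordinates.
#' @param plant_signal place the anchor triad (default `FALSE`).
#' @param pocket_size number of shell residues (default 8).
#' @param anchor_atoms ligand atom indices the anchor triad targets
#'   (default: the last three heavy atoms).
#' @return a `pl_complex`.
#' @export
gen_pocket_complex <- function(seed, ligand, plant_signal = FALSE,
                               pocket_size = 8, anchor_atoms = NULL) {
  set.seed(seed)
  lxyz <- coords(ligand)
  hv <- heavy_atoms(ligand)
  center <- colMeans(lxyz[hv, , drop = FALSE])
  if (is.null(anchor_atoms)) {
    anchor_atoms <- utils::tail(hv, 3)
  }
  res_names <- c("GLY", "ALA", "SER", "LYS", "ASP")
  atoms <- NULL
  resno <- 0L
  add_residue <- function(origin, dir, resname, atoms) {
    resno <<- resno + 1L
    # amide-like triad N-C=O plus one side-chain atom
    u <- dir / sqrt(sum(dir^2))
    # local orthogonal frame
    a1 <- origin
    w <- c(u[2], -u[1], 0); if (sum(w^2) < 1e-6) w <- c(0, u[3], -u[2])
    w <- w / sqrt(sum(w^2))
    # N at the origin, C at 1.5 along w, O double-bonded to C along u;
    # the side-chain atom sits opposite C so only the N-C, C=O and N-side
    # distances fall under the covalent bond-inference cutoff
    pos <- rbind(a1, a1 + 1.50 * w, a1 + 1.50 * w + 1.25 * u)
    el <- c("N", "C", "O")
    nm <- c("N", "C", "O")
    chg <- c(0L, 0L, 0L)
    if (resname == "LYS") {
      pos <- rbind(pos, a1 - 1.47 * w)
      el <- c(el, "N"); nm <- c(nm, "NZ"); chg <- c(chg, 1L)
    } else if (resname == "ASP") {
      pos <- rbind(pos, a1 - 1.36 * w)
      el <- c(el, "O"); nm <- c(nm, "OD2"); chg <- c(chg, -1L)
    } else if (resname != "GLY") {
      pos <- rbind(pos, a1 - 1.52 * w)
      el <- c(el, "C"); nm <- c(nm, "CB"); chg <- c(chg, 0L)
    }
    rbind(atoms, data.frame(element = el, x = pos[, 1], y = pos[, 2],
                            z = pos[, 3], charge = chg, aromatic = FALSE,
                            resname = resname, resno = resno, chain = "A",
                            atom_name = nm))
  }
  # shell residues: 2 in the contact shell, the rest further out
  for (r in seq_len(pocket_size)) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    base <- lxyz[hv[sample.int(length(hv), 1)], ]
    dist <- if (r <= 2) stats::runif(1, 3.6, 4.4) else stats::runif(1, 5, 8)
    origin <- base + dist * v
    atoms <- add_residue(origin, v, res_names[sample.int(5, 1)], atoms)
  }
  if (plant_signal) {
    # anchor triad at exact offsets in the local frame of the anchor
    # substructure, so every anchor-warhead distance — and therefore every
    # interaction-fingerprint bit the anchor contributes — is identical
    # across complexes
    a_xyz <- lxyz[anchor_atoms[1:3], , drop = FALSE]
    e1 <- a_xyz[2, ] - a_xyz[1, ]; e1 <- e1 / sqrt(sum(e1^2))
    v2 <- a_xyz[3, ] - a_xyz[1, ]
    v2 <- v2 - sum(v2 * e1) * e1
    if (sum(v2^2) < 1e-6) v2 <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- v2 / sqrt(sum(v2^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    # point the triad away from the ligand bulk
    if (sum((colMeans(a_xyz) - center) * e3) < 0) e3 <- -e3
    m0 <- colMeans(a_xyz) + 3.0 * e3
    resno_anchor <- max(atoms$resno) + 1L
    # the triad carries a sulfur: no shell residue contains one, so the
    # anchor's environment identifiers cannot arise from random pocket
    # geometry
    anchor <- data.frame(
      element = c("N", "C", "O", "S"),
      x = c(m0[1], m0[1] + 1.5 * e1[1], m0[1] + 1.5 * e1[1] + 1.25 * e2[1],
            m0[1] - 1.5 * e1[1]),
      y = c(m0[2], m0[2] + 1.5 * e1[2], m0[2] + 1.5 * e1[2] + 1.25 * e2[2],
            m0[2] - 1.5 * e1[2]),
      z = c(m0[3], m0[3] + 1.5 * e1[3], m0[3] + 1.5 * e1[3] + 1.25 * e2[3],
            m0[3] - 1.5 * e1[3]),
      charge = 0L, aromatic = FALSE, resname = "ANC",
      resno = resno_anchor, chain = "A",
      atom_name = c("N", "C", "O", "SD"))
    atoms <- rbind(atoms, anchor)
  }
  receptor <- mol_graph(atoms, infer_bonds(atoms), name = "pseudo-pocket")
  pl_complex(receptor, ligand)
}

# Append the standard warhead substructure (amide C(=O)N) to a molecule;
# its atoms are the designated anchor substructure. Placed along +x from
# the attachment atom.
.attach_warhead <- function(mol) {
  at <- mol$atoms
  free_h <- implicit_h(mol)
  host <- which(at$element == "C" & free_h >= 1)
  host <- if (length(host) == 0) 1L else host[length(host)]
  base <- as.numeric(at[host, c("x", "y", "z")])
  n0 <- nrow(at)
  add <- data.frame(element = c("C", "O", "N"),
                    x = base[1] + c(1.52, 2.13, 2.20),
                    y = base[2] + c(0, 1.05, -1.10),
                    z = base[3],
                    charge = 0L, aromatic = FALSE)
  for (col in setdiff(names(at), names(add))) add[[col]] <- at[[col]][1]
  bonds <- rbind(mol$bonds,
                 data.frame(i = c(host, n0 + 1, n0 + 1),
                            j = c(n0 + 1, n0 + 2, n0 + 3),
                            order = c(1, 2, 1)))
  out <- mol_graph(rbind(at, add), bonds, name = mol$name)
  attr(out, "warhead") <- (n0 + 1):(n0 + 3)
  out
}

#' Generate a synthetic activity table
#'
#' Emits a delimited-table-shaped data.frame (`compound_id`, `smiles`,
#' `relation`, `value_nM`, `assay_kind`) realizing the composition of a
#' `fixture_spec`: biochemical-only training compounds, cellular test
#' compounds with matching biochemical potencies, binding-only
#' compounds, replicate rows with controlled dispersion, planted
#' overdispersed compounds, censored ">" inactives, "<" rows, and rows
#' with missing SMILES. The `ground_truth` attribute records per-row and
#' per-compound intent for recovery tests.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame of activity rows with `ground_truth` attribute.
#' @export
gen_activity_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(split_seed(spec$seed, "activity-table"))
  groups <- c(rep("train_active", spec$n_train_active),
              rep("train_inactive", spec$n_train_inactive),
              rep("test_active", spec$n_test_active),
              rep("test_inactive", spec$n_test_inactive),
              rep("binding_only", spec$n_binding_only),
              rep("overdispersed", spec$n_overdispersed))
  n <- length(groups)
  ids <- sprintf("CPD%05d", seq_len(n))
  sizes <- sample(spec$heavy_atoms[1]:spec$heavy_atoms[2], n, replace = TRUE)
  mols <- lapply(seq_len(n), function(k) {
    gen_molecule(split_seed(spec$seed, paste0("mol-", k)), sizes[k],
                 embed = FALSE)
  })
  smiles <- canonical_smiles(mols)
  rep_flag <- stats::runif(n) < spec$replicate_fraction
  rows <- vector("list", n)
  truth <- data.frame(compound_id = ids, group = groups,
                      true_pic50 = NA_real_, stringsAsFactors = FALSE)
  mk_rows <- function(id, smi, kind, pic50 = NULL, relation = "=",
                      value = NULL, n_rep = 1, spread = 0.1) {
    if (is.null(value)) {
      vals <- pic50_to_ic50(pic50 + (if (n_rep > 1)
        seq(-spread, spread, length.out = n_rep) else 0))
    } else {
      vals <- rep(value, n_rep)
    }
    data.frame(compound_id = id, smiles = smi, relation = relation,
               value_nM = vals, assay_kind = kind,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {
    g <- groups[k]
    nr <- if (rep_flag[k]) sample(2:3, 1) else 1
    rows[[k]] <- switch(g,
      train_active = {
        p <- stats::runif(1, 6.2, 8.5); truth$true_pic50[k] <- p
        mk_rows(ids[k], smiles[k], "biochemical", pic50 = p, n_rep = nr)
      },
      train_inactive = {
        if (stats::runif(1) < spec$gt_fraction) {
          mk_rows(ids[k], smiles[k], "biochemical", relation = ">",
                  value = 1000)
        } else {
          p <- stats::runif(1, 3.5, 5.8); truth$true_pic50[k] <- p
          mk_rows(ids[k], smiles[k], "biochemical", pic50 = p, n_rep = nr)
        }
      },
      test_active = {
        p <- stats::runif(1, 6.2, 8.0); truth$true_pic50[k] <- p
        rbind(mk_rows(ids[k], smiles[k], "cellular", pic50 = p, n_rep = nr),
              mk_rows(ids[k], smiles[k], "biochemical",
                      pic50 = p + stats::runif(1, 0, 0.8)))
      },
      test_inactive = {
        p <- stats::runif(1, 3.5, 5.9); truth$true_pic50[k] <- p
        # biochemical potency often better than cellular; labeling must
        # rely on the cellular value alone. A fully inactive study
        # (active_fraction 0) contains no active-range potency at all.
        p_bio <- p + stats::runif(1, 0.5, 2.5)
        if (spec$active_fraction == 0) p_bio <- min(p_bio, 5.95)
        rbind(mk_rows(ids[k], smiles[k], "cellular", pic50 = p),
              mk_rows(ids[k], smiles[k], "biochemical", pic50 = p_bio))
      },
      binding_only = {
        p <- stats::runif(1, 4, 8)
        mk_rows(ids[k], smiles[k], "binding", pic50 = p)
      },
      overdispersed = {
        # replicates straddling the dispersion threshold (population SD
        # of pIC50 well above 2) while staying in the inactive range
        p <- stats::runif(1, 2.8, 3.2)
        mk_rows(ids[k], smiles[k], "biochemical", pic50 = p, n_rep = 2,
                spread = 2.6)
      })
  }
  tab <- do.call(rbind, rows)
  # planted "<" rows (attached to existing kept compounds)
  if (spec$n_uncertain > 0) {
    pick <- sample(which(groups %in% c("train_active", "train_inactive")),
                   min(spec$n_uncertain, n), replace = FALSE)
    tab <- rbind(tab, data.frame(compound_id = ids[pick],
                                 smiles = smiles[pick], relation = "<",
                                 value_nM = 100, assay_kind = "biochemical",
                                 stringsAsFactors = FALSE))
  }
  # planted missing-SMILES rows
  if (spec$n_missing_smiles > 0) {
    tab <- rbind(tab, data.frame(
      compound_id = sprintf("MISS%03d", seq_len(spec$n_missing_smiles)),
      smiles = "", relation = "=", value_nM = 5000,
      assay_kind = "biochemical", stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  attr(tab, "ground_truth") <- list(
    compounds = truth,
    molecules = stats::setNames(mols, ids),
    planted = c(missing_smiles = spec$n_missing_smiles,
                uncertain = spec$n_uncertain,
                overdispersed = spec$n_overdispersed))
  tab
}

#' Generate a complete planted-signal benchmark
#'
#' Composes the full study at toy scale: training actives/inactives with
#' biochemical annotations, test actives/inactives with cellular
#' annotations, property-matched decoys, and one docked pseudo-complex
#' per molecule. Every molecule carries the same warhead substructure;
#' activity follows the planted pocket anchor except for label flips with
#' probability `(1 - signal_strength) / 2`, so interaction features (not
#' ligand topology) carry the learnable signal.
#'
#' @param spec a [fixture_spec()].
#' @return list with `train` and `test` (each: `ids`, `complexes`,
#'   `labels` 0/1, `targets` pIC50 with inactives at 2), and
#'   `ground_truth` (per-molecule signal flags and composition counts).
#' @export
gen_benchmark <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(split_seed(spec$seed, "benchmark"))
  n_tr <- spec$n_train_active + spec$n_train_inactive
  n_te <- spec$n_test_active + spec$n_test_inactive
  n_dec <- spec$n_test_active * spec$decoy_ratio
  groups <- c(rep("train_active", spec$n_train_active),
              rep("train_inactive", spec$n_train_inactive),
              rep("test_active", spec$n_test_active),
              rep("test_inactive", spec$n_test_inactive),
              rep("decoy", n_dec))
  n <- length(groups)
  n_real <- n - n_dec
  ids <- sprintf("BMK%05d", seq_len(n))
  sizes <- sample(spec$heavy_atoms[1]:spec$heavy_atoms[2], n_real,
                  replace = TRUE)
  active <- groups %in% c("train_active", "test_active")
  flip <- stats::runif(n) < (1 - spec$signal_strength) / 2
  signal <- xor(active, flip)
  targets <- ifelse(active, stats::runif(n, 6.5, 8.5), 2.0)
  base <- lapply(seq_len(n_real), function(k) {
    gen_molecule(split_seed(spec$seed, paste0("bmk-mol-", k)), sizes[k],
                 embed = TRUE)
  })
  # decoys are property-matched to the test actives
  test_active_idx <- which(groups == "test_active")
  decoys <- gen_property_matched_decoys(
    base[test_active_idx], ratio = spec$decoy_ratio,
    seed = split_seed(spec$seed, "bmk-decoys"), embed = TRUE)
  if (length(decoys) < n_dec) {
    # budget shortfall already warned about; pad with unmatched molecules
    for (k in seq_len(n_dec - length(decoys))) {
      decoys[[length(decoys) + 1]] <-
        gen_molecule(split_seed(spec$seed, paste0("bmk-pad-", k)),
                     sizes[(k - 1) %% n_real + 1], embed = TRUE)
    }
  }
  base <- c(base, decoys[seq_len(n_dec)])
  mols <- vector("list", n)
  complexes <- vector("list", n)
  for (k in seq_len(n)) {
    m <- .attach_warhead(base[[k]])
    mols[[k]] <- m
    complexes[[k]] <- gen_pocket_complex(
      split_seed(spec$seed, paste0("bmk-cpx-", k)), m,
      plant_signal = signal[k], pocket_size = spec$pocket_size,
      anchor_atoms = attr(m, "warhead"))
  }
  tr <- seq_len(n_tr)
  te <- (n_tr + 1):n
  list(
    train = list(ids = ids[tr], molecules = mols[tr],
                 complexes = complexes[tr],
                 labels = as.integer(active[tr]), targets = targets[tr]),
    test = list(ids = ids[te], molecules = mols[te],
                complexes = complexes[te],
                labels = as.integer(active[te]), targets = targets[te],
                group = groups[te]),
    ground_truth = list(groups = groups, signal = signal, flips = flip,
                        counts = c(train = n_tr, test_true = n_te,
                                   decoys = n_dec,
                                   test_total = n_te + n_dec)))
}
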