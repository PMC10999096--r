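#' @title Structure file input/output
#' @description Readers for receptors (PDB), docked ligand poses (SDF V2000,
#'   MOL2) and writers for the plain-text fixtures the package generates.
#'   Docking itself is out of scope: poses are consumed, never produced.
#' @name structure-io
NULL

# ---- SDF ------------------------------------------------------------------

# Split raw SDF text lines into per-record character vectors.
.split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0 && length(lines) > 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

# Parse one molblock record (with ChemmineR; formal charges supplemented
# from the raw "M  CHG" lines, which ChemmineR's blocks do not carry).
.parse_sdf_record <- function(rec_lines) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  body <- rec_lines[!grepl("^\\$\\$\\$\\$", rec_lines)]
  writeLines(c(body, "$$$$"), tf)
  counts <- body[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1) stop("unparsable counts line")
  if (!is.na(nbonds) && nbonds == 0) {
    # ChemmineR garbles records without a bond block; parse the atom
    # lines of this (rare, e.g. single-atom) case directly
    at_lines <- body[5:(4 + natoms)]
    atoms <- data.frame(
      element = trimws(substr(at_lines, 32, 34)),
      x = as.numeric(substr(at_lines, 1, 10)),
      y = as.numeric(substr(at_lines, 11, 20)),
      z = as.numeric(substr(at_lines, 21, 30)))
    if (any(is.na(atoms$x)) || any(!nzchar(atoms$element)))
      stop("unparsable atom block")
    bb <- NULL
  } else {
    # record-level validity is handled by the caller (skip + log); the
    # advisory from ChemmineR is muted and malformed blocks surface as
    # parse errors below
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
    sdf <- sdfset[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = el,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3])
  }
  atoms$charge <- 0L
  for (ln in grep("^M  CHG", body, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    npair <- tok[1]
    for (p in seq_len(npair)) {
      atoms$charge[tok[2 * p]] <- tok[2 * p + 1]
    }
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) NULL else
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.numeric(bb[, 3]))
  atoms$aromatic <- FALSE
  if (!is.null(bonds) && any(bonds$order == 4)) {
    arom <- unique(c(bonds$i[bonds$order == 4], bonds$j[bonds$order == 4]))
    atoms$aromatic[arom] <- TRUE
  }
  props <- if (exists("sdf", inherits = FALSE)) {
    tryCatch(ChemmineR::datablock(sdf), error = function(e) NULL)
  } else {
    # bond-free path: collect "> <field>" data items from the raw lines
    keys <- grep("^>\\s*<", body)
    if (length(keys) > 0) {
      vals <- vapply(keys, function(k) {
        if (k < length(body)) trimws(body[k + 1]) else ""
      }, character(1))
      stats::setNames(as.list(vals), sub("^>\\s*<([^>]+)>.*$", "\\1",
                                         body[keys]))
    } else NULL
  }
  score <- NULL
  if (!is.null(props) && length(props) > 0) {
    hit <- grep("score", names(props), ignore.case = TRUE)
    if (length(hit) > 0) score <- suppressWarnings(as.numeric(props[[hit[1]]]))
    if (length(score) && is.na(score)) score <- NULL
  }
  m <- mol_graph(atoms, bonds, pose_score = score,
                 name = trimws(rec_lines[1]))
  attr(m, "properties") <- props
  m
}

#' Read docked ligand poses from an SDF or MOL2 file
#'
#' One `mol_graph` per record, 3D coordinates preserved. A record-level
#' docking-score property (any SDF data field whose name contains "score")
#' populates `pose_score`. Malformed records are skipped with a warning;
#' a file with zero valid records is an error.
#'
#' @param file path to an SDF (V2000) or MOL2 file.
#' @param format `"sdf"`, `"mol2"`, or `"auto"` (by extension).
#' @return list of `mol_graph` objects.
#' @export
read_ligand_poses <- function(file, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", file, ignore.case = TRUE)) "mol2" else "sdf"
  }
  if (format == "mol2") return(.read_mol2_poses(file))
  lines <- readLines(file, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("no records in SDF file: ", file)
  }
  recs <- .split_sdf_records(lines)
  if (length(recs) > 0 && !any(grepl("^\\$\\$\\$\\$", recs[[length(recs)]]))) {
    warning("SDF file does not end in '$$$$'; parsing available prefix")
  }
  out <- list(); nbad <- 0L
  for (r in recs) {
    if (all(!nzchar(trimws(r)))) next
    m <- tryCatch(.parse_sdf_record(r), error = function(e) NULL)
    if (is.null(m)) nbad <- nbad + 1L else out[[length(out) + 1L]] <- m
  }
  if (nbad > 0) warning(sprintf("skipped %d malformed SDF record(s)", nbad))
  if (length(out) == 0) stop("no valid records in SDF file: ", file)
  out
}

# MOL2 reading through bio3d; Tripos atom types are mapped to elements by
# their leading alphabetic token ("C.3" -> "C", "N.ar" -> "N").
.read_mol2_poses <- function(file) {
  m2 <- bio3d::read.mol2(file)
  if (inherits(m2, "mol2")) m2 <- list(m2)
  lapply(m2, function(m) {
    el <- sub("\\..*$", "", m$atom$elena)
    el <- sub("[0-9]+$", "", el)
    atoms <- data.frame(element = el, x = m$atom$x, y = m$atom$y,
                        z = m$atom$z,
                        charge = as.integer(round(m$atom$charge)))
    bonds <- NULL
    if (!is.null(m$bond) && nrow(m$bond) > 0) {
      ord <- m$bond$type
      ordn <- suppressWarnings(as.numeric(ord))
      ordn[is.na(ordn)] <- 4  # "ar"/"am" etc.
      bonds <- data.frame(i = as.integer(m$bond$origin),
                          j = as.integer(m$bond$target), order = ordn)
    }
    atoms$aromatic <- FALSE
    if (!is.null(bonds) && any(bonds$order == 4)) {
      arom <- unique(c(bonds$i[bonds$order == 4], bonds$j[bonds$order == 4]))
      atoms$aromatic[arom] <- TRUE
    }
    mol_graph(atoms, bonds, name = m$name)
  })
}

# ---- PDB ------------------------------------------------------------------

#' Read a receptor chain from a PDB file
#'
#' ATOM/HETATM records of the requested chain with residue annotations.
#' Connectivity is inferred by covalent distance (see [infer_bonds()]).
#'
#' @param file path to a PDB file.
#' @param chain chain identifier (e.g. `"A"`).
#' @param keep_waters keep HOH/WAT residues? Default `TRUE` (the receptor
#'   preparation this emulates retained a handful of ordered waters).
#' @return `mol_graph` with `resname`, `resno`, `chain` atom columns.
#' @export
read_receptor <- function(file, chain, keep_waters = TRUE) {
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  avail <- sort(unique(at$chain))
  if (!chain %in% avail) {
    stop("chain '", chain, "' not present; available: ",
         paste(avail, collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  el <- at$elesy
  miss <- is.na(el) | !nzchar(el)
  # fall back to the first letter of the atom name
  el[miss] <- sub("[^A-Za-z].*$", "", at$elety[miss])
  el[miss] <- substr(el[miss], 1, 1)
  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      charge = 0L, aromatic = FALSE,
                      resname = at$resid, resno = at$resno,
                      chain = at$chain, atom_name = at$elety)
  mol_graph(atoms, infer_bonds(atoms), name = basename(file))
}

#' Clip a binding pocket around a reference ligand
#'
#' Retains whole residues having any atom within `radius` Angstrom of any
#' reference-ligand atom — a distance-based stand-in for a manually curated
#' pocket definition.
#'
#' @param receptor `mol_graph` with residue annotations.
#' @param reference_ligand `mol_graph` giving the pocket center.
#' @param radius positive radius in Angstrom.
#' @return `mol_graph` restricted to the retained residues.
#' @export
clip_pocket <- function(receptor, reference_ligand, radius) {
  stopifnot(radius > 0)
  if (is.null(receptor$atoms$resno)) stop("receptor lacks residue annotations")
  rxyz <- coords(receptor)
  lxyz <- coords(reference_ligand)
  d2 <- outer(rowSums(rxyz^2), rep(1, nrow(lxyz))) +
    outer(rep(1, nrow(rxyz)), rowSums(lxyz^2)) - 2 * rxyz %*% t(lxyz)
  near <- apply(d2, 1, min) <= radius^2 + 1e-9
  rid <- paste(receptor$atoms$chain, receptor$atoms$resno,
               receptor$atoms$resname)
  keep_res <- unique(rid[near])
  idx <- which(rid %in% keep_res)
  if (length(idx) == 0) stop("no residues within ", radius, " Angstrom of the ligand")
  subset_atoms(receptor, idx)
}

#' Assemble a protein-ligand complex
#'
#' @param receptor receptor (or clipped pocket) `mol_graph`.
#' @param ligand one docked pose `mol_graph`.
#' @param pose_score optional docking score; defaults to the ligand's.
#' @return object of class `pl_complex`.
#' @export
pl_complex <- function(receptor, ligand, pose_score = ligand$pose_score) {
  stopifnot(n_atoms(receptor) > 0, n_atoms(ligand) > 0)
  structure(list(receptor = receptor, ligand = ligand,
                 pose_score = pose_score), class = "pl_complex")
}

#' @export
print.pl_complex <- function(x, ...) {
  cat(sprintf("<pl_complex: receptor %d atoms, ligand %d atoms%s>\n",
              n_atoms(x$receptor), n_atoms(x$ligand),
              if (!is.null(x$pose_score))
                sprintf(", pose score %.3f", x$pose_score) else ""))
  invisible(x)
}

# ---- writers (plain-text fixtures) ---------------------------------------

#' Write structures to an SDF (V2000) file
#'
#' @param mols a `mol_graph` or list of them.
#' @param file output path.
#' @param properties optional named list (per molecule) of SDF data fields;
#'   a `pose_score` on the structure is written as field `docking_score`.
#' @return `file`, invisibly.
#' @export
write_sdf <- function(mols, file, properties = NULL) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    a <- m$atoms; b <- m$bonds
    writeLines(c(if (is.null(m$name)) sprintf("mol_%d", k) else m$name,
                 "  mlscreen", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b) > 0) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j,
                         as.integer(b$order)), con)
    }
    chg <- which(a$charge != 0)
    if (length(chg) > 0) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    props <- if (!is.null(properties)) properties[[k]] else NULL
    if (!is.null(m$pose_score) && is.null(props$docking_score)) {
      props$docking_score <- m$pose_score
    }
    for (nm in names(props)) {
      writeLines(c(sprintf(">  <%s>", nm), as.character(props[[nm]]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(file)
}

#' Write a receptor to a PDB file
#'
#' Minimal fixed-column ATOM serialization for fixtures (residue
#' annotations required).
#'
#' @param mol `mol_graph` with `resname`, `resno`, `chain` columns.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(mol, file) {
  a <- mol$atoms
  if (is.null(a$resno)) stop("structure lacks residue annotations")
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)),
    substr(if (!is.null(a$atom_name)) a$atom_name else
      paste0(a$element, seq_len(nrow(a))), 1, 4),
    substr(a$resname, 1, 3), a$chain, a$resno, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), file)
  invisible(file)
}
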