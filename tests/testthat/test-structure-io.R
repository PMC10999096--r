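test_that("SDF poses round-trip with coordinates, bonds, charges and score tags", {
  mols <- lapply(1:3, function(k) {
    m <- gen_molecule(k, 6 + k)
    m$name <- sprintf("pose_%d", k)
    m$pose_score <- -5 - k * 0.5
    m
  })
  tf <- tempfile(fileext = ".sdf")
  write_sdf(mols, tf)
  back <- read_ligand_poses(tf)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(coords(back[[k]]), coords(mols[[k]]), tolerance = 1e-3)
    expect_identical(back[[k]]$atoms$element, mols[[k]]$atoms$element)
    expect_identical(back[[k]]$bonds$i, mols[[k]]$bonds$i)
    expect_identical(back[[k]]$bonds$order, mols[[k]]$bonds$order)
    expect_equal(back[[k]]$pose_score, mols[[k]]$pose_score)
  }
  # bond-free (single-atom) records round-trip too
  lone <- mol_graph(data.frame(element = "C", x = 1.5, y = 2, z = 0))
  lone$pose_score <- -3
  tf1 <- tempfile(fileext = ".sdf")
  write_sdf(lone, tf1)
  back1 <- read_ligand_poses(tf1)[[1]]
  expect_equal(coords(back1), coords(lone))
  expect_equal(back1$pose_score, -3)

  # formal charges survive via M CHG lines
  ion <- mol_graph(data.frame(element = c("N", "C"), x = c(0, 1.5),
                              y = 0, z = 0,
                              charge = c(1L, 0L)),
                   data.frame(i = 1, j = 2, order = 1))
  tf2 <- tempfile(fileext = ".sdf")
  write_sdf(ion, tf2)
  expect_equal(read_ligand_poses(tf2)[[1]]$atoms$charge, c(1L, 0L))
})

test_that("malformed SDF records are skipped and empty files error", {
  good <- gen_molecule(5, 6); good$name <- "ok"
  tf <- tempfile(fileext = ".sdf")
  write_sdf(good, tf)
  lines <- readLines(tf)
  writeLines(c("broken", "junk", "not a counts line", "$$$$", lines), tf)
  expect_warning(poses <- read_ligand_poses(tf), "malformed")
  expect_length(poses, 1)

  tf_empty <- tempfile(fileext = ".sdf")
  writeLines(character(0), tf_empty)
  expect_error(read_ligand_poses(tf_empty), "no records")

  # truncated file (no terminal $$$$): parsed prefix plus warning
  writeLines(head(lines, length(lines) - 1), tf)
  expect_warning(pfx <- read_ligand_poses(tf), "\\$\\$\\$\\$")
  expect_length(pfx, 1)
})

test_that("MOL2 poses map Tripos atom types to elements", {
  mol2 <- c("@<TRIPOS>MOLECULE", "toy", " 3 2 0 0 0", "SMALL",
            "NO_CHARGES", "",
            "@<TRIPOS>ATOM",
            "1 C1 0.0 0.0 0.0 C.3 1 LIG 0.0",
            "2 N1 1.5 0.0 0.0 N.ar 1 LIG 0.0",
            "3 O1 2.6 1.0 0.0 O.2 1 LIG 0.0",
            "@<TRIPOS>BOND", "1 1 2 1", "2 2 3 2")
  tf <- tempfile(fileext = ".mol2")
  writeLines(mol2, tf)
  pose <- read_ligand_poses(tf)[[1]]
  expect_equal(pose$atoms$element, c("C", "N", "O"))
  expect_equal(pose$bonds$order, c(1, 2))
  expect_equal(coords(pose)[2, 1], 1.5)
})

test_that("receptor reading selects chains, handles waters, and errors on absent chains", {
  lig <- gen_molecule(4, 6)
  cpx <- gen_pocket_complex(9, lig, pocket_size = 6)
  rec <- cpx$receptor
  tf <- tempfile(fileext = ".pdb")
  write_pdb(rec, tf)
  back <- read_receptor(tf, "A")
  expect_equal(n_atoms(back), n_atoms(rec))
  expect_equal(coords(back), coords(rec), tolerance = 1e-3)
  expect_equal(back$atoms$resno, rec$atoms$resno)
  expect_error(read_receptor(tf, "B"), "available: A")

  # water handling flag
  wat <- rec
  wat$atoms$resname[wat$atoms$resno == 1] <- "HOH"
  write_pdb(wat, tf)
  with_w <- read_receptor(tf, "A", keep_waters = TRUE)
  no_w <- read_receptor(tf, "A", keep_waters = FALSE)
  expect_gt(n_atoms(with_w), n_atoms(no_w))
  expect_false(any(no_w$atoms$resname == "HOH"))
})

test_that("pocket clipping keeps whole residues by distance, is monotone, and matches brute force", {
  lig <- gen_molecule(17, 8)
  cpx <- gen_pocket_complex(29, lig, pocket_size = 5)
  rec <- cpx$receptor
  expect_error(clip_pocket(rec, lig, 0.1), "no residues")
  # radius covering everything is the identity
  all_in <- clip_pocket(rec, lig, 1000)
  expect_equal(n_atoms(all_in), n_atoms(rec))

  # brute-force residue selection at an intermediate radius
  radius <- 5
  d <- as.matrix(stats::dist(rbind(coords(rec), coords(lig))))
  nrec <- n_atoms(rec)
  cross <- d[seq_len(nrec), nrec + seq_len(n_atoms(lig)), drop = FALSE]
  near_res <- sort(unique(rec$atoms$resno[apply(cross, 1, min) <= radius]))
  clipped <- clip_pocket(rec, lig, radius)
  expect_equal(sort(unique(clipped$atoms$resno)), near_res)
  # monotone nesting in radius
  r_small <- clip_pocket(rec, lig, 4.2)
  expect_true(all(unique(r_small$atoms$resno) %in%
                    unique(clipped$atoms$resno) |
                    length(unique(r_small$atoms$resno)) == 0))
})

test_that("structure containers validate bonds and support permutation/transformation", {
  expect_error(mol_graph(data.frame(element = "C", x = 0, y = 0, z = 0),
                         data.frame(i = 1, j = 2, order = 1)),
               "out of range")
  expect_error(mol_graph(data.frame(element = c("C", "C"),
                                    x = c(0, 1), y = 0, z = 0),
                         data.frame(i = c(1, 2), j = c(2, 1), order = 1)),
               "duplicated")
  expect_error(mol_graph(data.frame(element = "C", x = Inf, y = 0, z = 0)),
               "non-finite")
  m <- chain_mol(4, c("C", "N", "O", "C"))
  expect_equal(implicit_h(m), c(3L, 1L, 0L, 3L))
  p <- permute_atoms(m, c(4, 3, 2, 1))
  expect_equal(p$atoms$element, rev(m$atoms$element))
  rot <- rotation_matrix(3)
  t1 <- transform_structure(m, rot, c(1, 2, 3))
  expect_equal(as.matrix(stats::dist(coords(t1))),
               as.matrix(stats::dist(coords(m))), tolerance = 1e-10)
})
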