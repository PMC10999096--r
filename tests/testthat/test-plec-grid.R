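test_that("contact detection matches a brute-force distance scan with a closed boundary", {
  lig <- mol_graph(data.frame(element = c("C", "O"),
                              x = c(0, 1.4), y = 0, z = 0),
                   data.frame(i = 1, j = 2, order = 1))
  rec <- mol_graph(data.frame(element = c("N", "C", "H"),
                              x = c(4.5, 3.0, 2.0), y = 0, z = 0,
                              resname = "GLY", resno = 1L, chain = "A"))
  cpx <- pl_complex(rec, lig)
  got <- detect_contacts(cpx, 4.5)
  # brute force over all heavy pairs
  lxyz <- coords(lig); rxyz <- coords(rec)
  expected <- 0L
  for (i in 1:2) for (j in 1:2) {  # third receptor atom is H, excluded
    if (sqrt(sum((lxyz[i, ] - rxyz[j, ])^2)) <= 4.5) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
  expect_false(any(got$protein_atom == 3))  # hydrogens excluded
  # pair at exactly the cutoff is included
  exact <- pl_complex(
    mol_graph(data.frame(element = "N", x = 4.5, y = 0, z = 0)),
    mol_graph(data.frame(element = "C", x = 0, y = 0, z = 0)))
  expect_equal(nrow(detect_contacts(exact, 4.5)), 1)
  # far ligand: no contacts
  far <- pl_complex(
    mol_graph(data.frame(element = "N", x = 20, y = 0, z = 0)),
    mol_graph(data.frame(element = "C", x = 0, y = 0, z = 0)))
  expect_equal(nrow(detect_contacts(far, 4.5)), 0)
})

test_that("PLEC has the contracted length, zero vector without contacts, and pairing conventions", {
  far <- pl_complex(
    mol_graph(data.frame(element = "N", x = 50, y = 0, z = 0)),
    mol_graph(data.frame(element = "C", x = 0, y = 0, z = 0)))
  fp <- plec_fp(far)
  expect_equal(fp$length, 4092)
  expect_true(all(fp$values == 0))

  # single-atom/single-atom contact: all ligand depths collapse to one
  # identifier and all protein depths to another, so the 12 raw
  # cross-product pairs fold onto a single distinct bit
  touch <- pl_complex(
    mol_graph(data.frame(element = "N", x = 3, y = 0, z = 0)),
    mol_graph(data.frame(element = "C", x = 0, y = 0, z = 0)))
  expect_equal(sum(plec_fp(touch)$values), 1)

  # two contacting ligand atoms, each with distinct depth-0 and depth-1
  # environments, against one isolated protein atom (one identifier at
  # every depth): 2 contacts x 2 ligand depths = 4 distinct pair bits
  lig2 <- chain_mol(2, c("C", "O"))
  cpx2 <- pl_complex(
    mol_graph(data.frame(element = "N", x = 0, y = 3, z = 0)), lig2)
  expect_equal(sum(plec_fp(cpx2)$values), 4)
  expect_equal(sum(plec_fp(cpx2, pairing = "diagonal")$values), 4)
})

test_that("PLEC and GRID are invariant to rigid rototranslation and atom order", {
  for (k in 1:6) {
    cpx <- toy_complex(k, n_heavy = 8 + k)
    rot <- rotation_matrix(k)
    moved <- rigid_transform_complex(cpx, rot, c(7, -4, k))
    expect_identical(plec_fp(cpx)$values, plec_fp(moved)$values)
    expect_identical(grid_features(cpx)$values, grid_features(moved)$values)
    perm <- sample(n_atoms(cpx$ligand))
    permuted <- pl_complex(cpx$receptor, permute_atoms(cpx$ligand, perm))
    expect_identical(plec_fp(cpx)$values, plec_fp(permuted)$values)
    expect_identical(morgan_fp(cpx$ligand)$values,
                     morgan_fp(permute_atoms(cpx$ligand, perm))$values)
  }
})

test_that("GRID vector has 2052 features with the documented block structure", {
  cpx <- toy_complex(11)
  g <- grid_features(cpx)
  expect_equal(g$length, 2052)
  expect_true(all(g$values >= 0))
  expect_true(all(g$values == round(g$values)))  # counts

  # contact-free complex: SPLIF, hbond and salt blocks are all zero
  lig <- transform_structure(cpx$ligand, diag(3), c(500, 0, 0))
  apart <- pl_complex(cpx$receptor, lig)
  g0 <- grid_features(apart)
  expect_equal(g0$length, 2052)
  expect_true(all(g0$values[513:2052] == 0))
  # the environment-count block still sees the ligand itself
  expect_gt(sum(g0$values[1:512]), 0)

  # powers control the length: 2^e + 3 * 2^s + 4
  g_small <- grid_features(cpx, ecfp_power = 4, splif_power = 3)
  expect_equal(g_small$length, 2^4 + 3 * 2^3 + 4)
})

test_that("salt bridges and hydrogen bonds are counted by the typing rules", {
  # one N+ ... O- pair at 3.0 A
  lig <- mol_graph(data.frame(element = "N", x = 0, y = 0, z = 0,
                              charge = 1L))
  rec <- mol_graph(data.frame(element = "O", x = 3, y = 0, z = 0,
                              charge = -1L, resname = "ASP", resno = 1L,
                              chain = "A"))
  g <- grid_features(pl_complex(rec, lig))
  expect_equal(g$values[2052], 1)

  # neutral pair: no salt bridge, but a donor/acceptor hydrogen bond in
  # the (2, 3] A bin (amine N-H donating to carbonyl-like O)
  lig_n <- mol_graph(data.frame(element = "N", x = 0, y = 0, z = 0))
  rec_o <- mol_graph(data.frame(element = "O", x = 2.9, y = 0, z = 0,
                                resname = "SER", resno = 1L, chain = "A"))
  g2 <- grid_features(pl_complex(rec_o, lig_n))
  expect_equal(g2$values[2052], 0)
  hbond_bins <- g2$values[2049:2051]
  expect_equal(hbond_bins, c(0, 1, 0))

  # beyond 4.0 A: no salt bridge even for charged pairs
  rec_far <- mol_graph(data.frame(element = "O", x = 4.2, y = 0, z = 0,
                                  charge = -1L, resname = "ASP",
                                  resno = 1L, chain = "A"))
  g3 <- grid_features(pl_complex(rec_far, lig))
  expect_equal(g3$values[2052], 0)
})

test_that("receptor charge assignment follows residue rules", {
  atoms <- data.frame(element = c("N", "N", "O", "O", "C"),
                      x = 1:5, y = 0, z = 0,
                      resname = c("LYS", "GLY", "ASP", "SER", "ALA"),
                      resno = 1:5, chain = "A",
                      atom_name = c("NZ", "N", "OD2", "OG", "CB"))
  rec <- assign_receptor_charges(mol_graph(atoms))
  expect_equal(rec$atoms$charge, c(1L, 0L, -1L, 0L, 0L))
})
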