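# Shared builders for tests; everything is constructed in code.

# linear alkane-like chain of n carbons, 1.54 A apart on the x axis
chain_mol <- function(n, elements = rep("C", n)) {
  atoms <- data.frame(element = elements, x = 1.54 * (seq_len(n) - 1),
                      y = 0, z = 0)
  bonds <- if (n > 1) data.frame(i = seq_len(n - 1), j = 2:n, order = 1)
  mol_graph(atoms, bonds)
}

# deterministic proper rotation matrix (orthonormal, det +1)
rotation_matrix <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform_complex <- function(cpx, rot, shift) {
  pl_complex(transform_structure(cpx$receptor, rot, shift),
             transform_structure(cpx$ligand, rot, shift),
             pose_score = cpx$pose_score)
}

# brute-force enrichment oracle: explicit sort + count
brute_force_ef <- function(scores, labels, f) {
  ord <- order(-scores, seq_along(scores))
  n_top <- max(1, floor(f * length(scores)))
  hits <- sum(labels[ord][seq_len(n_top)])
  (hits / sum(labels)) / f
}

# brute-force binary fingerprint similarity
brute_force_tanimoto <- function(a, b) {
  ia <- which(a == 1); ib <- which(b == 1)
  if (length(union(ia, ib)) == 0) return(0)
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# a small docked pseudo-complex for featurizer tests
toy_complex <- function(seed = 1, n_heavy = 10, plant_signal = TRUE) {
  lig <- gen_molecule(seed, n_heavy)
  gen_pocket_complex(seed + 1000L, lig, plant_signal = plant_signal,
                     pocket_size = 5)
}
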